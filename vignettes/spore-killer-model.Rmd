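---
title: "Modelling Spok-mediated spore killing in Podospora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Spok-mediated spore killing in Podospora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spokdrive)
```

## The biological model

*Podospora anserina* packages the products of one meiosis into four
dikaryotic ascospores.  After karyogamy the diploid zygote completes
meiosis and one post-meiotic mitosis, giving eight haploid nuclei; each
spore receives two *non-sister* mitotic nuclei, so spores come in two
genotypically identical pairs.  For a locus heteroallelic between the
parents, the spore's two nuclei are identical (homoallelic spore) when the
locus segregates at meiosis I — *first-division segregation*, FDS, no
crossover between locus and centromere — and different (heteroallelic
spore) under *second-division segregation*, SDS, when a crossover
intervenes.

A *Spok* gene is a single-gene meiotic driver: one protein carries both a
killing activity (predicted nuclease domain) and a resistance activity
(predicted kinase domain).  In a cross between a killer and a non-carrier,
every spore that inherits no copy of the killer dies; spores carrying the
killer in either nucleus are protected.  FDS of a single unopposed killer
therefore yields a two-spored ascus, SDS a four-spored one, and the
percentage of two-spored asci (the *spore-killing percentage*) estimates
the killer's FDS frequency.  *Spok3* and *Spok4* travel inside a large
mobile region (the *Spok block*) found at different chromosome arms in
different strains; the block moves as a unit and is modelled as one
indivisible locus whose allele list is its gene content.

The killer/resistance calculus is a small matrix
(`default_resistance_model()`): within *P. anserina*, *Spok2*, *Spok3* and
*Spok4* are functionally independent (each resists only itself), while
*Spok1* of *P. comata* resists all of them and kills in the presence of
*Spok2* and *Spok3*; *Spok4* resists *Spok1*.  Loss-of-function variants
are attribute overrides of an existing homolog, not new homologs: the
nuclease-dead `spok3_K240A()` keeps resistance but cannot kill, as does
the natural `spok2_strainA()` allele.

## The crossover model and its closed forms

Crossovers are laid down per centromere-anchored interval of genetic
length $\Delta d$ Morgans as a Poisson count with mean $2\Delta d$ (the
bivalent rate corresponding to $\Delta d$ Morgans per product), with no
crossover or chromatid interference and no obligate chiasma.  Because
crossovers form on intact parental chromatids, a meiotic product followed
outward from its centromere switches parental origin at each crossover
with probability $1/2$ independently of its history.  Two classical
identities follow and are enforced by the test suite:

* **SDS frequency.**  Conditioning on $k$ crossovers between centromere
  and locus, $s_k = \tfrac23\left(1 - (-\tfrac12)^k\right)$; mixing over
  the Poisson gives
  $s(d) = \tfrac23\left(1 - e^{-3d}\right)$ (`sds_probability()`),
  saturating at $2/3$ under random spindle attachment.  The inverse
  (`distance_for_fds()`) exists only for FDS frequencies above $1/3$.
* **Haldane mapping.**  The recombinant fraction between linked loci at
  distance $\Delta d$ is $r = \tfrac12(1 - e^{-2\Delta d})$.

An implementation note: exchanging distal segments between chromatids
chosen *by centromere identity* (rather than by the parental molecule
currently being read) yields the correct single-locus SDS marginal but
depresses recombination between linked loci below Haldane's function,
because exchanges between two segments of the same current origin become
no-ops.  The engine therefore swaps one uniformly chosen product currently
reading each parental haplotype, which an enumeration over chromatid
choices (in the test helpers) confirms reproduces both identities.

Penetrance $q$ is the per-spore probability that an unresisted killer
actually kills.  The default is per-spore, per-homolog independent
Bernoulli events, which generates the observed three-spored asci at rate
$2 f q (1-q)$; an ascus-level alternative (killer active or silent for the
whole ascus), which produces no three-spored asci, is available via
`penetrance_mode = "ascus"`.  Killer expression is zygote-level: a killer
acts even when every carrier also dies, which is the only convention that
reproduces the completely empty asci of same-locus mutual killers.

## Map distances

Genetic distances of the *Spok* loci are not published.  The *Spok2*
distance is the one quantity that can be calibrated: the deletion-cross
killing percentage of 40.6% (80/197 two-spored asci) pins its FDS
frequency, giving $d = $ `distance_for_fds(0.406)` $= 0.7388$ M.  The
block insertion sites (3L, the 5L block site, 5R, 4R) are assumptions,
chosen once as round FDS frequencies in the range classical killing
percentages span: FDS 0.90 at 3L and 4R, 0.75 at the 5L block site, 0.50
at 5R.  They are labelled as assumptions in `default_genetic_map()` and
never tuned; every categorical result below (interaction verdicts, the
hierarchy) is insensitive to them because verdicts depend on presence or
absence of killing, not its magnitude.  The knock-in locus (*PaPKS1*) is
centromere-tight ($d = 0$), which is what makes simulated knock-in crosses
exactly 100% two-spored at $q = 1$.

## Interaction classification and the killing hierarchy

`classify_interaction()` implements the experimental F1-backcross design:
if the direct cross shows no killing the parents are the *same type*; if
killing occurs but no F1 can be recovered from a two-spored ascus (only
empty and four-spored asci), the parents are *mutual killers* at one
locus; otherwise an F1 from a two-spored ascus is backcrossed to both
parents and selfed — killing in both backcrosses or in the self means
*mutual killing*, in neither *mutual resistance*, and against exactly one
parent *dominance* of the other parent.

Two design choices deserve comment.  First, "killing observed" is a
two-spored (or empty) ascus fraction above 5% with at least a few hundred
asci — far below the weakest real killing signals (~25%) and far above
Monte-Carlo noise; calls whose diagnostic fraction lands within 50% of
the threshold return an `"unstable"` verdict rather than a guess.  Second,
the F1 is a single nucleus (the experiments crossed monokaryons), selected
from a two-spored ascus and *homoallelic at every drive locus*, mirroring
the selection of F1 progeny homoallelic for the killing locus.  This
matters: in crosses between strains whose blocks sit at different loci,
heteroallelic survivors exist whose backcross pattern is ambiguous, while
homoallelic survivors give the clean published verdicts.  With these
choices `build_hierarchy()` on the default registry reproduces the
published structure: the three-Spok types (Psk-1, Psk-7) are mutually
resistant and dominate everything; the two-Spok types (Psk-2, Psk-5,
Psk-8) kill each other; Psk-S dominates only naive strains; and Psk-5 is
the exception that kills mutually with Psk-S (its parent lacks *Spok2*).

The apparent paradox that Psk-1 and Psk-7 kill each other in the direct
cross yet classify as mutually resistant falls out of the model: the two
blocks segregate independently, so some spores inherit neither and die,
but the F1 (carrying both blocks, or either) is resistant to both parents.

## Estimators

With a single heteroallelic killer, the ascus classes are trinomial:
$P_2 = f q^2$, $P_3 = 2 f q (1 - q)$, $P_4 = 1 - P_2 - P_3$
(`expected_ascus_distribution()`).  The maximum-likelihood estimates have
closed form
$\hat q = 2 n_2 / (2 n_2 + n_3)$,
$\hat f = (n_2 + n_3) / (N \hat q (2 - \hat q))$
(`estimate_fds_penetrance()`, or `fit_ascus_counts()` for a model object
with `coef`/`summary`/`predict`/`simulate` methods).  $\hat f$ is clipped
to $(0, 1]$ with a warning when the counts imply more FDS than is
possible.  The estimator inverts noiseless expected counts exactly and its
mean absolute bias at $N = 10^4$ is below 0.01 for both parameters.

Killing percentages exclude three-spored asci from the denominator by
default ($100\,n_2/(n_2+n_4)$), matching the published analyses; the
inclusive policy is always reported alongside since the original
denominator convention is not stated per cross.  Zero-spored asci never
enter the denominator (they are uncountable in practice).

The observed killing deficit in crosses where *Spok2* is the only
heteroallelic killer (~25% two-spored instead of ~40%) is consistent with
incomplete penetrance of *Spok2*; under the trinomial model a penetrance
near $q \approx 0.72$ reproduces a 25% exclude-3 percentage at
$f = 0.406$.  The package exposes `set_penetrance(model, Spok2 = ...)`
rather than asserting a value, since none is published.

`binomial_consistency()` is the doubled-tail exact binomial p-value
$\min(1,\, 2\min(P(X \le x), P(X \ge x)))$, used to show that the printed
knock-in counts (118/119, 343/346, 163/165, 216/217, 109/109) are each
consistent with a per-ascus killing probability of 0.99.

## Introgression and pooled progeny

`simulate_backcross_series()` models recurrent backcrossing with
per-generation ascus selection.  Two-spored selection propagates a
surviving-spore nucleus, which always carries the donor killer, so the
killer locus itself is donor-fixed after every two-spored generation —
exactly, in all replicates.  Markers *between* killer and centromere are
near-fixed but not exactly fixed under this crossover model: a double
crossover straddling the marker can restore FDS at the killer while
leaving the surviving spore heteroallelic at the marker (about 7% of
selected nuclei for a marker 0.15 M out with the killer at 0.40 M; the
tests pin this to an exact enumeration over chromatid configurations).
Real chromosomes with strong crossover interference would sit closer to
complete fixation than this interference-free model.  Unlinked markers
decay towards the recurrent parent by exactly one half per generation in
expectation.  The alternating policy (four-spored selection on odd
generations, two-spored on even ones, as in the extended backcross series)
selects the killer-carrying nucleus at four-spored generations — the
experimental scheme verified that selected spores still drive — and ends
even generations killer-fixed while eroding the linked donor tract faster.

`pooled_allele_frequency()` emulates pool-sequencing of progeny: all
nuclei of all surviving spores of the selected ascus class are pooled
(each surviving spore contributes its two nuclei, matching read-depth
expectations).  Two-spored pools are fixed for the killer parent at the
killer locus; four-spored pools sit at exactly one half everywhere, since
an intact ascus contributes all eight nuclei and every meiosis segregates
4:4.

## Sequence diversity

`windowed_pi()` re-implements the sliding-window average pairwise
nucleotide difference statistic (default 100-bp windows, 20-bp steps): a
site with any gap or N in any sequence is excluded from numerator and
denominator; a bi-allelic site with major-state frequency $\hat p$ among
$n$ sequences scores $2\hat p(1-\hat p)\,n/(n-1)$, identical to the mean
pairwise mismatch over all $\binom n2$ pairs; invariant sites score zero;
sites with more than two states are skipped by default (the statistic is
defined per bi-allelic site) or scored as corrected heterozygosity via
`multiallelic = "heterozygosity"`.  The window value averages over scored
sites by default; whether the original normalised by valid sites or window
width is not stated, so `denominator = "window_width"` brackets the
alternative.  Output coordinates are 0-based half-open, declared in the
TSV header.  `gc_content_windows()` uses 4-kb windows with 2-kb steps and
excludes N from the denominator.  `count_variable_sites()` counts columns
with at least two distinct non-gap states.

## Synthetic data

The generators (`generate_map_and_strains()`, `generate_ascus_counts()`,
`generate_alignment()`) produce every input the pipeline needs, with
ground truth attached so each analysis stage can be verified against what
was planted.  They emulate: the strain registry and marker maps; ascus
counts from the trinomial model; and alignments with controlled
bi-allelic columns, gapped columns and GC-shaped segments.  They do not
emulate linkage disequilibrium, indel structure, sequencing error, or the
internal repeat content of the Spok block, so green tests certify the
estimators and window statistics, not robustness to real-data artefacts
such as alignment error.  All generators are bit-reproducible under a
fixed seed, and the registry/alignment writers emit the same text formats
(YAML, multi-FASTA) the readers parse, so fixtures exercise the I/O layer.

## Problem sizes, numerical choices, degenerate inputs

The test suite and the acceptance script use simulation sizes chosen to
make Monte-Carlo error negligible relative to the assertions: $10^5$
tetrads per distance for the SDS and Haldane checks (binomial SE
$\approx 0.0016$), 1000 asci per cross for the 21 pairwise hierarchy
calls, 500 replicates at $N = 10^4$ for estimator calibration, and
$10^4$ replicate lineages for introgression decay.  Stochastic assertions
use 3–4 standard-error bands; model identities (knock-in killing of
exactly 100%, killer-locus fixation, four-spored pool frequency of 1/2)
are asserted exactly.  Degenerate inputs are errors, not guesses: FDS
targets at or below $1/3$, zero denominators, unidentifiable counts
($n_2 = n_3 = 0$), unknown strains, maps with tied positions, selection
schemes whose qualifying ascus class cannot occur.

One transcription ambiguity is left to the user by design: the
*P. pauciseta* strain CBS237.71 is registered with block content *Spok3*
(following the strain table) alongside an explicit `"CBS237.71-alt"`
entry carrying *Spok3* and *Spok4* (following the text); crosses with
either entry can be run and compared.

## Known limitations

* No crossover interference; real tetrad data show fewer double
  crossovers than Poisson, so linked-tract fixation in backcrosses is
  underestimated here (see above).
* Five-spored asci (used experimentally to isolate monokaryons) and
  mating-type effects are not modelled; mating type is stored but ignored.
* Fertility differences, perithecium counts and vegetative (barrage)
  phenotypes are out of scope.
* Long-term population dynamics of driver frequencies require population
  genetic modelling beyond this package's per-cross scope.
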