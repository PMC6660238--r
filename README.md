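# spokdrive

Tetrad-level simulation and analysis of **spore killing by the *Spok* gene
family** in the filamentous fungus *Podospora anserina*.

Spore killers are single-gene meiotic drivers: one protein both kills
spores that do not inherit it and protects those that do.  In *Podospora*,
seven classically defined spore-killer types (*Psk*s) turn out to be
combinations of three *Spok* genes — *Spok2* at a fixed locus, and *Spok3*
/ *Spok4* inside a large mobile "*Spok* block" found at different
chromosome arms in different strains.  This package implements that
genetic model end to end, for anyone who wants to reason quantitatively
about killer–resistance systems in ordered tetrads:

* **Meiosis at the tetrad level.**  Four chromatids per chromosome,
  Poisson crossovers without interference, meiosis I/II segregation, the
  post-meiotic mitosis, and *Podospora*'s non-sister dikaryotic spore
  packaging.  First- versus second-division segregation (FDS/SDS) follows
  the closed form `s(d) = (2/3)(1 − e^(−3d))`, and recombination between
  linked loci follows Haldane's `r = (1/2)(1 − e^(−2Δd))`; both are
  enforced against simulation in the tests.
* **The killer/resistance calculus.**  Per-homolog kill competence, a
  resistance matrix `R[killer, carried]` (identity-only within
  *P. anserina*; *Spok1* resists all, *Spok4* resists *Spok1*), per-spore
  penetrance `q` (three-spored asci arise at rate `2fq(1−q)`), and
  zygote-level killer expression (same-locus mutual killers empty their
  FDS asci).
* **Cross phenotyping and the killing hierarchy.**  The spore-killing
  percentage (`100·n2/(n2+n4)`), the F1-backcross interaction
  classification (same type / mutual killing / mutual resistance /
  dominance), and the emergent dominance hierarchy of *Psk* types.
* **Estimators.**  Closed-form trinomial MLE
  `q̂ = 2n2/(2n2+n3)`, `f̂ = (n2+n3)/(N·q̂(2−q̂))` for FDS frequency and
  penetrance from ascus counts, plus an exact two-sided binomial
  consistency check.
* **Introgression and pool-sequencing expectations.**  Recurrent
  backcrosses with two-/four-spored ascus selection and marker tracking;
  pooled allele frequencies of surviving-spore nuclei.
* **Sequence diversity.**  Sliding-window average pairwise nucleotide
  differences (100-bp windows, 20-bp steps; gap sites skipped; `n/(n−1)`
  corrected), variable-site counts, and GC content in 4-kb/2-kb windows,
  on multi-FASTA alignments.
* **Synthetic data generators** for maps, strains, ascus counts and
  alignments with planted ground truth, so the whole pipeline is testable
  offline.

## A worked example

```r
library(spokdrive)

# the reference deletion cross: Spok2 carrier x Spok2-null
cross <- simulate_cross(genotype_of("s"), genotype_of("s_dSpok2"),
                        n_asci = 10000, seed = 1)
cross
#> <cross_result> s x s_dSpok2, 10000 asci
#>   n0   n1   n2   n3   n4
#>    0    0 4061    0 5939
#>   spore-killing %: 40.6 (3-spored excluded), 40.6 (included)
```

40.6% of asci are two-spored: the *Spok2* locus is calibrated so that its
FDS frequency matches the observed 80/197 killing percentage of this
cross.  Fitting ascus counts recovers FDS frequency and penetrance:

```r
fit <- fit_ascus_counts(ascus_counts(n2 = 256, n3 = 128, n4 = 616))
fit
#> Trinomial ascus-class model (single heteroallelic killer)
#>   FDS frequency f: 0.4000
#>   penetrance q:   0.8000
```

Pairwise interactions and the hierarchy follow the F1-backcross design:

```r
classify_interaction(genotype_of("Wa58"), genotype_of("Wa100"),
                     n_asci = 1000, seed = 2)
#> <interaction_call> Wa58 x Wa100: dominance [dominant: Wa58]

build_hierarchy(list("Psk-1" = genotype_of("Wa53"),
                     "Psk-5" = genotype_of("Y"),
                     "Psk-S" = genotype_of("S"),
                     "naive" = genotype_of("Wa46")),
                n_asci = 1000, seed = 3)
#> <hierarchy_graph> 4 node(s)
#>   level 1: Psk-1
#>   level 2: Psk-5, Psk-S
#>   level 3: naive
#>   dominance: Psk-1 > Psk-5; Psk-1 > Psk-S; Psk-1 > naive; Psk-5 > naive; Psk-S > naive
#>   mutual killing: Psk-5 ~ Psk-S
```

Psk-7 (three *Spok* genes) dominates Psk-8 (which lacks *Spok3*); the
two-*Spok* type Psk-5 kills mutually with Psk-S because its parent lacks
*Spok2* — the published exception, reproduced from genotypes alone.

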