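#' Recurrent backcross scheme
#'
#' Describes a donor killer strain introgressed into a recurrent background
#' by repeated backcrossing with per-generation ascus selection:
#' `"two_spored_spore"` picks a nucleus of a surviving spore from a
#' two-spored ascus every generation (the scheme used for five-generation
#' backcrosses to the reference strain), `"four_spored_spore"` picks from a
#' four-spored ascus, and `"alternating"` alternates four-spored (odd
#' generations) with two-spored (even generations) selection, ending even
#' generations homoallelic at the killer locus (the extended
#' fourteen-generation scheme).
#'
#' @param donor,recurrent [strain_genotype()]s; the donor must carry at
#'   least one kill-capable locus absent from the recurrent parent.
#' @param generations number of backcross generations (`>= 1`).
#' @param policy selection policy.
#' @return a `backcross_scheme`.
#' @export
backcross_scheme <- function(donor, recurrent, generations,
                             policy = c("two_spored_spore",
                                        "four_spored_spore", "alternating")) {
  policy <- match.arg(policy)
  stopifnot(generations >= 1)
  donor_killers <- any(vapply(unlist(donor$alleles, recursive = FALSE),
                              function(a) isTRUE(a$kills), logical(1)))
  if (!donor_killers && policy != "four_spored_spore")
    stop("donor carries no kill-capable allele; two-spored selection ",
         "is impossible")
  structure(list(donor = donor, recurrent = recurrent,
                 generations = as.integer(generations), policy = policy),
            class = "backcross_scheme")
}

generation_policy <- function(scheme, g) {
  switch(scheme$policy,
         two_spored_spore = "two_spored",
         four_spored_spore = "four_spored",
         alternating = if (g %% 2L == 1L) "four_spored" else "two_spored")
}

# draw one selected nucleus from a lineage x recurrent cross.  Four-spored
# selection keeps the killer-carrying nucleus of the chosen spore when one
# exists: the experimental scheme verifies that selected spores still drive,
# and in a killer cross a four-spored (SDS) ascus packages one killer and
# one killer-free nucleus per spore.
select_backcross_nucleus <- function(lineage, recurrent, map, model,
                                     want = c("two_spored", "four_spored"),
                                     max_asci = 5000, generation = NA) {
  want <- match.arg(want)
  target <- if (want == "two_spored") 2L else 4L
  kl <- names(lineage$alleles)[vapply(lineage$alleles, function(al) {
    any(vapply(al, function(a) isTRUE(a$kills), logical(1)))
  }, logical(1))]
  kli <- match(kl, map$name)
  tried <- 0
  batch <- 64L
  while (tried < max_asci) {
    nb <- min(batch, max_asci - tried)
    o <- sim_meioses(map, nb)
    kb <- kill_batch(o, map, lineage, recurrent, model)
    hit <- which(rowSums(kb$alive) == target)
    if (length(hit)) {
      i <- hit[1]
      spore <- sample(which(kb$alive[i, ]), 1L)
      s1 <- 2L * (if (spore <= 2) 1L else 2L) - 1L
      carries <- vapply(c(s1, s1 + 1L), function(sl) {
        any(o[i, kli, sl] == 1L)
      }, logical(1))
      slot <- if (want == "four_spored" && xor(carries[1], carries[2])) {
        s1 + (which(carries) - 1L)
      } else s1 + sample(0:1, 1L)
      origins <- matrix(o[i, , ], ncol = 4, dimnames = list(map$name, NULL))
      return(nucleus_genotype(origins, map, lineage, recurrent, slot,
                              name = lineage$name))
    }
    tried <- tried + nb
  }
  stop(errorCondition(
    sprintf("no %s ascus in %d attempts (generation %s)", want, max_asci,
            as.character(generation)),
    class = c("selection_failed", "error", "condition")))
}

#' Simulate a recurrent-backcross introgression series
#'
#' Each generation crosses the current lineage to the recurrent parent,
#' applies killing, selects one nucleus per the scheme policy, and carries
#' parent-of-origin tags at every map locus.  With two-spored selection the
#' surviving spore always carries the donor killer, so donor alleles are
#' retained at the killer locus while the unlinked genome decays towards
#' the recurrent parent by one half per generation.
#'
#' @param scheme a [backcross_scheme()].
#' @param map a [genetic_map()]; include neutral markers
#'   (`default_genetic_map(markers = TRUE)` or [marker_grid()]) to profile
#'   tracts.
#' @param model a [resistance_model()].
#' @param n_replicates number of independent replicate lineages.
#' @param seed optional integer seed.
#' @param max_asci_per_selection attempt budget per selection step.
#' @return a `donor_profile`: data frame (locus, chromosome, arm, d,
#'   donor_freq) with the per-replicate donor indicator matrix in attribute
#'   `"replicates"`.
#' @export
simulate_backcross_series <- function(scheme, map = default_genetic_map(markers = TRUE),
                                      model = default_resistance_model(),
                                      n_replicates = 100, seed = NULL,
                                      max_asci_per_selection = 5000) {
  stopifnot(inherits(scheme, "backcross_scheme"))
  if (!is.null(seed)) set.seed(seed)
  donor <- scheme$donor
  donor$tags <- setNames(rep("donor", nrow(map)), map$name)
  recurrent <- scheme$recurrent
  recurrent$tags <- setNames(rep("recurrent", nrow(map)), map$name)
  reps <- matrix(NA, n_replicates, nrow(map),
                 dimnames = list(NULL, map$name))
  for (r in seq_len(n_replicates)) {
    lineage <- donor
    for (g in seq_len(scheme$generations)) {
      lineage <- select_backcross_nucleus(
        lineage, recurrent, map, model,
        want = generation_policy(scheme, g),
        max_asci = max_asci_per_selection, generation = g)
    }
    reps[r, ] <- lineage$tags[map$name] == "donor"
  }
  out <- data.frame(locus = map$name, chromosome = map$chromosome,
                    arm = map$arm, d = map$d,
                    donor_freq = colMeans(reps))
  attr(out, "replicates") <- reps
  attr(out, "scheme") <- scheme[c("generations", "policy")]
  class(out) <- c("donor_profile", "data.frame")
  out
}

#' Expected pooled allele frequencies in selected ascus classes
#'
#' Emulates pool-sequencing of progeny: simulate a cross, keep asci of the
#' selected class (two- or four-spored), pool every nucleus of every
#' surviving spore (each surviving spore contributes its two nuclei,
#' matching read-depth expectations), and report the per-locus frequency of
#' the `p1`-origin allele.  In a killer x killer-lacking cross the
#' two-spored pool is fixed for the killer parent at the killer locus,
#' while four-spored asci are fully heterozygous (frequency 1/2 at every
#' locus, exactly, by the 4:4 segregation of each meiosis).
#'
#' @param p1,p2 parental genotypes.
#' @param map,model as in [simulate_cross()].
#' @param ascus_selection `"two_spored"` or `"four_spored"`.
#' @param n_asci number of asci to simulate.
#' @param seed optional integer seed.
#' @return data frame (locus, chromosome, arm, d, freq_p1, n_nuclei) with
#'   the number of selected asci in attribute `"n_selected"`.
#' @export
pooled_allele_frequency <- function(p1, p2, map = default_genetic_map(markers = TRUE),
                                    model = default_resistance_model(),
                                    ascus_selection = c("two_spored",
                                                        "four_spored"),
                                    n_asci = 2000, seed = NULL) {
  ascus_selection <- match.arg(ascus_selection)
  target <- if (ascus_selection == "two_spored") 2L else 4L
  if (!is.null(seed)) set.seed(seed)
  o <- sim_meioses(map, n_asci)
  kb <- kill_batch(o, map, p1, p2, model)
  sel <- rowSums(kb$alive) == target
  if (!any(sel))
    stop("no ", ascus_selection, " asci among ", n_asci, " simulated")
  L <- nrow(map)
  donor_count <- numeric(L)
  total <- 0
  for (p in 1:2) {
    # surviving spores in pair p (0, 1 or 2), each contributing two nuclei
    a_p <- rowSums(kb$alive[, c(2 * p - 1, 2 * p), drop = FALSE])[sel]
    o1 <- matrix(o[sel, , 2 * p - 1], ncol = L)
    o2 <- matrix(o[sel, , 2 * p], ncol = L)
    donor_count <- donor_count +
      colSums(a_p * ((o1 == 1) + (o2 == 1)))
    total <- total + 2 * sum(a_p)
  }
  data.frame(locus = map$name, chromosome = map$chromosome, arm = map$arm,
             d = map$d, freq_p1 = donor_count / total,
             n_nuclei = total) -> out
  attr(out, "n_selected") <- sum(sel)
  out
}
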