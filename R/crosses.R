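#' Simulate a cross and tabulate ascus classes
#'
#' Draws `n_asci` independent meioses, applies the killer/resistance
#' calculus, and tabulates the 0- to 4-spored classes.  The spore-killing
#' percentage is reported under two denominator policies: the default
#' excludes three-spored asci (`100 n2 / (n2 + n4)`), mirroring their
#' exclusion from the published analyses; the alternative includes them
#' (`100 n2 / (n2 + n3 + n4)`).  Empty (0-spored) asci are never part of
#' the denominator.
#'
#' @param p1,p2 parental [strain_genotype()]s.
#' @param map a [genetic_map()].
#' @param model a [resistance_model()].
#' @param n_asci number of asci to simulate (`>= 1`).
#' @param seed optional integer seed.
#' @param penetrance_mode `"spore"` or `"ascus"`; see [apply_killing()].
#' @return a `cross_result` with counts `n0..n4`, `n`, `killing_pct`
#'   (exclude-3 policy) and `killing_pct_include3`.
#' @export
simulate_cross <- function(p1, p2, map = default_genetic_map(),
                           model = default_resistance_model(),
                           n_asci = 1000, seed = NULL,
                           penetrance_mode = c("spore", "ascus")) {
  if (n_asci < 1) stop("n_asci must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  o <- sim_meioses(map, n_asci)
  kb <- kill_batch(o, map, p1, p2, model,
                   penetrance_mode = match.arg(penetrance_mode))
  n_alive <- rowSums(kb$alive)
  counts <- tabulate(n_alive + 1L, nbins = 5L)
  names(counts) <- paste0("n", 0:4)
  den2 <- counts["n2"] + counts["n4"]
  den3 <- counts["n2"] + counts["n3"] + counts["n4"]
  structure(list(
    counts = counts, n = n_asci,
    killing_pct = if (den2 > 0) unname(100 * counts["n2"] / den2) else NA_real_,
    killing_pct_include3 = if (den3 > 0) unname(100 * counts["n2"] / den3)
                           else NA_real_,
    parents = c(p1$name, p2$name), seed = seed),
    class = "cross_result")
}

#' @export
print.cross_result <- function(x, ...) {
  cat(sprintf("<cross_result> %s x %s, %d asci\n", x$parents[1],
              x$parents[2], x$n))
  print(x$counts)
  cat(sprintf("  spore-killing %%: %.1f (3-spored excluded), %.1f (included)\n",
              x$killing_pct, x$killing_pct_include3))
  invisible(x)
}

#' Expected ascus-class distribution for a single heteroallelic killer
#'
#' With FDS frequency `f` and per-spore penetrance `q`, killer-lacking
#' spores arise only in FDS asci and only as a duplicate pair, so
#' `P2 = f q^2`, `P3 = 2 f q (1 - q)` and `P4 = 1 - P2 - P3`.
#'
#' @param f FDS probability in `[0, 1]`.
#' @param q penetrance in `[0, 1]`.
#' @return named numeric vector `c(P2, P3, P4)`.
#' @export
expected_ascus_distribution <- function(f, q) {
  if (f < 0 || f > 1 || q < 0 || q > 1)
    stop("f and q must lie in [0, 1]")
  p2 <- f * q^2
  p3 <- 2 * f * q * (1 - q)
  c(P2 = p2, P3 = p3, P4 = 1 - p2 - p3)
}

#' Select an F1 nucleus from a two-spored ascus
#'
#' Reproduces the experimental selection step: simulate asci from the
#' direct cross until one is two-spored, then take one nucleus of a
#' surviving spore as the (monokaryotic) F1.  By default a spore that is
#' homoallelic at every drive locus is preferred -- the analogue of
#' selecting F1 progeny homoallelic for the killing locus; if only
#' heteroallelic survivors are found, one is returned with attribute
#' `heteroallelic = TRUE`.
#'
#' @param p1,p2 parental genotypes.
#' @param map,model as in [simulate_cross()].
#' @param max_asci attempt budget.
#' @param prefer_homoallelic prefer spores homoallelic at all drive loci.
#' @param seed optional integer seed.
#' @return a [strain_genotype()] named `"F1(p1 x p2)"`, with per-locus
#'   parent-of-origin tags.  If no qualifying ascus arises within
#'   `max_asci`, an error of condition class `"no_f1_available"` is
#'   signalled (the classifier interprets it as mutual killing when empty
#'   asci are seen).
#' @export
select_f1_from_two_spored <- function(p1, p2, map = default_genetic_map(),
                                      model = default_resistance_model(),
                                      max_asci = 20000,
                                      prefer_homoallelic = TRUE,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dl <- drive_loci(p1, p2, map)
  dli <- match(dl, map$name)
  tables <- NULL
  fallback <- NULL
  tried <- 0
  batch <- 256L
  while (tried < max_asci) {
    nb <- min(batch, max_asci - tried)
    o <- sim_meioses(map, nb)
    kb <- kill_batch(o, map, p1, p2, model, tables = tables)
    tables <- kb$tables
    two <- which(rowSums(kb$alive) == 2L)
    for (i in two) {
      spore <- which(kb$alive[i, ])[1]
      pair <- if (spore <= 2) 1L else 2L
      s1 <- 2L * pair - 1L
      homo <- all(o[i, dli, s1] == o[i, dli, s1 + 1L])
      origins <- matrix(o[i, , ], ncol = 4, dimnames = list(map$name, NULL))
      g <- nucleus_genotype(origins, map, p1, p2, s1,
                            name = sprintf("F1(%s x %s)", p1$name, p2$name))
      attr(g, "heteroallelic") <- !homo
      if (homo || !prefer_homoallelic) return(g)
      if (is.null(fallback)) fallback <- g
    }
    tried <- tried + nb
  }
  if (!is.null(fallback)) return(fallback)
  stop(errorCondition(
    sprintf("no two-spored ascus with a qualifying spore in %d asci of %s x %s",
            max_asci, p1$name, p2$name),
    class = c("no_f1_available", "error", "condition")))
}

killing_observed <- function(cr, threshold) {
  frac2 <- cr$counts["n2"] / cr$n
  frac0 <- cr$counts["n0"] / cr$n
  unname(frac2 > threshold | frac0 > threshold)
}

borderline <- function(cr, threshold) {
  m <- max(cr$counts["n2"], cr$counts["n0"]) / cr$n
  m > 0.5 * threshold && m < 1.5 * threshold
}

#' Classify a pairwise killer interaction by the F1-backcross design
#'
#' Implements the experimental decision tree: (a) a direct cross with no
#' killing signal means the parents are the same killer type; (b) if
#' killing occurs but no F1 can be recovered from a two-spored ascus (only
#' empty or four-spored asci), the parents are mutual killers at one locus;
#' (c) otherwise an F1 from a two-spored ascus is backcrossed to both
#' parents and selfed -- killing in both backcrosses or in the self means
#' mutual killing, killing in neither means mutual resistance, and killing
#' against exactly one parent (none in the self) means the other parent is
#' dominant.  "Killing observed" means the two-spored (or empty) fraction
#' exceeds `threshold` (default 5%, far below real killing signals and
#' above Monte-Carlo noise at `n_asci >= 200`).  If any diagnostic
#' fraction falls within 50% of the threshold the verdict is `"unstable"`
#' and the evidence is attached.
#'
#' @param p1,p2 parental genotypes.
#' @param map,model as in [simulate_cross()].
#' @param n_asci asci per simulated cross.
#' @param seed optional integer seed.
#' @param threshold killing-detection threshold (fraction of asci).
#' @return an `interaction_call` with fields `verdict` (one of
#'   `same_type`, `mutual_killing`, `mutual_resistance`, `dominance`,
#'   `unstable`), `dominant` (strain name, for dominance) and `evidence`
#'   (the underlying `cross_result`s).
#' @export
classify_interaction <- function(p1, p2, map = default_genetic_map(),
                                 model = default_resistance_model(),
                                 n_asci = 1000, seed = NULL,
                                 threshold = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  direct <- simulate_cross(p1, p2, map, model, n_asci)
  ev <- list(direct = direct)
  call_out <- function(verdict, dominant = NA_character_, unstable = FALSE) {
    structure(list(verdict = if (unstable) "unstable" else verdict,
                   proposed = verdict, dominant = dominant,
                   parents = c(p1$name, p2$name), evidence = ev),
              class = "interaction_call")
  }
  if (!killing_observed(direct, threshold))
    return(call_out("same_type", unstable = borderline(direct, threshold)))
  f1 <- tryCatch(
    select_f1_from_two_spored(p1, p2, map, model),
    no_f1_available = function(e) NULL)
  if (is.null(f1))
    return(call_out("mutual_killing", unstable = borderline(direct, threshold)))
  ev$f1 <- f1
  ev$backcross_p1 <- simulate_cross(f1, p1, map, model, n_asci)
  ev$backcross_p2 <- simulate_cross(f1, p2, map, model, n_asci)
  ev$f1_self <- simulate_cross(f1, f1, map, model, n_asci)
  k1 <- killing_observed(ev$backcross_p1, threshold)
  k2 <- killing_observed(ev$backcross_p2, threshold)
  ks <- killing_observed(ev$f1_self, threshold)
  unstable <- any(vapply(ev[c("backcross_p1", "backcross_p2", "f1_self")],
                         borderline, logical(1), threshold))
  if (ks || (k1 && k2)) return(call_out("mutual_killing", unstable = unstable))
  if (!k1 && !k2) return(call_out("mutual_resistance", unstable = unstable))
  # killing against exactly one parent: the unkilled parent is dominant
  call_out("dominance", dominant = if (k1) p2$name else p1$name,
           unstable = unstable)
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s x %s: %s", x$parents[1], x$parents[2],
              x$verdict))
  if (x$verdict == "unstable") cat(sprintf(" (proposed: %s)", x$proposed))
  if (!is.na(x$dominant)) cat(sprintf(" [dominant: %s]", x$dominant))
  cat("\n")
  invisible(x)
}
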