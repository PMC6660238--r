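# Precompute, for one cross, the killer homologs expressed by the zygote
# and per-parent, per-locus resistance indicators.  Killer expression is
# zygote-level: a killer contributed by either parent acts on every
# sensitive spore of the ascus, even if all carriers die too (mutual
# killing can empty an ascus).
cross_kill_tables <- function(p1, p2, map, model) {
  parents <- list(p1, p2)
  killers <- character(0)
  for (pr in parents) for (al in pr$alleles) for (a in al)
    if (a$kills && model_kill_capable(model, a$homolog))
      killers <- c(killers, a$homolog)
  killers <- sort(unique(killers))
  # restrict to loci carrying alleles in either parent: null loci and
  # neutral markers can neither kill nor protect
  act <- drive_loci(p1, p2, map)
  res <- array(FALSE, dim = c(length(act), 2L, length(killers)),
               dimnames = list(act, NULL, killers))
  for (li in seq_along(act)) for (pi in 1:2) {
    al <- alleles_at(parents[[pi]], act[li])
    for (h in killers)
      res[li, pi, h] <- alleles_resist(al, h, model)
  }
  q <- vapply(killers, function(h) model_penetrance(model, h), numeric(1))
  list(killers = killers, loci = act, res = res, q = q)
}

# Batch killing: origins (n, L, 4) from sim_meioses, returns n x 4 logical
# matrix of spore survival (columns = spores; 1-2 and 3-4 are the duplicate
# pairs) plus the per-pair survival probabilities.
kill_batch <- function(origins, map, p1, p2, model,
                       penetrance_mode = c("spore", "ascus"),
                       tables = NULL) {
  penetrance_mode <- match.arg(penetrance_mode)
  n <- dim(origins)[1]
  if (is.null(tables)) tables <- cross_kill_tables(p1, p2, map, model)
  kl <- tables$killers
  alive <- matrix(TRUE, n, 4)
  if (!length(kl)) return(list(alive = alive, tables = tables))
  li <- match(tables$loci, map$name)
  # resistance of each spore pair to each killer
  resist <- array(FALSE, dim = c(n, 2L, length(kl)))
  for (p in 1:2) {
    o1 <- origins[, li, 2 * p - 1, drop = FALSE]
    o2 <- origins[, li, 2 * p, drop = FALSE]
    dim(o1) <- dim(o2) <- c(n, length(li))
    for (hi in seq_along(kl)) {
      r <- matrix(FALSE, n, 1)
      for (j in seq_along(li)) {
        r <- r | (tables$res[j, 1, hi] & (o1[, j] == 1 | o2[, j] == 1)) |
                 (tables$res[j, 2, hi] & (o1[, j] == 2 | o2[, j] == 2))
      }
      resist[, p, hi] <- r
    }
  }
  if (penetrance_mode == "spore") {
    # per-spore, per-homolog independent Bernoulli kill events
    for (p in 1:2) {
      surv <- rep(1, n)
      for (hi in seq_along(kl))
        surv <- surv * ifelse(resist[, p, hi], 1, 1 - tables$q[hi])
      alive[, 2 * p - 1] <- runif(n) < surv
      alive[, 2 * p]     <- runif(n) < surv
    }
  } else {
    # ascus-level penetrance: a killer is either active in the whole ascus
    # (probability q) or silent
    active <- matrix(runif(n * length(kl)), n) <
      matrix(tables$q, n, length(kl), byrow = TRUE)
    for (p in 1:2) {
      killed <- rep(FALSE, n)
      for (hi in seq_along(kl))
        killed <- killed | (active[, hi] & !resist[, p, hi])
      alive[, 2 * p - 1] <- !killed
      alive[, 2 * p]     <- !killed
    }
  }
  list(alive = alive, tables = tables)
}

#' Apply the killer/resistance calculus to an ascus
#'
#' Every kill-capable homolog present in the zygote (either parent) acts on
#' each spore that carries no protecting allele in either of its nuclei;
#' an unresisted killer kills the spore with its penetrance `q`,
#' independently across homologs and spores (the default; an ascus-level
#' penetrance mode, in which a killer is active or silent for the whole
#' ascus, is available as a switch).  Killer expression is zygote-level, so
#' two unresisted killers at one locus abort all four spores (empty asci).
#'
#' @param ascus an `ascus` from [simulate_tetrad()].
#' @param model a [resistance_model()].
#' @param penetrance_mode `"spore"` (default) or `"ascus"`.
#' @param seed optional integer seed.
#' @return a `killed_ascus`: the ascus plus `fates` (`"alive"`/`"dead"` per
#'   spore), `n_alive` and `class` (0- to 4-spored).
#' @export
apply_killing <- function(ascus, model = default_resistance_model(),
                          penetrance_mode = c("spore", "ascus"),
                          seed = NULL) {
  stopifnot(inherits(ascus, "ascus"))
  if (!is.null(seed)) set.seed(seed)
  origins <- array(ascus$origins, dim = c(1, nrow(ascus$origins), 4))
  kb <- kill_batch(origins, ascus$map, ascus$parents[[1]],
                   ascus$parents[[2]], model,
                   penetrance_mode = match.arg(penetrance_mode))
  fates <- ifelse(kb$alive[1, ], "alive", "dead")
  out <- ascus
  out$fates <- fates
  out$n_alive <- sum(kb$alive[1, ])
  out$class <- out$n_alive
  class(out) <- c("killed_ascus", "ascus")
  out
}

#' @export
print.killed_ascus <- function(x, ...) {
  cat(sprintf("<killed_ascus> %d-spored (%s)\n", x$n_alive,
              paste(x$fates, collapse = ", ")))
  invisible(x)
}

#' Ascus class (number of surviving spores)
#'
#' @param k a `killed_ascus` from [apply_killing()].
#' @return integer in 0..4.
#' @export
ascus_class <- function(k) {
  if (!inherits(k, "killed_ascus") || is.null(k$fates))
    stop("spore fates are not resolved; run apply_killing() first")
  k$n_alive
}
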