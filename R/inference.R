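#' Ascus count data
#'
#' Counts of two-, three- and four-spored asci from one cross.  Empty
#' (0-spored) asci are not tabulated: they are uncountable in practice and
#' never enter published percentages.
#'
#' @param n2,n3,n4 non-negative counts.  Non-integer values are accepted so
#'   that noiseless expected counts can be fed to the estimators.
#' @return an `ascus_counts` object with total `N`.
#' @export
ascus_counts <- function(n2, n3 = 0, n4 = 0) {
  stopifnot(n2 >= 0, n3 >= 0, n4 >= 0)
  N <- n2 + n3 + n4
  if (N < 1) stop("at least one ascus is required")
  structure(list(n2 = as.numeric(n2), n3 = as.numeric(n3),
                 n4 = as.numeric(n4), N = as.numeric(N)),
            class = "ascus_counts")
}

#' @export
print.ascus_counts <- function(x, ...) {
  cat(sprintf("<ascus_counts> n2=%g n3=%g n4=%g (N=%g)\n",
              x$n2, x$n3, x$n4, x$N))
  invisible(x)
}

#' @export
as.data.frame.ascus_counts <- function(x, ...) {
  data.frame(n2 = x$n2, n3 = x$n3, n4 = x$n4, N = x$N)
}

#' Spore-killing percentage from ascus counts
#'
#' `exclude3` (the default, matching the published analyses) is
#' `100 n2 / (n2 + n4)`; `include3` is `100 n2 / (n2 + n3 + n4)`.
#'
#' @param counts an [ascus_counts()] object (or a `cross_result`).
#' @param policy denominator policy.
#' @param round round to one decimal, the reporting precision used for
#'   killing percentages; the raw value is kept in attribute `"raw"`.
#' @return percentage in `[0, 100]`.
#' @export
killing_percentage <- function(counts, policy = c("exclude3", "include3"),
                               round = FALSE) {
  policy <- match.arg(policy)
  if (inherits(counts, "cross_result"))
    counts <- ascus_counts(counts$counts["n2"], counts$counts["n3"],
                           counts$counts["n4"])
  stopifnot(inherits(counts, "ascus_counts"))
  den <- switch(policy, exclude3 = counts$n2 + counts$n4, include3 = counts$N)
  if (den == 0) stop("zero denominator under policy '", policy, "'")
  raw <- 100 * counts$n2 / den
  if (round) structure(round(raw, 1), raw = raw) else raw
}

#' Closed-form trinomial MLE of FDS frequency and penetrance
#'
#' Under the single-killer model the ascus classes are trinomial with
#' `P2 = f q^2`, `P3 = 2 f q (1 - q)` (see
#' [expected_ascus_distribution()]); the maximum-likelihood estimates have
#' the closed form `q_hat = 2 n2 / (2 n2 + n3)` and
#' `f_hat = (n2 + n3) / (N q_hat (2 - q_hat))`.  `f_hat` is clipped to
#' `(0, 1]` with a warning when the data imply `f > 1`.
#'
#' @param counts an [ascus_counts()] object.
#' @return named vector `c(f = f_hat, q = q_hat)`.
#' @seealso [fit_ascus_counts()] for the full model-object interface.
#' @export
estimate_fds_penetrance <- function(counts) {
  stopifnot(inherits(counts, "ascus_counts"))
  if (counts$n2 + counts$n3 == 0)
    stop("f and q are unidentifiable when no 2- or 3-spored asci are observed")
  q <- 2 * counts$n2 / (2 * counts$n2 + counts$n3)
  f <- if (q > 0) (counts$n2 + counts$n3) / (counts$N * q * (2 - q)) else Inf
  if (f > 1) {
    warning("counts imply FDS frequency > 1 (f_hat = ", signif(f, 4),
            "); clipping to 1")
    f <- 1
  }
  c(f = f, q = q)
}

#' Fit the trinomial ascus-class model
#'
#' Wraps [estimate_fds_penetrance()] into a fitted-model object with the
#' usual methods (`print`, `coef`, `summary`, `predict`, `simulate`,
#' `logLik`).
#'
#' @param counts an [ascus_counts()] object.
#' @return an object of class `fds_fit`.
#' @export
fit_ascus_counts <- function(counts) {
  est <- estimate_fds_penetrance(counts)
  p <- expected_ascus_distribution(est["f"], est["q"])
  x <- c(counts$n2, counts$n3, counts$n4)
  ll <- if (all(abs(x - round(x)) < 1e-9))
    stats::dmultinom(round(x), prob = pmax(p, 1e-300), log = TRUE)
  else NA_real_
  structure(list(coefficients = est, counts = counts, prob = p,
                 logLik = ll),
            class = "fds_fit")
}

#' @export
print.fds_fit <- function(x, ...) {
  cat("Trinomial ascus-class model (single heteroallelic killer)\n")
  cat(sprintf("  FDS frequency f: %.4f\n  penetrance q:   %.4f\n",
              x$coefficients["f"], x$coefficients["q"]))
  invisible(x)
}

#' @export
coef.fds_fit <- function(object, ...) object$coefficients

#' @export
logLik.fds_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$counts$N, class = "logLik")
}

#' @export
summary.fds_fit <- function(object, ...) {
  cts <- object$counts
  expected <- object$prob * cts$N
  out <- list(coefficients = object$coefficients,
              table = data.frame(class = c("2-spored", "3-spored", "4-spored"),
                                 observed = c(cts$n2, cts$n3, cts$n4),
                                 expected = unname(expected)),
              logLik = object$logLik)
  class(out) <- "summary.fds_fit"
  out
}

#' @export
print.summary.fds_fit <- function(x, ...) {
  cat("Trinomial ascus-class model\n")
  cat(sprintf("  f_hat = %.4f, q_hat = %.4f, logLik = %.2f\n",
              x$coefficients["f"], x$coefficients["q"], x$logLik))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.fds_fit <- function(object, N = object$counts$N,
                            type = c("probability", "counts"), ...) {
  type <- match.arg(type)
  if (type == "probability") object$prob else object$prob * N
}

#' @export
simulate.fds_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- object$coefficients
  lapply(seq_len(nsim), function(i)
    generate_ascus_counts(est["f"], est["q"], object$counts$N))
}

#' Exact two-sided binomial consistency check
#'
#' Doubled-tail exact binomial p-value of observing `n2` successes in `N`
#' trials under success probability `p_model`:
#' `min(1, 2 min(P(X <= n2), P(X >= n2)))`.  Used to reconcile simulated
#' expectations with printed ascus counts (e.g. 118/119 against a
#' near-complete killing probability).  Degenerate `p_model` of 0 or 1 is
#' handled analytically: probability 1 iff the counts match exactly.
#'
#' @param n2 observed count, `0 <= n2 <= N`.
#' @param N number of trials.
#' @param p_model model success probability in `[0, 1]`.
#' @return two-sided exact p-value.
#' @export
binomial_consistency <- function(n2, N, p_model) {
  stopifnot(n2 >= 0, n2 <= N, N >= 1, p_model >= 0, p_model <= 1)
  if (p_model == 0) return(as.numeric(n2 == 0))
  if (p_model == 1) return(as.numeric(n2 == N))
  lower <- pbinom(n2, N, p_model)
  upper <- pbinom(n2 - 1, N, p_model, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
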