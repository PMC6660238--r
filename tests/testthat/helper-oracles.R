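# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the chromatid bookkeeping is done by explicit
# enumeration over the 6 possible origin configurations, and the diversity
# statistic by brute force over all sequence pairs.

# The four meiotic products are 1,2 (sisters attached to the homolog-1
# centromere) and 3,4 (homolog-2 centromere).  A state is the set of two
# products currently reading homolog-1 (donor) sequence distal to the
# current position.  A crossover involves one chromatid of each parental
# molecule; followed along the products, it swaps a uniformly chosen
# donor-reading product with a uniformly chosen recurrent-reading one (so
# every crossover changes the state, and a product toggles origin with
# probability 1/2 independently of history).
chromatid_states <- combn(4, 2, simplify = FALSE)

chromatid_transition <- function() {
  T <- matrix(0, 6, 6)
  for (si in 1:6) {
    s <- chromatid_states[[si]]
    comp <- setdiff(1:4, s)
    for (a in s) for (b in comp) {
      s2 <- c(setdiff(s, a), b)
      ti <- state_index(s2)
      T[si, ti] <- T[si, ti] + 0.25
    }
  }
  T
}

# distribution over states after Poisson(2 * d) crossovers, starting from p0
pois_mix_states <- function(p0, d, kmax = NULL) {
  T <- chromatid_transition()
  lambda <- 2 * d
  if (is.null(kmax)) kmax <- max(20, ceiling(lambda + 12 * sqrt(lambda + 1)))
  p <- p0 * stats::dpois(0, lambda)
  pk <- p0
  for (k in seq_len(kmax)) {
    pk <- pk %*% T
    p <- p + pk * stats::dpois(k, lambda)
  }
  p
}

state_index <- function(s) {
  which(vapply(chromatid_states, function(x) setequal(x, s), logical(1)))
}

# SDS probability at distance d by enumeration over chromatid choices
oracle_sds <- function(d) {
  p0 <- rep(0, 6); p0[state_index(c(1, 2))] <- 1
  p <- pois_mix_states(p0, d)
  fds <- p[state_index(c(1, 2))] + p[state_index(c(3, 4))]
  1 - fds
}

# Donor-allele frequency among single nuclei selected from surviving spores
# of two-spored asci, at a marker `a` Morgans from the centromere with the
# killer `a + b` Morgans out (q = 1, single killer from parent 1).
# Two-spored <=> killer locus FDS; the surviving sister pair is the one
# whose chromatids both carry the donor segment at the killer.
oracle_linked_donor_freq <- function(a, b) {
  p0 <- rep(0, 6); p0[state_index(c(1, 2))] <- 1
  # joint over (state at marker, state at killer)
  pk_cond <- function(sm_idx) {
    p0k <- rep(0, 6); p0k[sm_idx] <- 1
    pois_mix_states(p0k, b)
  }
  p_marker <- pois_mix_states(p0, a)
  num <- 0; den <- 0
  for (sm in 1:6) {
    if (p_marker[sm] == 0) next
    pk <- pk_cond(sm)
    for (pole in list(c(1, 2), c(3, 4))) {
      psel <- pk[state_index(pole)]        # killer FDS with this pair donor
      if (psel == 0) next
      w <- p_marker[sm] * psel
      donor_at_m <- length(intersect(chromatid_states[[sm]], pole)) / 2
      num <- num + w * donor_at_m
      den <- den + w
    }
  }
  num / den
}

# Brute-force windowed average pairwise differences: mean over all sequence
# pairs of per-site mismatch indicators, gap (- or N) sites removed, scaled
# by n/(n-1), averaged over scored sites per window.
bf_windowed_pi <- function(aln, window, step, biallelic_only = FALSE) {
  n <- nrow(aln); L <- ncol(aln)
  persite <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    col <- aln[, j]
    if (any(col %in% c("-", "N"))) next
    if (biallelic_only && length(unique(col)) > 2) next
    mism <- 0; npair <- 0
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      mism <- mism + (col[x] != col[y]); npair <- npair + 1
    }
    persite[j] <- (mism / npair) * 1  # mean pairwise difference per site
  }
  starts <- if (L < window) 0L else seq(0L, L - window, by = step)
  vals <- numeric(length(starts)); nv <- integer(length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):min(starts[i] + window, L)
    v <- persite[idx]
    nv[i] <- sum(!is.na(v))
    vals[i] <- if (nv[i] > 0) mean(v, na.rm = TRUE) else NA_real_
  }
  list(start = starts, value = vals, n_valid = nv)
}

random_alignment <- function(n, L, alphabet = c("A", "C", "G", "T", "-")) {
  matrix(sample(alphabet, n * L, replace = TRUE,
                prob = c(rep(0.23, 4), 0.08)[seq_along(alphabet)]),
         nrow = n, dimnames = list(paste0("s", 1:n), NULL))
}

# convenience: registry genotypes on the default map
psk_set <- function() {
  list("Psk-1" = genotype_of("Wa53"), "Psk-7" = genotype_of("Wa58"),
       "Psk-2" = genotype_of("Wa28"), "Psk-5" = genotype_of("Y"),
       "Psk-8" = genotype_of("Wa100"), "Psk-S" = genotype_of("S"),
       "naive" = genotype_of("Wa46"))
}
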