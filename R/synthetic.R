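#' Synthetic map and strain set
#'
#' Generates every input the pipeline needs without external data.  The
#' default specification reproduces the canonical setting: a
#' seven-chromosome map with the Spok2 locus calibrated to the observed
#' ~40.6% killing, the four Spok-block insertion sites at their assumed
#' distances, neutral markers on a regular grid, and the transcribed
#' strain registry.
#'
#' @param spec list with elements `n_chrom`, `arm_length` (Morgans),
#'   `marker_spacing` (Morgans; `NA` for no markers), `killers` (optional
#'   data frame of extra loci: name, chromosome, arm, d) -- all optional.
#' @return `list(map, strains)`.
#' @export
generate_map_and_strains <- function(spec = list()) {
  spec <- modifyList(list(n_chrom = 7, arm_length = 1, marker_spacing = 0.1,
                          killers = NULL, use_registry = TRUE), spec)
  if (spec$arm_length <= 0) stop("arm length must be positive")
  if (spec$use_registry) {
    base <- as.data.frame(default_genetic_map())[,
      c("name", "chromosome", "arm", "d")]
    strains <- default_strain_registry()
  } else {
    base <- NULL
    strains <- list()
  }
  if (!is.null(spec$killers)) base <- rbind(base, spec$killers)
  loci <- base
  if (!is.na(spec$marker_spacing)) {
    loci <- rbind(loci, marker_grid(seq_len(spec$n_chrom),
                                    spacing = spec$marker_spacing,
                                    arm_length = spec$arm_length,
                                    avoid = base))
  }
  if (is.null(loci) || !nrow(loci)) stop("specification yields no loci")
  if (anyDuplicated(paste(loci$chromosome, loci$arm, loci$d)))
    stop("overlapping locus positions in specification")
  list(map = genetic_map(loci), strains = strains)
}

#' Draw ascus counts from the trinomial killing model
#'
#' One trinomial draw of size `N` with class probabilities
#' `expected_ascus_distribution(f, q)`.
#'
#' @param f FDS frequency in `[0, 1]`.
#' @param q penetrance in `[0, 1]`.
#' @param N number of asci.
#' @param seed optional integer seed.
#' @return an [ascus_counts()] object.
#' @export
generate_ascus_counts <- function(f, q, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N < 1) stop("N must be >= 1")
  p <- expected_ascus_distribution(f, q)
  draw <- rmultinom(1, N, p)[, 1]
  ascus_counts(draw[1], draw[2], draw[3])
}

#' Generate an alignment with planted structure
#'
#' Builds an alignment of `n_seq` sequences of length `length` with exactly
#' `n_variable` planted bi-allelic columns, `n_gap_cols` columns carrying a
#' gap (non-variable otherwise), and optional GC-rich segments, and returns
#' the ground truth so analysis results can be verified against the
#' generator.
#'
#' @param spec list: `n_seq` (default 4), `length` (default 500),
#'   `n_variable` (default 10), `n_gap_cols` (default 0) or alternatively
#'   `gap_fraction` (fraction of columns carrying a gap), `gc` (background
#'   GC fraction, default 0.5), `gc_segments` (optional data frame
#'   start/end/gc, 1-based inclusive).
#' @param seed optional integer seed.
#' @return `list(alignment, truth)` where `truth` lists the planted
#'   variable columns, gap columns and GC segments.
#' @export
generate_alignment <- function(spec = list(), seed = NULL) {
  spec <- modifyList(list(n_seq = 4, length = 500, n_variable = 10,
                          n_gap_cols = 0, gap_fraction = NULL, gc = 0.5,
                          gc_segments = NULL), spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_seq
  L <- spec$length
  if (n < 2) stop("need at least 2 sequences")
  ngap <- if (!is.null(spec$gap_fraction)) round(spec$gap_fraction * L)
          else spec$n_gap_cols
  if (spec$n_variable + ngap > L)
    stop("more planted columns (", spec$n_variable + ngap,
         ") than alignment length (", L, ")")
  pick_base <- function(m, gc) {
    sample(c("A", "T", "G", "C"), m, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  }
  # invariant backbone, GC-shaped
  gc_of <- rep(spec$gc, L)
  if (!is.null(spec$gc_segments)) {
    for (i in seq_len(nrow(spec$gc_segments))) {
      gs <- spec$gc_segments[i, ]
      gc_of[gs$start:gs$end] <- gs$gc
    }
  }
  backbone <- vapply(gc_of, function(g) pick_base(1, g), character(1))
  aln <- matrix(rep(backbone, each = n), nrow = n,
                dimnames = list(paste0("seq", seq_len(n)), NULL))
  planted <- sample(L, spec$n_variable + ngap)
  var_cols <- sort(planted[seq_len(spec$n_variable)])
  gap_cols <- sort(planted[spec$n_variable + seq_len(ngap)])
  for (j in var_cols) {
    states <- sample(c("A", "C", "G", "T"), 2)
    k <- sample(n - 1, 1)  # minor-state count, both states present
    rows <- sample(n, k)
    aln[, j] <- states[1]
    aln[rows, j] <- states[2]
  }
  for (j in gap_cols) aln[sample(n, 1), j] <- "-"
  list(alignment = aln,
       truth = list(variable_cols = var_cols, gap_cols = gap_cols,
                    gc_segments = spec$gc_segments, backbone_gc = spec$gc))
}
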