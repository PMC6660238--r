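#' Alignment handling
#'
#' Alignments are character matrices (rows = sequences, columns = sites)
#' over the alphabet A, C, G, T, `-`, N.  `read_alignment` loads a
#' multi-FASTA file; `as_alignment` validates a matrix or character vector
#' of equal-length sequences.  For the diversity statistics N is treated
#' like a gap (the site is skipped).
#'
#' @param path path to a multi-FASTA alignment.
#' @return a character matrix with sequence labels as row names.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  as_alignment(setNames(as.character(ss), names(ss)))
}

#' @rdname read_alignment
#' @param x character matrix, or named character vector of equal-length
#'   sequences.
#' @export
as_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    L <- unique(nchar(x))
    if (length(L) != 1) stop("sequences must have equal length")
    labs <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    x <- matrix(unlist(strsplit(toupper(x), "")), nrow = length(x),
                byrow = TRUE, dimnames = list(labs, NULL))
  }
  stopifnot(is.matrix(x), is.character(x))
  if (nrow(x) < 2) stop("an alignment needs at least 2 sequences")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("unexpected alignment characters: ", paste(bad, collapse = ", "))
  x
}

#' @rdname read_alignment
#' @param aln alignment matrix.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

window_starts <- function(L, window, step) {
  if (window < 1 || step < 1) stop("window and step must be >= 1")
  if (L < window) {
    warning("window (", window, ") exceeds sequence length (", L,
            "); returning a single truncated window")
    return(0L)
  }
  seq(0L, L - window, by = step)
}

make_track <- function(start, window, L, value, n_valid, stat) {
  out <- data.frame(start = start, end = pmin(start + window, L),
                    value = value, n_valid_sites = n_valid)
  attr(out, "coordinates") <- "0-based, half-open [start, end)"
  attr(out, "stat") <- stat
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' Sliding-window average pairwise nucleotide differences
#'
#' Computes per-site average pairwise differences, corrected by
#' `n / (n - 1)` and ignoring sites with gaps, then averages them in
#' overlapping windows (default 100 bp, step 20 bp).  A site with any gap
#' (`-` or N) in any sequence is excluded from both numerator and
#' denominator.  A bi-allelic site with major-state frequency `p` among
#' `n` sequences scores `2 p (1 - p) n / (n - 1)`, identical to the mean
#' of pairwise mismatch indicators over all `n (n - 1) / 2` pairs;
#' invariant sites score 0.  Sites with more than two states are skipped
#' by default (`multiallelic = "skip"`); `"heterozygosity"` scores them as
#' `(1 - sum p_i^2) n / (n - 1)`.
#'
#' @param aln alignment matrix (see [as_alignment()]).
#' @param window,step window length and step in bp.
#' @param multiallelic treatment of sites with > 2 non-gap states.
#' @param denominator `"valid_sites"` (default: mean over scored sites in
#'   the window) or `"window_width"`.
#' @return a `diversity_track` data frame (start, end, value,
#'   n_valid_sites) in 0-based half-open coordinates.
#' @export
windowed_pi <- function(aln, window = 100, step = 20,
                        multiallelic = c("skip", "heterozygosity"),
                        denominator = c("valid_sites", "window_width")) {
  multiallelic <- match.arg(multiallelic)
  denominator <- match.arg(denominator)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  L <- ncol(aln)
  persite <- numeric(L)
  valid <- logical(L)
  for (j in seq_len(L)) {
    col <- aln[, j]
    if (any(col == "-" | col == "N")) next
    tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")), 4L)
    k <- sum(tab > 0)
    if (k <= 2) {
      valid[j] <- TRUE
      if (k == 2) {
        p <- max(tab) / n
        persite[j] <- 2 * p * (1 - p) * n / (n - 1)
      }
    } else if (multiallelic == "heterozygosity") {
      valid[j] <- TRUE
      persite[j] <- (1 - sum((tab / n)^2)) * n / (n - 1)
    }
  }
  starts <- window_starts(L, window, step)
  vals <- numeric(length(starts))
  nv <- integer(length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):min(starts[i] + window, L)
    nv[i] <- sum(valid[idx])
    vals[i] <- if (denominator == "valid_sites") {
      if (nv[i] > 0) sum(persite[idx]) / nv[i] else NA_real_
    } else sum(persite[idx]) / window
  }
  make_track(starts, window, L, vals, nv, "pi")
}

#' Count variable sites in an alignment
#'
#' A site is variable when it shows at least two distinct non-gap states
#' (`-` and N excluded); all-gap columns are not variable.
#'
#' @param aln alignment matrix.
#' @return named integer vector `c(n_variable, n_total)`.
#' @export
count_variable_sites <- function(aln) {
  aln <- as_alignment(aln)
  nvar <- sum(apply(aln, 2, function(col) {
    states <- unique(col[col != "-" & col != "N"])
    length(states) >= 2
  }))
  c(n_variable = as.integer(nvar), n_total = ncol(aln))
}

#' GC content in sliding windows
#'
#' Per window (default 4 kb, step 2 kb), the fraction (G + C) over the
#' non-N length of the window.
#'
#' @param seq a single sequence: character string, character vector of
#'   bases, or one-row alignment.
#' @param window,step window length and step in bp.
#' @return a `diversity_track` data frame.
#' @export
gc_content_windows <- function(seq, window = 4000, step = 2000) {
  if (is.matrix(seq)) seq <- seq[1, ]
  if (length(seq) == 1 && nchar(seq) > 1)
    seq <- strsplit(toupper(seq), "")[[1]]
  seq <- toupper(seq)
  L <- length(seq)
  if (L == 0) stop("empty sequence")
  starts <- window_starts(L, window, step)
  vals <- numeric(length(starts))
  nv <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- seq[(starts[i] + 1):min(starts[i] + window, L)]
    keep <- s != "N" & s != "-"
    nv[i] <- sum(keep)
    vals[i] <- if (nv[i] > 0) sum(s[keep] %in% c("G", "C")) / nv[i]
               else NA_real_
  }
  make_track(starts, window, L, vals, nv, "gc")
}

#' @export
print.diversity_track <- function(x, ...) {
  cat(sprintf("<diversity_track> %s, %d window(s), %s\n",
              attr(x, "stat"), nrow(x), attr(x, "coordinates")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.diversity_track <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  plot(mid, x$value, type = "l", xlab = "position (bp)",
       ylab = attr(x, "stat"), ...)
  invisible(x)
}

#' Write a diversity track to TSV
#'
#' Columns: label, start, end, value, n_sites; coordinates 0-based,
#' half-open (stated in the header comment).
#'
#' @param x a `diversity_track`.
#' @param path output file.
#' @param label track label for the first column.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path, label = "aln") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coordinates: ", attr(x, "coordinates")), con)
  writeLines(paste("label", "start", "end", "value", "n_sites", sep = "\t"),
             con)
  utils::write.table(data.frame(label, x$start, x$end, x$value,
                                x$n_valid_sites),
                     con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}
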