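test_that("windowed pi: identical sequences and the worked bi-allelic site", {
  aln <- as_alignment(c(a = strrep("ACGT", 25), b = strrep("ACGT", 25)))
  tr <- windowed_pi(aln, window = 100, step = 20)
  expect_true(all(tr$value == 0))
  # 4 sequences, one (A,A,C,C) site in a 100-bp otherwise invariant window
  base <- strrep("A", 100)
  seqs <- c(s1 = base, s2 = base, s3 = base, s4 = base)
  m <- as_alignment(seqs)
  m[3:4, 50] <- "C"
  tr2 <- windowed_pi(m, window = 100, step = 20)
  expect_equal(tr2$value, (2 * 0.5 * 0.5 * 4 / 3) / 100, tolerance = 1e-12)
  expect_equal(tr2$n_valid_sites, 100L)
})

test_that("sites with gaps are excluded from numerator and denominator", {
  base <- strrep("A", 100)
  m <- as_alignment(c(s1 = base, s2 = base, s3 = base, s4 = base))
  m[3:4, 50] <- "C"
  m[1, 60] <- "-"   # gap site: skipped entirely
  m[2, 70] <- "N"   # N treated as gap
  tr <- windowed_pi(m, window = 100, step = 20)
  expect_equal(tr$n_valid_sites, 98L)
  expect_equal(tr$value, (2 * 0.5 * 0.5 * 4 / 3) / 98, tolerance = 1e-12)
})

test_that("windowed pi equals the brute-force all-pairs oracle", {
  set.seed(46)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    L <- sample(60:300, 1)
    aln <- random_alignment(n, L)
    w <- sample(c(25, 50, 100), 1)
    s <- sample(c(10, 20), 1)
    # multi-allelic sites handled via full heterozygosity = all-pairs mean
    tr <- suppressWarnings(
      windowed_pi(aln, w, s, multiallelic = "heterozygosity"))
    bf <- bf_windowed_pi(aln, w, s)
    expect_equal(tr$value, bf$value, tolerance = 1e-12)
    expect_equal(tr$n_valid_sites, bf$n_valid)
    # default mode: oracle restricted to bi-allelic sites
    tr2 <- suppressWarnings(windowed_pi(aln, w, s))
    bf2 <- bf_windowed_pi(aln, w, s, biallelic_only = TRUE)
    expect_equal(tr2$value, bf2$value, tolerance = 1e-12)
  }
})

test_that("pi is invariant to row order and bounded by n/(2(n-1))", {
  set.seed(47)
  aln <- random_alignment(5, 200)
  tr <- windowed_pi(aln, 50, 20)
  perm <- aln[sample(nrow(aln)), ]
  tr2 <- windowed_pi(perm, 50, 20)
  expect_equal(tr$value, tr2$value)
  n <- nrow(aln)
  expect_true(all(tr$value <= n / (2 * (n - 1)) + 1e-12, na.rm = TRUE))
})

test_that("a window longer than the alignment truncates with a warning", {
  aln <- as_alignment(c(a = strrep("ACGT", 10), b = strrep("ACGT", 10)))
  expect_warning(tr <- windowed_pi(aln, window = 100, step = 20),
                 "truncated")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$end, 40)
})

test_that("variable-site counting matches planted ground truth", {
  aln <- as_alignment(c(a = strrep("A", 30), b = strrep("A", 30)))
  expect_equal(count_variable_sites(aln),
               c(n_variable = 0L, n_total = 30L))
  g <- generate_alignment(list(n_seq = 5, length = 400, n_variable = 37,
                               n_gap_cols = 11), seed = 48)
  expect_equal(count_variable_sites(g$alignment),
               c(n_variable = 37L, n_total = 400L))
  # an all-gap column is not variable
  m <- g$alignment
  m[, 1] <- "-"
  cv <- count_variable_sites(m)
  expect_lte(cv["n_variable"], 37L)
})

test_that("GC windows: constant sequences and planted GC-rich segment", {
  expect_equal(gc_content_windows(strrep("G", 10000))$value,
               rep(1, 4))
  expect_equal(unique(gc_content_windows(strrep("ATGC", 1000))$value), 0.5)
  expect_error(gc_content_windows(character(0)), "empty")
  # N excluded from the denominator
  s <- paste0(strrep("G", 50), strrep("N", 50))
  tr <- suppressWarnings(gc_content_windows(s, window = 200, step = 100))
  expect_equal(tr$value, 1)
  expect_equal(tr$n_valid_sites, 50L)
  g <- generate_alignment(list(n_seq = 2, length = 20000, n_variable = 0,
                               gc = 0.40,
                               gc_segments = data.frame(start = 8001,
                                                        end = 12000,
                                                        gc = 0.62)),
                          seed = 49)
  tr2 <- gc_content_windows(g$alignment[1, ], window = 4000, step = 2000)
  inside <- tr2$start >= 8000 & tr2$end <= 12000
  expect_gt(min(tr2$value[inside]), max(tr2$value[!inside & tr2$start < 6000]))
})

test_that("alignments round-trip through FASTA", {
  g <- generate_alignment(list(n_seq = 4, length = 120, n_variable = 9,
                               n_gap_cols = 3), seed = 50)
  path <- tempfile(fileext = ".fasta")
  write_alignment(g$alignment, path)
  back <- read_alignment(path)
  expect_equal(back, g$alignment)
  tsv <- tempfile(fileext = ".tsv")
  write_track_tsv(windowed_pi(back, 50, 25), tsv)
  expect_match(readLines(tsv, n = 1), "0-based")
})
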