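test_that("expected ascus distribution: plug-in values and simulation", {
  expect_equal(expected_ascus_distribution(0.4, 1),
               c(P2 = 0.4, P3 = 0, P4 = 0.6))
  expect_equal(expected_ascus_distribution(0.5, 0),
               c(P2 = 0, P3 = 0, P4 = 1))
  expect_equal(expected_ascus_distribution(0.4, 0.8),
               c(P2 = 0.256, P3 = 0.128, P4 = 0.616))
  expect_error(expected_ascus_distribution(1.2, 0.5), "\\[0, 1\\]")
  # cross-check against the simulator at the same (f, q)
  d <- distance_for_fds(0.4)
  map <- genetic_map(locus("x", 1, "L", d))
  p1 <- strain_genotype("k", list(x = list(spok_allele("Spok2"))))
  p2 <- strain_genotype("n", list())
  model <- set_penetrance(default_resistance_model(), Spok2 = 0.8)
  cr <- simulate_cross(p1, p2, map, model, n_asci = 60000, seed = 20)
  obs <- cr$counts[c("n2", "n3", "n4")] / cr$n
  exp <- expected_ascus_distribution(0.4, 0.8)
  for (i in 1:3) {
    se <- sqrt(exp[i] * (1 - exp[i]) / cr$n)
    expect_lt(abs(obs[i] - exp[i]), 4 * se)
  }
})

test_that("a centromere-tight knock-in killer gives exactly 100% killing", {
  reg <- default_strain_registry()
  cr <- simulate_cross(genotype_of("Spok3_PaPKS1", reg),
                       genotype_of("s_dSpok2", reg),
                       n_asci = 2000, seed = 21)
  expect_equal(cr$killing_pct, 100)
  expect_equal(unname(cr$counts["n2"]), 2000L)
})

test_that("a cross without killers yields no killing", {
  reg <- default_strain_registry()
  cr <- simulate_cross(genotype_of("Wa46", reg), genotype_of("s_dSpok2", reg),
                       n_asci = 500, seed = 22)
  expect_equal(cr$killing_pct, 0)
  expect_equal(unname(cr$counts["n4"]), 500L)
})

test_that("F1 selection recovers the resistant genotype from 2-spored asci", {
  reg <- default_strain_registry()
  # Psk-1 x Psk-S: the F1 carries Spok2 and the 3L block
  f1 <- select_f1_from_two_spored(genotype_of("Wa53", reg),
                                  genotype_of("S", reg), seed = 23)
  expect_setequal(names(f1$alleles), c("spok2", "block_3L"))
  expect_false(attr(f1, "heteroallelic"))
  # mutual killers at the same locus produce no F1 (only 0-/4-spored asci)
  err <- tryCatch(
    select_f1_from_two_spored(genotype_of("Spok3_PaPKS1", reg),
                              genotype_of("Spok4_PaPKS1_dSpok2", reg),
                              max_asci = 2000, seed = 24),
    no_f1_available = function(e) "signalled")
  expect_equal(err, "signalled")
  # a killing-free cross has no 2-spored asci either
  err2 <- tryCatch(
    select_f1_from_two_spored(genotype_of("S", reg), genotype_of("Wa63", reg),
                              max_asci = 2000, seed = 25),
    no_f1_available = function(e) "signalled")
  expect_equal(err2, "signalled")
})

test_that("interaction classification reproduces the published verdicts", {
  reg <- default_strain_registry()
  cl <- classify_interaction(genotype_of("Wa53"), genotype_of("Wa58"),
                             n_asci = 600, seed = 26)
  expect_equal(cl$verdict, "mutual_resistance")
  # the direct Psk-1 x Psk-7 cross DOES kill (the apparent paradox)
  expect_gt(cl$evidence$direct$counts["n2"] / cl$evidence$direct$n, 0.05)
  cl2 <- classify_interaction(genotype_of("Wa58"), genotype_of("Wa100"),
                              n_asci = 600, seed = 27)
  expect_equal(cl2$verdict, "dominance")
  expect_equal(cl2$dominant, "Wa58")
  cl3 <- classify_interaction(genotype_of("Y"), genotype_of("S"),
                              n_asci = 600, seed = 28)
  expect_equal(cl3$verdict, "mutual_killing")
  cl4 <- classify_interaction(genotype_of("S"), genotype_of("Wa63"),
                              n_asci = 600, seed = 29)
  expect_equal(cl4$verdict, "same_type")
})

test_that("classification is symmetric up to relabeling", {
  reg <- default_strain_registry()
  pairs <- list(c("Wa58", "Wa100"), c("Wa53", "Wa58"), c("Y", "S"))
  for (pr in pairs) {
    a <- classify_interaction(genotype_of(pr[1]), genotype_of(pr[2]),
                              n_asci = 600, seed = 30)
    b <- classify_interaction(genotype_of(pr[2]), genotype_of(pr[1]),
                              n_asci = 600, seed = 31)
    expect_equal(a$verdict, b$verdict, info = paste(pr, collapse = " x "))
    if (a$verdict == "dominance") expect_equal(a$dominant, b$dominant)
  }
})

test_that("every registry strain is same_type with itself", {
  for (nm in c("Wa53", "Wa28", "Y", "S", "Wa46")) {
    g <- genotype_of(nm)
    cl <- classify_interaction(g, g, n_asci = 400, seed = 32)
    expect_equal(cl$verdict, "same_type", info = nm)
  }
})

test_that("hierarchy handles degenerate inputs", {
  h1 <- build_hierarchy(list(solo = genotype_of("S")), n_asci = 200, seed = 33)
  expect_equal(h1$nodes, "solo")
  expect_equal(nrow(h1$dominance), 0)
  h2 <- build_hierarchy(list(a = genotype_of("Wa46"),
                             b = strain_genotype("b2", list())),
                        n_asci = 300, seed = 34)
  expect_equal(nrow(h2$same_type), 1)
  expect_true(all(h2$levels == 1L))
})

test_that("dominance cycles are rejected as model violations", {
  dom <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
  expect_error(spokdrive:::dominance_levels(c("a", "b", "c"), dom), "cycle")
})
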