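single_killer_cross <- function(d = 0.3) {
  list(map = genetic_map(locus("x", 1, "L", d)),
       p1 = strain_genotype("k", list(x = list(spok_allele("Spok2")))),
       p2 = strain_genotype("n", list()))
}

test_that("FDS asci with one killer become two-spored; SDS stay four-spored", {
  kc <- single_killer_cross(0.5)
  set.seed(10)
  for (i in 1:40) {
    a <- simulate_tetrad(kc$p1, kc$p2, kc$map)
    k <- apply_killing(a)
    if (a$fds_by_locus["x"] == "FDS") {
      expect_equal(ascus_class(k), 2)
      # the survivors are the killer carriers
      surv_pair <- if (k$fates[1] == "alive") 1:2 else 3:4
      expect_true(all(a$origins["x", surv_pair] == 1))
    } else {
      expect_equal(ascus_class(k), 4)
    }
  }
})

test_that("same-locus heteroallelic killers empty the FDS asci", {
  map <- genetic_map(locus("x", 1, "L", 0.3))
  p1 <- strain_genotype("a", list(x = list(spok_allele("Spok3"))))
  p2 <- strain_genotype("b", list(x = list(spok_allele("Spok4"))))
  set.seed(11)
  for (i in 1:40) {
    a <- simulate_tetrad(p1, p2, map)
    k <- apply_killing(a)
    expect_equal(ascus_class(k),
                 if (a$fds_by_locus["x"] == "FDS") 0 else 4)
  }
})

test_that("a spore carrying every zygote killer never dies", {
  map <- default_genetic_map()
  p1 <- genotype_of("Wa53"); p2 <- genotype_of("Wa28")
  set.seed(12)
  o <- spokdrive:::sim_meioses(map, 20000)
  kb <- spokdrive:::kill_batch(o, map, p1, p2, default_resistance_model())
  # spores carrying Spok2 + both blocks resist all killers
  li <- match(c("spok2", "block_3L", "block_5R"), map$name)
  for (p in 1:2) {
    full <- (o[, li[1], 2 * p - 1] == 1 | o[, li[1], 2 * p] == 1 |
             o[, li[1], 2 * p - 1] == 2 | o[, li[1], 2 * p] == 2) &
            (o[, li[2], 2 * p - 1] == 1 | o[, li[2], 2 * p] == 1) &
            (o[, li[3], 2 * p - 1] == 2 | o[, li[3], 2 * p] == 2)
    expect_true(all(kb$alive[full, c(2 * p - 1, 2 * p)]))
  }
})

test_that("incomplete penetrance generates three-spored asci at 2q(1-q)", {
  q <- 0.8
  kc <- single_killer_cross(0.3)
  model <- set_penetrance(default_resistance_model(), Spok2 = q)
  cr <- simulate_cross(kc$p1, kc$p2, kc$map, model, n_asci = 40000, seed = 13)
  f <- 1 - sds_probability(0.3)
  exp_p3 <- 2 * f * q * (1 - q)
  se <- sqrt(exp_p3 * (1 - exp_p3) / cr$n)
  expect_lt(abs(cr$counts["n3"] / cr$n - exp_p3), 4 * se)
  # with q = 1, three-spored asci are impossible
  cr1 <- simulate_cross(kc$p1, kc$p2, kc$map, n_asci = 5000, seed = 14)
  expect_equal(unname(cr1$counts["n3"]), 0)
  expect_equal(unname(cr1$counts["n0"]), 0)
})

test_that("with q = 1 and one killer, classes are {2,4} at the FDS frequency", {
  d <- 0.4
  kc <- single_killer_cross(d)
  cr <- simulate_cross(kc$p1, kc$p2, kc$map, n_asci = 30000, seed = 15)
  expect_equal(sum(cr$counts[c("n2", "n4")]), cr$n)
  f <- 1 - sds_probability(d)
  se <- sqrt(f * (1 - f) / cr$n)
  expect_lt(abs(cr$counts["n2"] / cr$n - f), 3 * se)
})

test_that("expected two-spored fraction decreases with distance", {
  pcts <- vapply(c(0.05, 0.2, 0.5, 0.9), function(d) {
    kc <- single_killer_cross(d)
    simulate_cross(kc$p1, kc$p2, kc$map, n_asci = 8000,
                   seed = round(1000 * d))$killing_pct
  }, numeric(1))
  expect_true(all(diff(pcts) < 0))
})

test_that("adding a resistance pair cannot increase death (seed-coupled)", {
  map <- genetic_map(locus("x", 1, "L", 0.3))
  p1 <- strain_genotype("a", list(x = list(spok_allele("Spok3"))))
  p2 <- strain_genotype("b", list(x = list(spok_allele("Spok4"))))
  base <- default_resistance_model()
  plus <- base
  plus$resistance["Spok3", "Spok4"] <- TRUE  # Spok4 now protects against Spok3
  set.seed(16); o <- spokdrive:::sim_meioses(map, 5000)
  set.seed(17); k0 <- spokdrive:::kill_batch(o, map, p1, p2, base)
  set.seed(17); k1 <- spokdrive:::kill_batch(o, map, p1, p2, plus)
  expect_true(all(k1$alive >= k0$alive))
})

test_that("ascus-level penetrance mode yields no three-spored asci", {
  q <- 0.7
  kc <- single_killer_cross(0.2)
  model <- set_penetrance(default_resistance_model(), Spok2 = q)
  cr <- simulate_cross(kc$p1, kc$p2, kc$map, model, n_asci = 10000,
                       seed = 18, penetrance_mode = "ascus")
  expect_equal(unname(cr$counts["n3"]), 0)
  f <- 1 - sds_probability(0.2)
  p2 <- f * q
  se <- sqrt(p2 * (1 - p2) / cr$n)
  expect_lt(abs(cr$counts["n2"] / cr$n - p2), 4 * se)
})

test_that("unresolved fates are rejected by ascus_class", {
  kc <- single_killer_cross(0.2)
  a <- simulate_tetrad(kc$p1, kc$p2, kc$map, seed = 19)
  expect_error(ascus_class(a), "not resolved")
})
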