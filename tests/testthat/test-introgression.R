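# small two-chromosome map: killer at 0.4 M on 1L with two intermediate
# markers, plus an unlinked marker on chromosome 2
intro_fixture <- function() {
  map <- genetic_map(rbind(
    locus("m1", 1, "L", 0.15), locus("m2", 1, "L", 0.30),
    locus("kill", 1, "L", 0.40), locus("far", 1, "L", 0.80),
    locus("un", 2, "L", 0.30)))
  donor <- strain_genotype("donor", list(kill = list(spok_allele("Spok3"))))
  recurrent <- strain_genotype("rec", list())
  list(map = map, donor = donor, recurrent = recurrent)
}

test_that("two-spored selection keeps the killer locus donor-fixed, and
           linked markers match the chromatid-enumeration oracle", {
  fx <- intro_fixture()
  sch <- backcross_scheme(fx$donor, fx$recurrent, generations = 1)
  prof <- simulate_backcross_series(sch, fx$map, n_replicates = 1500,
                                    seed = 37)
  reps <- attr(prof, "replicates")
  # the surviving spore of a two-spored ascus always carries the killer
  expect_equal(prof$donor_freq[prof$locus == "kill"], 1.0)
  expect_true(all(reps[, "kill"]))
  # intermediate markers: donor frequency equals the enumeration oracle
  # (slightly below 1: double crossovers can restore killer FDS while
  # leaving the survivor heteroallelic at the marker)
  for (mk in c("m1", "m2")) {
    a <- fx$map$d[fx$map$name == mk]
    b <- 0.40 - a
    ora <- oracle_linked_donor_freq(a, b)
    obs <- prof$donor_freq[prof$locus == mk]
    se <- sqrt(ora * (1 - ora) / nrow(reps))
    expect_lt(abs(obs - ora), 4 * se)
    expect_gt(ora, 0.9)  # near-fixation of the donor tract
  }
})

test_that("unlinked markers decay by one half per backcross generation", {
  fx <- intro_fixture()
  for (gen in c(1L, 3L)) {
    sch <- backcross_scheme(fx$donor, fx$recurrent, generations = gen)
    prof <- simulate_backcross_series(sch, fx$map, n_replicates = 1200,
                                      seed = 38 + gen)
    expected <- 0.5^gen
    se <- sqrt(expected * (1 - expected) / 1200)
    expect_lt(abs(prof$donor_freq[prof$locus == "un"] - expected), 3.5 * se)
    # killer locus stays fixed across generations
    expect_equal(prof$donor_freq[prof$locus == "kill"], 1.0)
  }
})

test_that("alternating selection ends even generations killer-fixed", {
  fx <- intro_fixture()
  sch <- backcross_scheme(fx$donor, fx$recurrent, generations = 4,
                          policy = "alternating")
  prof <- simulate_backcross_series(sch, fx$map, n_replicates = 300,
                                    seed = 40)
  expect_equal(prof$donor_freq[prof$locus == "kill"], 1.0)
  # background decays faster than pure two-spored towards the recurrent
  expect_lt(prof$donor_freq[prof$locus == "un"], 0.15)
})

test_that("selection failure is signalled with the generation index", {
  fx <- intro_fixture()
  # recurrent parent also carries the killer: never any two-spored ascus
  rec2 <- strain_genotype("rec2", list(kill = list(spok_allele("Spok3"))))
  sch <- backcross_scheme(fx$donor, rec2, generations = 1)
  expect_error(
    simulate_backcross_series(sch, fx$map, n_replicates = 1, seed = 41,
                              max_asci_per_selection = 256),
    class = "selection_failed")
  expect_error(backcross_scheme(fx$recurrent, fx$donor, 1),
               "no kill-capable")
})

test_that("pooled two-spored progeny are fixed at the killer locus,
           four-spored pools are exactly heterozygous", {
  fx <- intro_fixture()
  pool2 <- pooled_allele_frequency(fx$donor, fx$recurrent, fx$map,
                                   ascus_selection = "two_spored",
                                   n_asci = 3000, seed = 42)
  expect_equal(pool2$freq_p1[pool2$locus == "kill"], 1.0)
  pool4 <- pooled_allele_frequency(fx$donor, fx$recurrent, fx$map,
                                   ascus_selection = "four_spored",
                                   n_asci = 3000, seed = 43)
  # every four-spored ascus contributes all 8 nuclei: exactly 4:4
  expect_true(all(pool4$freq_p1 == 0.5))
  # no-killer cross: every marker at 1/2
  p0 <- pooled_allele_frequency(fx$recurrent,
                                strain_genotype("rec_b", list()), fx$map,
                                ascus_selection = "four_spored",
                                n_asci = 500, seed = 44)
  expect_true(all(p0$freq_p1 == 0.5))
  # requesting an absent class names the class
  expect_error(
    pooled_allele_frequency(fx$recurrent, strain_genotype("x", list()),
                            fx$map, ascus_selection = "two_spored",
                            n_asci = 200, seed = 45),
    "two_spored")
})
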