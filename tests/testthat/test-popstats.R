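test_that("genotype labels of both published dialects normalize", {
  expect_equal(parse_genotype_label("p'agiB1.2"), c("p'agiB1", "p'agiB2"))
  expect_equal(parse_genotype_label("p'agiB2.2"), c("p'agiB2", "p'agiB2"))
  expect_equal(parse_genotype_label("h'agiC1.p'agiC2"), c("h'agiC1", "p'agiC2"))
  expect_error(parse_genotype_label("p'agiB1"), "malformed")
})

test_that("allele frequencies follow p_i = f(ii) + sum f(ij)/2", {
  s <- population_sample("X", n = 100, counts = data.frame(
    arm = "B", seq1 = c("b1", "b1", "b2"), seq2 = c("b1", "b2", "b2"),
    count = c(25, 50, 25)))
  expect_equal(unname(allele_frequencies(s)$arms$B), c(0.5, 0.5))

  s2 <- population_sample("Y", n = 10, counts = data.frame(
    arm = "B", seq1 = c("b1", "b1", "b2"), seq2 = c("b1", "b2", "b2"),
    count = c(0, 0.4, 0.6)))
  expect_equal(unname(allele_frequencies(s2)$arms$B), c(0.2, 0.8))

  # monomorphic arm from the packaged genotype table
  kha <- fixture_samples(fx)[["KHA-EV"]]
  expect_equal(allele_frequencies(kha)$arms$B, c("p'agiB2" = 1))

  # frequencies sum to one per arm, on exact count arithmetic
  for (s in fixture_samples(fx)) {
    sums <- vapply(allele_frequencies(s)$arms, sum, numeric(1))
    expect_equal(unname(sums), rep(1, length(sums)))
  }
})

test_that("polymorphism indices count heterozygous arms once each", {
  lv <- data.frame(
    A = c("a1/a1", "a1/a1", "a1/a1"),
    B = c("b1/b2", "b1/b2", "b1/b1"),
    F = c("f1/f1", "f1/f2", "f1/f1"))
  s <- population_sample("X", n = 3, larvae = lv)
  ps <- polymorphism_summary(s)
  expect_equal(ps$pct_het_larvae, 100 * 2 / 3)
  expect_equal(ps$het_inv_per_larva, 1)
  expect_equal(ps$n_sequences, 5)
  expect_equal(ps$n_genotypes, 5)

  hom <- population_sample("Y", n = 2, larvae = data.frame(
    A = c("a1/a1", "a1/a1"), B = c("b1/b1", "b1/b1")))
  ph <- polymorphism_summary(hom)
  expect_equal(ph$pct_het_larvae, 0)
  expect_equal(ph$het_inv_per_larva, 0)

  mono <- population_sample("Z", n = 1, larvae = data.frame(
    A = "a1/a1", B = "b1/b1", C = "c1/c1", D = "d1/d1",
    E = "e1/e1", F = "f1/f1", G = "g1/g1"))
  expect_equal(polymorphism_summary(mono)$n_sequences, 7)
})

test_that("panel means are unweighted across admitted populations", {
  same <- replicate(4, list(pct_het_larvae = 40, het_inv_per_larva = 0.5),
                    simplify = FALSE)
  pm <- quantitative_panel_means(same)
  expect_equal(unname(pm["pct_het_larvae"]), 40)
  expect_equal(unname(pm["het_inv_per_larva"]), 0.5)
  expect_error(quantitative_panel_means(list()), "empty")
})

test_that("Hardy-Weinberg expectations match the published arm-B figures", {
  sh <- fx$table3[["NSK-SH"]]$arms$B
  e_sh <- hw_expected(sh)
  expect_equal(round(100 * unname(e_sh["p'agiB1/p'agiB2"]), 1), 41.1)
  li <- fx$table3[["NSK-LI"]]$arms$B
  expect_equal(round(100 * unname(hw_expected(li)["p'agiB1/p'agiB2"]), 1), 46.0)
  # degenerate corner: a fixed allele puts all mass on its homozygote
  expect_equal(unname(hw_expected(c(a = 1, b = 0))["a/a"]), 1)
  expect_equal(sum(hw_expected(c(a = 0.3, b = 0.2, c = 0.5))), 1)
  expect_error(hw_expected(c(a = -0.1, b = 1.1)), "negative")
})

test_that("chi-square HW test matches the hand-computed oracle", {
  # exact HW proportions: no deviation
  h0 <- hw_chi_square(c("a/a" = 25, "a/b" = 50, "b/b" = 25))
  expect_equal(h0$chi_square, 0)
  expect_equal(h0$df, 1)

  # hand oracle: p_hat = 0.5 so E = (25, 50, 25); observed (10, 80, 10)
  # gives X2 = 15^2/25 + 30^2/50 + 15^2/25 = 36
  h1 <- hw_chi_square(c("a/a" = 10, "a/b" = 80, "b/b" = 10))
  expect_equal(h1$chi_square, (15^2 / 25) * 2 + 30^2 / 50)
  expect_equal(h1$chi_square, 36)
  expect_equal(h1$direction, "het excess")
  expect_lt(h1$p_value, 0.05)

  # monomorphic sample: df = 0, no test
  hm <- hw_chi_square(c("a/a" = 40))
  expect_equal(hm$df, 0)
  expect_true(is.na(hm$p_value))
  expect_equal(hm$direction, "none")

  # invariant under allele relabeling
  h2 <- hw_chi_square(c("z/z" = 10, "q/z" = 80, "q/q" = 10))
  expect_equal(h2$chi_square, h1$chi_square)

  # three alleles: df = k(k+1)/2 - k = 3
  h3 <- hw_chi_square(c("a/a" = 10, "a/b" = 20, "b/b" = 15, "a/c" = 5,
                        "b/c" = 10, "c/c" = 5))
  expect_equal(h3$df, 3)
})

test_that("exact HW enumeration agrees with the biallelic closed form", {
  cases <- list(c(3, 4, 3), c(8, 4, 8), c(1, 10, 1), c(12, 2, 6))
  for (cs in cases) {
    got <- hw_exact_test(c("a/a" = cs[1], "a/b" = cs[2], "b/b" = cs[3]))
    expect_equal(got$p_value, oracle_biallelic_exact(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10)
  }
  expect_error(hw_exact_test(c("a/a" = 60, "a/b" = 10), max_n = 50), "too large")
})

test_that("pool census counts distinct sequences and is monotone", {
  t1 <- allele_frequency_table("P1", list(A = c(a1 = 1), B = c(b1 = 0.5, b2 = 0.5)))
  t2 <- allele_frequency_table("P2", list(A = c(a1 = 0.9, a2 = 0.1), B = c(b1 = 1, b2 = 0)))
  c1 <- pool_census(list(t1))
  c12 <- pool_census(list(t1, t2))
  expect_equal(c1$pool_size, 3)
  expect_equal(c12$pool_size, 4)         # a2 enters, zero-frequency b2 does not
  expect_gte(c12$pool_size, c1$pool_size)
  expect_equal(unname(c12$per_population), c(3, 3))

  mono <- allele_frequency_table("M", setNames(
    lapply(paste0(letters[1:7], "1"), function(i) setNames(1, i)), LETTERS[1:7]))
  expect_equal(pool_census(list(mono))$per_population[["M"]], 7)
})
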