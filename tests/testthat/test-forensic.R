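test_that("observed heterozygosity counts distinct-allele calls", {
  g <- geno_one_locus(list(c("10", "10"), c("11", "11")))
  expect_equal(observed_heterozygosity(g)$ho, 0)

  # 376 heterozygotes of 400 -> 0.94
  calls <- c(replicate(376, c("10", "11"), simplify = FALSE),
             replicate(24, c("10", "10"), simplify = FALSE))
  expect_equal(observed_heterozygosity(geno_one_locus(calls))$ho, 0.94)

  # brute-force counting oracle on a random table
  set.seed(31)
  calls <- replicate(80, sample(as.character(5:9), 2, replace = TRUE),
                     simplify = FALSE)
  g3 <- geno_one_locus(calls)
  manual <- sum(vapply(calls, function(x) x[1] != x[2], logical(1))) / 80
  expect_equal(observed_heterozygosity(g3)$ho, manual)
})

test_that("expected heterozygosity applies the unbiased correction", {
  expect_equal(expected_heterozygosity(freq_tbl(c("7" = 1), n = 10))$he, 0)
  f <- freq_tbl(c("10" = 0.5, "11" = 0.5), n = 20)
  expect_equal(expected_heterozygosity(f)$he, (20 / 19) * 0.5)
  expect_equal(expected_heterozygosity(f, unbiased = FALSE)$he, 0.5)
})

test_that("PIC follows its closed form", {
  expect_equal(pic(freq_tbl(c("7" = 1)))$pic, 0)
  expect_equal(pic(freq_tbl(c("10" = 0.5, "11" = 0.5)))$pic, 0.375)
})

test_that("published He and PIC are reproduced from the printed frequencies", {
  f <- kuwait_frequencies()
  stats <- kuwait_locus_stats()
  he <- expected_heterozygosity(f)
  picv <- pic(f)
  joined <- dplyr::left_join(stats, he, by = "locus") |>
    dplyr::left_join(picv, by = "locus")
  expect_true(all(abs(joined$he.x - joined$he.y) <= 0.002))
  expect_true(all(abs(joined$pic.x - joined$pic.y) <= 0.002))
})

test_that("match probability matches brute force in both modes", {
  g <- geno_one_locus(replicate(5, c("9", "9"), simplify = FALSE))
  pm <- match_probability(g)
  expect_equal(pm$pm, 1)
  expect_equal(pm$dp, 0)

  g2 <- geno_one_locus(list(c("10", "10"), c("10", "11"), c("11", "10"), c("11", "11")))
  expect_equal(match_probability(g2)$pm, 0.25^2 + 0.5^2 + 0.25^2)

  # hwe_expected equals enumeration over all genotype pairs, small allele sets
  for (k in 2:6) {
    set.seed(k)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    f <- freq_tbl(setNames(p, as.character(seq_len(k))), n = 200)
    geno_freqs <- c()
    for (i in seq_len(k)) for (j in i:k) {
      geno_freqs <- c(geno_freqs, if (i == j) p[i]^2 else 2 * p[i] * p[j])
    }
    expect_equal(match_probability(f, mode = "hwe_expected")$pm,
                 sum(geno_freqs^2), tolerance = 1e-12)
  }
  expect_error(match_probability(f, mode = "observed"), "genotype")
})

test_that("the published DP column is the complement of the RMP column", {
  stats <- kuwait_locus_stats()
  expect_equal(stats$dp, 1 - stats$rmp, tolerance = 1e-9)
})

test_that("PE and TPI follow their closed forms and are monotone in Ho", {
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(power_of_exclusion(0.5), 0.25 * (1 - 2 * 0.5 * 0.25))
  expect_equal(report_round(power_of_exclusion(0.94)), 0.878)
  expect_equal(typical_paternity_index(0), 0.5)
  expect_equal(typical_paternity_index(0.75), 2)
  expect_equal(report_round(typical_paternity_index(0.94)), 8.333)
  expect_error(typical_paternity_index(1), class = "strpopgen_domain_error")
  expect_error(power_of_exclusion(1.2), class = "strpopgen_domain_error")
  hos <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(power_of_exclusion(hos)) > 0))
  expect_true(all(diff(typical_paternity_index(hos)) > 0))
})

test_that("PIC never exceeds raw gene diversity", {
  f <- kuwait_frequencies()
  raw <- expected_heterozygosity(f, unbiased = FALSE)
  joined <- dplyr::left_join(pic(f), raw, by = "locus")
  expect_true(all(joined$pic <= joined$he + 1e-12))
})

test_that("combined parameters multiply across loci", {
  one <- tibble::tibble(pm = 0.3, pe = 0.5)
  expect_equal(combine_forensic(one)$cmp, 0.3)
  two <- tibble::tibble(pm = c(0.1, 0.2), pe = c(0.5, 0.5))
  comb <- combine_forensic(two)
  expect_equal(comb$cmp, 0.02)
  expect_equal(comb$cdp, 0.98)
  expect_equal(comb$cpe, 1 - 0.25)
  expect_equal(comb$one_in, 50)
  expect_error(combine_forensic(two[0, ]), "at least one")
})

test_that("statistics computed on HWE simulations track the source table", {
  f <- kuwait_frequencies()
  g <- simulate_genotypes(f, n = 2000, seed = 17)
  smry <- locus_summary(g, hwe = FALSE)
  pop <- dplyr::left_join(
    expected_heterozygosity(f, unbiased = FALSE) |> dplyr::rename(h_exp = he),
    pic(f), by = "locus")
  joined <- dplyr::left_join(smry, pop, by = "locus")
  se_ho <- sqrt(joined$h_exp * (1 - joined$h_exp) / 2000)
  expect_true(all(abs(joined$ho - joined$h_exp) < 3 * se_ho + 0.005))
  expect_true(all(abs(joined$he - joined$h_exp) < 0.03))
  expect_true(all(abs(joined$pic.x - joined$pic.y) < 0.03))
})
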