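test_that("K = 1 collapses to a single population with unit ancestry", {
  g <- simulate_genotypes(kuwait_subset(5), n = 30, seed = 1)
  run <- run_structure(g, k = 1, burnin = 20, iters = 60, thin = 2, seed = 1)
  expect_true(all(run$q == 1))
  expect_true(all(is.finite(run$loglik)))
  expect_true(is.finite(run$lnp))
})

test_that("ancestry rows and cluster frequencies renormalize", {
  g <- simulate_genotypes(kuwait_subset(5), n = 30, seed = 2)
  run <- run_structure(g, k = 3, burnin = 30, iters = 90, thin = 3, seed = 2)
  expect_true(all(abs(rowSums(run$q) - 1) < 1e-9))
  for (p in run$p) expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_equal(length(run$loglik), 30)
})

test_that("missing and off-ladder calls are skipped, not fatal", {
  g <- simulate_genotypes(kuwait_subset(4), n = 20, seed = 12)
  g$allele_1[1] <- NA
  g$allele_2[1] <- NA
  g$allele_1[6] <- "OL"
  run <- run_structure(g, k = 2, burnin = 20, iters = 40, thin = 2, seed = 3)
  expect_true(all(is.finite(run$loglik)))
  expect_true(all(abs(rowSums(run$q) - 1) < 1e-9))
})

test_that("runs are reproducible given the seed", {
  g <- simulate_genotypes(kuwait_subset(4), n = 20, seed = 3)
  r1 <- run_structure(g, k = 2, burnin = 20, iters = 40, thin = 2, seed = 9)
  r2 <- run_structure(g, k = 2, burnin = 20, iters = 40, thin = 2, seed = 9)
  expect_identical(r1$q, r2$q)
  expect_identical(r1$loglik, r2$loglik)
})

test_that("the evidence estimate is mean minus half the sample variance", {
  expect_equal(lnp_estimate(c(-5, -5, -5)), -5)
  expect_equal(lnp_estimate(c(-10, -12)), -12)
  set.seed(4)
  tr <- rnorm(50, -100, 3)
  expect_equal(lnp_estimate(tr), mean(tr) - var(tr) / 2, tolerance = 1e-12)
  expect_error(lnp_estimate(-1), "at least 2")
})

test_that("two diverged subpopulations are recovered at K = 2", {
  sub <- tibble::tibble(label = c("p1", "p2"), size = c(100, 100), f = 0.15)
  g <- simulate_genotypes(kuwait_subset(10), subpops = sub, seed = 51)
  run <- run_structure(g, k = 2, burnin = 300, iters = 600, thin = 3, seed = 51)
  expect_gt(mean(apply(run$q, 1, max)), 0.8)
  truth <- rep(c(1, 2), each = 100)
  assign <- apply(run$q, 1, which.max)
  agree <- max(mean(assign == truth), mean(assign == 3 - truth))
  expect_gt(agree, 0.9)
})

test_that("balanced admixture is recovered in the ancestry matrix", {
  sub <- tibble::tibble(label = c("p1", "p2"), size = c(80, 80), f = 0.2)
  adm <- tibble::tibble(size = 40, p1 = 0.5, p2 = 0.5)
  g <- simulate_genotypes(kuwait_subset(10), subpops = sub, admixed = adm,
                          seed = 52)
  run <- run_structure(g, k = 2, burnin = 300, iters = 600, thin = 3, seed = 52)
  adm_rows <- grepl("admixed", g$subgroup[match(rownames(run$q), g$sample_id)])
  q_adm <- run$q[adm_rows, ]
  expect_lt(abs(mean(q_adm[, 1]) - 0.5), 0.15)
  expect_lt(abs(mean(q_adm[, 2]) - 0.5), 0.15)
})

test_that("unstructured data yields diffuse ancestry at K = 2", {
  g <- simulate_genotypes(kuwait_subset(10), n = 100, seed = 53)
  run <- run_structure(g, k = 2, burnin = 300, iters = 600, thin = 3, seed = 53)
  expect_lt(mean(apply(run$q, 1, max)), 0.7)
})

test_that("the Evanno table reproduces its worked example exactly", {
  runs <- tibble::tibble(
    k = rep(1:4, each = 3),
    lnp = c(-1005, -1000, -995, -505, -500, -495, -500, -495, -490,
            -499, -494, -489))
  ev <- evanno_delta_k(runs)
  expect_equal(ev$mean_lnp, c(-1000, -500, -495, -494))
  expect_equal(ev$sd_lnp[2], 5)
  expect_equal(ev$l_second_abs[2], 495)
  expect_equal(ev$delta_k[2], 99)
  expect_equal(attr(ev, "best_k"), 2L)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))
})

test_that("a linear mean Ln P profile gives zero deltaK everywhere", {
  runs <- tibble::tibble(k = rep(1:4, each = 2),
                         lnp = rep(c(-400, -300, -200, -100), each = 2) +
                           rep(c(-1, 1), 4))
  ev <- evanno_delta_k(runs)
  expect_equal(ev$l_second_abs[2:3], c(0, 0))
  expect_equal(ev$delta_k[2:3], c(0, 0))
})

test_that("zero SD leaves deltaK undefined with a warning", {
  runs <- tibble::tibble(k = rep(1:3, each = 2),
                         lnp = c(-10, -10, -5, -5, -4, -4))
  expect_warning(ev <- evanno_delta_k(runs), "zero SD")
  expect_true(is.na(ev$delta_k[2]))
})

test_that("evanno input validation catches malformed run sets", {
  expect_error(evanno_delta_k(tibble::tibble(k = c(1, 1, 2, 2), lnp = 1:4)),
               "at least 3")
  expect_error(evanno_delta_k(tibble::tibble(k = c(1, 1, 3, 3, 4, 4), lnp = 1:6)),
               "contiguous")
  expect_error(evanno_delta_k(tibble::tibble(k = 1:3, lnp = 1:3)), "2 runs")
})

test_that("cluster relabeling is recovered by greedy matching", {
  set.seed(6)
  q <- matrix(rgamma(60, 1), 20, 3)
  q <- q / rowSums(q)
  perm <- c(3, 1, 2)
  expect_equal(match_clusters(q, q[, perm]), order(perm))
  expect_equal(q[, perm][, match_clusters(q, q[, perm])], q)
})
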