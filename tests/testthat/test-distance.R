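test_that("harmonization keeps shared loci and zero-fills absent alleles", {
  full <- kuwait_frequencies()
  thirteen <- c("CSF1PO", "D13S317", "D16S539", "D18S51", "D21S11", "D3S1358",
                "D5S818", "D7S820", "D8S1179", "FGA", "TH01", "TPOX", "vWA")
  partial <- full[full$locus %in% thirteen, ]
  pan <- harmonize_panel(list(kw = full, other = partial))
  expect_equal(sort(attr(pan, "shared_loci")), sort(thirteen))

  # identical panels harmonize to themselves
  pan2 <- harmonize_panel(list(a = full, b = full))
  expect_equal(length(attr(pan2, "shared_loci")), 23)
  expect_equal(nrow(pan2), 2 * nrow(full))
  expect_true(all(pan2$freq > 0))

  # an allele present in one population only gets an explicit zero
  f1 <- freq_tbl(c("10" = 0.5, "11" = 0.5))
  f2 <- freq_tbl(c("10" = 1))
  pan3 <- harmonize_panel(list(a = f1, b = f2))
  expect_equal(pan3$freq[pan3$population == "b" & pan3$allele == "11"], 0)

  expect_error(harmonize_panel(list(a = f1, b = freq_tbl(c("9" = 1), locus = "Lx"))),
               "shared")
  expect_error(harmonize_panel(list(a = full, b = partial), loci = "SE33"),
               class = "strpopgen_domain_error")
})

test_that("Nei DA honours its closed form and bounds", {
  f1 <- freq_tbl(c("10" = 0.5, "11" = 0.5))
  expect_equal(nei_da(list(a = f1, b = f1))["a", "b"], 0)

  disj <- harmonize_panel(list(a = freq_tbl(c("10" = 1)),
                               b = freq_tbl(c("11" = 1))))
  expect_equal(nei_da(disj)["a", "b"], 1)

  f2 <- freq_tbl(c("10" = 0.9, "11" = 0.1))
  d <- nei_da(list(a = f1, b = f2))["a", "b"]
  expect_equal(d, 1 - (sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)

  # symmetry, bounds, zero iff identical -- over random panels
  for (s in 1:5) {
    pans <- lapply(1:4, function(i) draw_subpop_frequencies(kuwait_subset(4),
                                                            0.1, seed = 10 * s + i))
    names(pans) <- paste0("p", 1:4)
    dm <- nei_da(harmonize_panel(pans))
    expect_equal(unclass(dm), t(unclass(dm)))
    expect_true(all(dm >= 0 & dm <= 1))
    expect_equal(diag(dm), setNames(rep(0, 4), names(pans)))
    expect_true(all(dm[upper.tri(dm)] > 1e-12))
  }
})

test_that("mean DA grows with the simulated divergence parameter", {
  base <- kuwait_subset(6)
  mean_da <- vapply(c(0.01, 0.05, 0.1, 0.2), function(fst) {
    dms <- vapply(1:5, function(s) {
      a <- draw_subpop_frequencies(base, fst, seed = 100 * s + 1)
      b <- draw_subpop_frequencies(base, fst, seed = 100 * s + 2)
      nei_da(list(a = a, b = b))["a", "b"]
    }, numeric(1))
    mean(dms)
  }, numeric(1))
  expect_true(all(diff(mean_da) > 0))
})

test_that("neighbour joining recovers known trees exactly", {
  # hand-built additive matrix from the 4-taxon tree ((a:1,b:2):1,(c:3,d:4))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5
  d["a", "d"] <- d["d", "a"] <- 6
  d["b", "c"] <- d["c", "b"] <- 6
  d["b", "d"] <- d["d", "b"] <- 7
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- nj_tree(d)
  coph <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(coph, d, tolerance = 1e-9)

  # three equidistant taxa -> star with branches 1,1,1
  d3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  tr3 <- nj_tree(d3)
  expect_equal(sort(tr3$edge.length), c(1, 1, 1))

  # two taxa -> a single split of total length d
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- nj_tree(d2)
  expect_equal(sum(tr2$edge.length), 0.4)
  expect_setequal(tr2$tip.label, c("x", "y"))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), class = "strpopgen_domain_error")
})

test_that("newick serialization of an NJ tree round-trips", {
  pans <- lapply(1:4, function(i) draw_subpop_frequencies(kuwait_subset(3),
                                                          0.05, seed = i))
  names(pans) <- paste0("pop", 1:4)
  tr <- nj_tree(nei_da(harmonize_panel(pans)))
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-6)
})

test_that("population PCA separates a diverged outlier on PC1", {
  base <- kuwait_subset(8)
  hits <- 0
  for (s in 1:50) {
    pans <- c(lapply(1:4, function(i)
      draw_subpop_frequencies(base, 0.02, seed = 1000 * s + i)),
      list(draw_subpop_frequencies(base, 0.3, seed = 1000 * s + 99)))
    names(pans) <- c(paste0("bg", 1:4), "outlier")
    pca <- pca_populations(harmonize_panel(pans))
    sc <- tidy(pca)
    if (sc$population[which.max(abs(sc$PC1))] == "outlier") hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("population PCA satisfies its structural identities", {
  f <- kuwait_subset(5)
  pans <- list(a = f, b = f,
               c = draw_subpop_frequencies(f, 0.1, seed = 3))
  pca <- pca_populations(harmonize_panel(pans), n_components = 2)
  sc <- tidy(pca)
  expect_equal(unlist(sc[sc$population == "a", -1]),
               unlist(sc[sc$population == "b", -1]), tolerance = 1e-9)
  expect_equal(sum(pca$explained_variance_all), 1, tolerance = 1e-9)
  expect_error(pca_populations(harmonize_panel(pans), n_components = 10),
               class = "strpopgen_domain_error")
})

test_that("individual PCA separates strong structure and not panmixia", {
  base <- kuwait_subset(10)
  sub <- tibble::tibble(label = c("p1", "p2"), size = c(100, 100), f = 0.3)
  g <- simulate_genotypes(base, subpops = sub, seed = 77)
  pca <- pca_individuals(g)
  sc <- tidy(pca)
  lab <- sc$subgroup
  # best 1-D threshold on PC1
  y <- (lab == "p1")[order(sc$PC1)]
  n_tot <- length(y)
  cum <- c(0, cumsum(y))
  correct <- cum + (n_tot - sum(y)) - (seq_along(cum) - 1 - cum)
  acc <- max(correct, n_tot - correct) / n_tot
  expect_gte(acc, 0.9)

  # duplicated individuals land on identical coordinates
  g2 <- dplyr::bind_rows(g, g |> dplyr::mutate(sample_id = paste0(sample_id, "_dup")))
  pca2 <- pca_individuals(g2)
  sc2 <- tidy(pca2)
  orig <- sc2[!grepl("_dup$", sc2$sample_id), c("PC1", "PC2")]
  dup <- sc2[grepl("_dup$", sc2$sample_id), c("PC1", "PC2")]
  expect_equal(orig, dup, tolerance = 1e-9, ignore_attr = TRUE)

  # panmictic data: arbitrary labels show no silhouette structure on PC1-2
  g0 <- simulate_genotypes(base, subpops = tibble::tibble(
    label = c("p1", "p2"), size = c(100, 100), f = 0), seed = 78)
  pca0 <- pca_individuals(g0)
  sc0 <- tidy(pca0)
  s <- silhouette_mean(as.matrix(sc0[c("PC1", "PC2")]), sc0$subgroup)
  expect_lt(abs(s), 0.1)
})
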