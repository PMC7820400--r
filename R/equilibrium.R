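# Conditional probability of a genotype array given its allele counts:
#   P = n! * prod_i(m_i!) * 2^h / ((2n)! * prod_{i<=j}(n_ij!))
# computed in log space. `het` is the number of heterozygotes, `lfact_cells`
# the sum of log-factorials of the genotype counts.
.log_array_prob <- function(const, het, lfact_cells) {
  const + het * log(2) - lfact_cells
}

# Enumerate all genotype-count arrays compatible with allele counts `m`.
# Returns a list with vectors `het` and `lfact`, or NULL if the number of
# arrays exceeds `cap`.
.enumerate_arrays <- function(m, cap = 1e5) {
  k <- length(m)
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  het <- numeric(0)
  lfact <- numeric(0)
  count <- 0L
  overflow <- FALSE
  rec <- function(ci, rem, h, lf) {
    if (overflow) return()
    if (ci > nrow(cells)) {
      if (all(rem == 0)) {
        count <<- count + 1L
        if (count > cap) { overflow <<- TRUE; return() }
        het[count] <<- h
        lfact[count] <<- lf
      }
      return()
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    last_of_row <- (j == k)
    if (i == j) {
      cmax <- rem[i] %/% 2
      cs <- if (last_of_row) {
        if (rem[i] %% 2 == 0) rem[i] %/% 2 else -1
      } else 0:cmax
    } else {
      cmax <- min(rem[i], rem[j])
      cs <- if (last_of_row) rem[i] else 0:cmax
    }
    for (c in cs) {
      if (c < 0 || c > cmax) next
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2 * c
      else { rem2[i] <- rem2[i] - c; rem2[j] <- rem2[j] - c }
      rec(ci + 1, rem2,
          h + if (i == j) 0 else c,
          lf + lfactorial(c))
    }
  }
  rec(1, m, 0, 0)
  if (overflow) NULL else list(het = het, lfact = lfact)
}

# HWE test for one locus given the two allele-code vectors of called
# individuals.
.hwe_one <- function(a1, a2, n_perm, max_arrays) {
  lev <- sort(unique(c(a1, a2)))
  k <- length(lev)
  n <- length(a1)
  if (k == 1) {
    return(tibble(statistic = 1, p_value = 1, method = "exhaustive",
                  n_perm_used = 0L, monomorphic = TRUE))
  }
  x1 <- match(a1, lev); x2 <- match(a2, lev)
  m <- tabulate(c(x1, x2), nbins = k)
  const <- lfactorial(n) + sum(lfactorial(m)) - lfactorial(2 * n)
  key <- pmin(x1, x2) * (k + 1) + pmax(x1, x2)
  obs_cells <- tabulate(factor(key), nbins = length(unique(key)))
  lp_obs <- .log_array_prob(const, sum(x1 != x2), sum(lfactorial(obs_cells)))
  # enumeration is worthwhile only where the array space is small: with two
  # alleles it is linear in n, otherwise it grows explosively with k and n
  tractable <- k == 2 || (k <= 6 && n <= 12)
  enum <- if (tractable) .enumerate_arrays(m, cap = max_arrays) else NULL
  if (!is.null(enum)) {
    lp_all <- .log_array_prob(const, enum$het, enum$lfact)
    p <- sum(exp(lp_all[lp_all <= lp_obs + 1e-9]))
    return(tibble(statistic = exp(lp_obs), p_value = min(p, 1),
                  method = "exhaustive", n_perm_used = 0L, monomorphic = FALSE))
  }
  pool <- c(x1, x2)
  idx1 <- seq_len(n) * 2 - 1
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    p1 <- perm[idx1]; p2 <- perm[idx1 + 1]
    kk <- pmin(p1, p2) * (k + 1) + pmax(p1, p2)
    cells <- tabulate(factor(kk), nbins = length(unique(kk)))
    lp <- .log_array_prob(const, sum(p1 != p2), sum(lfactorial(cells)))
    if (lp <= lp_obs + 1e-9) hits <- hits + 1L
  }
  tibble(statistic = exp(lp_obs), p_value = (hits + 1) / (n_perm + 1),
         method = "permutation", n_perm_used = as.integer(n_perm),
         monomorphic = FALSE)
}

#' Hardy-Weinberg exact test per locus
#'
#' The conditional exact test: the probability of the observed genotype
#' array given its allele counts is compared against the distribution of
#' that probability over all arrays with the same allele counts. When the
#' number of distinct arrays is at most `max_arrays` the null distribution
#' is enumerated exhaustively (the p-value is then seed-independent and
#' `n_perm_used = 0`); otherwise it is estimated by shuffling the pooled
#' gene copies into pairs `n_perm` times, counting the observed array in
#' both numerator and denominator so `p >= 1/(n_perm + 1)`. A monomorphic
#' locus admits a single array and is reported as `p = 1` with a flag.
#'
#' @param g A long genotype tibble.
#' @param loci Loci to test (default: all).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Integer seed for the Monte-Carlo null.
#' @param max_arrays Exhaustive-enumeration threshold on the number of
#'   distinct genotype arrays.
#' @return A tibble: `locus`, `statistic` (the conditional probability of
#'   the observed array), `p_value`, `method`, `n_perm_used`, `seed`,
#'   `monomorphic`.
#' @export
hwe_exact_test <- function(g, loci = NULL, n_perm = 1e5, seed = 1,
                           max_arrays = 1e5) {
  g <- validate_genotypes(g)
  loci <- loci %||% unique(g$locus)
  run <- function() {
    map(loci, function(l) {
      gl <- g |> filter(.data$locus == l, !is.na(.data$allele_1),
                        .data$allele_1 != "OL", .data$allele_2 != "OL")
      if (nrow(gl) < 2) abort(paste0("fewer than 2 calls at locus ", l))
      .hwe_one(gl$allele_1, gl$allele_2, n_perm, max_arrays) |>
        mutate(locus = l, .before = 1)
    }) |> list_rbind()
  }
  res <- withr::with_seed(seed, run())
  res |> mutate(seed = seed)
}

# G statistic on a two-locus genotype contingency table vs independence.
.g_stat <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- tab
  2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
}

#' Pairwise linkage-disequilibrium permutation test
#'
#' A log-likelihood-ratio (G) test of independence on the joint two-locus
#' genotype contingency table, with the null distribution obtained by
#' permuting one locus's genotypes across individuals. This tests
#' association between single-locus genotypes without requiring gametic
#' phase. The observed table counts toward the p-value, so
#' `p >= 1/(n_perm + 1)`. If either locus is monomorphic the table is
#' degenerate and `p = 1` is reported with a flag.
#'
#' @param g A long genotype tibble.
#' @param pairs Optional two-column matrix/data frame of locus pairs
#'   (default: all `choose(L, 2)` pairs).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble: `locus_a`, `locus_b`, `statistic` (G), `p_value`,
#'   `n_perm_used`, `seed`, `monomorphic`.
#' @export
ld_test <- function(g, pairs = NULL, n_perm = 1000, seed = 1) {
  g <- validate_genotypes(g)
  loci <- unique(g$locus)
  if (is.null(pairs)) {
    if (length(loci) < 2) abort("need at least two loci")
    pairs <- t(combn(loci, 2))
  }
  pairs <- as.matrix(pairs)
  geno <- g |>
    filter(!is.na(.data$allele_1), .data$allele_1 != "OL", .data$allele_2 != "OL") |>
    mutate(geno = paste(pmin(.data$allele_1, .data$allele_2),
                        pmax(.data$allele_1, .data$allele_2), sep = "/"))
  run <- function() {
    map(seq_len(nrow(pairs)), function(r) {
      la <- pairs[r, 1]; lb <- pairs[r, 2]
      ga <- geno |> filter(.data$locus == la)
      gb <- geno |> filter(.data$locus == lb)
      shared <- intersect(ga$sample_id, gb$sample_id)
      if (length(shared) < 2) abort(paste0("fewer than 2 shared calls for ", la, "/", lb))
      xa <- ga$geno[match(shared, ga$sample_id)]
      xb <- gb$geno[match(shared, gb$sample_id)]
      mono_a <- length(unique(c(ga$allele_1, ga$allele_2))) == 1
      mono_b <- length(unique(c(gb$allele_1, gb$allele_2))) == 1
      if (mono_a || mono_b) {
        return(tibble(locus_a = la, locus_b = lb, statistic = 0,
                      p_value = 1, n_perm_used = 0L, monomorphic = TRUE))
      }
      fa <- factor(xa); fb <- factor(xb)
      g_obs <- .g_stat(table(fa, fb))
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (.g_stat(table(fa, sample(fb))) >= g_obs - 1e-9) hits <- hits + 1L
      }
      tibble(locus_a = la, locus_b = lb, statistic = g_obs,
             p_value = (hits + 1) / (n_perm + 1),
             n_perm_used = as.integer(n_perm), monomorphic = FALSE)
    }) |> list_rbind()
  }
  withr::with_seed(seed, run()) |> mutate(seed = seed)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Nominal significance level.
#' @param n_tests Number of tests (`>= 1`).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni(0.05, n_pairs(23)) # 0.05 / 253
#' @export
bonferroni <- function(alpha, n_tests) {
  if (n_tests < 1) abort("n_tests must be >= 1", class = "strpopgen_domain_error")
  alpha / n_tests
}

#' Number of unordered locus pairs
#'
#' @param n_loci Number of loci.
#' @return `n_loci * (n_loci - 1) / 2`.
#' @export
n_pairs <- function(n_loci) n_loci * (n_loci - 1) / 2
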