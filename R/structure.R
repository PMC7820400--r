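#' Admixture-model Bayesian clustering of multilocus genotypes
#'
#' A Gibbs sampler for the admixture model with uncorrelated cluster allele
#' frequencies: each individual `i` has ancestry proportions `q_i` over `K`
#' clusters, each gene copy draws its cluster of origin `z` from `q_i`, and
#' an allele from the cluster's frequency vector `p_{k,l}`. One sweep
#' samples (i) every gene copy's `z` with
#' `Pr(z = k) proportional to q_ik * p_kla`, (ii) `p` from
#' `Dirichlet(lambda + cluster allele counts)`, (iii) each `q_i` from
#' `Dirichlet(alpha + per-individual cluster counts)` and (iv) the shared
#' admixture parameter `alpha` by symmetric random-walk Metropolis on
#' `log(alpha)`. No population prior is used. Reported `q` and `p` are
#' posterior means over the recorded (post-burn-in, thinned) sweeps.
#'
#' @param g A long genotype tibble.
#' @param k Number of clusters (`>= 1`).
#' @param burnin,iters,thin MCMC schedule: `burnin` sweeps discarded, then
#'   `iters` sweeps of which every `thin`-th is recorded.
#' @param lambda Dirichlet prior parameter for cluster allele frequencies.
#' @param alpha_init,alpha_step,alpha_max Initial value, log-scale proposal
#'   SD and upper prior bound for `alpha`.
#' @param seed Integer seed; runs are deterministic given the seed.
#' @return A `structure_run` object: `k`, `q` (posterior-mean ancestry
#'   matrix with sample ids), `p` (per-locus posterior-mean cluster allele
#'   frequencies), `loglik` (recorded data log-likelihood trace),
#'   `alpha_trace`, `lnp` (the model-evidence estimate of
#'   [lnp_estimate()]), `seed` and the schedule.
#' @examples
#' \donttest{
#' g <- simulate_genotypes(kuwait_frequencies(), n = 40, seed = 1)
#' run <- run_structure(g, k = 2, burnin = 50, iters = 100, seed = 1)
#' }
#' @export
run_structure <- function(g, k, burnin = 5000, iters = 10000, thin = 10,
                          lambda = 1, alpha_init = 1, alpha_step = 0.05,
                          alpha_max = 10, seed = 1) {
  g <- validate_genotypes(g)
  if (k < 1) abort("k must be >= 1", class = "strpopgen_domain_error")
  loci <- unique(g$locus)
  samples <- unique(g$sample_id)
  n <- length(samples)
  nl <- length(loci)
  lev <- vector("list", nl)
  a1 <- a2 <- matrix(NA_integer_, n, nl)
  for (j in seq_len(nl)) {
    gl <- g[g$locus == loci[j], ]
    gl$allele_1[which(gl$allele_1 == "OL")] <- NA
    gl$allele_2[which(gl$allele_2 == "OL")] <- NA
    gl$allele_2[which(is.na(gl$allele_1))] <- NA
    gl$allele_1[which(is.na(gl$allele_2))] <- NA
    lev[[j]] <- sort(unique(c(gl$allele_1, gl$allele_2)))
    ii <- match(gl$sample_id, samples)
    a1[ii, j] <- match(gl$allele_1, lev[[j]])
    a2[ii, j] <- match(gl$allele_2, lev[[j]])
  }
  n_rec <- iters %/% thin
  if (n_rec < 2) abort("schedule must record at least 2 sweeps")

  rdirich_rows <- function(shape_mat) {
    gmat <- matrix(rgamma(length(shape_mat), shape = shape_mat),
                   nrow = nrow(shape_mat))
    gmat[gmat == 0] <- 1e-300
    gmat / rowSums(gmat)
  }

  run <- function() {
    z1 <- matrix(sample.int(k, n * nl, replace = TRUE), n, nl)
    z2 <- matrix(sample.int(k, n * nl, replace = TRUE), n, nl)
    z1[is.na(a1)] <- NA
    z2[is.na(a2)] <- NA
    alpha <- alpha_init
    q <- matrix(1 / k, n, k)
    p <- vector("list", nl)
    q_sum <- matrix(0, n, k)
    p_sum <- map(lev, ~ matrix(0, k, length(.x)))
    loglik <- numeric(n_rec)
    alpha_trace <- numeric(n_rec)
    rec <- 0L

    for (it in seq_len(burnin + iters)) {
      # p | z: cluster-by-allele counts per locus
      for (j in seq_len(nl)) {
        na <- length(lev[[j]])
        cnt <- tabulate((c(a1[, j], a2[, j]) - 1) * k + c(z1[, j], z2[, j]),
                        nbins = k * na)
        p[[j]] <- rdirich_rows(matrix(lambda + cnt, nrow = k))
      }
      # q | z: per-individual cluster counts
      ccnt <- matrix(0, n, k)
      for (kk in seq_len(k)) {
        ccnt[, kk] <- rowSums(z1 == kk, na.rm = TRUE) +
          rowSums(z2 == kk, na.rm = TRUE)
      }
      q <- rdirich_rows(alpha + ccnt)
      # z | q, p per gene copy, vectorized over individuals
      for (j in seq_len(nl)) {
        pj <- p[[j]]
        for (copy in 1:2) {
          a <- if (copy == 1) a1[, j] else a2[, j]
          ok <- !is.na(a)
          if (!any(ok)) next
          w <- q[ok, , drop = FALSE] * t(pj[, a[ok], drop = FALSE])
          cum <- w
          if (k > 1) for (kk in 2:k) cum[, kk] <- cum[, kk - 1] + w[, kk]
          u <- runif(sum(ok)) * cum[, k]
          znew <- rowSums(cum < u) + 1L
          if (copy == 1) z1[ok, j] <- znew else z2[ok, j] <- znew
        }
      }
      # alpha | q: random-walk Metropolis on log(alpha), uniform(0, alpha_max]
      if (k > 1) {
        s_logq <- sum(log(pmax(q, 1e-300)))
        la_target <- function(a) {
          n * (lgamma(k * a) - k * lgamma(a)) + (a - 1) * s_logq
        }
        prop <- exp(log(alpha) + rnorm(1, 0, alpha_step))
        if (is.finite(prop) && prop > 0 && prop <= alpha_max) {
          lr <- la_target(prop) - la_target(alpha) + log(prop) - log(alpha)
          if (is.finite(lr) && log(runif(1)) < lr) alpha <- prop
        }
      }
      # record
      if (it > burnin && (it - burnin) %% thin == 0) {
        rec <- rec + 1L
        ll <- 0
        for (j in seq_len(nl)) {
          pj <- p[[j]]
          for (copy in 1:2) {
            a <- if (copy == 1) a1[, j] else a2[, j]
            ok <- !is.na(a)
            if (!any(ok)) next
            mix <- rowSums(q[ok, , drop = FALSE] * t(pj[, a[ok], drop = FALSE]))
            ll <- ll + sum(log(mix))
          }
        }
        loglik[rec] <- ll
        alpha_trace[rec] <- alpha
        q_sum <- q_sum + q
        for (j in seq_len(nl)) p_sum[[j]] <- p_sum[[j]] + p[[j]]
      }
    }
    q_mean <- q_sum / rec
    p_mean <- map(p_sum, ~ .x / rec)
    list(q = q_mean, p = p_mean, loglik = loglik, alpha_trace = alpha_trace)
  }

  st <- withr::with_seed(seed, run())
  rownames(st$q) <- samples
  colnames(st$q) <- paste0("cluster_", seq_len(k))
  for (j in seq_len(nl)) {
    dimnames(st$p[[j]]) <- list(paste0("cluster_", seq_len(k)), lev[[j]])
  }
  names(st$p) <- loci
  structure(
    list(k = k, q = st$q, p = st$p, loglik = st$loglik,
         alpha_trace = st$alpha_trace, lnp = lnp_estimate(st$loglik),
         seed = seed, burnin = burnin, iters = iters, thin = thin,
         samples = samples),
    class = "structure_run"
  )
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("<structure_run> K = %d, %d individuals, Ln P(X|K) = %.2f (seed %d)\n",
              x$k, nrow(x$q), x$lnp, x$seed))
  invisible(x)
}

#' @method tidy structure_run
#' @export
tidy.structure_run <- function(x, ...) {
  as_tibble(x$q) |>
    mutate(sample_id = rownames(x$q), .before = 1) |>
    pivot_longer(-"sample_id", names_to = "cluster", values_to = "q")
}

#' @method glance structure_run
#' @export
glance.structure_run <- function(x, ...) {
  tibble(k = x$k, lnp = x$lnp, mean_alpha = mean(x$alpha_trace),
         n_recorded = length(x$loglik), seed = x$seed)
}

#' @method autoplot structure_run
#' @export
autoplot.structure_run <- function(object, ...) {
  td <- tidy(object)
  td$sample_id <- factor(td$sample_id, levels = object$samples)
  ggplot(td, aes(.data$sample_id, .data$q, fill = .data$cluster)) +
    geom_col(width = 1) +
    labs(x = NULL, y = "ancestry proportion") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Model-evidence estimate from a log-likelihood trace
#'
#' `mean(trace) - var(trace) / 2` (sample variance): the estimator of
#' Ln P(X|K) reported by the reference clustering program, which penalises
#' the mean recorded log-likelihood by half its variance.
#'
#' @param trace Numeric vector of recorded log-likelihood values (`>= 2`).
#' @return A single number.
#' @examples
#' lnp_estimate(c(-10, -12)) # mean -11, variance 2 -> -12
#' @export
lnp_estimate <- function(trace) {
  if (length(trace) < 2) abort("need at least 2 recorded values")
  mean(trace) - var(trace) / 2
}

#' Evanno delta-K model selection table
#'
#' Given replicate Ln P(X|K) estimates over a contiguous range of K:
#' `L'(K) = mean L(K) - mean L(K-1)`,
#' `|L''(K)| = |mean L(K+1) - 2 mean L(K) + mean L(K-1)|`, and
#' `deltaK = |L''(K)| / SD(L(K))`, defined for interior K only. The best K
#' is the interior K maximising deltaK.
#'
#' @param runs A tibble with columns `k` and `lnp` (one row per replicate
#'   run), or a named list mapping K to a vector of estimates.
#' @return A tibble `k`, `n_runs`, `mean_lnp`, `sd_lnp`, `l_prime`,
#'   `l_second_abs`, `delta_k`, with attribute `"best_k"`. A zero SD at
#'   some K leaves its deltaK `NA` with a warning.
#' @examples
#' evanno_delta_k(tibble::tibble(
#'   k = rep(1:4, each = 2),
#'   lnp = rep(c(-1000, -500, -495, -494), each = 2)
#' ))
#' @export
evanno_delta_k <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs)) {
    runs <- tibble(k = rep(as.integer(names(runs)), lengths(runs)),
                   lnp = unlist(runs, use.names = FALSE))
  }
  if (!all(c("k", "lnp") %in% names(runs))) abort("runs needs columns k and lnp")
  agg <- runs |>
    group_by(.data$k) |>
    summarise(n_runs = dplyr::n(), mean_lnp = mean(.data$lnp),
              sd_lnp = sd(.data$lnp), .groups = "drop") |>
    arrange(.data$k)
  ks <- agg$k
  if (length(ks) < 3) abort("need at least 3 values of K")
  if (!all(diff(ks) == 1)) abort("K range must be contiguous")
  if (any(agg$n_runs < 2)) abort("need >= 2 runs per K")
  m <- agg$mean_lnp
  interior <- seq(2, length(ks) - 1)
  l_prime <- c(NA, diff(m))
  l_second <- rep(NA_real_, length(ks))
  l_second[interior] <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1])
  delta <- l_second / agg$sd_lnp
  if (any(agg$sd_lnp[interior] == 0 & !is.na(l_second[interior]))) {
    warn("zero SD at some K: deltaK undefined there")
    delta[agg$sd_lnp == 0] <- NA
  }
  out <- agg |>
    mutate(l_prime = l_prime, l_second_abs = l_second, delta_k = delta)
  best <- out$k[which.max(out$delta_k)]
  attr(out, "best_k") <- if (length(best)) best else NA_integer_
  out
}

#' Plot an Evanno table
#'
#' Delta-K against K; the peak marks the selected number of clusters.
#'
#' @param ev An [evanno_delta_k()] table.
#' @return A ggplot.
#' @export
plot_evanno <- function(ev) {
  ggplot(ev[!is.na(ev$delta_k), ], aes(.data$k, .data$delta_k)) +
    geom_line() +
    geom_point() +
    labs(x = "K", y = expression(Delta * K)) +
    theme_minimal()
}

#' Align cluster labels between two ancestry matrices
#'
#' Clusters are identifiable only up to label permutation; for cross-run
#' comparison this greedily matches columns of `q` to columns of `q_ref` by
#' smallest summed absolute difference.
#'
#' @param q_ref,q Ancestry matrices with identical dimensions.
#' @return An integer permutation `perm` such that `q[, perm]` aligns with
#'   `q_ref`.
#' @export
match_clusters <- function(q_ref, q) {
  stopifnot(all(dim(q_ref) == dim(q)))
  k <- ncol(q)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cost[i, j] <- sum(abs(q_ref[, i] - q[, j]))
  }
  perm <- integer(k)
  row_done <- col_done <- rep(FALSE, k)
  for (step in seq_len(k)) {
    c2 <- cost
    c2[row_done, ] <- Inf
    c2[, col_done] <- Inf
    ij <- which(c2 == min(c2), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    row_done[ij[1]] <- TRUE
    col_done[ij[2]] <- TRUE
  }
  perm
}
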