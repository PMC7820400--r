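# Shared builders and independent oracles used across test files.

# genotype tibble from explicit calls: list of c(a1, a2) per sample, one locus
geno_one_locus <- function(calls, locus = "L1") {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(calls)),
    locus = locus,
    allele_1 = vapply(calls, function(x) x[1], character(1)),
    allele_2 = vapply(calls, function(x) x[2], character(1))
  )
}

# two-allele genotype table from genotype counts
geno_from_counts <- function(n_aa, n_ab, n_bb, locus = "L1",
                             a = "10", b = "11") {
  calls <- c(replicate(n_aa, c(a, a), simplify = FALSE),
             replicate(n_ab, c(a, b), simplify = FALSE),
             replicate(n_bb, c(b, b), simplify = FALSE))
  geno_one_locus(calls, locus)
}

# frequency tibble from a named vector of frequencies
freq_tbl <- function(p, locus = "L1", n = 800) {
  tibble::tibble(locus = locus, allele = names(p), freq = unname(p), n = n)
}

# Independent HWE oracle for TWO alleles: enumerate arrays by heterozygote
# count h (h has the parity of the minor allele count), using the
# conditional-probability formula directly.
hwe_oracle_two_alleles <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  m_a <- 2 * n_aa + n_ab
  m_b <- 2 * n_bb + n_ab
  prob_of <- function(h) {
    aa <- (m_a - h) / 2
    bb <- (m_b - h) / 2
    if (aa < 0 || bb < 0 || aa != floor(aa) || bb != floor(bb)) return(NA_real_)
    exp(lfactorial(n) + lfactorial(m_a) + lfactorial(m_b) + h * log(2) -
          lfactorial(2 * n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb))
  }
  hs <- seq(m_a %% 2, min(m_a, m_b), by = 2)
  probs <- vapply(hs, prob_of, numeric(1))
  p_obs <- prob_of(n_ab)
  sum(probs[probs <= p_obs + 1e-12], na.rm = TRUE)
}

# mean silhouette width on a score matrix given integer labels
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# subset of the packaged frequency table, for cheaper simulations
kuwait_subset <- function(n_loci = 10) {
  f <- kuwait_frequencies()
  keep <- unique(f$locus)[seq_len(n_loci)]
  f[f$locus %in% keep, ]
}
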