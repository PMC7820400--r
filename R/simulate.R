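#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Given ancestral frequencies `p` and a divergence parameter `f_st`, each
#' locus's subpopulation frequencies are drawn from
#' `Dirichlet(p * (1 - F) / F)`, so each allele's frequency has mean `p` and
#' variance `F * p * (1 - p)` -- the standard forensic-genetics model of
#' population substructure. `f_st = 0` is the defined limit and returns the
#' base table unchanged.
#'
#' @param f A frequency tibble (see [validate_frequencies()]).
#' @param f_st Divergence parameter in `[0, 1)`.
#' @param seed Optional integer seed for reproducible draws.
#' @return A frequency tibble with the same loci/alleles and `n`, with
#'   `freq` replaced by the drawn subpopulation frequencies (and `count`
#'   dropped).
#' @examples
#' draw_subpop_frequencies(kuwait_frequencies(), f_st = 0.05, seed = 1)
#' @export
draw_subpop_frequencies <- function(f, f_st, seed = NULL) {
  f <- validate_frequencies(f)
  if (!is.numeric(f_st) || length(f_st) != 1 || f_st < 0 || f_st >= 1) {
    abort("f_st must be a single value in [0, 1)", class = "strpopgen_domain_error")
  }
  if (f_st == 0) return(f |> select("locus", "allele", "freq", "n"))
  bn_draw <- function(p) {
    g <- rgamma(length(p), shape = p * (1 - f_st) / f_st)
    g / sum(g)
  }
  draw <- function() {
    f |>
      group_by(.data$locus) |>
      mutate(freq = bn_draw(.data$freq)) |>
      ungroup() |>
      select("locus", "allele", "freq", "n")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate diploid STR genotypes
#'
#' Draws each individual's two alleles per locus independently from the
#' (sub)population frequency table -- Hardy-Weinberg equilibrium within
#' population, all loci unlinked. Optional subpopulations diverge from the
#' base table under the Balding-Nichols model ([draw_subpop_frequencies()]);
#' optional admixed individuals draw the population of origin of *each gene
#' copy* independently from their ancestry proportions, matching the
#' admixture model used by [run_structure()].
#'
#' @param f Base frequency tibble.
#' @param n Number of individuals (single unstructured population). Ignored
#'   when `subpops` is given.
#' @param subpops Optional tibble `label`, `size`, `f` giving subpopulation
#'   labels, sizes and Balding-Nichols divergence parameters.
#' @param admixed Optional tibble with columns `size` and one column per
#'   subpopulation label giving ancestry proportions (rows sum to 1); each
#'   row adds `size` admixed individuals with subgroup label `"admixed"` (or
#'   a `label` column if present).
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return A long genotype tibble with a `subgroup` column.
#' @examples
#' g <- simulate_genotypes(kuwait_frequencies(), n = 20, seed = 1)
#' @export
simulate_genotypes <- function(f, n = NULL, subpops = NULL, admixed = NULL,
                               seed = NULL) {
  f <- validate_frequencies(f)
  loci <- unique(f$locus)
  run <- function() {
    if (is.null(subpops)) {
      if (is.null(n) || n < 1) abort("n must be a positive integer")
      pop_freqs <- list(all = f)
      groups <- tibble(label = "all", size = as.integer(n))
    } else {
      if (!all(c("label", "size", "f") %in% names(subpops))) {
        abort("subpops needs columns label, size, f")
      }
      pop_freqs <- setNames(
        map(seq_len(nrow(subpops)),
            ~ draw_subpop_frequencies(f, subpops$f[.x])),
        subpops$label
      )
      groups <- tibble(label = subpops$label, size = as.integer(subpops$size))
      if (!is.null(n) && is.null(admixed) && sum(groups$size) != n) {
        abort("subpop sizes must sum to n", class = "strpopgen_domain_error")
      }
    }
    draw_pop <- function(label, size) {
      ff <- pop_freqs[[label]]
      calls <- map(loci, function(l) {
        fl <- ff[ff$locus == l, ]
        if (nrow(fl) == 0) abort(paste0("empty frequency map at locus ", l))
        a <- sample(fl$allele, 2 * size, replace = TRUE, prob = fl$freq)
        tibble(locus = l, allele_1 = a[seq_len(size)],
               allele_2 = a[size + seq_len(size)], row = seq_len(size))
      }) |> list_rbind()
      calls |> mutate(subgroup = label)
    }
    parts <- map2(groups$label, groups$size, draw_pop)
    offsets <- cumsum(c(0, groups$size))
    parts <- imap(parts, function(p, i) mutate(p, row = .data$row + offsets[[i]]))
    if (!is.null(admixed)) {
      if (is.null(subpops)) abort("admixed requires subpops")
      labs <- names(pop_freqs)
      if (!all(labs %in% names(admixed))) {
        abort("admixed needs one ancestry column per subpop label")
      }
      qs <- as.matrix(admixed[labs])
      if (any(abs(rowSums(qs) - 1) > 1e-8)) abort("ancestry rows must sum to 1")
      off <- sum(groups$size)
      for (r in seq_len(nrow(admixed))) {
        size <- as.integer(admixed$size[r])
        lab <- if ("label" %in% names(admixed)) admixed$label[r] else "admixed"
        calls <- map(loci, function(l) {
          # each gene copy's population of origin drawn from the ancestry vector
          o1 <- sample(labs, size, replace = TRUE, prob = qs[r, ])
          o2 <- sample(labs, size, replace = TRUE, prob = qs[r, ])
          draw_from <- function(origin) {
            vapply(origin, function(lb) {
              fl <- pop_freqs[[lb]]
              fl <- fl[fl$locus == l, ]
              sample(fl$allele, 1, prob = fl$freq)
            }, character(1))
          }
          tibble(locus = l, allele_1 = draw_from(o1), allele_2 = draw_from(o2),
                 row = seq_len(size))
        }) |> list_rbind()
        parts <- c(parts, list(calls |> mutate(subgroup = lab, row = .data$row + off)))
        off <- off + size
      }
    }
    all <- list_rbind(parts)
    total <- max(all$row)
    ids <- sprintf("ind_%04d", seq_len(total))
    all |>
      mutate(sample_id = ids[.data$row]) |>
      select("sample_id", "subgroup", "locus", "allele_1", "allele_2") |>
      arrange(match(.data$sample_id, ids), match(.data$locus, loci))
  }
  g <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  validate_genotypes(g)
}

#' Weir-Cockerham fixation index
#'
#' Multi-allelic, multi-locus theta (the variance-components estimator of
#' F_ST), computed by summing the among-population component `a` and total
#' `a + b + c` over alleles and loci. Used to check that simulated
#' subpopulation divergence matches the Balding-Nichols parameter it was
#' generated with.
#'
#' @param g A long genotype tibble with a grouping column.
#' @param by Name of the grouping column (default `"subgroup"`).
#' @return A single numeric theta estimate.
#' @export
wc_fst <- function(g, by = "subgroup") {
  g <- validate_genotypes(g)
  if (!by %in% names(g)) abort(paste0("missing grouping column ", sQuote(by)))
  pops <- unique(g[[by]])
  r <- length(pops)
  if (r < 2) abort("need at least two populations")
  num <- den <- 0
  for (l in unique(g$locus)) {
    gl <- g[g$locus == l & !is.na(g$allele_1) & g$allele_1 != "OL" &
              g$allele_2 != "OL", ]
    alleles <- unique(c(gl$allele_1, gl$allele_2))
    n_i <- vapply(pops, function(p) sum(gl[[by]] == p), numeric(1))
    if (any(n_i < 2)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (a in alleles) {
      p_i <- vapply(pops, function(p) {
        sub <- gl[gl[[by]] == p, ]
        (sum(sub$allele_1 == a) + sum(sub$allele_2 == a)) / (2 * nrow(sub))
      }, numeric(1))
      h_i <- vapply(pops, function(p) {
        sub <- gl[gl[[by]] == p, ]
        mean(xor(sub$allele_1 == a, sub$allele_2 == a))
      }, numeric(1))
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      va <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      vb <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      vc <- hbar / 2
      num <- num + va
      den <- den + va + vb + vc
    }
  }
  num / den
}
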