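#' Harmonize allele-frequency tables across populations
#'
#' Restricts a set of population frequency tables to their shared loci
#' (or an explicit subset of them) and completes each population's table
#' with explicit zero frequencies for every allele observed in any
#' population at a shared locus, so tables are directly comparable.
#'
#' @param x A named list of frequency tibbles, or a single long tibble with
#'   a `population` column.
#' @param loci Optional explicit locus list (must be a subset of the
#'   intersection).
#' @return A long tibble `population`, `locus`, `allele`, `freq` (zeros for
#'   absent alleles) with attribute `"shared_loci"`.
#' @export
harmonize_panel <- function(x, loci = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || length(x) < 2) {
      abort("x must be a named list of >= 2 population tables")
    }
    x <- purrr::imap(x, ~ mutate(as_tibble(.x), population = .y)) |> list_rbind()
  }
  if (!all(c("population", "locus", "allele", "freq") %in% names(x))) {
    abort("panel needs columns population, locus, allele, freq")
  }
  pops <- unique(x$population)
  if (length(pops) < 2) abort("need >= 2 populations")
  per_pop_loci <- split(x$locus, x$population) |> map(unique)
  shared <- Reduce(intersect, per_pop_loci)
  if (!is.null(loci)) {
    if (!all(loci %in% shared)) {
      abort("explicit loci must be a subset of the shared intersection",
            class = "strpopgen_domain_error")
    }
    shared <- loci
  }
  if (length(shared) == 0) abort("no shared loci", class = "strpopgen_data_error")
  kept <- x |>
    filter(.data$locus %in% shared) |>
    select("population", "locus", "allele", "freq")
  # complete each population against the union of (locus, allele) pairs --
  # pairing keeps alleles from leaking across loci
  grid <- tidyr::crossing(tibble(population = unique(kept$population)),
                          distinct(kept, .data$locus, .data$allele))
  out <- grid |>
    left_join(kept, by = c("population", "locus", "allele")) |>
    mutate(freq = ifelse(is.na(.data$freq), 0, .data$freq))
  attr(out, "shared_loci") <- shared
  out
}

#' Nei's DA genetic distance
#'
#' `DA = 1 - (1/r) * sum over loci of sum over alleles of sqrt(x_i * y_i)`,
#' averaged over the `r` shared loci: 0 for identical frequency tables, 1
#' when the two populations share no alleles at any locus. Averaging (not
#' summing) over loci keeps distances comparable between panels with
#' different locus counts.
#'
#' @param panel A harmonized panel (see [harmonize_panel()]), or anything
#'   [harmonize_panel()] accepts.
#' @return A symmetric matrix of pairwise DA values with population labels
#'   as dimnames, of class `c("nei_da", "matrix")`.
#' @export
nei_da <- function(panel) {
  if (is.null(attr(panel, "shared_loci"))) panel <- harmonize_panel(panel)
  pops <- unique(panel$population)
  r <- length(attr(panel, "shared_loci"))
  wide <- panel |>
    pivot_wider(names_from = "population", values_from = "freq", values_fill = 0)
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (j <= i) next
      d[i, j] <- d[j, i] <-
        1 - sum(sqrt(wide[[pops[i]]] * wide[[pops[j]]])) / r
    }
  }
  structure(d, class = c("nei_da", class(d)))
}

#' @method tidy nei_da
#' @export
tidy.nei_da <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(item1 = labs[idx[, 1]], item2 = labs[idx[, 2]],
         distance = x[upper.tri(x)])
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); exactly recovers additive
#' distance matrices. Branch lengths may come out negative on non-additive
#' input -- a property of the algorithm -- and are kept by default;
#' `clamp_negative = TRUE` floors them at zero for display.
#'
#' @param d A symmetric non-negative distance matrix with labels (e.g. from
#'   [nei_da()]). Two taxa yield a single edge of total length `d`.
#' @param clamp_negative Floor negative branch lengths at 0.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  d <- unclass(as.matrix(d))
  if (!isSymmetric(unname(d), tol = 1e-12) || any(d < 0) || any(diag(d) != 0)) {
    abort("d must be a symmetric non-negative matrix with zero diagonal",
          class = "strpopgen_domain_error")
  }
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 2) abort("need at least two taxa")
  if (nrow(d) == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", labs[1], d[1, 2] / 2,
                                        labs[2], d[1, 2] / 2))
  } else {
    dimnames(d) <- list(labs, labs)
    tr <- ape::nj(stats::as.dist(d))
  }
  if (clamp_negative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# shared PCA result constructor
.str_pca <- function(scores, pr, kind, n_components) {
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(scores = scores, explained_variance = ev[seq_len(n_components)],
         explained_variance_all = ev, kind = kind,
         n_components = n_components),
    class = "str_pca"
  )
}

#' Population-level PCA on allele frequencies
#'
#' Rows are populations, variables are the allele-frequency columns of the
#' harmonized panel (column-centred, unscaled: frequencies share a scale);
#' scores come from the singular value decomposition.
#'
#' @param panel A harmonized panel or anything [harmonize_panel()] accepts.
#' @param n_components Number of components to keep (must not exceed the
#'   rank, `min(n_pops - 1, n_variables)`).
#' @return A `str_pca` object: `scores` (tibble `population`, `PC1`, ...),
#'   `explained_variance` (kept components), `explained_variance_all`.
#' @export
pca_populations <- function(panel, n_components = 2) {
  if (is.null(attr(panel, "shared_loci"))) panel <- harmonize_panel(panel)
  wide <- panel |>
    mutate(var = paste(.data$locus, .data$allele, sep = ":")) |>
    select("population", "var", "freq") |>
    pivot_wider(names_from = "var", values_from = "freq", values_fill = 0)
  m <- as.matrix(wide[-1])
  rk <- min(nrow(m) - 1, ncol(m))
  if (n_components > rk) {
    abort(sprintf("n_components (%d) exceeds rank (%d)", n_components, rk),
          class = "strpopgen_domain_error")
  }
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- bind_cols(tibble(population = wide$population),
                      as_tibble(pr$x[, seq_len(n_components), drop = FALSE]))
  .str_pca(scores, pr, "populations", n_components)
}

#' Individual-level PCA on allele dosages
#'
#' Each individual is encoded as the number of copies (0/1/2) it carries of
#' every allele at every locus; columns are centred and missing calls are
#' mean-imputed per column (all-missing columns are dropped with a
#' warning). Scores come from the singular value decomposition of the
#' centred dosage matrix.
#'
#' @param g A long genotype tibble.
#' @param n_components Number of components to keep.
#' @return A `str_pca` object with `scores` keyed by `sample_id` (plus
#'   `subgroup` when present).
#' @export
pca_individuals <- function(g, n_components = 2) {
  g <- validate_genotypes(g)
  samples <- unique(g$sample_id)
  long <- g |>
    filter(!is.na(.data$allele_1), .data$allele_1 != "OL", .data$allele_2 != "OL") |>
    pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    count(.data$sample_id, .data$locus, .data$allele, name = "dosage") |>
    mutate(var = paste(.data$locus, .data$allele, sep = ":"))
  wide <- long |>
    select("sample_id", "var", "dosage") |>
    pivot_wider(names_from = "var", values_from = "dosage")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  m <- m[match(samples, rownames(m)), , drop = FALSE]
  # a sample called at a locus but absent from a column has dosage 0;
  # a sample *uncalled* at the column's locus is genuinely missing
  called <- g |>
    mutate(called = !is.na(.data$allele_1) & .data$allele_1 != "OL" &
             .data$allele_2 != "OL") |>
    select("sample_id", "locus", "called") |>
    pivot_wider(names_from = "locus", values_from = "called")
  called_m <- as.matrix(called[-1])
  called_m[is.na(called_m)] <- FALSE # locus row absent => not called
  rownames(called_m) <- called$sample_id
  col_locus <- sub(":.*$", "", colnames(m))
  for (jj in seq_len(ncol(m))) {
    miss <- !called_m[match(samples, rownames(called_m)), col_locus[jj]]
    m[!miss & is.na(m[, jj]), jj] <- 0
    m[miss, jj] <- NA
  }
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warn(paste0("dropping all-missing dosage columns: ",
                paste(colnames(m)[all_missing], collapse = ", ")))
    m <- m[, !all_missing, drop = FALSE]
  }
  for (jj in seq_len(ncol(m))) {
    mu <- mean(m[, jj], na.rm = TRUE)
    m[is.na(m[, jj]), jj] <- mu
  }
  rk <- min(nrow(m) - 1, ncol(m))
  if (n_components > rk) {
    abort(sprintf("n_components (%d) exceeds rank (%d)", n_components, rk),
          class = "strpopgen_domain_error")
  }
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- tibble(sample_id = rownames(m))
  if ("subgroup" %in% names(g)) {
    meta <- g |> distinct(.data$sample_id, .data$subgroup)
    scores <- scores |> left_join(meta, by = "sample_id")
  }
  scores <- bind_cols(scores, as_tibble(pr$x[, seq_len(n_components), drop = FALSE]))
  .str_pca(scores, pr, "individuals", n_components)
}

#' @export
print.str_pca <- function(x, ...) {
  cat(sprintf("<str_pca: %s> %d components, variance explained %s\n",
              x$kind, x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  print(x$scores)
  invisible(x)
}

#' @method tidy str_pca
#' @export
tidy.str_pca <- function(x, ...) x$scores

#' @method glance str_pca
#' @export
glance.str_pca <- function(x, ...) {
  tibble(kind = x$kind, n_components = x$n_components,
         var_explained = sum(x$explained_variance))
}

#' @method autoplot str_pca
#' @export
autoplot.str_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  key <- if (object$kind == "populations") "population" else "sample_id"
  colour <- colour %||% if ("subgroup" %in% names(sc)) "subgroup" else key
  ggplot(sc, aes(.data$PC1, .data$PC2, colour = .data[[colour]])) +
    geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
}
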