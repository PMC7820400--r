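#' Read a diploid STR genotype table
#'
#' The on-disk format is one row per individual: a `sample` column, optional
#' `sex` and `subgroup` metadata columns, then two columns `<locus>_a1`,
#' `<locus>_a2` per locus. Empty cells are missing calls; `"OL"` marks an
#' off-ladder allele. The two alleles of a call are an unordered pair.
#'
#' @param path Path to a CSV file.
#' @return A long genotype tibble with columns `sample_id`, `locus`,
#'   `allele_1`, `allele_2` (character labels, `NA` = missing call) plus any
#'   metadata columns present (`sex`, `subgroup`).
#' @seealso [write_genotypes()], [allele_frequencies()]
#' @export
read_genotypes <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sample" %in% names(raw) || nrow(raw) == 0) {
    abort("genotype CSV must have a 'sample' column and at least one row",
          class = "strpopgen_schema_error")
  }
  meta_cols <- intersect(c("sex", "subgroup"), names(raw))
  allele_cols <- setdiff(names(raw), c("sample", meta_cols))
  if (length(allele_cols) == 0 || length(allele_cols) %% 2 != 0 ||
      !all(str_detect(allele_cols, "_a[12]$"))) {
    abort("allele columns must come in <locus>_a1/<locus>_a2 pairs",
          class = "strpopgen_schema_error")
  }
  g <- raw |>
    pivot_longer(all_of(allele_cols),
                 names_to = c("locus", ".value"),
                 names_pattern = "^(.*)_(a[12])$") |>
    rename(sample_id = "sample", allele_1 = "a1", allele_2 = "a2") |>
    mutate(across(c("allele_1", "allele_2"), ~ ifelse(.x == "", NA_character_, .x)))
  # locate bad labels with their file position before validating pairs
  for (col in c("allele_1", "allele_2")) {
    v <- g[[col]]
    bad <- !is.na(v) & v != "OL" & !str_detect(v, "^[0-9]+(\\.[0-9])?$")
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("cannot parse allele %s at sample '%s', locus %s (%s)",
                    sQuote(v[i]), g$sample_id[i], g$locus[i], col),
            class = "strpopgen_parse_error")
    }
  }
  validate_genotypes(g)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(g, p))`
#' round-trips.
#'
#' @param g A long genotype tibble (see [read_genotypes()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  g <- validate_genotypes(g)
  meta_cols <- intersect(c("sex", "subgroup"), names(g))
  wide <- g |>
    pivot_wider(id_cols = all_of(c("sample_id", meta_cols)),
                names_from = "locus",
                values_from = c("allele_1", "allele_2"),
                names_glue = "{locus}_{ifelse(.value == 'allele_1', 'a1', 'a2')}")
  loci <- unique(g$locus)
  ord <- as.vector(rbind(paste0(loci, "_a1"), paste0(loci, "_a2")))
  wide <- wide |> select(all_of(c("sample_id", meta_cols, ord))) |> rename(sample = "sample_id")
  readr::write_csv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a long genotype tibble
#'
#' Checks the column contract, that every non-missing call carries exactly
#' two alleles, that no sample/locus combination is duplicated, and that all
#' allele labels parse.
#'
#' @param g A data frame with columns `sample_id`, `locus`, `allele_1`,
#'   `allele_2`.
#' @return `g` as a validated tibble (invisibly usable in pipes).
#' @export
validate_genotypes <- function(g) {
  need <- c("sample_id", "locus", "allele_1", "allele_2")
  if (!all(need %in% names(g))) {
    abort(paste0("genotype table needs columns: ", paste(need, collapse = ", ")),
          class = "strpopgen_schema_error")
  }
  g <- as_tibble(g)
  if (length(unique(g$sample_id)) == 0) abort("no samples", class = "strpopgen_schema_error")
  half <- xor(is.na(g$allele_1), is.na(g$allele_2))
  if (any(half)) {
    i <- which(half)[1]
    abort(sprintf("half-missing call at sample '%s', locus %s: a call has exactly 2 alleles or none",
                  g$sample_id[i], g$locus[i]), class = "strpopgen_schema_error")
  }
  if (anyDuplicated(g[c("sample_id", "locus")])) {
    abort("duplicated sample/locus rows", class = "strpopgen_schema_error")
  }
  parse_allele(g$allele_1)
  parse_allele(g$allele_2)
  g
}

#' Estimate allele frequencies from genotypes
#'
#' Tallies gene copies per locus; `freq` is the relative frequency among the
#' `n` gene copies typed at that locus (missing calls and unresolved
#' off-ladder alleles are excluded, so `n` -- the "2n" of frequency surveys
#' -- is per locus, not global).
#'
#' @param g A long genotype tibble (see [read_genotypes()]).
#' @return A frequency tibble with columns `locus`, `allele`, `count`,
#'   `freq`, `n`, sorted by locus and numeric allele order.
#' @examples
#' g <- tibble::tibble(sample_id = c("s1", "s2"), locus = "TPOX",
#'                     allele_1 = c("10", "10"), allele_2 = c("11", "10"))
#' allele_frequencies(g)
#' @export
allele_frequencies <- function(g) {
  g <- validate_genotypes(g)
  long <- g |>
    pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    filter(!is.na(.data$allele), .data$allele != "OL")
  if (!all(unique(g$locus) %in% unique(long$locus))) {
    missing_loci <- setdiff(unique(g$locus), unique(long$locus))
    abort(paste0("no usable calls at locus/loci: ",
                 paste(missing_loci, collapse = ", ")),
          class = "strpopgen_data_error")
  }
  f <- long |>
    count(.data$locus, .data$allele, name = "count") |>
    group_by(.data$locus) |>
    mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    ungroup()
  p <- parse_allele(f$allele)
  f[order(match(f$locus, unique(g$locus)), p$repeats, p$partial), ]
}
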