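#' Validate an allele-frequency tibble
#'
#' A frequency tibble has columns `locus`, `allele`, `freq` and `n` (the
#' number of gene copies surveyed at the locus, i.e. "2n"). Checks that all
#' frequencies are positive, that each locus sums to 1 within `tol`
#' (3-decimal published tables round, so the default tolerates 0.01), and
#' that `n` is a positive even integer constant within locus.
#'
#' @param f A data frame with columns `locus`, `allele`, `freq`, `n`.
#' @param tol Allowed deviation of per-locus frequency sums from 1.
#' @return `f` as a validated tibble.
#' @export
validate_frequencies <- function(f, tol = 0.01) {
  need <- c("locus", "allele", "freq", "n")
  if (!all(need %in% names(f))) {
    abort(paste0("frequency table needs columns: ", paste(need, collapse = ", ")),
          class = "strpopgen_schema_error")
  }
  f <- as_tibble(f)
  if (any(f$freq <= 0)) abort("all frequencies must be > 0", class = "strpopgen_data_error")
  if (anyDuplicated(f[c("locus", "allele")])) {
    abort("duplicated locus/allele rows", class = "strpopgen_data_error")
  }
  chk <- f |>
    group_by(.data$locus) |>
    summarise(s = sum(.data$freq), n_distinct_n = dplyr::n_distinct(.data$n),
              n1 = .data$n[1], .groups = "drop")
  off <- chk$locus[abs(chk$s - 1) > tol]
  if (length(off) > 0) {
    abort(paste0("frequencies do not sum to 1 (tol ", tol, ") at: ",
                 paste(off, collapse = ", ")), class = "strpopgen_data_error")
  }
  if (any(chk$n_distinct_n != 1) || any(chk$n1 <= 0) || any(chk$n1 %% 2 != 0)) {
    abort("n must be a positive even constant per locus", class = "strpopgen_data_error")
  }
  parse_allele(f$allele)
  f
}

#' Write an allele-frequency table in survey layout
#'
#' Loci as columns, alleles as rows, a dash for absent alleles, and a final
#' `Alleles(n)` row carrying the per-locus number of gene copies -- the
#' layout of published forensic frequency tables.
#'
#' @param f A frequency tibble (see [validate_frequencies()]).
#' @param path Output CSV path.
#' @param decimals Decimal places for rendered frequencies (default 3,
#'   matching published tables).
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(f, path, decimals = 3) {
  f <- validate_frequencies(f)
  loci <- unique(f$locus)
  alleles <- unique(f$allele)
  alleles <- alleles[allele_order(alleles)]
  wide <- f |>
    mutate(txt = formatC(round(.data$freq, decimals), format = "f", digits = decimals)) |>
    select("locus", "allele", "txt") |>
    pivot_wider(names_from = "locus", values_from = "txt", values_fill = "-")
  wide <- wide[match(alleles, wide$allele), c("allele", loci)]
  ns <- f |> distinct(.data$locus, .data$n)
  nrow_df <- as.list(setNames(as.character(ns$n[match(loci, ns$locus)]), loci))
  nrow_df <- tibble(allele = "Alleles(n)", !!!nrow_df)
  readr::write_csv(bind_rows(wide, nrow_df), path, progress = FALSE)
  invisible(path)
}

#' Read an allele-frequency table in survey layout
#'
#' Inverse of [write_frequencies()].
#'
#' @param path CSV path (loci as columns, alleles as rows, `-` for absent,
#'   final `Alleles(n)` row with gene-copy counts).
#' @return A frequency tibble with columns `locus`, `allele`, `freq`, `n`.
#' @export
read_frequencies <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "allele") {
    abort("first column must be 'allele'", class = "strpopgen_schema_error")
  }
  nrow_i <- which(raw$allele == "Alleles(n)")
  if (length(nrow_i) != 1) {
    abort("expected exactly one 'Alleles(n)' row", class = "strpopgen_schema_error")
  }
  ns <- raw[nrow_i, -1] |> unlist() |> as.numeric()
  body <- raw[-nrow_i, ]
  f <- body |>
    pivot_longer(-"allele", names_to = "locus", values_to = "freq") |>
    filter(.data$freq != "-", !is.na(.data$freq)) |>
    mutate(freq = as.numeric(.data$freq),
           n = ns[match(.data$locus, names(raw)[-1])]) |>
    select("locus", "allele", "freq", "n")
  validate_frequencies(f)
}

#' Published 23-locus Kuwaiti allele-frequency table
#'
#' The packaged transcription of a published survey of 400 Kuwaiti
#' individuals typed at the 23 autosomal PowerPlex Fusion 6C STR loci
#' (800 gene copies per locus, frequencies printed to 3 decimals).
#'
#' @return A frequency tibble (`locus`, `allele`, `freq`, `n`).
#' @examples
#' kuwait_frequencies() |> dplyr::filter(locus == "TPOX")
#' @export
kuwait_frequencies <- function() {
  read_frequencies(system.file("extdata", "kuwait_fusion6c_freqs.csv",
                               package = "strpopgen", mustWork = TRUE))
}

#' Published per-locus forensic statistics for the Kuwaiti survey
#'
#' The statistic rows printed alongside [kuwait_frequencies()]: number of
#' allelic variants, observed/expected heterozygosity, Hardy-Weinberg test
#' p-value, random match probability, discrimination power, power of
#' exclusion, typical paternity index and polymorphic information content.
#'
#' @return A tibble with one row per locus and columns `locus`,
#'   `n_variants`, `ho`, `he`, `hwe_p`, `rmp`, `dp`, `pe`, `tpi`, `pic`.
#' @export
kuwait_locus_stats <- function() {
  raw <- readr::read_csv(system.file("extdata", "kuwait_fusion6c_stats.csv",
                                     package = "strpopgen", mustWork = TRUE),
                         col_types = readr::cols(statistic = readr::col_character(),
                                                 .default = readr::col_double()),
                         progress = FALSE)
  raw |>
    pivot_longer(-"statistic", names_to = "locus") |>
    pivot_wider(names_from = "statistic", values_from = "value") |>
    rename(n_variants = "n_variants", ho = "Ho", he = "He", hwe_p = "HWE_p",
           rmp = "RMP", dp = "DP", pe = "PE", tpi = "TPI", pic = "PIC")
}

#' Published off-ladder repeat structures
#'
#' Sequence-derived bracketed repeat structures for the off-ladder alleles
#' observed in the Kuwaiti survey, with the allele designation each was
#' identified as.
#'
#' @return A tibble with columns `locus`, `repeat_structure`,
#'   `identified_allele`.
#' @export
ol_structures <- function() {
  readr::read_csv(system.file("extdata", "ol_repeat_structures.csv",
                              package = "strpopgen", mustWork = TRUE),
                  col_types = "ccc", progress = FALSE)
}
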