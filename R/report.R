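#' Run the full frequency-survey report pipeline
#'
#' Reads a genotype CSV, estimates allele frequencies, computes the
#' per-locus forensic summary (including Hardy-Weinberg p-values) and the
#' combined parameters, and writes three files to `out_dir`:
#' `allele_frequencies.csv` (survey layout, see [write_frequencies()]),
#' `locus_summary.tsv` and `combined.tsv`. Values are rounded half-even to
#' `decimals` places at this reporting layer only. On failure any partial
#' outputs are removed.
#'
#' @param genotypes Path to a genotype CSV (see [read_genotypes()]).
#' @param out_dir Output directory (created if absent).
#' @param decimals Reporting precision (default 3).
#' @param n_perm,seed Hardy-Weinberg permutation settings (see
#'   [hwe_exact_test()]).
#' @return Invisibly, a list with elements `frequencies`, `summary`,
#'   `combined` (the unrounded tibbles) and `paths`.
#' @export
popreport_pipeline <- function(genotypes, out_dir, decimals = 3,
                               n_perm = 10000, seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("allele_frequencies.csv", "locus_summary.tsv",
                                "combined.tsv"))
  names(paths) <- c("frequencies", "summary", "combined")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  g <- read_genotypes(genotypes)
  f <- allele_frequencies(g)
  smry <- locus_summary(g, hwe = TRUE, n_perm = n_perm, seed = seed)
  comb <- combine_forensic(smry)
  write_frequencies(f, paths["frequencies"], decimals = decimals)
  smry_out <- smry |>
    mutate(across(where(is.numeric) & !c("n_typed", "n_alleles"),
                  ~ report_round(.x, decimals)))
  readr::write_tsv(smry_out, paths["summary"], progress = FALSE)
  comb_out <- comb |>
    mutate(cdp = report_round(.data$cdp, 6), cpe = report_round(.data$cpe, 10),
           one_in = signif(.data$one_in, decimals),
           cmp = signif(.data$cmp, decimals))
  readr::write_tsv(comb_out, paths["combined"], progress = FALSE)
  ok <- TRUE
  invisible(list(frequencies = f, summary = smry, combined = comb,
                 paths = paths))
}
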