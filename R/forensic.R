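#' Observed heterozygosity per locus
#'
#' The fraction of called individuals carrying two distinct alleles.
#'
#' @param g A long genotype tibble.
#' @return A tibble with columns `locus`, `n_typed`, `ho`.
#' @export
observed_heterozygosity <- function(g) {
  g <- validate_genotypes(g)
  called <- g |> filter(!is.na(.data$allele_1), .data$allele_1 != "OL",
                        .data$allele_2 != "OL")
  if (!all(unique(g$locus) %in% unique(called$locus))) {
    abort(paste0("no calls at locus/loci: ",
                 paste(setdiff(unique(g$locus), unique(called$locus)), collapse = ", ")),
          class = "strpopgen_data_error")
  }
  called |>
    group_by(.data$locus) |>
    summarise(n_typed = dplyr::n(),
              ho = mean(.data$allele_1 != .data$allele_2), .groups = "drop") |>
    arrange(match(.data$locus, unique(g$locus)))
}

#' Expected heterozygosity per locus
#'
#' Unbiased gene diversity `He = (2n / (2n - 1)) * (1 - sum(p^2))`; set
#' `unbiased = FALSE` for the raw gene diversity `1 - sum(p^2)`.
#'
#' @param f A frequency tibble.
#' @param unbiased Apply the small-sample `2n/(2n-1)` correction (default).
#' @return A tibble with columns `locus`, `he`.
#' @export
expected_heterozygosity <- function(f, unbiased = TRUE) {
  f <- validate_frequencies(f)
  if (unbiased && any(f$n < 2)) abort("need n >= 2 for the unbiased estimator")
  f |>
    group_by(.data$locus) |>
    summarise(he = (if (unbiased) .data$n[1] / (.data$n[1] - 1) else 1) *
                (1 - sum(.data$freq^2)), .groups = "drop") |>
    arrange(match(.data$locus, unique(f$locus)))
}

#' Polymorphic information content per locus
#'
#' `PIC = 1 - sum(p^2) - (sum(p^2))^2 + sum(p^4)`, the classical marker
#' informativeness index for linkage and paternity work.
#'
#' @param f A frequency tibble.
#' @return A tibble with columns `locus`, `pic`.
#' @export
pic <- function(f) {
  f <- validate_frequencies(f)
  f |>
    group_by(.data$locus) |>
    summarise(pic = 1 - sum(.data$freq^2) - sum(.data$freq^2)^2 + sum(.data$freq^4),
              .groups = "drop") |>
    arrange(match(.data$locus, unique(f$locus)))
}

#' Random match probability and discrimination power per locus
#'
#' With `mode = "observed"` (the default, and what STR survey tools report
#' from genotype data), `PM = sum(f_g^2)` over the observed genotype
#' relative frequencies. With `mode = "hwe_expected"`, PM is the
#' Hardy-Weinberg expectation `sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`
#' computed from allele frequencies alone -- pass a frequency tibble when
#' only a published frequency table is available. `DP = 1 - PM` either way.
#'
#' @param x A long genotype tibble, or a frequency tibble (the latter only
#'   supports `mode = "hwe_expected"`).
#' @param mode `"observed"` or `"hwe_expected"`.
#' @return A tibble with columns `locus`, `pm`, `dp`.
#' @export
match_probability <- function(x, mode = c("observed", "hwe_expected")) {
  mode <- match.arg(mode)
  is_freq <- all(c("freq", "n") %in% names(x)) && !"allele_1" %in% names(x)
  if (is_freq) {
    if (mode == "observed") {
      abort("mode = \"observed\" needs genotype data, not a frequency table")
    }
    f <- validate_frequencies(x)
    out <- f |>
      group_by(.data$locus) |>
      summarise(pm = 2 * sum(.data$freq^2)^2 - sum(.data$freq^4), .groups = "drop")
  } else {
    g <- validate_genotypes(x)
    if (mode == "hwe_expected") {
      return(match_probability(allele_frequencies(g), mode = "hwe_expected"))
    }
    called <- g |> filter(!is.na(.data$allele_1), .data$allele_1 != "OL",
                          .data$allele_2 != "OL")
    # canonical unordered genotype key (any consistent within-pair order works)
    out <- called |>
      mutate(geno = paste(pmin(.data$allele_1, .data$allele_2),
                          pmax(.data$allele_1, .data$allele_2), sep = "/")) |>
      count(.data$locus, .data$geno) |>
      group_by(.data$locus) |>
      summarise(pm = sum((.data$n / sum(.data$n))^2), .groups = "drop")
  }
  out |>
    mutate(dp = 1 - .data$pm) |>
    arrange(match(.data$locus, unique(x$locus)))
}

#' Power of exclusion from observed heterozygosity
#'
#' `PE = Ho^2 * (1 - 2 * Ho * (1 - Ho)^2)`, strictly increasing in Ho.
#'
#' @param ho Observed heterozygosity in `[0, 1]` (vectorized).
#' @return Numeric vector of PE values.
#' @export
power_of_exclusion <- function(ho) {
  if (any(ho < 0 | ho > 1, na.rm = TRUE)) {
    abort("ho must lie in [0, 1]", class = "strpopgen_domain_error")
  }
  ho^2 * (1 - 2 * ho * (1 - ho)^2)
}

#' Typical paternity index from observed heterozygosity
#'
#' `TPI = 1 / (2 * (1 - Ho))`; undefined at `Ho = 1`.
#'
#' @param ho Observed heterozygosity in `[0, 1)` (vectorized).
#' @return Numeric vector of TPI values (`>= 0.5`).
#' @export
typical_paternity_index <- function(ho) {
  if (any(ho < 0 | ho > 1, na.rm = TRUE)) {
    abort("ho must lie in [0, 1]", class = "strpopgen_domain_error")
  }
  if (any(ho == 1, na.rm = TRUE)) {
    abort("TPI is undefined at ho = 1", class = "strpopgen_domain_error")
  }
  1 / (2 * (1 - ho))
}

#' Per-locus forensic summary
#'
#' Assembles the statistic bundle of a forensic frequency survey for every
#' locus: observed and unbiased expected heterozygosity, PIC, match
#' probability (observed-genotype estimator), discrimination power, power of
#' exclusion, typical paternity index, the Hardy-Weinberg exact-test p-value
#' and the number of distinct alleles observed.
#'
#' @param g A long genotype tibble.
#' @param hwe Run the Hardy-Weinberg test per locus (default TRUE).
#' @param n_perm Permutations for the Hardy-Weinberg test when exhaustive
#'   enumeration is infeasible.
#' @param seed Seed for the Hardy-Weinberg permutation null.
#' @return A tibble with one row per locus: `locus`, `n_typed`,
#'   `n_alleles`, `ho`, `he`, `pic`, `pm`, `dp`, `pe`, `tpi`, `hwe_p`.
#' @export
locus_summary <- function(g, hwe = TRUE, n_perm = 10000, seed = 1) {
  g <- validate_genotypes(g)
  f <- allele_frequencies(g)
  out <- observed_heterozygosity(g) |>
    left_join(f |> count(.data$locus, name = "n_alleles"), by = "locus") |>
    left_join(expected_heterozygosity(f), by = "locus") |>
    left_join(pic(f), by = "locus") |>
    left_join(match_probability(g, mode = "observed"), by = "locus") |>
    mutate(pe = power_of_exclusion(.data$ho),
           tpi = typical_paternity_index(.data$ho))
  if (hwe) {
    h <- hwe_exact_test(g, n_perm = n_perm, seed = seed) |>
      select("locus", hwe_p = "p_value")
    out <- out |> left_join(h, by = "locus")
  }
  out
}

#' Combine per-locus forensic parameters across independent loci
#'
#' `CMP = prod(PM)`, `CDP = 1 - CMP`, `CPE = 1 - prod(1 - PE)`; the
#' reciprocal of CMP is the familiar "1 in X" figure. Multiplication across
#' loci assumes linkage equilibrium (see [ld_test()]).
#'
#' @param per_locus A tibble with columns `pm` and `pe` (e.g. from
#'   [locus_summary()]).
#' @return A one-row tibble: `n_loci`, `cmp`, `cdp`, `cpe`, `one_in`.
#' @export
combine_forensic <- function(per_locus) {
  if (nrow(per_locus) == 0) abort("need at least one locus")
  if (!all(c("pm", "pe") %in% names(per_locus))) {
    abort("per_locus needs columns pm and pe")
  }
  cmp <- prod(per_locus$pm)
  tibble(n_loci = nrow(per_locus), cmp = cmp, cdp = 1 - cmp,
         cpe = 1 - prod(1 - per_locus$pe), one_in = 1 / cmp)
}

#' Round for reporting
#'
#' Half-even rounding applied only at the reporting layer; internal
#' computation is never rounded.
#'
#' @param x Numeric vector.
#' @param decimals Decimal places (default 3, the survey-table convention).
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, decimals = 3) round(x, decimals)
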