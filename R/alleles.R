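#' Parse CE allele labels into exact repeat/microvariant pairs
#'
#' Capillary-electrophoresis (CE) STR alleles are named by their full repeat
#' count, with a `".x"` suffix for microvariants carrying `x` extra bases
#' (e.g. `"15.3"` is 15 full repeats plus 3 bases). Labels are kept as exact
#' integer pairs -- never floating point -- so that `"9.3"` can never collide
#' with `"9.30"`. The sentinel `"OL"` marks an off-ladder allele awaiting
#' sequence-based designation (see [designate_allele()]).
#'
#' @param x Character vector of allele labels (`"12"`, `"15.3"`, `"OL"`).
#'   `NA` entries are carried through as missing.
#' @return A tibble with one row per element of `x` and columns `label`,
#'   `repeats` (integer), `partial` (integer, 0 when no microvariant) and
#'   `off_ladder` (logical).
#' @examples
#' parse_allele(c("15", "15.3", "OL"))
#' @export
parse_allele <- function(x) {
  x <- as.character(x)
  ok <- is.na(x) | x == "OL" | str_detect(x, "^[0-9]+(\\.[0-9])?$")
  if (!all(ok)) {
    bad <- unique(x[!ok])
    abort(paste0(
      "malformed allele label(s): ",
      paste(sQuote(head(bad, 5)), collapse = ", "),
      " (expected \"<repeats>\", \"<repeats>.<bases>\" or \"OL\")"
    ), class = "strpopgen_parse_error")
  }
  m <- str_match(x, "^([0-9]+)(?:\\.([0-9]))?$")
  off <- !is.na(x) & x == "OL"
  tibble(
    label = x,
    repeats = ifelse(off, NA_integer_, as.integer(m[, 2])),
    partial = ifelse(off | is.na(x), NA_integer_,
                     ifelse(is.na(m[, 3]), 0L, as.integer(m[, 3]))),
    off_ladder = off
  )
}

#' Render (repeats, partial) pairs as CE allele labels
#'
#' Inverse of [parse_allele()]: `partial = 0` renders as `"R"`, otherwise
#' `"R.p"`.
#'
#' @param repeats Integer vector of full repeat counts (non-negative).
#' @param partial Integer vector of extra bases (default 0).
#' @return Character vector of labels.
#' @examples
#' format_allele(c(15L, 9L), c(3L, 0L))
#' @export
format_allele <- function(repeats, partial = 0L) {
  if (any(repeats < 0, na.rm = TRUE) || any(partial < 0, na.rm = TRUE)) {
    abort("repeats and partial must be non-negative")
  }
  ifelse(partial > 0, paste0(repeats, ".", partial), as.character(repeats))
}

#' Order allele labels numerically
#'
#' Sorts by `(repeats, partial)` so `"9.3"` falls between `"9"` and `"10"`,
#' which lexicographic sorting gets wrong. Off-ladder labels sort last.
#'
#' @param x Character vector of allele labels.
#' @return An integer permutation, as [base::order()].
#' @export
allele_order <- function(x) {
  p <- parse_allele(x)
  order(p$off_ladder, p$repeats, p$partial)
}
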