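#' Parse a bracketed STR repeat-structure string
#'
#' Sequence-based STR nomenclature writes an allele as an ordered series of
#' blocks: `"(MOTIF)n"` for `n` tandem copies of a motif, or a bare DNA run
#' (count 1). `"(MOTIF)"` with no digit also means count 1. Whitespace
#' between blocks is optional, so forms like `"(CTTT)9T"` (a bracketed block
#' immediately followed by a bare base) parse as two blocks.
#'
#' @param text A single repeat-structure string, e.g. `"AAGA (AAAGA)15"`.
#' @return An object of class `repeat_structure`: a list with `blocks` (a
#'   tibble of `motif`, `count`), `total_length` (base pairs) and `source`.
#' @examples
#' parse_repeat_structure("AAGA (AAAGA)15")
#' @export
parse_repeat_structure <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("text must be a single string")
  }
  chars <- str_split_1(text, "")
  i <- 1L
  n <- length(chars)
  motifs <- character(0)
  counts <- integer(0)
  perr <- function(msg, at) {
    abort(sprintf("repeat-structure parse error at offset %d: %s (in %s)",
                  at, msg, sQuote(text)), class = "strpopgen_parse_error")
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] %in% c("A", "C", "G", "T")) j <- j + 1L
      if (j > n || chars[j] != ")") perr("unbalanced or non-DNA bracket", i)
      if (j == i + 1L) perr("empty motif", i)
      motif <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      j <- j + 1L
      d <- j
      while (d <= n && chars[d] %in% as.character(0:9)) d <- d + 1L
      count <- if (d > j) as.integer(paste(chars[j:(d - 1L)], collapse = "")) else 1L
      if (count == 0L) perr("zero repeat count", j)
      motifs <- c(motifs, motif)
      counts <- c(counts, count)
      i <- d
    } else if (ch %in% c("A", "C", "G", "T")) {
      j <- i
      while (j <= n && chars[j] %in% c("A", "C", "G", "T")) j <- j + 1L
      motifs <- c(motifs, paste(chars[i:(j - 1L)], collapse = ""))
      counts <- c(counts, 1L)
      i <- j
    } else {
      perr(paste0("illegal character ", sQuote(ch)), i)
    }
  }
  if (length(motifs) == 0) perr("empty structure", 1L)
  structure(
    list(blocks = tibble(motif = motifs, count = counts),
         total_length = sum(nchar(motifs) * counts),
         source = text),
    class = "repeat_structure"
  )
}

#' @export
format.repeat_structure <- function(x, ...) {
  paste(ifelse(x$blocks$count == 1L, x$blocks$motif,
               paste0("(", x$blocks$motif, ")", x$blocks$count)),
        collapse = " ")
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat("<repeat_structure> ", format(x), "  [", x$total_length, " bp]\n", sep = "")
  invisible(x)
}

#' Compute the CE allele designation of a repeat structure
#'
#' Length-based designation: with effective length
#' `L = total_length - length_offset`, the allele is `L %/% motif_length`
#' full repeats, with a `".x"` microvariant suffix when `L %% motif_length`
#' is non-zero. Designation is purely length-based within the analysed
#' region; motifs need not be sequence-identical.
#'
#' @param rs A `repeat_structure` (or a string, parsed on the fly).
#' @param motif_length Repeat unit length in bases (3-5 for common loci).
#' @param length_offset Bases subtracted from the total length before
#'   designation (default 0); some loci (notably SE33) use published
#'   designations that exclude part of the amplified region.
#' @return A single allele label string (see [parse_allele()]).
#' @examples
#' designate_allele(parse_repeat_structure("AAAGA AA (AAAGA)9"), 5) # "10.2"
#' @export
designate_allele <- function(rs, motif_length, length_offset = 0) {
  if (is.character(rs)) rs <- parse_repeat_structure(rs)
  if (!inherits(rs, "repeat_structure")) abort("rs must be a repeat_structure")
  if (is.na(motif_length) || motif_length < 2) {
    abort("motif_length must be >= 2 (NA disables designation)",
          class = "strpopgen_domain_error")
  }
  l_eff <- rs$total_length - length_offset
  if (l_eff <= 0) abort("effective length must be positive",
                        class = "strpopgen_domain_error")
  format_allele(l_eff %/% motif_length, l_eff %% motif_length)
}

#' Default locus nomenclature registry
#'
#' Motif lengths and designation offsets for the loci with sequence-based
#' off-ladder designation support. SE33 ships with designation disabled
#' (`motif_length` given, `length_offset` `NA`): its published CE
#' designations do not correspond to total structure length under any
#' single offset, so a calibrated offset must be supplied explicitly.
#'
#' @return A tibble with columns `locus`, `motif_length`, `length_offset`.
#' @export
default_locus_registry <- function() {
  tibble(
    locus = c("PentaE", "PentaD", "D22S1045", "SE33"),
    motif_length = c(5L, 5L, 3L, 4L),
    length_offset = c(0L, 0L, 0L, NA_integer_)
  )
}

#' Designate alleles for a table of repeat structures
#'
#' Vectorised wrapper around [parse_repeat_structure()] and
#' [designate_allele()]: rows whose locus is absent from the registry, or
#' whose registry entry has `length_offset = NA` (designation disabled), get
#' `NA` designations.
#'
#' @param x A data frame with columns `locus` and `repeat_structure`.
#' @param registry A registry tibble (see [default_locus_registry()]).
#' @return `x` with added columns `total_length` and `designated`.
#' @export
designate_structures <- function(x, registry = default_locus_registry()) {
  if (!all(c("locus", "repeat_structure") %in% names(x))) {
    abort("x needs columns locus and repeat_structure")
  }
  rs <- map(x$repeat_structure, parse_repeat_structure)
  reg <- registry[match(x$locus, registry$locus), ]
  as_tibble(x) |>
    mutate(
      total_length = map_dbl(rs, "total_length"),
      designated = purrr::pmap_chr(
        list(rs, reg$motif_length, reg$length_offset),
        function(r, m, off) {
          if (is.na(m) || is.na(off)) NA_character_
          else designate_allele(r, m, off)
        }
      )
    )
}

#' Resolve off-ladder calls using sequence-derived repeat structures
#'
#' Replaces `"OL"` alleles in a genotype table with their length-based
#' designations, flagging each resolved call. A designation present in the
#' kit ladder is a regular allele (`"in_ladder"`); one absent from the
#' ladder is `"off_ladder_identified"`; one additionally absent from the
#' known-allele catalogue is `"novel"` (meaning only: not in the supplied
#' catalogue). OL calls without a structure entry stay `"OL"`, flagged
#' `"unresolved"`. A structure supplied for a non-OL call produces a
#' warning, not an error.
#'
#' @param g A long genotype tibble with possible `"OL"` alleles.
#' @param structures A data frame `sample_id`, `locus`, `repeat_structure`.
#' @param registry Nomenclature registry (see [default_locus_registry()]).
#' @param ladder Optional named list mapping locus to the character vector
#'   of ladder allele labels.
#' @param catalogue Optional named list mapping locus to known allele
#'   labels; defaults to the alleles of the packaged Kuwaiti frequency
#'   table.
#' @return The genotype tibble with OL calls replaced where possible, plus
#'   an attribute `"resolutions"`: a tibble `sample_id`, `locus`, `allele`,
#'   `flag`.
#' @export
identify_off_ladder <- function(g, structures, registry = default_locus_registry(),
                                ladder = NULL, catalogue = NULL) {
  g <- validate_genotypes(g)
  if (is.null(catalogue)) {
    kf <- kuwait_frequencies()
    catalogue <- split(kf$allele, kf$locus)
  }
  des <- designate_structures(structures, registry)
  res <- list()
  for (r in seq_len(nrow(des))) {
    sid <- des$sample_id[r]; loc <- des$locus[r]
    row <- which(g$sample_id == sid & g$locus == loc)
    if (length(row) != 1) {
      warn(sprintf("no genotype row for sample '%s' locus %s; structure ignored", sid, loc))
      next
    }
    is_ol <- c(g$allele_1[row] == "OL", g$allele_2[row] == "OL")
    if (!any(is_ol, na.rm = TRUE)) {
      warn(sprintf("structure supplied for non-OL call at sample '%s' locus %s", sid, loc))
      next
    }
    new_lab <- des$designated[r]
    if (is.na(new_lab)) next # designation disabled for this locus
    flag <- if (!is.null(ladder) && new_lab %in% (ladder[[loc]] %||% character(0))) {
      "in_ladder"
    } else if (new_lab %in% (catalogue[[loc]] %||% character(0))) {
      "off_ladder_identified"
    } else {
      "novel"
    }
    slot <- which(is_ol)[1] # resolve one OL gene copy per structure row
    if (slot == 1) g$allele_1[row] <- new_lab else g$allele_2[row] <- new_lab
    res[[length(res) + 1]] <- tibble(sample_id = sid, locus = loc,
                                     allele = new_lab, flag = flag)
  }
  still <- g |> filter(.data$allele_1 == "OL" | .data$allele_2 == "OL")
  if (nrow(still) > 0) {
    res[[length(res) + 1]] <- tibble(sample_id = still$sample_id,
                                     locus = still$locus,
                                     allele = "OL", flag = "unresolved")
  }
  attr(g, "resolutions") <- if (length(res)) list_rbind(res) else
    tibble(sample_id = character(), locus = character(),
           allele = character(), flag = character())
  g
}
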