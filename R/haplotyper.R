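#' @title Tier one: rbcL SNP profiling and haplotype calling
#'
#' @description
#' A query rbcL amplicon is reduced to its bases at the panel's informative
#' positions (an `snp_profile`), the genus is read from the diagnostic G/A
#' site at position 431, and the nearest panel haplotype is called by
#' Hamming distance with IUPAC-aware matching.
#'
#' @name haplotyper
NULL

#' Extract a query's SNP profile at the panel positions
#'
#' @param query rbcL query sequence (named character or
#'   [Biostrings::DNAStringSet] element).
#' @param panel A `haplotype_panel`.
#' @param ... Passed to [align_to_reference()] (e.g. `identity_floor`).
#' @return An `snp_profile`: list with `id`, `bases` (named by position,
#'   `"-"` for deletions/uncovered positions) and `n_ambiguous`.
#' @export
extract_profile <- function(query, panel, ...) {
  ref <- c(rbcL = panel$reference_sequences[["rbcL"]])
  cm <- align_to_reference(query, ref, ...)
  bases <- vapply(panel$positions, function(p) base_at(cm, query, p),
                  character(1))
  names(bases) <- as.character(panel$positions)
  structure(list(id = .seq_id(query), bases = bases,
                 n_ambiguous = sum(!bases %in% c("A", "C", "G", "T")),
                 identity = cm$identity, coverage = cm$coverage),
            class = "snp_profile")
}

#' Call genus from the diagnostic rbcL site
#'
#' G at position 431 reads as *Ophiopogon*, A as *Liriope*; anything else
#' (including an N or a deletion) is `"undetermined"`. The genus is called
#' from this single site even when the full haplotype is ambiguous.
#'
#' @param profile An `snp_profile`.
#' @param panel A `haplotype_panel`.
#' @return `"Ophiopogon"`, `"Liriope"` or `"undetermined"`.
#' @export
call_genus <- function(profile, panel) {
  b <- profile$bases[[as.character(panel$genus_position$position)]]
  alleles <- panel$genus_position$alleles
  hit <- names(alleles)[alleles == b]
  if (length(hit) == 1L) hit else "undetermined"
}

# IUPAC-aware per-position agreement: an ambiguity code whose base set
# contains the haplotype base counts as a match; a gap always mismatches.
.base_matches <- function(query_base, hap_base) {
  s <- IUPAC_SETS[[query_base]]
  !is.null(s) && hap_base %in% s
}

#' Call the nearest rbcL haplotype
#'
#' Hamming distance against every panel row, counting IUPAC-compatible
#' ambiguities as matches and gaps as mismatches. Ties at the minimum
#' distance are reported and flagged `"ambiguous"`; a distance above
#' `max_distance` is flagged `"fail"`. The default `max_distance` of 1
#' tolerates a single Sanger-style miscall (flagged `"near"`) while treating
#' panel haplotypes as effectively exact matches.
#'
#' @param profile An `snp_profile`.
#' @param panel A `haplotype_panel`.
#' @param max_distance Maximum accepted Hamming distance (default 1).
#' @return A `haplotype_call`: list with `best`, `distance`, `ties`
#'   (character vector of equally-near alternatives, empty if none),
#'   `genus`, and `flag` in `exact | near | ambiguous | fail`.
#' @export
call_haplotype <- function(profile, panel, max_distance = 1L) {
  stopifnot(inherits(profile, "snp_profile"))
  unambiguous <- profile$bases %in% c("A", "C", "G", "T")
  genus <- call_genus(profile, panel)
  if (!any(unambiguous)) {
    return(structure(list(best = NA_character_, distance = NA_integer_,
                          ties = character(0), genus = genus, flag = "fail"),
                     class = "haplotype_call"))
  }
  dists <- vapply(panel$haplotypes, function(h) {
    sum(!mapply(.base_matches, profile$bases, h$bases))
  }, numeric(1))
  dmin <- min(dists)
  nearest <- names(dists)[dists == dmin]
  best <- nearest[1]
  ties <- nearest[-1]
  flag <- if (dmin > max_distance) "fail"
          else if (length(ties) > 0L) "ambiguous"
          else if (dmin == 0) "exact"
          else "near"
  if (flag == "fail") best <- NA_character_
  structure(list(best = best, distance = as.integer(dmin), ties = ties,
                 genus = genus, flag = flag),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat("<haplotype_call> ",
      if (is.na(x$best)) "no call" else x$best,
      " (distance ", x$distance, ", ", x$flag, "), genus ", x$genus,
      if (length(x$ties)) paste0(", ties: ", paste(x$ties, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.snp_profile <- function(x, ...) {
  cat("<snp_profile> ", x$id, ": ",
      paste(x$bases, collapse = ""), " (", x$n_ambiguous,
      " ambiguous)\n", sep = "")
  invisible(x)
}
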