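#' @title rbcL haplotype panel
#'
#' @description
#' The panel is the tier-one reference key of the pipeline: a set of
#' diagnostic SNP positions in the rbcL barcode region, one row of bases per
#' named haplotype (Type 1 -- Type 6), a haplotype-to-taxon map, the
#' genus-diagnostic G/A site at position 431 (G = *Ophiopogon*,
#' A = *Liriope*), and the three-SNP ITS key (positions 46/231/545) that
#' separates *O. planiscapus* from *O. bodinieri*. Coordinates are 1-based in
#' the packaged reference sequences; the rbcLa sub-region spans columns
#' 1--500 and rbcLb 501--900 of the combined rbcL reference.
#'
#' All structural constraints are enforced at load time so that a
#' transcription error in the panel file fails loudly rather than silently
#' mis-keying a collection.
#'
#' @name haplotype_panel
NULL

PANEL_FORMAT <- "liriopogon-panel-1"

#' Load and validate a haplotype panel
#'
#' @param path Path to a panel JSON file. Defaults to the panel packaged in
#'   `inst/extdata/rbcl_panel.json`.
#' @return A validated object of class `haplotype_panel`.
#' @export
load_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rbcl_panel.json", package = "liriopogon",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$format) || !identical(raw$format, PANEL_FORMAT)) {
    stop("not a liriopogon panel file: ", path)
  }
  positions <- sort(vapply(raw$positions, function(p) as.integer(p$position),
                           integer(1)))
  haps <- lapply(raw$haplotypes, function(h) {
    bases <- unlist(h$bases)
    list(name = h$name,
         taxa = as.character(unlist(h$taxa)),
         bases = bases[as.character(positions)],
         low_confidence = isTRUE(h$low_confidence))
  })
  names(haps) <- vapply(haps, `[[`, character(1), "name")
  panel <- structure(list(
    reference_sequences = vapply(raw$reference_sequences, as.character,
                                 character(1)),
    regions = lapply(raw$regions, function(r) as.integer(unlist(r))),
    consensus = raw$consensus,
    positions = positions,
    haplotypes = haps,
    genus_position = list(
      position = as.integer(raw$genus_position$position),
      alleles = vapply(raw$genus_position$alleles, as.character, character(1))),
    its_triplet = list(
      positions = as.integer(unlist(raw$its_triplet$positions)),
      patterns = lapply(raw$its_triplet$patterns,
                        function(p) as.character(unlist(p))))
  ), class = "haplotype_panel")
  validate_panel(panel)
  panel
}

#' Validate a haplotype panel
#'
#' Checks every structural invariant of the panel and stops with a message
#' naming the offending haplotype or position on the first violation.
#'
#' @param panel A `haplotype_panel`.
#' @return The panel, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ref_len <- nchar(panel$reference_sequences[["rbcL"]])
  pos <- panel$positions
  if (any(pos < 1L) || any(pos > ref_len)) {
    stop("panel position outside reference length [1, ", ref_len, "]: ",
         paste(pos[pos < 1L | pos > ref_len], collapse = ", "))
  }
  if (anyDuplicated(pos)) stop("duplicate panel positions")
  haps <- panel$haplotypes
  if (anyDuplicated(names(haps))) stop("duplicate haplotype names")
  for (h in haps) {
    if (length(h$taxa) == 0L) stop("haplotype ", h$name, " has no taxa")
    if (!identical(names(h$bases), as.character(pos)) || anyNA(h$bases)) {
      stop("haplotype ", h$name, " does not define a base at every position")
    }
    bad <- !h$bases %in% c("A", "C", "G", "T")
    if (any(bad)) {
      stop("haplotype ", h$name, " has a non-ACGT allele at position ",
           paste(names(h$bases)[bad], collapse = ", "))
    }
  }
  rows <- vapply(haps, function(h) paste(h$bases, collapse = ""), character(1))
  if (anyDuplicated(rows)) {
    dup <- names(rows)[duplicated(rows) | duplicated(rows, fromLast = TRUE)]
    stop("identical haplotype rows: ", paste(dup, collapse = ", "))
  }
  # every position must be informative (>= 2 distinct alleles across rows)
  base_mat <- do.call(rbind, lapply(haps, `[[`, "bases"))
  n_alleles <- apply(base_mat, 2, function(col) length(unique(col)))
  if (any(n_alleles < 2L)) {
    stop("non-informative panel position (single allele): ",
         paste(pos[n_alleles < 2L], collapse = ", "))
  }
  # reference sequence must carry the consensus haplotype bases
  cons <- haps[[panel$consensus]]
  if (is.null(cons)) stop("consensus haplotype not in panel: ", panel$consensus)
  ref_bases <- substring(panel$reference_sequences[["rbcL"]], pos, pos)
  if (!identical(unname(cons$bases), ref_bases)) {
    stop("rbcL reference disagrees with consensus haplotype ", panel$consensus)
  }
  # genus-diagnostic site: Liriope row(s) carry A, all Ophiopogon rows G
  gpos <- as.character(panel$genus_position$position)
  if (!gpos %in% names(cons$bases)) stop("genus position not a panel position")
  for (h in haps) {
    is_liriope <- any(grepl("^Liriope", h$taxa))
    expect <- panel$genus_position$alleles[[if (is_liriope) "Liriope" else "Ophiopogon"]]
    if (!identical(unname(h$bases[[gpos]]), expect)) {
      stop("haplotype ", h$name, " carries ", h$bases[[gpos]], " at the genus",
           " site (expected ", expect, ")")
    }
  }
  trip <- panel$its_triplet
  if (length(trip$positions) != 3L) stop("ITS triplet must have 3 positions")
  its_len <- nchar(panel$reference_sequences[["ITS"]])
  if (any(trip$positions < 1L | trip$positions > its_len)) {
    stop("ITS triplet position outside ITS reference")
  }
  if (length(trip$patterns) != 2L) stop("ITS triplet needs exactly 2 patterns")
  pats <- do.call(rbind, trip$patterns)
  if (any(pats[1, ] == pats[2, ])) {
    stop("ITS triplet patterns must differ at all three positions")
  }
  invisible(panel)
}

#' Informative positions of the panel
#'
#' @param panel A `haplotype_panel`.
#' @param region Optional sub-region name (`"rbcLa"` or `"rbcLb"`); when
#'   given, only positions falling inside that region are returned.
#' @return Sorted integer vector of 1-based reference positions.
#' @export
informative_positions <- function(panel, region = NULL) {
  pos <- panel$positions
  if (!is.null(region)) {
    r <- panel$regions[[region]]
    if (is.null(r)) stop("unknown region: ", region)
    pos <- pos[pos >= r[1] & pos <= r[2]]
  }
  pos
}

#' Differences of a haplotype from the panel consensus
#'
#' Lists the positions at which the named haplotype differs from the
#' consensus row (Type 2), and marks which of those variants are unique to
#' the haplotype, i.e. carried by no other row at that position.
#'
#' @param panel A `haplotype_panel`.
#' @param name Haplotype name, e.g. `"Type 6"`.
#' @return A data.frame with columns `position`, `consensus`, `base`,
#'   `unique`; zero rows for the consensus haplotype itself.
#' @export
diff_from_consensus <- function(panel, name) {
  h <- panel$haplotypes[[name]]
  if (is.null(h)) stop("unknown haplotype name: ", name)
  cons <- panel$haplotypes[[panel$consensus]]
  differs <- h$bases != cons$bases
  pos <- panel$positions[differs]
  base <- unname(h$bases[differs])
  others <- panel$haplotypes[setdiff(names(panel$haplotypes), name)]
  uniq <- vapply(seq_along(pos), function(i) {
    p <- as.character(pos[i])
    !any(vapply(others, function(o) identical(unname(o$bases[[p]]), base[i]),
                logical(1)))
  }, logical(1))
  data.frame(position = pos, consensus = unname(cons$bases[differs]),
             base = base, unique = uniq)
}

#' Serialize a panel back to JSON
#'
#' Inverse of [load_panel()]; reloading the written file yields an identical
#' panel object.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- list(
    format = PANEL_FORMAT,
    reference_sequences = as.list(panel$reference_sequences),
    regions = panel$regions,
    consensus = panel$consensus,
    positions = lapply(panel$positions,
                       function(p) list(locus = "rbcL", position = p)),
    haplotypes = lapply(unname(panel$haplotypes), function(h) {
      x <- list(name = h$name, taxa = as.list(h$taxa),
                bases = as.list(h$bases))
      if (isTRUE(h$low_confidence)) x$low_confidence <- TRUE
      x
    }),
    genus_position = list(locus = "rbcL",
                          position = panel$genus_position$position,
                          alleles = as.list(panel$genus_position$alleles)),
    its_triplet = list(positions = panel$its_triplet$positions,
                       patterns = panel$its_triplet$patterns)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", length(x$haplotypes), " haplotypes, ",
      length(x$positions), " informative rbcL positions\n", sep = "")
  cat("  genus site: rbcL ", x$genus_position$position, " (",
      paste(names(x$genus_position$alleles), x$genus_position$alleles,
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  ITS triplet:", paste(x$its_triplet$positions, collapse = "/"), "\n")
  for (h in x$haplotypes) {
    cat("  ", format(h$name, width = 7), " -> ",
        paste(h$taxa, collapse = "; "),
        if (isTRUE(h$low_confidence)) "  [low confidence]" else "", "\n",
        sep = "")
  }
  invisible(x)
}
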