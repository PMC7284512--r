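#' @title Decision engine: combine rbcL and ITS evidence per accession
#'
#' @description
#' The rule table encodes how the two barcode tiers are reconciled: the rbcL
#' haplotype keys the genus and the coarse species group; the ITS clade
#' refines it; and within the *O. planiscapus* / *O. bodinieri* pair the ITS
#' SNP triplet (cis-locus evidence) outranks tree placement when the two
#' disagree. Identifications are compared against the synonym-normalized
#' original label to score each accession confirmed, newly identified, or
#' mis-identified at the species or genus level.
#'
#' @name decision
NULL

#' Default taxon synonym table
#'
#' Maps superseded names to their accepted synonyms before any comparison
#' (L. exiliflora -> L. muscari; O. wallichianus -> O. japonicus). The
#' O. wallichianus entry is debatable (some treatments synonymize it with
#' O. intermedius instead); override by passing your own table.
#'
#' @return Named character vector: label -> accepted name.
#' @export
default_synonyms <- function() {
  c("Liriope exiliflora"      = "Liriope muscari",
    "Ophiopogon wallichianus" = "Ophiopogon japonicus")
}

GENUS_ABBREV <- c(L = "Liriope", O = "Ophiopogon")

#' Normalize a taxon label
#'
#' Expands genus abbreviations ("L.", "O."), strips cultivar epithets in
#' quotes, collapses whitespace, then applies the synonym table. Unknown
#' labels pass through unchanged.
#'
#' @param label Character vector of taxon labels.
#' @param synonyms Named character vector (see [default_synonyms()]).
#' @return Character vector of normalized labels.
#' @export
normalize_label <- function(label, synonyms = default_synonyms()) {
  vapply(label, function(x) {
    x <- gsub("['‘’\"].*?['‘’\"]", "", x)  # cultivar epithets
    x <- gsub("\\s+", " ", trimws(x))
    m <- regmatches(x, regexec("^([A-Z])\\.\\s+(.*)$", x))[[1]]
    if (length(m) == 3L && m[2] %in% names(GENUS_ABBREV)) {
      x <- paste(GENUS_ABBREV[[m[2]]], m[3])
    }
    if (x %in% names(synonyms)) unname(synonyms[[x]]) else x
  }, character(1), USE.NAMES = FALSE)
}

# split a (normalized) label into genus / species epithet / qualifier;
# "sp."-type epithets and bare genus names count as genus-only
parse_taxon <- function(label) {
  label <- gsub("\\s+", " ", trimws(label))
  parts <- strsplit(label, " ")[[1]]
  genus <- if (length(parts) >= 1L) parts[1] else NA_character_
  epithet <- if (length(parts) >= 2L) parts[2] else NA_character_
  qualifier <- if (length(parts) >= 3L) paste(parts[-(1:2)], collapse = " ")
               else NA_character_
  genus_only <- is.na(epithet) || epithet %in% c("sp.", "spp.", "sp", "spp",
                                                 "species", "indet.")
  list(genus = genus, epithet = if (genus_only) NA_character_ else epithet,
       qualifier = qualifier, genus_only = genus_only)
}

CLADE_GENUS <- c("Liriope-muscari" = "Liriope", "Liriope-spicata" = "Liriope",
                 "B2" = "Ophiopogon", "B3a" = "Ophiopogon",
                 "B3b" = "Ophiopogon", "jaburan-branch" = "Ophiopogon")
CLADE_SPECIES <- c("Liriope-muscari" = "Liriope muscari",
                   "Liriope-spicata" = "Liriope spicata",
                   "B2"  = "Ophiopogon japonicus",
                   "B3a" = "Ophiopogon planiscapus",
                   "B3b" = "Ophiopogon bodinieri",
                   "jaburan-branch" = "Ophiopogon jaburan")

.trip_is <- function(triplet, species) {
  !is.null(triplet) && !is.na(triplet$call) && triplet$call == species
}

#' Combine per-accession evidence into an identification
#'
#' Applies the rule table, in order: Type 6 is *Liriope* with the species
#' read from the ITS cluster; Types 1 and 5 are unique keys (O. japonicus
#' (I), O. jaburan); Type 3 is *O. planiscapus* and must be corroborated by
#' the ITS triplet; Type 2 is resolved by ITS -- clade B2 means O. japonicus
#' (II), while a B3 placement with the bodinieri triplet means O. bodinieri,
#' the triplet overriding a conflicting B3a/B3b placement; Type 4 falls back
#' on the panel's (low-confidence) taxon list. With no usable rbcL call the
#' identification is ITS-only and flagged `single_locus`.
#'
#' @param haplotype A `haplotype_call`, or `NULL` if the locus is missing.
#' @param clade A `clade_assignment`, or `NULL` if the locus is missing.
#' @param triplet A `triplet_call`, or `NULL`.
#' @param panel A `haplotype_panel`.
#' @return List with `genus`, `species` (NA when unresolved), `flags`
#'   (character vector).
#' @export
identify_accession <- function(haplotype, clade, triplet, panel) {
  flags <- character(0)
  hap_ok <- !is.null(haplotype) && !is.na(haplotype$best) &&
    haplotype$flag %in% c("exact", "near")
  clade_label <- if (!is.null(clade) &&
                     clade$label %in% names(CLADE_GENUS)) clade$label else NA
  if (!is.null(haplotype) && haplotype$flag == "ambiguous") {
    flags <- c(flags, "haplotype_ambiguous")
  }
  if (!is.null(clade) && identical(clade$flag, "low_confidence")) {
    flags <- c(flags, "clade_low_confidence")
  }
  if (!hap_ok && is.null(clade)) {
    if (is.null(haplotype)) stop("at least one locus must have produced a call")
    return(list(genus = haplotype$genus, species = NA_character_,
                flags = c(flags, "undetermined")))
  }
  plan <- "Ophiopogon planiscapus"; bod <- "Ophiopogon bodinieri"
  if (hap_ok) {
    type <- haplotype$best
    genus <- if (identical(haplotype$genus, "undetermined")) {
      if (type == "Type 6") "Liriope" else "Ophiopogon"
    } else haplotype$genus
    if (!is.na(clade_label) && CLADE_GENUS[[clade_label]] != genus) {
      flags <- c(flags, "genus_discordance")
    }
    species <- NA_character_
    if (type == "Type 6") {
      species <- switch(ifelse(is.na(clade_label), "none", clade_label),
                        "Liriope-muscari" = "Liriope muscari",
                        "Liriope-spicata" = "Liriope spicata",
                        NA_character_)
      if (is.na(species)) flags <- c(flags, "its_unresolved")
    } else if (type == "Type 1") {
      species <- "Ophiopogon japonicus (I)"
      if (!is.na(clade_label) && clade_label != "B2") {
        flags <- c(flags, "clade_conflict")
      }
    } else if (type == "Type 5") {
      species <- "Ophiopogon jaburan"
      if (!is.na(clade_label) && clade_label != "jaburan-branch") {
        flags <- c(flags, "clade_conflict")
      }
    } else if (type == "Type 3") {
      species <- plan
      if (.trip_is(triplet, plan)) {
        if (isTRUE(triplet$partial)) flags <- c(flags, "triplet_partial")
        if (!is.na(clade_label) && clade_label == "B3b") {
          flags <- c(flags, "triplet_overrides_placement")
        }
      } else {
        flags <- c(flags, "triplet_conflict")
      }
    } else if (type == "Type 2") {
      if (!is.na(clade_label) && clade_label == "B2") {
        species <- "Ophiopogon japonicus (II)"
      } else if (!is.na(clade_label) && clade_label %in% c("B3a", "B3b")) {
        if (.trip_is(triplet, bod)) {
          species <- bod
          if (isTRUE(triplet$partial)) flags <- c(flags, "triplet_partial")
          if (clade_label == "B3a") {
            flags <- c(flags, "triplet_overrides_placement")
          }
        } else if (.trip_is(triplet, plan)) {
          # a planiscapus triplet contradicts the non-planiscapus haplotype
          flags <- c(flags, "rbcl_its_conflict")
        } else if (clade_label == "B3b") {
          species <- bod
          flags <- c(flags, "triplet_undetermined")
        } else {
          flags <- c(flags, "rbcl_its_conflict")
        }
      } else {
        flags <- c(flags, "its_unresolved")
      }
    } else if (type == "Type 4") {
      species <- panel$haplotypes[["Type 4"]]$taxa[1]
      flags <- c(flags, "low_confidence")
    }
    return(list(genus = genus, species = species, flags = unique(flags)))
  }
  # ITS-only path
  flags <- c(flags, "single_locus")
  if (is.na(clade_label)) {
    return(list(genus = "undetermined", species = NA_character_,
                flags = c(flags, "undetermined")))
  }
  genus <- CLADE_GENUS[[clade_label]]
  species <- CLADE_SPECIES[[clade_label]]
  if (clade_label == "B3a" && !.trip_is(triplet, plan)) {
    flags <- c(flags, "triplet_conflict")
  }
  if (clade_label == "B3b" && .trip_is(triplet, plan)) {
    species <- plan
    flags <- c(flags, "triplet_overrides_placement")
  }
  list(genus = genus, species = species, flags = unique(flags))
}

#' Score an identification against the original label
#'
#' Comparison is at the accepted-name level: labels are assumed already
#' normalized, and subgroup Roman numerals ("(I)", "(II)") are ignored.
#' A genus mismatch always scores `genus_misid`, even for a genus-only
#' label; a genus-only label resolved to species scores `newly_identified`.
#'
#' @param genus,species Final identification (species may be NA).
#' @param normalized_label Synonym-normalized original label.
#' @return One of `confirmed`, `species_misid`, `genus_misid`,
#'   `newly_identified`, `undetermined`.
#' @export
status_of <- function(genus, species, normalized_label) {
  lab <- parse_taxon(normalized_label)
  if (is.na(genus) || identical(genus, "undetermined")) return("undetermined")
  if (!is.na(lab$genus) && lab$genus %in% unname(GENUS_ABBREV) &&
      lab$genus != genus) {
    return("genus_misid")
  }
  if (is.na(species)) return("undetermined")
  if (lab$genus_only || !lab$genus %in% unname(GENUS_ABBREV)) {
    return("newly_identified")
  }
  fin <- parse_taxon(strip_subgroup(species))
  if (identical(fin$epithet, lab$epithet)) "confirmed" else "species_misid"
}

strip_subgroup <- function(x) {
  gsub("\\s*\\((I{1,3}|IV|V)\\)\\s*$", "", x)
}

#' Build a collection report from per-accession identifications
#'
#' @param identifications List of per-accession lists, each with fields
#'   `accession_id`, `original_label`, `normalized_label`, `genus`,
#'   `species`, `status`, `flags`, and the evidence columns
#'   (`rbcl_haplotype`, `rbcl_distance`, `genus_snp`, `its_clade`,
#'   `its_support`, `triplet`).
#' @return A `collection_report`: list with `table` (data.frame, one row per
#'   accession, stable column order) and `tallies`.
#' @export
collection_report <- function(identifications) {
  if (length(identifications) == 0L) stop("no identifications")
  take <- function(f, default = NA_character_) {
    vapply(identifications, function(x) {
      v <- x[[f]]
      if (is.null(v) || length(v) == 0L || is.na(v[1])) default else as.character(v[1])
    }, character(1))
  }
  tab <- data.frame(
    accession_id = take("accession_id"),
    original_label = take("original_label"),
    normalized_label = take("normalized_label"),
    rbcl_haplotype = take("rbcl_haplotype"),
    rbcl_distance = take("rbcl_distance"),
    genus_snp = take("genus_snp"),
    its_clade = take("its_clade"),
    its_support = take("its_support"),
    triplet = take("triplet"),
    final_genus = take("genus"),
    final_identity = take("species"),
    status = take("status"),
    flags = vapply(identifications, function(x) {
      paste(x$flags, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  status <- tab$status
  n_misid <- sum(status %in% c("species_misid", "genus_misid"))
  tallies <- list(
    total = nrow(tab),
    confirmed = sum(status == "confirmed"),
    newly_identified = sum(status == "newly_identified"),
    misidentified = n_misid,
    species_misid = sum(status == "species_misid"),
    genus_misid = sum(status == "genus_misid"),
    undetermined = sum(status == "undetermined"),
    by_genus = table(tab$final_genus, tab$status)
  )
  stopifnot(tallies$confirmed + tallies$newly_identified +
              tallies$misidentified + tallies$undetermined == tallies$total,
            tallies$species_misid + tallies$genus_misid ==
              tallies$misidentified)
  structure(list(table = tab, tallies = tallies), class = "collection_report")
}

#' @export
print.collection_report <- function(x, ...) {
  t <- x$tallies
  cat("<collection_report> ", t$total, " accessions: ",
      t$confirmed, " confirmed, ", t$newly_identified, " newly identified, ",
      t$misidentified, " misidentified (", t$genus_misid, " genus-level, ",
      t$species_misid, " species-level), ", t$undetermined,
      " undetermined\n", sep = "")
  invisible(x)
}

#' Write a collection report as TSV
#'
#' @param report A `collection_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a collection report as JSON (per-accession rows plus tallies)
#'
#' @param report A `collection_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  tall <- report$tallies
  tall$by_genus <- NULL
  jsonlite::write_json(list(accessions = report$table, tallies = tall),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
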