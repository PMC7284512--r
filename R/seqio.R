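#' @title Sequence and manifest I/O, reference-anchored coordinates
#'
#' @description
#' All coordinate logic in the pipeline is pairwise-to-reference: each query
#' amplicon is globally aligned to the packaged locus reference
#' (Needleman-Wunsch with affine gaps, via Biostrings) and panel lookups are
#' made through the resulting coordinate map. No multiple sequence alignment
#' is performed.
#'
#' @name seqio
NULL

IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and alignment gap characters (`-`, `.`) are
#' stripped with a warning. Duplicate ids are kept but suffix-deduplicated
#' (`id`, `id.2`, ...) with a warning.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  chr <- toupper(as.character(seqs))
  if (any(grepl("[-.]", chr))) {
    warning("gap characters stripped from input sequences in ", basename(path))
    chr <- gsub("[-.]", "", chr)
  }
  if (any(nchar(chr) == 0L)) stop("empty sequence record in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids in ", basename(path),
            "; suffix-deduplicated")
    ids <- make.unique(ids, sep = ".")
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a collection manifest
#'
#' Tab-separated with a header row; `#` lines are comments. Requires at
#' least `accession_id` and `original_label` columns.
#'
#' @param path Manifest TSV path.
#' @return A data.frame, one row per accession.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("accession_id", "original_label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$accession_id)) stop("duplicate accession_id in manifest")
  m
}

# IUPAC-aware substitution matrix: any overlap between the two base sets
# scores as a match (so N and compatible ambiguity codes align silently).
iupac_substitution_matrix <- function(match = 1, mismatch = -1) {
  letters <- names(IUPAC_SETS)
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (a in letters) for (b in letters) {
    if (length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L) {
      m[a, b] <- match
    }
  }
  m
}

#' Align a query to a locus reference and map coordinates
#'
#' Global pairwise alignment (affine gap penalties; defaults mirror the
#' Clustal-style costs used for the published alignments: gap open 10, gap
#' extension 1, with simple match/mismatch scores of +1/-1). The result maps
#' every reference position to the aligned query position, or `NA` where the
#' query has a deletion.
#'
#' @param query Single-sequence [Biostrings::DNAStringSet] element, `DNAString`
#'   or character scalar (optionally named).
#' @param reference Reference sequence in the same forms.
#' @param match,mismatch,gap_open,gap_ext Alignment scores; penalties are
#'   given as positive numbers.
#' @param identity_floor Minimum identity over reference positions covered by
#'   the query (default 0.7); below this the query is rejected as the wrong
#'   locus.
#' @return An object of class `coord_map`: list with `query_id`,
#'   `reference_id`, `map` (integer vector, one entry per reference
#'   position, `NA` = gap), `score`, `identity` and `coverage`.
#' @export
align_to_reference <- function(query, reference, match = 1, mismatch = -1,
                               gap_open = 10, gap_ext = 1,
                               identity_floor = 0.7) {
  qc <- .as_seq_chr(query); rc <- .as_seq_chr(reference)
  if (nchar(qc) == 0L || nchar(rc) == 0L) stop("empty sequence")
  sub_mat <- iupac_substitution_matrix(match, mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = qc, subject = rc, type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_len <- nchar(rc)
  map <- rep(NA_integer_, ref_len)
  qi <- 0L; ri <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") qi <- qi + 1L
    if (sbj[k] != "-") {
      ri <- ri + 1L
      if (pat[k] != "-") map[ri] <- qi
    }
  }
  covered <- !is.na(map)
  qb <- strsplit(qc, "")[[1]]
  rb <- strsplit(rc, "")[[1]]
  matches <- sum(vapply(which(covered), function(p) {
    qs <- IUPAC_SETS[[qb[map[p]]]]
    !is.null(qs) && rb[p] %in% qs
  }, logical(1)))
  identity <- if (any(covered)) matches / sum(covered) else 0
  if (identity < identity_floor) {
    stop("alignment identity ", round(identity, 3), " below floor ",
         identity_floor, " for query '", .seq_id(query),
         "': wrong locus or unusable sequence")
  }
  structure(list(query_id = .seq_id(query), reference_id = .seq_id(reference),
                 map = map, score = Biostrings::score(aln),
                 identity = identity, coverage = mean(covered)),
            class = "coord_map")
}

#' Query base aligned to a reference position
#'
#' @param map A `coord_map` from [align_to_reference()].
#' @param query The query sequence the map was built from.
#' @param position 1-based reference coordinate.
#' @return A single uppercase character; `"-"` where the query has a
#'   deletion spanning the position.
#' @export
base_at <- function(map, query, position) {
  stopifnot(inherits(map, "coord_map"))
  if (position < 1L || position > length(map$map)) {
    stop("position ", position, " outside reference [1, ",
         length(map$map), "]")
  }
  qpos <- map$map[position]
  if (is.na(qpos)) return("-")
  substr(.as_seq_chr(query), qpos, qpos)
}

#' @export
print.coord_map <- function(x, ...) {
  cat("<coord_map> ", x$query_id, " -> ", x$reference_id,
      sprintf(" (score %.1f, identity %.1f%%, coverage %.1f%%)\n",
              x$score, 100 * x$identity, 100 * x$coverage), sep = "")
  invisible(x)
}

.as_seq_chr <- function(x) {
  if (is.character(x)) return(toupper(unname(x[1])))
  toupper(as.character(x)[1])
}

.seq_id <- function(x) {
  n <- names(x)
  if (!is.null(n) && nzchar(n[1])) n[1] else "seq"
}
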