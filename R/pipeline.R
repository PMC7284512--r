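#' @title End-to-end orchestration
#'
#' @description
#' `run_verify()` drives the full two-tier identification: tier one (genus
#' SNP and rbcL haplotype) per accession, tier two (ITS tree, bootstrap,
#' clade assignment, SNP triplet), then the decision engine and the
#' collection report. `run_simulate()` writes a synthetic collection to
#' disk in the formats `run_verify()` consumes.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param rbcl_fasta,its_fasta Paths to query FASTA files (either may be
#'   `NULL` for a single-locus run, not both).
#' @param manifest Path to the collection manifest TSV
#'   (accession_id / original_label).
#' @param its_refs Path to the labelled ITS reference FASTA; headers carry
#'   the clade as a `clade=LABEL` token in the description.
#' @param panel Optional panel JSON path (default: packaged panel).
#' @param out_dir Optional output directory for artifacts.
#' @param bootstrap Bootstrap replicates (default 100; use 1000 to match a
#'   publication-grade consensus).
#' @param threshold Consensus/support threshold in (0, 1], default 0.5.
#' @param max_distance Maximum accepted haplotype Hamming distance.
#' @param seed Integer seed for the bootstrap resampling.
#' @param identity_floor Minimum alignment identity before a query is
#'   rejected as wrong-locus.
#' @param verbose Narrate the per-accession evidence trail.
#' @return A `run_config` list.
#' @export
run_config <- function(rbcl_fasta = NULL, its_fasta = NULL, manifest = NULL,
                       its_refs = NULL, panel = NULL, out_dir = NULL,
                       bootstrap = 100L, threshold = 0.5, max_distance = 1L,
                       seed = 42L, identity_floor = 0.7, verbose = FALSE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (bootstrap < 1L) stop("bootstrap replicates must be >= 1")
  structure(list(rbcl_fasta = rbcl_fasta, its_fasta = its_fasta,
                 manifest = manifest, its_refs = its_refs, panel = panel,
                 out_dir = out_dir, bootstrap = as.integer(bootstrap),
                 threshold = threshold, max_distance = as.integer(max_distance),
                 seed = as.integer(seed), identity_floor = identity_floor,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a labelled ITS reference FASTA
#'
#' @param path FASTA whose headers contain a `clade=LABEL` token.
#' @return List with `seqs` (named character) and `labels` (ref id ->
#'   clade label).
#' @export
read_labelled_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty reference FASTA: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  m <- regmatches(names(raw), regexpr("clade=[^\\s]+", names(raw), perl = TRUE))
  if (length(m) != length(raw)) {
    stop("every reference header needs a clade=LABEL token: ", path)
  }
  labels <- sub("^clade=", "", m)
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  names(labels) <- ids
  list(seqs = seqs, labels = labels)
}

# reference-anchored alignment matrix: one row per sequence, one column per
# reference position; deletions/uncovered positions become "-"
.anchored_matrix <- function(seqs, reference, identity_floor = 0.7) {
  ref_len <- nchar(reference[[1]])
  rows <- lapply(names(seqs), function(id) {
    cm <- align_to_reference(stats::setNames(seqs[id], id), reference,
                             identity_floor = identity_floor)
    v <- strsplit(seqs[[id]], "")[[1]]
    out <- rep("-", ref_len)
    ok <- !is.na(cm$map)
    out[ok] <- v[cm$map[ok]]
    out
  })
  M <- do.call(rbind, rows)
  rownames(M) <- names(seqs)
  M
}

#' Run the full two-tier verification
#'
#' @param config A `run_config`.
#' @return A `collection_report`; with `config$out_dir` set, also writes
#'   `report.tsv`, `report.json`, `its_nj.nwk` (point-estimate tree with
#'   supports), `its_consensus.nwk` and `accession_log.txt`.
#' @export
run_verify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panel <- load_panel(config$panel)
  manifest <- read_manifest(config$manifest)
  manifest$normalized_label <- normalize_label(manifest$original_label)
  note <- function(...) if (config$verbose) message(...)

  rbcl <- if (!is.null(config$rbcl_fasta)) {
    s <- read_fasta(config$rbcl_fasta); stats::setNames(as.character(s), names(s))
  }
  its <- if (!is.null(config$its_fasta)) {
    s <- read_fasta(config$its_fasta); stats::setNames(as.character(s), names(s))
  }
  if (is.null(rbcl) && is.null(its)) stop("no query sequences given")

  # ---- tier one: rbcL haplotype ----
  hap_calls <- list()
  if (!is.null(rbcl)) {
    for (id in intersect(manifest$accession_id, names(rbcl))) {
      hap_calls[[id]] <- tryCatch({
        prof <- extract_profile(stats::setNames(rbcl[id], id), panel,
                                identity_floor = config$identity_floor)
        call <- call_haplotype(prof, panel, max_distance = config$max_distance)
        note(id, ": genus SNP -> ", call$genus, "; haplotype -> ",
             if (is.na(call$best)) "none" else call$best,
             " (distance ", call$distance, ", ", call$flag, ")")
        call
      }, error = function(e) {
        warning("rbcL call failed for ", id, ": ", conditionMessage(e))
        NULL
      })
    }
  }

  # ---- tier two: ITS tree, clades, triplet ----
  clades <- list(); triplets <- list()
  nj <- NULL; cons <- NULL
  if (!is.null(its)) {
    if (is.null(config$its_refs)) stop("ITS queries given without its_refs")
    refs <- read_labelled_fasta(config$its_refs)
    its_q <- its[intersect(manifest$accession_id, names(its))]
    reference <- c(ITS = panel$reference_sequences[["ITS"]])
    aln <- .anchored_matrix(c(refs$seqs, its_q), reference,
                            identity_floor = config$identity_floor)
    D <- k2p_matrix(aln)
    nj <- nj_tree(D)
    cons <- bootstrap_consensus(aln, B = config$bootstrap,
                                threshold = config$threshold,
                                seed = config$seed)
    nj <- map_supports(nj, attr(cons, "replicate_trees"))
    for (id in names(its_q)) {
      clades[[id]] <- assign_clade(nj, id, refs$labels,
                                   threshold = config$threshold)
      triplets[[id]] <- tryCatch(
        triplet_call(stats::setNames(its_q[id], id), panel,
                     identity_floor = config$identity_floor),
        error = function(e) NULL)
      note(id, ": ITS clade -> ", clades[[id]]$label,
           " (", clades[[id]]$flag, "); triplet -> ",
           if (is.null(triplets[[id]])) "none" else triplets[[id]]$call)
    }
  }

  # ---- decision ----
  idents <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$accession_id[i]
    hap <- hap_calls[[id]]
    cl <- clades[[id]]
    tr <- triplets[[id]]
    if (is.null(hap) && is.null(cl)) {
      res <- list(genus = "undetermined", species = NA_character_,
                  flags = c("no_data", "undetermined"))
    } else {
      res <- identify_accession(hap, cl, tr, panel)
      if (is.null(hap) || is.null(cl)) {
        res$flags <- unique(c(res$flags, "single_locus"))
      }
    }
    status <- status_of(res$genus, res$species, manifest$normalized_label[i])
    note(id, ": decision -> ",
         if (is.na(res$species)) res$genus else res$species, " [", status, "]")
    list(accession_id = id,
         original_label = manifest$original_label[i],
         normalized_label = manifest$normalized_label[i],
         rbcl_haplotype = if (!is.null(hap)) hap$best else NA,
         rbcl_distance = if (!is.null(hap)) hap$distance else NA,
         genus_snp = if (!is.null(hap)) hap$genus else NA,
         its_clade = if (!is.null(cl)) cl$label else NA,
         its_support = if (!is.null(cl)) cl$support else NA,
         triplet = if (!is.null(tr)) tr$call else NA,
         genus = res$genus, species = res$species,
         status = status, flags = res$flags)
  })
  report <- collection_report(idents)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(report, file.path(config$out_dir, "report.tsv"))
    write_report_json(report, file.path(config$out_dir, "report.json"))
    if (!is.null(nj)) {
      ape::write.tree(nj, file.path(config$out_dir, "its_nj.nwk"))
      ape::write.tree(cons, file.path(config$out_dir, "its_consensus.nwk"))
    }
    log_lines <- vapply(idents, function(x) {
      paste(x$accession_id, x$status,
            if (is.na(x$species)) x$genus else x$species,
            paste(x$flags, collapse = ";"), sep = "\t")
    }, character(1))
    writeLines(log_lines, file.path(config$out_dir, "accession_log.txt"))
  }
  report
}

#' Write a synthetic collection to disk
#'
#' With `collection = TRUE`, reconstructs the packaged 73-accession
#' collection; otherwise generates `n` accessions of `species`. Outputs
#' `rbcl.fasta`, `its.fasta`, `manifest.tsv` and `its_refs.fasta` under
#' `out_dir`; byte-identical across runs for a fixed configuration.
#'
#' @param config A `generator_config`.
#' @param out_dir Output directory (created if needed).
#' @param collection Reconstruct the packaged collection (default TRUE).
#' @param n,species Number of accessions and species name when
#'   `collection = FALSE`.
#' @return Named list of output paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, collection = TRUE, n = 5L,
                         species = "Ophiopogon jaburan") {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_panel()
  if (collection) {
    coll <- reconstruct_collection(config, panel = panel)
    rbcl <- coll$rbcl; its <- coll$its
    manifest <- coll$manifest
    refset <- coll$reference_set
  } else {
    refset <- make_reference_set(panel, seed = config$seed)
    rbcl <- character(0); its <- character(0)
    ids <- sprintf("SIM_%03d", seq_len(n))
    with_seed(config$seed, {
      for (id in ids) {
        acc <- generate_accession(species, refset, config, id = id)
        rbcl <- c(rbcl, acc$rbcl)
        its <- c(its, acc$its)
      }
    })
    manifest <- data.frame(accession_id = ids, original_label = species,
                           collection = strsplit(species, " ")[[1]][1])
  }
  paths <- list(rbcl = file.path(out_dir, "rbcl.fasta"),
                its = file.path(out_dir, "its.fasta"),
                manifest = file.path(out_dir, "manifest.tsv"),
                its_refs = file.path(out_dir, "its_refs.fasta"))
  write_fasta(rbcl, paths$rbcl)
  write_fasta(its, paths$its)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref_seqs <- Biostrings::DNAStringSet(refset$its_refs)
  names(ref_seqs) <- sprintf("%s clade=%s", names(refset$its_refs),
                             unname(refset$ref_labels))
  Biostrings::writeXStringSet(ref_seqs, paths$its_refs)
  invisible(paths)
}
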