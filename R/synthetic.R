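#' @title Synthetic two-locus collections
#'
#' @description
#' Generates rbcL and ITS amplicons realizing any panel haplotype and ITS
#' clade signature, entirely from the packaged reference backbones: an rbcL
#' sequence for a haplotype is the reference with that row's bases
#' substituted; ITS clade references share a common backbone and differ by
#' clade-diagnostic substitution blocks (~2% per clade, plus a shared
#' *Liriope* block that makes the genus monophyletic, and the diagnostic
#' 46/231/545 triplet separating the B3a and B3b signatures). Per-base
#' substitution noise, N injection and indels are seeded and optional;
#' diagnostic positions can be protected so that noise emulates Sanger
#' miscalls without destroying the signal the pipeline keys on.
#'
#' Only the diagnostic positions of these sequences carry biological
#' meaning; the backbones themselves are fixed synthetic sequences, not
#' GenBank material.
#'
#' @name synthetic_data
NULL

# clade-diagnostic ITS substitution blocks (1-based backbone coordinates);
# each clade's references carry a transition at every listed position
ITS_CLADE_POSITIONS <- list(
  "Liriope-muscari" = c(250, 262, 274, 286, 298, 310, 322, 334, 346, 358, 370, 382),
  "Liriope-spicata" = c(255, 267, 279, 291, 303, 315, 327, 339, 351, 363, 375, 387),
  "B2"              = c(400, 410, 420, 430, 440, 450, 460, 470, 480, 490, 500, 510),
  "B3a"             = c(70, 85, 100, 115, 130, 145, 160, 175, 190, 205, 220, 235),
  "B3b"             = c(72, 87, 102, 117, 132, 147, 162, 177, 192, 207, 222, 237),
  "jaburan-branch"  = c(515, 521, 527, 533, 539, 551, 557, 563, 569, 575, 581, 587)
)
ITS_LIRIOPE_SHARED <- c(60, 75, 90, 105, 120, 135, 150, 165, 180, 195, 210, 225)

# species -> (rbcL haplotype, ITS clade); the pipeline's ground-truth map
SPECIES_MAP <- list(
  "Liriope muscari"           = list(haplotype = "Type 6", clade = "Liriope-muscari"),
  "Liriope spicata"           = list(haplotype = "Type 6", clade = "Liriope-spicata"),
  "Ophiopogon japonicus (I)"  = list(haplotype = "Type 1", clade = "B2"),
  "Ophiopogon japonicus (II)" = list(haplotype = "Type 2", clade = "B2"),
  "Ophiopogon jaburan"        = list(haplotype = "Type 5", clade = "jaburan-branch"),
  "Ophiopogon planiscapus"    = list(haplotype = "Type 3", clade = "B3a"),
  "Ophiopogon bodinieri"      = list(haplotype = "Type 2", clade = "B3b"),
  "Ophiopogon chingii"        = list(haplotype = "Type 3", clade = "B3b"),
  "Ophiopogon longifolius"    = list(haplotype = "Type 4", clade = "B2")
)

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Generator configuration
#'
#' @param seed Integer seed (mandatory).
#' @param substitution_rate Per-base substitution probability in [0, 0.2].
#' @param n_rate Per-base ambiguity (N) injection probability in [0, 0.2].
#' @param protect_diagnostic Keep panel/clade/triplet positions untouched by
#'   noise (default TRUE).
#' @param indel_rate Per-base indel probability in [0, 0.2] (default 0).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, substitution_rate = 0, n_rate = 0,
                             protect_diagnostic = TRUE, indel_rate = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  rates <- c(substitution_rate, n_rate, indel_rate)
  if (any(rates < 0 | rates > 0.2)) stop("rates must be in [0, 0.2]")
  structure(list(seed = as.integer(seed),
                 substitution_rate = substitution_rate,
                 n_rate = n_rate,
                 protect_diagnostic = isTRUE(protect_diagnostic),
                 indel_rate = indel_rate),
            class = "generator_config")
}

.substitute_bases <- function(seq, positions, bases) {
  v <- strsplit(seq, "")[[1]]
  v[positions] <- bases
  paste(v, collapse = "")
}

#' Build the synthetic reference set
#'
#' One rbcL sequence per panel haplotype, and `n_refs` labelled ITS
#' reference sequences per clade (the first is the clade consensus; the
#' others add two private substitutions each at seeded non-diagnostic
#' positions, so every clade is a supported group even at zero noise).
#'
#' @param panel A `haplotype_panel`.
#' @param seed Integer seed for the private reference variation.
#' @param n_refs References per clade (>= 2 for clade assignment; default 3).
#' @return A `reference_set`: list with `rbcl` (named character, one per
#'   haplotype), `its_refs` (named character), `ref_labels` (ref id ->
#'   clade), `its_clade_consensus`, `protect` (diagnostic positions per
#'   locus) and `species_map`.
#' @export
make_reference_set <- function(panel, seed = 42L, n_refs = 3L) {
  backbone_r <- panel$reference_sequences[["rbcL"]]
  backbone_i <- panel$reference_sequences[["ITS"]]
  rbcl <- vapply(panel$haplotypes, function(h) {
    .substitute_bases(backbone_r, panel$positions, unname(h$bases))
  }, character(1))
  trip <- panel$its_triplet
  clade_cons <- vapply(names(ITS_CLADE_POSITIONS), function(cl) {
    pos <- ITS_CLADE_POSITIONS[[cl]]
    if (grepl("^Liriope", cl)) pos <- c(pos, ITS_LIRIOPE_SHARED)
    v <- strsplit(backbone_i, "")[[1]]
    v[pos] <- TRANSITION[v[pos]]
    if (cl == "B3b") {
      # backbone carries the planiscapus triplet; B3b flips to bodinieri
      v[trip$positions] <- trip$patterns[["Ophiopogon bodinieri"]]
    }
    paste(v, collapse = "")
  }, character(1))
  diagnostic_its <- sort(unique(c(unlist(ITS_CLADE_POSITIONS),
                                  ITS_LIRIOPE_SHARED, trip$positions)))
  free <- setdiff(seq_len(nchar(backbone_i)), diagnostic_its)
  refs <- character(0); labels <- character(0)
  with_seed(seed, {
    for (cl in names(clade_cons)) {
      for (k in seq_len(n_refs)) {
        s <- clade_cons[[cl]]
        if (k > 1L) {
          pos <- sample(free, 2L)
          v <- strsplit(s, "")[[1]]
          v[pos] <- TRANSITION[v[pos]]
          s <- paste(v, collapse = "")
        }
        id <- sprintf("REF_%s_%d", gsub("[^A-Za-z0-9]", "", cl), k)
        refs[id] <- s
        labels[id] <- cl
      }
    }
  })
  structure(list(rbcl = rbcl, its_refs = refs, ref_labels = labels,
                 its_clade_consensus = clade_cons,
                 protect = list(rbcL = panel$positions, ITS = diagnostic_its),
                 species_map = SPECIES_MAP, panel = panel),
            class = "reference_set")
}

# apply seeded noise to one sequence; uses the current RNG stream
.mutate <- function(seq, config, protect) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  eligible <- if (config$protect_diagnostic) setdiff(seq_len(n), protect)
              else seq_len(n)
  if (config$substitution_rate > 0 && length(eligible) > 0) {
    hit <- eligible[stats::runif(length(eligible)) < config$substitution_rate]
    for (p in hit) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    }
  }
  if (config$n_rate > 0 && length(eligible) > 0) {
    hit <- eligible[stats::runif(length(eligible)) < config$n_rate]
    v[hit] <- "N"
  }
  if (config$indel_rate > 0 && length(eligible) > 0) {
    del <- eligible[stats::runif(length(eligible)) < config$indel_rate / 2]
    ins <- eligible[stats::runif(length(eligible)) < config$indel_rate / 2]
    if (length(del) > 0 || length(ins) > 0) {
      keep <- rep(TRUE, n); keep[del] <- FALSE
      out <- character(0)
      for (p in seq_len(n)) {
        if (p %in% ins) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
        if (keep[p]) out <- c(out, v[p])
      }
      v <- out
    }
  }
  paste(v, collapse = "")
}

#' Generate one accession's two-locus sequences
#'
#' Copies the species' rbcL haplotype sequence and ITS clade consensus and
#' applies the configured noise. Uses the current RNG stream: seed it once
#' per collection (as [reconstruct_collection()] and [run_simulate()] do)
#' rather than per accession.
#'
#' @param species True species name (must be in the reference set's map).
#' @param refset A `reference_set` from [make_reference_set()].
#' @param config A `generator_config`.
#' @param id Accession id used to name the records.
#' @return List with named character elements `rbcl` and `its`.
#' @export
generate_accession <- function(species, refset, config, id = "ACC") {
  sm <- refset$species_map[[species]]
  if (is.null(sm)) stop("unknown species: ", species)
  rb <- .mutate(refset$rbcl[[sm$haplotype]], config, refset$protect$rbcL)
  it <- .mutate(refset$its_clade_consensus[[sm$clade]], config,
                refset$protect$ITS)
  list(rbcl = stats::setNames(rb, id), its = stats::setNames(it, id))
}

#' Load the packaged truth manifest
#'
#' @param path Optional path to a truth manifest TSV; defaults to the
#'   packaged reconstruction of the 73-accession collection.
#' @return A data.frame with columns `accession_id`, `collection`,
#'   `original_label`, `true_species`, `rbcl_type`, `its_clade`,
#'   `reconstructed`.
#' @export
load_truth_manifest <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "truth_manifest.tsv",
                        package = "liriopogon", mustWork = TRUE)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate the truth manifest against the published category totals
#'
#' Before any sequence is generated, checks that the fixture is internally
#' consistent (haplotype and clade agree with the species map) and that the
#' statuses implied by label-vs-truth comparison reproduce the published
#' integers: 73 tested, 36 confirmed, 4 newly identified, 33 misidentified
#' (7 genus-level, 26 species-level), 46 Liriope-collection rows with 27
#' confirmed, and 9 Type 3 accessions.
#'
#' @param truth Truth manifest data.frame.
#' @param panel A `haplotype_panel`.
#' @return The implied tally list, invisibly.
#' @export
validate_truth_manifest <- function(truth, panel) {
  need <- c("accession_id", "collection", "original_label", "true_species",
            "rbcl_type", "its_clade")
  if (!all(need %in% names(truth))) {
    stop("truth manifest missing columns: ",
         paste(setdiff(need, names(truth)), collapse = ", "))
  }
  if (anyDuplicated(truth$accession_id)) stop("duplicate accession ids")
  for (i in seq_len(nrow(truth))) {
    sm <- SPECIES_MAP[[truth$true_species[i]]]
    if (is.null(sm)) stop("unknown true species: ", truth$true_species[i])
    if (!identical(sm$haplotype, truth$rbcl_type[i]) ||
        !identical(sm$clade, truth$its_clade[i])) {
      stop("haplotype/clade inconsistent with species map for ",
           truth$accession_id[i])
    }
  }
  norm <- normalize_label(truth$original_label)
  status <- vapply(seq_len(nrow(truth)), function(i) {
    sp <- truth$true_species[i]
    status_of(genus = strsplit(sp, " ")[[1]][1], species = sp,
              normalized_label = norm[i])
  }, character(1))
  t <- list(total = nrow(truth),
            confirmed = sum(status == "confirmed"),
            newly_identified = sum(status == "newly_identified"),
            misidentified = sum(status %in% c("species_misid", "genus_misid")),
            species_misid = sum(status == "species_misid"),
            genus_misid = sum(status == "genus_misid"),
            liriope_collection = sum(truth$collection == "Liriope"),
            liriope_confirmed = sum(status == "confirmed" &
                                      truth$collection == "Liriope"),
            type3 = sum(truth$rbcl_type == "Type 3"))
  expect <- list(total = 73L, confirmed = 36L, newly_identified = 4L,
                 misidentified = 33L, species_misid = 26L, genus_misid = 7L,
                 liriope_collection = 46L, liriope_confirmed = 27L,
                 type3 = 9L)
  for (k in names(expect)) {
    if (t[[k]] != expect[[k]]) {
      stop("truth manifest inconsistent with published totals: ", k, " = ",
           t[[k]], " (expected ", expect[[k]], ")")
    }
  }
  invisible(t)
}

#' Reconstruct the 73-accession collection as sequences plus manifest
#'
#' Validates the packaged truth manifest against the published totals, then
#' generates each accession's rbcL and ITS sequences from its true species
#' under the given noise configuration. Deterministic for a fixed seed.
#'
#' @param config A `generator_config`.
#' @param panel Optional `haplotype_panel` (default: packaged panel).
#' @param truth Optional truth manifest data.frame (default: packaged).
#' @return List with `rbcl` and `its` (named character vectors of
#'   sequences), `manifest` (accession_id / original_label / collection),
#'   `truth`, and `reference_set`.
#' @export
reconstruct_collection <- function(config, panel = NULL, truth = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(panel)) panel <- load_panel()
  if (is.null(truth)) truth <- load_truth_manifest()
  validate_truth_manifest(truth, panel)
  refset <- make_reference_set(panel, seed = config$seed)
  rbcl <- character(0); its <- character(0)
  with_seed(config$seed, {
    for (i in seq_len(nrow(truth))) {
      acc <- generate_accession(truth$true_species[i], refset, config,
                                id = truth$accession_id[i])
      rbcl <- c(rbcl, acc$rbcl)
      its <- c(its, acc$its)
    }
  })
  list(rbcl = rbcl, its = its,
       manifest = truth[, c("accession_id", "original_label", "collection")],
       truth = truth, reference_set = refset)
}
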