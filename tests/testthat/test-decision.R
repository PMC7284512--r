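panel <- load_panel()
PLAN <- "Ophiopogon planiscapus"
BOD <- "Ophiopogon bodinieri"

test_that("synonym normalization applies accepted names and passes others", {
  expect_identical(normalize_label("L. exiliflora"), "Liriope muscari")
  expect_identical(normalize_label("Liriope exiliflora"), "Liriope muscari")
  expect_identical(normalize_label("O. wallichianus"), "Ophiopogon japonicus")
  expect_identical(normalize_label("O. planiscapus"), "Ophiopogon planiscapus")
  expect_identical(normalize_label("Ophiopogon planiscapus 'Nigrescens'"),
                   "Ophiopogon planiscapus")
  expect_identical(normalize_label("Something else"), "Something else")
})

test_that("the rule table reproduces the worked identifications", {
  cases <- list(
    # (haplotype, clade, triplet) -> expected species
    list(fake_hap("Type 3"), fake_clade("B3b"), fake_trip(PLAN), PLAN),
    list(fake_hap("Type 2"), fake_clade("B3a"), fake_trip(BOD), BOD),
    list(fake_hap("Type 5"), fake_clade("jaburan-branch"), NULL,
         "Ophiopogon jaburan"),
    list(fake_hap("Type 1"), fake_clade("B2"), NULL,
         "Ophiopogon japonicus (I)"),
    list(fake_hap("Type 6"), fake_clade("Liriope-muscari"), NULL,
         "Liriope muscari"),
    list(fake_hap("Type 6"), fake_clade("Liriope-spicata"), NULL,
         "Liriope spicata"),
    list(fake_hap("Type 2"), fake_clade("B2"), NULL,
         "Ophiopogon japonicus (II)"),
    list(fake_hap("Type 2"), fake_clade("B3b"), fake_trip(BOD), BOD),
    list(fake_hap("Type 3"), fake_clade("B3a"), fake_trip(PLAN), PLAN)
  )
  for (cs in cases) {
    res <- identify_accession(cs[[1]], cs[[2]], cs[[3]], panel)
    expect_identical(res$species, cs[[4]],
                     label = paste(cs[[1]]$best, cs[[2]]$label))
  }
  # triplet overrides a conflicting B3a/B3b tree placement, and says so
  over <- identify_accession(fake_hap("Type 3"), fake_clade("B3b"),
                             fake_trip(PLAN), panel)
  expect_true("triplet_overrides_placement" %in% over$flags)
  over2 <- identify_accession(fake_hap("Type 2"), fake_clade("B3a"),
                              fake_trip(BOD), panel)
  expect_true("triplet_overrides_placement" %in% over2$flags)
})

test_that("conflicts and gaps are flagged rather than silently resolved", {
  # Type 3 without triplet corroboration
  r <- identify_accession(fake_hap("Type 3"), fake_clade("B3a"),
                          fake_trip("undetermined"), panel)
  expect_identical(r$species, PLAN)
  expect_true("triplet_conflict" %in% r$flags)
  # Type 2 in B3 with a planiscapus triplet contradicts the haplotype
  r2 <- identify_accession(fake_hap("Type 2"), fake_clade("B3b"),
                           fake_trip(PLAN), panel)
  expect_true(is.na(r2$species))
  expect_true("rbcl_its_conflict" %in% r2$flags)
  # Type 4 falls back on the panel's low-confidence taxon
  r3 <- identify_accession(fake_hap("Type 4"), fake_clade("B2"), NULL, panel)
  expect_identical(r3$species, "Ophiopogon longifolius")
  expect_true("low_confidence" %in% r3$flags)
  # ITS-only call is flagged single-locus
  r4 <- identify_accession(NULL, fake_clade("B2"), NULL, panel)
  expect_identical(r4$species, "Ophiopogon japonicus")
  expect_true("single_locus" %in% r4$flags)
  # rbcL genus vs ITS genus discordance
  r5 <- identify_accession(fake_hap("Type 1"), fake_clade("Liriope-muscari"),
                           NULL, panel)
  expect_true("genus_discordance" %in% r5$flags)
})

test_that("every evidence combination maps to exactly one defined outcome", {
  types <- c(paste("Type", 1:6), NA)
  clades <- c("Liriope-muscari", "Liriope-spicata", "B2", "B3a", "B3b",
              "jaburan-branch", "unassigned")
  trips <- list(fake_trip(PLAN), fake_trip(BOD),
                fake_trip("undetermined"), NULL)
  for (ty in types) for (cl in clades) for (tr in trips) {
    hap <- if (is.na(ty)) NULL else fake_hap(ty)
    res <- identify_accession(hap, fake_clade(cl), tr, panel)
    expect_true(res$genus %in% c("Liriope", "Ophiopogon", "undetermined"))
    expect_true(is.na(res$species) || nzchar(res$species))
    if (is.na(res$species)) expect_gt(length(res$flags), 0L)
  }
})

test_that("status scoring distinguishes the four outcomes", {
  expect_identical(
    status_of("Ophiopogon", "Ophiopogon japonicus (I)", "Ophiopogon japonicus"),
    "confirmed")  # subgroup qualifiers ignored
  expect_identical(
    status_of("Liriope", "Liriope muscari", "Ophiopogon japonicus"),
    "genus_misid")
  expect_identical(
    status_of("Ophiopogon", "Ophiopogon japonicus", "Ophiopogon sp."),
    "newly_identified")
  expect_identical(
    status_of("Ophiopogon", "Ophiopogon planiscapus", "Ophiopogon jaburan"),
    "species_misid")
  # a genus-only label in the wrong genus is a genus-level misid, not new
  expect_identical(
    status_of("Liriope", "Liriope muscari", "Ophiopogon sp."),
    "genus_misid")
  expect_identical(status_of("undetermined", NA, "Liriope muscari"),
                   "undetermined")
  expect_identical(status_of("Ophiopogon", NA, "Ophiopogon jaburan"),
                   "undetermined")
})

test_that("report tallies are conserved on random collections (property)", {
  set.seed(77)
  statuses <- c("confirmed", "species_misid", "genus_misid",
                "newly_identified", "undetermined")
  for (i in 1:20) {
    n <- sample(1:60, 1)
    ids <- lapply(seq_len(n), function(k) {
      st <- sample(statuses, 1)
      list(accession_id = sprintf("A%03d", k), original_label = "x",
           normalized_label = "x", rbcl_haplotype = NA, rbcl_distance = NA,
           genus_snp = NA, its_clade = NA, its_support = NA, triplet = NA,
           genus = "Ophiopogon", species = "y", status = st,
           flags = character(0))
    })
    rep <- collection_report(ids)
    t <- rep$tallies
    expect_identical(t$confirmed + t$newly_identified + t$misidentified +
                       t$undetermined, t$total)
    expect_identical(t$species_misid + t$genus_misid, t$misidentified)
    expect_identical(t$total, n)
  }
})

test_that("reports render identically and round-trip through TSV and JSON", {
  ids <- list(list(accession_id = "BTG_1", original_label = "O. jaburan",
                   normalized_label = "Ophiopogon jaburan",
                   rbcl_haplotype = "Type 5", rbcl_distance = 0L,
                   genus_snp = "Ophiopogon", its_clade = "jaburan-branch",
                   its_support = 100, triplet = NA,
                   genus = "Ophiopogon", species = "Ophiopogon jaburan",
                   status = "confirmed", flags = character(0)))
  rep <- collection_report(ids)
  expect_identical(rep$tallies$total, 1L)
  expect_identical(rep$tallies$misidentified, 0L)
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  write_report_tsv(rep, t1); write_report_tsv(rep, t2)
  expect_identical(readLines(t1), readLines(t2))
  back <- utils::read.delim(t1, stringsAsFactors = FALSE)
  expect_identical(back$accession_id, "BTG_1")
  j <- tempfile(fileext = ".json")
  write_report_json(rep, j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_identical(parsed$tallies$confirmed, 1L)
})
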