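test_that("K2P matches the closed form on constructed proportions", {
  a <- strrep("A", 100)
  ti <- paste0(strrep("G", 10), strrep("A", 90))   # 10 transitions
  tv <- paste0(strrep("C", 25), strrep("A", 75))   # 25 transversions
  r1 <- k2p_distance(a, ti)
  expect_equal(r1$P, 0.1); expect_equal(r1$Q, 0); expect_equal(r1$L, 100L)
  expect_equal(r1$d, 0.1115718, tolerance = 1e-6)
  r2 <- k2p_distance(a, tv)
  expect_equal(r2$d, 0.3171278, tolerance = 1e-6)
  same <- k2p_distance(a, a)
  expect_identical(c(same$P, same$Q, same$d), c(0, 0, 0))
})

test_that("K2P drops ambiguous sites, is symmetric, and flags saturation", {
  a <- "ACGTNNACGT-A"
  b <- "ACGTACGTAC-A"  # gap column dropped on both sides
  r <- k2p_distance(a, b)
  expect_identical(r$L, 9L)
  expect_equal(k2p_distance(b, a)$d, r$d)
  expect_error(k2p_distance(strrep("A", 50), strrep("C", 50)), "saturated")
  expect_error(k2p_distance("NNN", "ACG"), "no comparable sites")
})

test_that("k2p_matrix agrees with per-pair k2p_distance and with ape", {
  set.seed(21)
  base <- random_seq(300)
  seqs <- c(s1 = base, s2 = mutate_fraction(base, 0.05),
            s3 = mutate_fraction(base, 0.10), s4 = mutate_fraction(base, 0.15))
  D <- k2p_matrix(seqs)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(D[i, j], k2p_distance(seqs[[i]], seqs[[j]])$d)
  }
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[rownames(D), colnames(D)]),
               tolerance = 1e-12)
})

test_that("NJ solves the three-taxon case exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("NJ recovers additive quartets including the internal branch", {
  # quartet ((A,B),(C,D)) with all five branches length 1
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  path <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(path), unname(D), tolerance = 1e-12)
  expect_identical(splits_from_phylo(tr), "C|D")
})

test_that("NJ reproduces any additive matrix as path lengths (property)", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    D <- stats::cophenetic(ref)
    o <- sample(rownames(D))  # shuffle taxon order
    tr <- nj_tree(D[o, o])
    expect_equal(unname(stats::cophenetic(tr)[o, o]), unname(D[o, o]),
                 tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref),
                                            ape::unroot(tr))), 0)
  }
})

test_that("degenerate and malformed matrices are handled", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star <- nj_tree(Z)
  expect_identical(star$Nnode, 1L)           # all-zero matrix -> star
  expect_true(all(star$edge.length == 0))
  bad <- Z; bad[1, 2] <- 1
  expect_error(nj_tree(bad), "symmetric")
  bad2 <- Z; bad2[1, 2] <- bad2[2, 1] <- NA
  expect_error(nj_tree(bad2), "NA")
  expect_error(nj_tree(Z[1:2, 1:2]), "at least 3")
})

test_that("negative branch lengths are clamped with the deficit recorded", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("majority consensus counts bipartitions like ape and keeps ties", {
  t_ab <- ape::read.tree(text = "((A,B),(C,D),E);")
  t_ac <- ape::read.tree(text = "((A,C),(B,D),E);")
  trees <- c(rep(list(t_ab), 6), rep(list(t_ac), 4))
  cons <- majority_consensus(trees, threshold = 0.5)
  sup <- attr(cons, "split_support")
  # t_ab carries bipartitions AB|CDE ("C|D|E") and CD|ABE ("C|D"): 6/10 each
  expect_identical(sort(names(sup)), c("C|D", "C|D|E"))
  expect_equal(unname(sup[c("C|D", "C|D|E")]), c(60, 60))
  expect_identical(sort(splits_from_phylo(cons)), sort(names(sup)))
  # oracle: ape's own majority-rule consensus has the same topology
  expect_equal(as.numeric(ape::dist.topo(cons, ape::consensus(trees, p = 0.5))),
               0)

  # a bipartition at exactly the threshold is retained, not collapsed
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  half <- c(rep(list(t_ab), 5), rep(list(star), 5))
  cons2 <- majority_consensus(half, threshold = 0.5)
  expect_true(all(c("C|D", "C|D|E") %in% names(attr(cons2, "split_support"))))
  expect_equal(unname(attr(cons2, "split_support")["C|D"]), 50)
})

test_that("consensus splits are mutually compatible (property)", {
  set.seed(9)
  for (i in 1:5) {
    trees <- lapply(1:20, function(k) ape::rtree(8))
    trees <- lapply(trees, function(t) {
      t$tip.label <- paste0("t", seq_len(8)); t
    })
    cons <- majority_consensus(trees, threshold = 0.3)
    sides <- lapply(names(attr(cons, "split_support")),
                    function(k) strsplit(k, "|", fixed = TRUE)[[1]])
    tips <- sort(trees[[1]]$tip.label)
    for (a in seq_along(sides)) for (b in seq_along(sides)) {
      if (a < b) {
        ia <- intersect(sides[[a]], sides[[b]])
        compatible <- length(ia) == 0 ||
          length(ia) == length(sides[[a]]) || length(ia) == length(sides[[b]]) ||
          length(union(sides[[a]], sides[[b]])) == length(tips)
        expect_true(compatible)
      }
    }
    expect_true(all(attr(cons, "split_support") >= 30))
  }
})

test_that("bootstrap of an unambiguous alignment gives full support", {
  # every informative column supports AB|CD; constant columns are neutral
  col_sig <- c(A = "A", B = "A", C = "G", D = "G")
  aln <- cbind(matrix(rep(col_sig, 30), nrow = 4,
                      dimnames = list(names(col_sig), NULL)),
               matrix("T", 4, 70, dimnames = list(names(col_sig), NULL)))
  cons <- bootstrap_consensus(aln, B = 50, seed = 1)
  sup <- attr(cons, "split_support")
  expect_identical(names(sup), "C|D")
  expect_equal(unname(sup), 100)
  expect_length(attr(cons, "replicate_trees"), 50L)
  # and the consensus topology equals the point-estimate NJ topology
  nj <- nj_tree(k2p_matrix(aln))
  expect_identical(sort(splits_from_phylo(nj)), sort(splits_from_phylo(cons)))
})

test_that("bootstrap is deterministic for a fixed seed", {
  set.seed(1234)
  base <- random_seq(200)
  aln <- vapply(1:6, function(i) mutate_fraction(base, 0.08), character(1))
  names(aln) <- paste0("s", 1:6)
  c1 <- bootstrap_consensus(aln, B = 20, seed = 99)
  c2 <- bootstrap_consensus(aln, B = 20, seed = 99)
  expect_identical(ape::write.tree(c1), ape::write.tree(c2))
})

test_that("clade assignment picks the smallest supported homogeneous group", {
  tr <- ape::read.tree(
    text = "((q:0.01,r1:0.02,r2:0.02)95:0.1,(r3:0.02,r4:0.02)99:0.1,r5:0.3);")
  labels <- c(r1 = "B3a", r2 = "B3a", r3 = "B2", r4 = "B2", r5 = "jaburan-branch")
  a <- assign_clade(tr, "q", labels)
  expect_identical(a$label, "B3a")
  expect_equal(a$support, 95)
  expect_identical(a$flag, "ok")
  expect_identical(a$nearest_ref, "r1")
  expect_equal(a$nearest_distance, 0.03)
  expect_error(assign_clade(tr, "nope", labels), "not in tree")
})

test_that("conflicting supported groups yield unassigned, weak ones fall back", {
  # the only supported group containing q mixes labels -> unassigned
  tr <- ape::read.tree(
    text = "((q:0.1,r1:0.1,r3:0.1)90:0.1,(r2:0.1,r4:0.1)90:0.1,r5:0.3);")
  labels <- c(r1 = "X", r2 = "X", r3 = "Y", r4 = "Y", r5 = "Z")
  a <- assign_clade(tr, "q", labels)
  expect_identical(a$label, "unassigned")
  expect_true(is.na(a$support))

  # no supported group at all -> nearest reference, flagged low-confidence
  tr2 <- ape::read.tree(
    text = "((q:1,r1:1)20:1,(r2:1,r3:1)20:1,r4:4);")
  a2 <- assign_clade(tr2, "q", c(r1 = "X", r2 = "Y", r3 = "Y", r4 = "Z"))
  expect_identical(a2$flag, "low_confidence")
  expect_identical(a2$label, "X")
  expect_identical(a2$nearest_ref, "r1")
})

test_that("a full synthetic B3b query lands in B3b with full support", {
  panel <- load_panel()
  refset <- make_reference_set(panel, seed = 2)
  q <- stats::setNames(refset$its_clade_consensus[["B3b"]], "q")
  aln <- rbind(as_alignment_matrix(refset$its_refs),
               as_alignment_matrix(q))
  cons <- bootstrap_consensus(aln, B = 30, seed = 3)
  nj <- map_supports(nj_tree(k2p_matrix(aln)), attr(cons, "replicate_trees"))
  a <- assign_clade(nj, "q", refset$ref_labels)
  expect_identical(a$label, "B3b")
  expect_equal(a$support, 100)
  trip <- triplet_call(q, panel)
  expect_identical(trip$call, "Ophiopogon bodinieri")
  expect_false(trip$partial)
})

test_that("the ITS triplet scores 3-of-3, 2-of-3 and undetermined correctly", {
  panel <- load_panel()
  refset <- make_reference_set(panel, seed = 2)
  plan <- stats::setNames(refset$its_clade_consensus[["B3a"]], "q")
  expect_identical(triplet_call(plan, panel)$call, "Ophiopogon planiscapus")
  # flip one triplet base of a planiscapus sequence to the bodinieri allele
  mixed <- plan
  substr(mixed, 46, 46) <- "G"
  tm <- triplet_call(mixed, panel)
  expect_identical(tm$call, "Ophiopogon planiscapus")
  expect_true(tm$partial)
  # all three positions N -> no pattern
  und <- plan
  for (p in panel$its_triplet$positions) substr(und, p, p) <- "N"
  expect_identical(triplet_call(und, panel)$call, "undetermined")
})
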