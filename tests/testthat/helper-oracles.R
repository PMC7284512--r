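# Independent oracles used by the contract tests. These deliberately share
# no code with the implementation they check.

# Gotoh global alignment score with affine gaps: a gap of length L costs
# open + L * ext. Small inputs only (quadratic, plain loops).
oracle_affine_score <- function(a, b, match = 1, mismatch = -1,
                                open = 10, ext = 1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Closed-form K2P from transition/transversion proportions.
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# Brute-force Hamming distance of a profile against every panel row, with
# the same IUPAC semantics as the caller contract (set overlap containing
# the haplotype base = match, gap = mismatch).
oracle_panel_distances <- function(bases, panel) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  vapply(panel$haplotypes, function(h) {
    d <- 0L
    for (p in names(h$bases)) {
      s <- sets[[bases[[p]]]]
      if (is.null(s) || !h$bases[[p]] %in% s) d <- d + 1L
    }
    d
  }, integer(1))
}

# Random sequence near a template (for unsaturated K2P test pairs).
mutate_fraction <- function(seq, frac) {
  v <- strsplit(seq, "")[[1]]
  k <- max(1L, round(frac * length(v)))
  idx <- sample(length(v), k)
  for (p in idx) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evidence-object constructors for decision-engine tests.
fake_hap <- function(type, distance = 0L, flag = "exact", genus = NULL,
                     ties = character(0)) {
  if (is.null(genus)) {
    genus <- if (identical(type, "Type 6")) "Liriope" else "Ophiopogon"
  }
  structure(list(best = type, distance = distance, ties = ties,
                 genus = genus, flag = flag), class = "haplotype_call")
}

fake_clade <- function(label, support = 100, flag = "ok") {
  structure(list(query = "q", label = label, support = support,
                 nearest_ref = NA_character_, nearest_distance = NA_real_,
                 flag = flag), class = "clade_assignment")
}

fake_trip <- function(call, partial = FALSE) {
  structure(list(call = call, partial = partial,
                 bases = c(`46` = "A", `231` = "C", `545` = "C")),
            class = "triplet_call")
}

make_profile <- function(bases, id = "q") {
  structure(list(id = id, bases = bases,
                 n_ambiguous = sum(!bases %in% c("A", "C", "G", "T"))),
            class = "snp_profile")
}
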