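#' @title Tier two: ITS phylogeny and clade assignment
#'
#' @description
#' The ITS tree is estimated in-package: Kimura 2-parameter distances with
#' pairwise deletion of gaps/ambiguities, neighbor-joining with a
#' deterministic tie-break, seeded nonparametric bootstrap, and a
#' majority-rule consensus keeping bipartitions present in at least the
#' threshold fraction (default 50%) of replicates. Queries are assigned to
#' the clade of labelled reference sequences they nest within; a three-SNP
#' ITS key resolves the *O. planiscapus* / *O. bodinieri* pair that the tree
#' alone cannot separate reliably.
#'
#' Trees are `ape::phylo` objects, unrooted in spirit; written Newick roots
#' arbitrarily (at the final agglomeration), with bootstrap supports as
#' internal node labels.
#'
#' @name phylogeny
NULL

PURINES <- c("A", "G")

.as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    strsplit(toupper(x), "")[[1]]
  } else {
    toupper(as.character(x))
  }
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence has a gap or ambiguity are dropped (pairwise
#' deletion). Over the `L` retained sites, with transition proportion `P`
#' and transversion proportion `Q`, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b Aligned sequences of equal length (character strings or
#'   vectors of single characters).
#' @return A `k2p` object: list with `P`, `Q`, `L` and `d`.
#' @export
k2p_distance <- function(a, b) {
  av <- .as_base_vector(a); bv <- .as_base_vector(b)
  if (length(av) != length(bv)) stop("sequences must be of equal length")
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  L <- sum(keep)
  if (L == 0L) stop("no comparable sites after pairwise deletion")
  av <- av[keep]; bv <- bv[keep]
  diff <- av != bv
  transitions <- diff & ((av %in% PURINES) == (bv %in% PURINES))
  P <- sum(transitions) / L
  Q <- sum(diff & !transitions) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (P = ", signif(P, 4), ", Q = ",
         signif(Q, 4), ")")
  }
  structure(list(P = P, Q = Q, L = L,
                 d = -0.5 * log(w1) - 0.25 * log(w2)),
            class = "k2p")
}

#' @export
print.k2p <- function(x, ...) {
  cat(sprintf("<k2p> d = %.6f (P = %.4f, Q = %.4f, L = %d)\n",
              x$d, x$P, x$Q, x$L))
  invisible(x)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Vectorized over all sequence pairs with indicator-matrix products;
#' identical in value to calling [k2p_distance()] on every pair.
#'
#' @param aln Alignment: character matrix (rows = sequences), named
#'   character vector of equal-length strings, or a
#'   [Biostrings::DNAStringSet] of equal widths.
#' @return Symmetric numeric matrix of K2P distances with zero diagonal.
#' @export
k2p_matrix <- function(aln) {
  M <- as_alignment_matrix(aln)
  n <- nrow(M)
  if (n < 2L) stop("need at least two sequences")
  X <- lapply(c("A", "C", "G", "T"), function(b) (M == b) * 1)
  names(X) <- c("A", "C", "G", "T")
  V <- X$A + X$C + X$G + X$T
  Lm <- V %*% t(V)
  Mm <- X$A %*% t(X$A) + X$C %*% t(X$C) + X$G %*% t(X$G) + X$T %*% t(X$T)
  Sm <- X$A %*% t(X$G) + X$G %*% t(X$A) + X$C %*% t(X$T) + X$T %*% t(X$C)
  off <- row(Lm) != col(Lm)
  if (any(Lm[off] == 0)) stop("sequence pair with no comparable sites")
  P <- Sm / Lm
  Q <- (Lm - Mm - Sm) / Lm
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1[off] <= 0) || any(w2[off] <= 0)) {
    stop("K2P distance saturated for at least one sequence pair")
  }
  D <- -0.5 * log(w1) - 0.25 * log(w2)
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Coerce sequences to an alignment matrix
#'
#' @param aln See [k2p_matrix()].
#' @return Character matrix, rows named by sequence id.
#' @export
as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    M <- toupper(aln)
  } else {
    chr <- if (is.character(aln)) toupper(aln) else toupper(as.character(aln))
    if (length(unique(nchar(chr))) != 1L) {
      stop("alignment rows must all have the same length")
    }
    M <- do.call(rbind, strsplit(chr, ""))
    rownames(M) <- names(chr)
  }
  if (is.null(rownames(M))) rownames(M) <- paste0("seq", seq_len(nrow(M)))
  M
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou--Nei agglomeration on the Q criterion with the usual
#' branch-length formulas. Ties in Q are broken by the lowest (row, column)
#' index pair, so the result is reproducible across platforms. Negative
#' branch lengths are clamped to zero with the total deficit recorded in
#' `attr(tree, "clamped")`.
#'
#' @param D Symmetric numeric matrix (zero diagonal, no NA), or `dist`.
#' @return An `ape::phylo` tree (trifurcating at the final join).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (anyNA(D)) stop("D contains NA/NaN")
  if (max(abs(D - t(D))) > 1e-8) stop("D is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(grepl("[(),:;\\s]", labels, perl = TRUE))) {
    stop("tip labels must not contain Newick metacharacters or whitespace")
  }
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  sub <- labels  # newick fragment per active cluster
  dm <- D
  while (length(sub) > 3L) {
    m <- length(sub)
    r <- rowSums(dm)
    Qm <- (m - 2) * dm - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    hits <- which(Qm == qmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    bi <- clamp(dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- clamp(dm[i, j] - dm[i, j] / 2 - (r[i] - r[j]) / (2 * (m - 2)))
    dnew <- (dm[i, -c(i, j)] + dm[j, -c(i, j)] - dm[i, j]) / 2
    merged <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], bi, sub[j], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    sub <- c(sub[keep], merged)
  }
  b1 <- clamp((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  b2 <- clamp((dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  b3 <- clamp((dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1], b1, sub[2], b2, sub[3], b3)
  tree <- ape::read.tree(text = nwk)
  # zero-length internal edges carry no grouping information: collapse them,
  # so e.g. an all-zero matrix yields a star
  tree <- ape::di2multi(tree, tol = 1e-12)
  attr(tree, "clamped") <- clamped
  tree
}

# ---- bipartitions -----------------------------------------------------------

# Canonical split keys of all internal (non-root) edges: the side of the
# split NOT containing the alphabetically first leaf, as a sorted
# "|"-joined string. Trivial (terminal) splits are not represented.
splits_from_phylo <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips)[1]
  nodes <- .node_tipsets(tree)
  keys <- character(0)
  for (set in nodes) {
    side <- if (anchor %in% set) setdiff(tips, set) else set
    if (length(side) >= 2L && length(side) <= ntip - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

# tip-label sets of every internal non-root node
.node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", ntip + nnode)
  # explicit post-order traversal (children resolved before parents)
  stack <- root; post <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(v, post)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  for (v in post) {
    if (v <= ntip) {
      sets[[v]] <- tree$tip.label[v]
    } else {
      sets[[v]] <- unlist(sets[children[[as.character(v)]]])
    }
  }
  internal <- setdiff(seq_len(nnode) + ntip, root)
  out <- sets[internal]
  names(out) <- as.character(internal)
  out
}

.splits_compatible <- function(a, b, all_tips) {
  ia <- intersect(a, b)
  if (length(ia) == 0L) return(TRUE)
  if (length(ia) == length(a) || length(ia) == length(b)) return(TRUE)
  length(union(a, b)) == length(all_tips)
}

#' Bootstrap the alignment and build a majority-rule consensus tree
#'
#' Columns are resampled with replacement `B` times; a neighbor-joining
#' tree is built from K2P distances for each replicate; bipartitions present
#' in at least `threshold` of the replicates (at exactly the threshold they
#' are kept, matching the "collapse below 50%" convention) are assembled
#' into a consensus tree whose internal node labels carry the support as a
#' percentage.
#'
#' @param aln Alignment as in [k2p_matrix()]; at least 3 rows.
#' @param B Number of bootstrap replicates (>= 1).
#' @param threshold Retention fraction in (0, 1], default 0.5.
#' @param seed Optional integer seed for the resampling.
#' @return An `ape::phylo` consensus tree (no branch lengths; supports as
#'   node labels) with attributes `replicate_trees` (list of `phylo`) and
#'   `split_support` (named percentage vector of retained splits).
#' @export
bootstrap_consensus <- function(aln, B = 100L, threshold = 0.5, seed = NULL) {
  M <- as_alignment_matrix(aln)
  if (nrow(M) < 3L) stop("alignment must have at least 3 rows")
  if (B < 1L) stop("B must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  trees <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      nj_tree(k2p_matrix(M[, cols, drop = FALSE]))
    })
  })
  cons <- majority_consensus(trees, threshold = threshold)
  attr(cons, "replicate_trees") <- trees
  cons
}

#' Majority-rule consensus of a set of trees
#'
#' Counts the bipartitions of every input tree and keeps those whose
#' frequency is at or above `threshold`; kept splits are assembled into a
#' multifurcating tree with supports (percentages) as internal node labels.
#' Conflicting splits at exactly the threshold are resolved
#' deterministically (higher frequency first, then lexicographic split key).
#'
#' @param trees Non-empty list of `phylo` objects over the same leaf set.
#' @param threshold Retention fraction in (0, 1], default 0.5.
#' @return `phylo` consensus tree with a `split_support` attribute.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (length(trees) == 0L) stop("no trees")
  tips <- sort(trees[[1]]$tip.label)
  B <- length(trees)
  counts <- table(unlist(lapply(trees, splits_from_phylo)))
  freq <- as.numeric(counts) / B
  names(freq) <- names(counts)
  retained <- freq[freq >= threshold - 1e-12]
  ord <- order(-retained, names(retained))
  clusters <- list(); support <- numeric(0)
  for (k in ord) {
    side <- strsplit(names(retained)[k], "|", fixed = TRUE)[[1]]
    ok <- all(vapply(clusters, .splits_compatible, logical(1),
                     b = side, all_tips = tips))
    if (ok) {
      clusters <- c(clusters, list(side))
      support <- c(support, retained[k])
      names(support)[length(support)] <- names(retained)[k]
    }
  }
  cons <- .tree_from_clusters(tips, clusters, round(100 * support))
  attr(cons, "split_support") <- 100 * support
  cons
}

# Build a rooted-at-anchor multifurcating Newick from a laminar cluster set.
.tree_from_clusters <- function(tips, clusters, supports) {
  build <- function(members) {
    inside <- which(vapply(clusters, function(cl) {
      length(cl) < length(members) && all(cl %in% members)
    }, logical(1)))
    # maximal clusters within members
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j) {
        j != i && length(clusters[[i]]) < length(clusters[[j]]) &&
          all(clusters[[i]] %in% clusters[[j]])
      }, logical(1)))
    }, logical(1))]
    used <- unlist(clusters[maximal])
    parts <- c(
      vapply(maximal, function(i) {
        sprintf("(%s)%d", build(clusters[[i]]), supports[i])
      }, character(1)),
      sort(setdiff(members, used))
    )
    paste(sort(parts), collapse = ",")
  }
  nwk <- sprintf("(%s);", build(tips))
  ape::read.tree(text = nwk)
}

#' Map bootstrap supports onto a fixed tree
#'
#' For every internal edge of `tree`, counts the fraction of `trees`
#' containing the same bipartition; the percentages are written into
#' `tree$node.label` (empty label on the root).
#'
#' @param tree Target `phylo` (e.g. the point-estimate NJ tree).
#' @param trees List of replicate `phylo` trees over the same leaf set.
#' @return `tree` with `node.label` set to support percentages.
#' @export
map_supports <- function(tree, trees) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  counts <- table(unlist(lapply(trees, splits_from_phylo)))
  sets <- .node_tipsets(tree)
  labels <- character(tree$Nnode)
  labels[1] <- ""  # root
  for (nm in names(sets)) {
    set <- sets[[nm]]
    side <- if (anchor %in% set) setdiff(tree$tip.label, set) else set
    key <- paste(sort(side), collapse = "|")
    hit <- if (key %in% names(counts)) counts[[key]] else 0L
    labels[as.integer(nm) - ntip] <- as.character(round(100 * hit / length(trees)))
  }
  tree$node.label <- labels
  tree
}

#' Assign a query leaf to a labelled reference clade
#'
#' The query's label is that of the smallest clade (side of an internal
#' edge) containing the query and at least two reference leaves, all of the
#' same label, whose defining edge has bootstrap support at or above the
#' threshold. If supported clades containing the query exist but all mix
#' labels, the query is `"unassigned"`. If no supported multi-reference
#' clade contains the query at all, the nearest labelled reference by
#' patristic distance is used, flagged `"low_confidence"`.
#'
#' @param tree `phylo` with branch lengths and support percentages in
#'   `node.label` (see [map_supports()]).
#' @param query Query tip label.
#' @param ref_labels Named character vector: reference tip label -> clade
#'   label. Tips absent from this vector are treated as queries.
#' @param threshold Minimum support as a fraction (default 0.5).
#' @return A `clade_assignment`: list with `query`, `label`, `support`,
#'   `nearest_ref`, `nearest_distance`, `flag`.
#' @export
assign_clade <- function(tree, query, ref_labels, threshold = 0.5) {
  tips <- tree$tip.label
  if (!query %in% tips) stop("query not in tree: ", query)
  refs <- intersect(names(ref_labels), tips)
  if (length(refs) < 2L) stop("need at least 2 labelled references in tree")
  ntip <- length(tips)
  sets <- .node_tipsets(tree)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  pat <- if (!is.null(tree$edge.length)) stats::cophenetic(tree) else NULL
  nearest_ref <- NA_character_; nearest_dist <- NA_real_
  if (!is.null(pat)) {
    dq <- pat[query, refs]
    nearest_ref <- refs[which.min(dq)]
    nearest_dist <- unname(min(dq))
  }
  cand <- list()
  for (nm in names(sets)) {
    set <- sets[[nm]]
    side <- if (query %in% set) set else setdiff(tips, set)
    if (!query %in% side || length(side) >= ntip) next
    side_refs <- intersect(side, refs)
    if (length(side_refs) < 2L) next
    sup <- supports[as.integer(nm) - ntip]
    if (is.na(sup) || sup < 100 * threshold) next
    cand[[length(cand) + 1L]] <- list(side = side, refs = side_refs,
                                      support = sup)
  }
  if (length(cand) > 0L) {
    homog <- Filter(function(x) {
      length(unique(ref_labels[x$refs])) == 1L
    }, cand)
    if (length(homog) > 0L) {
      key <- vapply(homog, function(x) paste(sort(x$side), collapse = "|"),
                    character(1))
      o <- order(vapply(homog, function(x) length(x$side), integer(1)),
                 -vapply(homog, `[[`, numeric(1), "support"), key)
      pick <- homog[[o[1]]]
      return(structure(list(query = query,
                            label = unname(ref_labels[pick$refs[1]]),
                            support = pick$support,
                            nearest_ref = nearest_ref,
                            nearest_distance = nearest_dist,
                            flag = "ok"),
                       class = "clade_assignment"))
    }
    return(structure(list(query = query, label = "unassigned", support = NA_real_,
                          nearest_ref = nearest_ref,
                          nearest_distance = nearest_dist,
                          flag = "conflicting_labels"),
                     class = "clade_assignment"))
  }
  # no supported multi-reference clade: nearest-reference fallback
  if (is.null(pat)) {
    return(structure(list(query = query, label = "unassigned",
                          support = NA_real_, nearest_ref = NA_character_,
                          nearest_distance = NA_real_, flag = "no_clade"),
                     class = "clade_assignment"))
  }
  structure(list(query = query, label = unname(ref_labels[nearest_ref]),
                 support = NA_real_, nearest_ref = nearest_ref,
                 nearest_distance = nearest_dist, flag = "low_confidence"),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("<clade_assignment> ", x$query, " -> ", x$label,
      if (!is.na(x$support)) sprintf(" (support %g%%)", x$support),
      " [", x$flag, "]\n", sep = "")
  invisible(x)
}

#' Evaluate the diagnostic ITS SNP triplet
#'
#' Reads the query bases at the three key positions (reference coordinates
#' 46/231/545) and compares them with the two packaged allele patterns. A
#' full three-of-three match calls the species; two-of-three calls it with
#' a `partial` flag; anything else is undetermined. The key is only
#' meaningful for sequences in the *O. planiscapus* / *O. bodinieri*
#' neighbourhood of the tree; callers are expected to consult it only
#' there.
#'
#' @param query ITS query sequence (named character or `DNAStringSet`
#'   element).
#' @param panel A `haplotype_panel`.
#' @param ... Passed to [align_to_reference()].
#' @return A `triplet_call`: list with `call` (matched pattern name or
#'   `"undetermined"`), `partial` (logical), `bases`.
#' @export
triplet_call <- function(query, panel, ...) {
  ref <- c(ITS = panel$reference_sequences[["ITS"]])
  cm <- align_to_reference(query, ref, ...)
  trip <- panel$its_triplet
  bases <- vapply(trip$positions, function(p) base_at(cm, query, p),
                  character(1))
  names(bases) <- as.character(trip$positions)
  scores <- vapply(trip$patterns, function(pat) {
    sum(mapply(.base_matches, bases, pat))
  }, numeric(1))
  best <- max(scores)
  call <- "undetermined"; partial <- FALSE
  if (best >= 2L && sum(scores == best) == 1L) {
    call <- names(scores)[which.max(scores)]
    partial <- best == 2L
  }
  structure(list(call = call, partial = partial, bases = bases),
            class = "triplet_call")
}

#' @export
print.triplet_call <- function(x, ...) {
  cat("<triplet_call> ", x$call, if (x$partial) " (partial)",
      " [", paste(names(x$bases), x$bases, sep = "=", collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards; with `seed = NULL` the expression runs on the current
#' stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
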