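# Distance-based subtype phylogeny: Kimura two-parameter distances from
# aligned sequences, neighbor-joining topology (ape), and nonparametric
# bootstrap support from column resampling.

K2P_CEILING <- 5.0

base_code <- function(chars) {
  unname(c(A = 1L, C = 2L, G = 3L, T = 4L)[chars])
}

# P (transition) and Q (transversion) proportions over gap-free, unambiguous
# columns of two equal-length aligned rows.
pq_proportions <- function(xa, xb) {
  ok <- !is.na(xa) & !is.na(xb)
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns")
  a <- xa[ok]; b <- xb[ok]
  diff <- a != b
  purine_a <- a == 1L | a == 3L
  purine_b <- b == 1L | b == 3L
  ts <- diff & (purine_a == purine_b)
  c(P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura two-parameter distance
#'
#' \deqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}
#' where P and Q are the transition and transversion proportions over
#' columns where neither row has a gap or ambiguity. Saturated pairs
#' (log argument non-positive) are set to a ceiling of 5.0
#' substitutions/site and flagged with a warning and the
#' \code{"saturated"} attribute.
#'
#' @param a,b aligned sequences of equal length (gaps allowed; gap or N
#'   columns are excluded pairwise).
#' @return distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  sa <- if (inherits(a, "seq_record")) a$seq else a
  sb <- if (inherits(b, "seq_record")) b$seq else b
  stopifnot(nchar(sa) == nchar(sb))
  xa <- base_code(strsplit(toupper(sa), "", fixed = TRUE)[[1]])
  xb <- base_code(strsplit(toupper(sb), "", fixed = TRUE)[[1]])
  pq <- pq_proportions(xa, xb)
  w1 <- 1 - 2 * pq[["P"]] - pq[["Q"]]
  w2 <- 1 - 2 * pq[["Q"]]
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated pair; distance set to ceiling ", K2P_CEILING)
    return(structure(K2P_CEILING, saturated = TRUE))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix
#'
#' For pre-aligned input (\code{aligned = TRUE}, equal-length rows) distances
#' use each pair's mutually gap-free columns. For unaligned input each pair
#' is globally aligned first (pairwise, not via a multiple alignment).
#'
#' @param seqs named character vector or list of \code{\link{seq_record}}s.
#' @param aligned whether rows are already aligned.
#' @param scoring alignment scoring for \code{aligned = FALSE}.
#' @return symmetric numeric matrix with zero diagonal; saturated pairs are
#'   set to the ceiling (see \code{\link{k2p_distance}}).
#' @export
k2p_matrix <- function(seqs, aligned = TRUE, scoring = align_scoring()) {
  if (is.list(seqs) && all(vapply(seqs, inherits, FALSE, "seq_record")))
    seqs <- setNames(vapply(seqs, `[[`, "", "seq"),
                     vapply(seqs, `[[`, "", "id"))
  n <- length(seqs)
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (aligned) {
    stopifnot(length(unique(nchar(seqs))) == 1L)
    codes <- lapply(seqs, function(s)
      base_code(strsplit(toupper(s), "", fixed = TRUE)[[1]]))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      pq <- pq_proportions(codes[[i]], codes[[j]])
      w1 <- 1 - 2 * pq[["P"]] - pq[["Q"]]; w2 <- 1 - 2 * pq[["Q"]]
      d[i, j] <- d[j, i] <- if (w1 <= 0 || w2 <= 0) K2P_CEILING else
        -0.5 * log(w1) - 0.25 * log(w2)
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      aln <- global_align(seqs[[i]], seqs[[j]], scoring)
      d[i, j] <- d[j, i] <- suppressWarnings(
        k2p_distance(aln$aligned_a, aln$aligned_b))
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (via \code{ape::nj}) on a symmetric distance
#' matrix. Negative branch lengths are clamped to zero and flagged with the
#' \code{"clamped"} attribute.
#'
#' @param dm symmetric numeric matrix with labels as dimnames (>= 3 taxa).
#' @return an \code{ape::phylo} tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(dm))
  clamped <- tr$edge.length < 0
  if (any(clamped)) tr$edge.length[clamped] <- 0
  attr(tr, "clamped") <- any(clamped)
  tr
}

tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(i) sort(labs[i]))
}

#' Does a tree contain a given bipartition?
#'
#' Tests whether the (unrooted) tree has an edge separating \code{tips} from
#' all remaining leaves.
#'
#' @param tree an \code{ape::phylo}.
#' @param tips character vector of tip labels on one side of the split.
#' @return logical.
#' @export
tree_has_split <- function(tree, tips) {
  tips <- sort(tips)
  all_tips <- sort(tree$tip.label)
  stopifnot(all(tips %in% all_tips))
  comp <- sort(setdiff(all_tips, tips))
  if (!length(comp) || !length(tips)) return(TRUE)
  for (s in tip_sets(tree))
    if (identical(s, tips) || identical(s, comp)) return(TRUE)
  FALSE
}

#' Bootstrap support for NJ splits
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and scores each internal edge of the original tree by the
#' fraction of replicates containing its bipartition. Supports are reported
#' in [0, 1] as node labels.
#'
#' @param seqs aligned set: named character vector (equal lengths, gaps
#'   allowed) or list of \code{\link{seq_record}}s.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed RNG seed; fixed seed gives identical supports.
#' @return the NJ tree on the full alignment with \code{node.label} set to
#'   supports and a \code{"replicates"} attribute holding the replicate
#'   trees.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (is.list(seqs) && all(vapply(seqs, inherits, FALSE, "seq_record")))
    seqs <- setNames(vapply(seqs, `[[`, "", "seq"),
                     vapply(seqs, `[[`, "", "id"))
  lens <- unique(nchar(seqs))
  stopifnot(length(lens) == 1L)
  ncol <- lens
  orig <- nj_tree(k2p_matrix(seqs, aligned = TRUE))
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol, ncol, replace = TRUE)
    boot <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste, collapse = ""),
                     names(seqs))
    reps[[r]] <- nj_tree(k2p_matrix(boot, aligned = TRUE))
  }
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  orig$node.label <- sprintf("%.3f", counts / n_reps)
  attr(orig, "replicates") <- reps
  orig
}

#' Support of a specific bipartition in a bootstrapped tree
#'
#' @param tree result of \code{\link{bootstrap_support}}.
#' @param tips tip labels on one side of the split.
#' @return support in [0, 1], or NA if the tree lacks the split.
#' @export
split_support <- function(tree, tips) {
  tips <- sort(tips)
  all_tips <- sort(tree$tip.label)
  comp <- sort(setdiff(all_tips, tips))
  sets <- tip_sets(tree)
  for (i in seq_along(sets)) {
    if (identical(sets[[i]], tips) || identical(sets[[i]], comp))
      return(as.numeric(tree$node.label[i]))
  }
  NA_real_
}

#' Write a tree in Newick format
#'
#' Bootstrap supports, when present, are emitted as internal node labels.
#'
#' @param tree an \code{ape::phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
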