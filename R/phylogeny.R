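## Neighbor-joining tree construction (Saitou-Nei Q-criterion agglomeration)
## with site-resampling bootstrap support and outgroup rooting. Trees are
## ape "phylo" objects throughout.

#' Construct a distance matrix object
#'
#' @param labels ordered taxon labels.
#' @param d square numeric matrix; must be symmetric within 1e-12 with a
#'   zero diagonal and nonnegative entries.
#' @return matrix of class `DistanceMatrix` with dimnames set to `labels`.
#' @export
distance_matrix <- function(labels, d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) != length(labels))
    stop("distance matrix dimensions do not match labels")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is asymmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0")
  if (any(d < 0)) stop("distances must be nonnegative")
  dimnames(d) <- list(labels, labels)
  class(d) <- c("DistanceMatrix", "matrix")
  d
}

#' Read a square distance matrix from TSV
#'
#' Expects a header row and a label column (row names).
#'
#' @param path TSV file.
#' @return a `DistanceMatrix`.
#' @export
read_distance_matrix <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  distance_matrix(rownames(tb), as.matrix(tb))
}

#' Write a distance matrix as square TSV
#' @param dm a `DistanceMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  write.table(cbind(label = rownames(dm), as.data.frame(unclass(dm))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties in the Q minimization
#' are broken by the lexicographically lowest pair of subtree keys (the
#' smallest tip label under each subtree), so the result is deterministic
#' across platforms. Negative branch lengths are set to zero with the excess
#' transferred to the sibling edge (standard practice); the number of
#' adjusted branches is recorded in `attr(tree, "negative_branches")`.
#'
#' On additive matrices the algorithm is exact: path lengths in the output
#' tree reproduce the input distances.
#'
#' @param dm a `DistanceMatrix` (>= 3 taxa).
#' @return an unrooted `phylo` tree with branch lengths in the units of the
#'   input distances.
#' @export
nj_tree <- function(dm) {
  if (!inherits(dm, "DistanceMatrix"))
    dm <- distance_matrix(rownames(dm), dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  labels <- rownames(dm)
  D <- unclass(dm)
  ## active nodes: newick fragment + lexicographic key (smallest tip label)
  frag <- labels
  key <- labels
  n_neg <- 0L
  fmt <- function(x) sprintf("%.12g", x)
  while (length(frag) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0; n_neg <- n_neg + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; n_neg <- n_neg + 1L }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    newkey <- min(key[i], key[j])
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    dnew[dnew < 0] <- 0
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    frag <- c(frag[others], newfrag)
    key <- c(key[others], newkey)
  }
  ## final three-point formulas
  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  lx <- (dxy + dxz - dyz) / 2
  ly <- (dxy + dyz - dxz) / 2
  lz <- (dxz + dyz - dxy) / 2
  for (v in c("lx", "ly", "lz")) {
    if (get(v) < 0) { assign(v, 0); n_neg <- n_neg + 1L }
  }
  ## order final children by key for determinism
  o <- order(key)
  lens <- c(lx, ly, lz)[o]
  txt <- paste0("(", paste0(frag[o], ":", fmt(lens), collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branches") <- n_neg
  if (n_neg > 0L)
    pa_log("nj_tree: ", n_neg, " negative branch length(s) set to 0")
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns (sites) with replacement `n_reps` times, rebuilds a tree
#' per replicate, and reports for each internal bipartition of the point
#' tree the percentage of replicates containing it (stored in
#' `tree$node.label`).
#'
#' @param aln multi-sequence alignment: character matrix (rows = taxa) or
#'   named character vector of equal-length gapped strings.
#' @param n_reps bootstrap replicates (>= 1; >= 100 for reportable support).
#' @param seed RNG seed (same seed and input give identical supports).
#' @param deletion gap policy for the p-distance matrices.
#' @return a `phylo` tree with node labels = bootstrap percentages.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  mat <- as_aln_matrix(aln)
  point <- nj_tree(dist_matrix_p(mat, deletion))
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    nj_tree(dist_matrix_p(mat[, cols, drop = FALSE], deletion))
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(round(100 * counts / n_reps))
  point
}

#' Root a tree on an outgroup
#'
#' Places the root on the outgroup's pendant edge.
#'
#' @param tree a `phylo` tree.
#' @param outgroup tip label present in the tree.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not in tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Unrooted bipartition set of a tree
#'
#' Each internal edge is represented by the lexicographically smaller side
#' of its tip-label split; used to compare topologies irrespective of
#' rooting.
#'
#' @param tree a `phylo` tree.
#' @return character vector (sorted) of canonical bipartition strings.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  out <- vapply(parts, function(p) {
    a <- sort(tips[p]); b <- sort(setdiff(tips, tips[p]))
    if (length(a) < 2L || length(b) < 2L) return(NA_character_)
    sides <- sort(c(paste(a, collapse = ","), paste(b, collapse = ",")))
    paste(sides, collapse = "|")
  }, character(1))
  sort(unique(out[!is.na(out)]))
}
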