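## Gene-conversion detection between aligned duplicates: Sawyer's fragment
## statistic over informative (polymorphic) sites with permutation
## significance, in the spirit of the classic GENECONV inner-fragment test.

#' Build the polymorphic site table of a multi-sequence alignment
#'
#' Keeps ungapped, N-free columns with at least two alleles among the
#' sequences, with their original alignment coordinates.
#'
#' @param aln character matrix (rows = sequences) or named character vector
#'   of equal-length gapped strings; >= 3 sequences.
#' @return list of class `PolymorphicSiteTable`: `positions` (1-based
#'   alignment columns), `alleles` (sequences x sites character matrix),
#'   `n_seq`, `aln_length`.
#' @export
build_site_table <- function(aln) {
  mat <- as_aln_matrix(aln)
  if (nrow(mat) < 3L) stop("need >= 3 sequences for fragment context")
  clean <- colSums(matrix(!(mat %in% DNA_BASES), nrow(mat))) == 0L
  nall <- apply(mat, 2L, function(col) length(unique(col)))
  keep <- which(clean & nall >= 2L)
  if (length(keep) < 2L)
    stop("fewer than 2 polymorphic ungapped sites; nothing to test")
  pa_log("build_site_table: ", length(keep), " informative site(s)")
  structure(list(positions = keep,
                 alleles = mat[, keep, drop = FALSE],
                 n_seq = nrow(mat), aln_length = ncol(mat)),
            class = "PolymorphicSiteTable")
}

## all maximal positive-scoring disjoint segments of a score vector,
## extracted iteratively (largest first, then masked)
max_segments <- function(sc, max_frags = 20L) {
  segs <- list()
  s <- sc
  for (rep in seq_len(max_frags)) {
    cs <- cumsum(s)
    pref <- c(0, cs[-length(cs)])
    prefmin <- cummin(pref)
    gains <- cs - prefmin
    jmax <- which.max(gains)
    best <- gains[jmax]
    if (best <= 0) break
    imin <- which.min(pref[seq_len(jmax)])
    segs[[length(segs) + 1L]] <- c(start = imin, end = jmax, score = best)
    s[imin:jmax] <- -Inf
  }
  segs
}

max_score_only <- function(s) {
  cs <- cumsum(s)
  max(cs - cummin(c(0, cs[-length(cs)])))
}

#' Sawyer fragment statistic with permutation significance
#'
#' For every sequence pair, informative sites where the pair agrees score
#' `+1` and sites where it disagrees score `-(g + 1)`; maximal positive-
#' scoring disjoint runs are candidate conversion fragments. Significance is
#' assessed by permuting the site order `n_permutations` times and comparing
#' each fragment score with the null distribution of the pairwise maximum
#' score; Bonferroni correction across sequence pairs is reported in
#' `sim_p_adj`.
#'
#' @param table a [build_site_table()] result.
#' @param g nonnegative mismatch penalty scale (site mismatch scores
#'   `-(g+1)`; `g = 1` mirrors the common gscale=1 setting).
#' @param n_permutations permutations for the null (>= 1000 for reported
#'   p-values).
#' @param seed RNG seed; fixed seed gives identical fragment lists.
#' @param alpha significance level applied to `sim_p_adj` for the
#'   `significant` flag.
#' @return data.frame of `ConversionFragment` rows: `seq_a`, `seq_b`,
#'   `start_site`, `end_site` (indices into the site table), `start_bp`,
#'   `end_bp` (0-based half-open alignment coordinates), `n_sites`, `score`,
#'   `sim_p`, `sim_p_adj`, `significant`, `listing` (always `"inner"`).
#' @export
sawyer_fragments <- function(table, g = 1, n_permutations = 1000L,
                             seed = 1L, alpha = 0.05) {
  if (g < 0) stop("mismatch penalty g must be >= 0")
  stopifnot(inherits(table, "PolymorphicSiteTable"))
  set.seed(seed)
  al <- table$alleles
  ids <- rownames(al)
  nseq <- nrow(al); nsite <- ncol(al)
  pairs <- combn(nseq, 2L)
  n_pairs <- ncol(pairs)
  rows <- list()
  for (p in seq_len(n_pairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    agree <- al[i, ] == al[j, ]
    if (all(agree)) next   # no informative contrast within the pair
    sc <- ifelse(agree, 1, -(g + 1))
    segs <- max_segments(sc)
    if (!length(segs)) next
    ## null: site-order permutation of the same score multiset
    nullmax <- vapply(seq_len(n_permutations), function(r)
      max_score_only(sample(sc)), numeric(1))
    for (sg in segs) {
      pval <- (1 + sum(nullmax >= sg[["score"]])) / (n_permutations + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_a = ids[i], seq_b = ids[j],
        start_site = sg[["start"]], end_site = sg[["end"]],
        start_bp = table$positions[sg[["start"]]] - 1L,
        end_bp = table$positions[sg[["end"]]],
        n_sites = sg[["end"]] - sg[["start"]] + 1L,
        score = sg[["score"]], sim_p = pval,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(seq_a = character(0), seq_b = character(0),
                      start_site = integer(0), end_site = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_sites = integer(0), score = numeric(0),
                      sim_p = numeric(0), sim_p_adj = numeric(0),
                      significant = logical(0), listing = character(0))
  } else {
    out <- do.call(rbind, rows)
    out$sim_p_adj <- pmin(1, out$sim_p * n_pairs)
    out$significant <- out$sim_p_adj <= alpha
    out$listing <- "inner"
  }
  class(out) <- c("ConversionFragment", "data.frame")
  out
}

#' Per-unit summary of conversion fragments
#'
#' Groups significant fragments by the duplicated units they overlap and
#' reports, per sequence pair and unit, the fraction of the unit covered by
#' significant fragments (union of spans).
#'
#' @param fragments a [sawyer_fragments()] result.
#' @param units list of [duplicated_unit()] in the same (alignment)
#'   coordinate space as `start_bp`/`end_bp`.
#' @return data.frame: `seq_a`, `seq_b`, `unit`, `covered_bp`,
#'   `unit_length`, `coverage`. Empty when no significant fragments.
#' @export
conversion_summary <- function(fragments, units) {
  sig <- fragments[fragments$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(seq_a = character(0), seq_b = character(0),
                      unit = character(0), covered_bp = numeric(0),
                      unit_length = numeric(0), coverage = numeric(0))
  if (!nrow(sig)) return(empty)
  rows <- list()
  for (key in unique(paste(sig$seq_a, sig$seq_b, sep = "\r"))) {
    fr <- sig[paste(sig$seq_a, sig$seq_b, sep = "\r") == key, ]
    for (u in units) {
      st <- pmax(fr$start_bp, u$start); en <- pmin(fr$end_bp, u$end)
      iv <- cbind(st, en)[en > st, , drop = FALSE]
      cov <- 0
      if (nrow(iv)) {
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
        for (r in seq_len(nrow(iv))[-1]) {
          if (iv[r, 1] <= cur_e) cur_e <- max(cur_e, iv[r, 2])
          else { cov <- cov + cur_e - cur_s; cur_s <- iv[r, 1]
                 cur_e <- iv[r, 2] }
        }
        cov <- cov + cur_e - cur_s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_a = fr$seq_a[1], seq_b = fr$seq_b[1], unit = u$label,
        covered_bp = cov, unit_length = u$end - u$start,
        coverage = cov / (u$end - u$start), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
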