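## Alignment containers consumed by the divergence and window modules.
## Alignments are accepted as pre-computed input (equal-length gapped rows);
## the package never depends on an external aligner.

#' Construct a pairwise alignment
#'
#' @param a,b gapped residue strings of equal length (`-` is the gap
#'   character); no column may be gap in both rows.
#' @param id_a,id_b sequence labels.
#' @return object of class `PairwiseAlignment` with character-matrix rows and
#'   a column map back to ungapped coordinates.
#' @export
pairwise_alignment <- function(a, b, id_a = "a", id_b = "b") {
  a <- toupper(as_seq_string(a)); b <- toupper(as_seq_string(b))
  if (nchar(a) != nchar(b)) stop("aligned rows differ in length")
  ra <- strsplit(a, "", fixed = TRUE)[[1]]
  rb <- strsplit(b, "", fixed = TRUE)[[1]]
  both_gap <- which(ra == "-" & rb == "-")
  if (length(both_gap))
    stop("column ", both_gap[1], " is gap in both rows")
  structure(list(id_a = id_a, id_b = id_b, a = ra, b = rb,
                 map_a = cumsum(ra != "-"), map_b = cumsum(rb != "-")),
            class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("<PairwiseAlignment %s vs %s: %d columns>\n",
              x$id_a, x$id_b, length(x$a)))
  invisible(x)
}

#' Construct a codon alignment
#'
#' @param seqs character vector (or list of `NucSequence`) of gapped coding
#'   sequences, equal aligned length.
#' @param ids row labels (defaults to names of `seqs`).
#' @param frame_anchor 1-based alignment column where codon 1 starts.
#'   Columns before the anchor are dropped; the aligned length from the
#'   anchor must be divisible by 3.
#' @return object of class `CodonAlignment`: a row x column character matrix
#'   plus the codon-column partition. CpG flags are attached by
#'   [flag_cpg_codons()].
#' @export
codon_alignment <- function(seqs, ids = NULL, frame_anchor = 1L) {
  if (inherits(seqs, "NucSequence")) seqs <- list(seqs)
  if (is.list(seqs)) {
    if (is.null(ids)) ids <- vapply(seqs, function(s)
      if (inherits(s, "NucSequence")) s$id else "", character(1))
    seqs <- vapply(seqs, as_seq_string, character(1))
  } else seqs <- toupper(seqs)
  if (is.null(ids) || !any(nzchar(ids)))
    ids <- if (!is.null(names(seqs))) names(seqs)
           else paste0("seq", seq_along(seqs))
  if (length(seqs) < 1L) stop("codon alignment needs >= 1 row")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned rows differ in length")
  if (frame_anchor < 1L || frame_anchor > L) stop("bad frame_anchor")
  if ((L - frame_anchor + 1L) %% 3L != 0L)
    stop("aligned length after frame anchoring is not divisible by 3")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  mat <- mat[, frame_anchor:L, drop = FALSE]
  rownames(mat) <- ids
  bad <- which(!mat %in% c(DNA_BASES, "N", "-"))
  if (length(bad)) stop("illegal residue in codon alignment: '",
                        mat[bad[1]], "'")
  n_codon <- ncol(mat) / 3L
  ## every fully ungapped triplet must be a valid codon over ACGT/N
  structure(list(mat = mat, ids = ids, n_codon = n_codon,
                 cpg_flags = NULL, cpg_rule = NULL),
            class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat(sprintf("<CodonAlignment: %d row(s), %d codon column(s)%s>\n",
              nrow(x$mat), x$n_codon,
              if (!is.null(x$cpg_flags))
                sprintf(", %d CpG-flagged (%s)", sum(x$cpg_flags), x$cpg_rule)
              else ""))
  invisible(x)
}

## codon strings for one row, one per codon column ("---" style kept as-is)
row_codons <- function(caln, row) {
  v <- caln$mat[row, ]
  idx <- seq_len(caln$n_codon)
  paste0(v[3 * idx - 2], v[3 * idx - 1], v[3 * idx])
}

## codon columns where both rows are fully A/C/G/T (comparable for counting)
comparable_codons <- function(caln, row_a, row_b) {
  ca <- row_codons(caln, row_a); cb <- row_codons(caln, row_b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  list(a = ca, b = cb, ok = ok)
}
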