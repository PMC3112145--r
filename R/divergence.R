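## Nucleotide- and codon-level divergence statistics: p-distance,
## Nei-Gojobori synonymous/nonsynonymous divergence with pathway averaging,
## CpG-codon masking, the dN/dS test and regional rate comparisons.

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

is_stop <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon]) == "*"
}

#' Proportion of differing sites between two aligned sequences
#'
#' Columns where either row is a gap or `N` are excluded (pairwise deletion;
#' for a two-row alignment complete deletion is identical). The standard
#' error is the binomial `sqrt(p(1-p)/n)`.
#'
#' @param aln a [pairwise_alignment()].
#' @param deletion gap policy; kept for interface symmetry with
#'   [dist_matrix_p()].
#' @return list of class `DistanceResult`: `p`, `n_sites`, `se`,
#'   `mismatches`.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  ok <- aln$a %in% DNA_BASES & aln$b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable (non-gap, non-N) columns")
  mism <- sum(aln$a[ok] != aln$b[ok])
  p <- mism / n
  structure(list(p = p, n_sites = n, se = sqrt(p * (1 - p) / n),
                 mismatches = mism, id_a = aln$id_a, id_b = aln$id_b),
            class = "DistanceResult")
}

#' @export
print.DistanceResult <- function(x, ...) {
  cat(sprintf("p-distance %s vs %s: %.4f (+/- %.4f), n = %d sites\n",
              x$id_a, x$id_b, x$p, x$se, x$n_sites))
  invisible(x)
}

#' Pairwise p-distance matrix for a multi-sequence alignment
#'
#' @param mat character matrix (rows = taxa, gapped alignment columns) with
#'   rownames, or a named character vector of equal-length gapped strings.
#' @param deletion `"pairwise"` (per-pair exclusion of gap/N columns) or
#'   `"complete"` (columns with any gap/N dropped for all pairs; the policy
#'   used for tree building).
#' @return `DistanceMatrix`: symmetric matrix with zero diagonal and taxon
#'   labels.
#' @export
dist_matrix_p <- function(mat, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- as_aln_matrix(mat)
  m <- nrow(mat)
  if (deletion == "complete") {
    keep <- colSums(matrix(mat %in% DNA_BASES, m)) == m
    if (!any(keep)) stop("no comparable columns under complete deletion")
    mat <- mat[, keep, drop = FALSE]
  }
  d <- matrix(0, m, m, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- mat[i, ] %in% DNA_BASES & mat[j, ] %in% DNA_BASES
    if (!any(ok)) stop("no comparable columns for pair ", i, ",", j)
    d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
  }
  distance_matrix(rownames(mat), d)
}

as_aln_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    x <- vapply(x, as_seq_string, character(1))
    if (length(unique(nchar(x))) != 1L) stop("rows differ in length")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

## --- Nei-Gojobori machinery -----------------------------------------------

## synonymous site count of one codon: at each position, the fraction of the
## three single-nucleotide neighbors that are synonymous, with neighbors that
## are stop codons removed from the denominator (NG86/MEGA convention).
ng_sites_codon <- function(codon) {
  key <- paste0("S_", codon)
  hit <- .pa_env[[key]]
  if (!is.null(hit)) return(hit)
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa0 <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- DNA_BASES[DNA_BASES != ch[pos]]
    neigh <- vapply(alts, function(b) {
      cc <- ch; cc[pos] <- b; paste(cc, collapse = "")
    }, character(1))
    keep <- !is_stop(neigh)
    if (any(keep))
      s <- s + sum(translate_codon(neigh[keep]) == aa0) / sum(keep)
  }
  .pa_env[[key]] <- s
  s
}

perms_list <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## synonymous/nonsynonymous difference counts between two codons, averaged
## with equal weights over all minimal substitution pathways that avoid stop
## codons (all pathways used if every one passes through a stop).
ng_diffs_codon <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  key <- paste0("D_", ca, cb)
  hit <- .pa_env[[key]]
  if (!is.null(hit)) return(hit)
  va <- strsplit(ca, "", fixed = TRUE)[[1]]
  vb <- strsplit(cb, "", fixed = TRUE)[[1]]
  dpos <- which(va != vb)
  paths <- perms_list[[as.character(length(dpos))]]
  tally <- function(order, allow_stop) {
    cur <- va; sd <- 0; nd <- 0
    for (p in dpos[order]) {
      nxt <- cur; nxt[p] <- vb[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (!allow_stop && is_stop(c2) && c2 != cb) return(NULL)
      if (translate_codon(c1) == translate_codon(c2)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  avg <- Reduce(`+`, res) / length(res)
  out <- c(sd = avg[1], nd = avg[2])
  .pa_env[[key]] <- out
  out
}

## per-codon-column NG statistics for a pair of rows; the reusable core for
## nei_gojobori, bootstrap resampling and substitution-class counting.
ng_codon_stats <- function(caln, row_a, row_b) {
  cc <- comparable_codons(caln, row_a, row_b)
  idx <- which(cc$ok)
  if (!length(idx)) stop("no comparable ungapped codon pairs")
  st <- vapply(idx, function(i) {
    s <- (ng_sites_codon(cc$a[i]) + ng_sites_codon(cc$b[i])) / 2
    d <- ng_diffs_codon(cc$a[i], cc$b[i])
    c(S = s, N = 3 - s, Sd = d[["sd"]], Nd = d[["nd"]])
  }, numeric(4))
  list(codon = idx, S = st["S", ], N = st["N", ],
       Sd = st["Sd", ], Nd = st["Nd", ])
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4)
    stop("Jukes-Cantor correction undefined for p >= 3/4 (p = ",
         signif(p, 4), ")")
  -3 / 4 * log(1 - 4 * p / 3)
}

ng_from_stats <- function(st, correction, boot = 0L, seed = NULL,
                          row_names = c("a", "b")) {
  S <- sum(st$S); N <- sum(st$N); Sd <- sum(st$Sd); Nd <- sum(st$Nd)
  pS <- Sd / S; pN <- Nd / N
  dS <- if (correction == "jukes_cantor") jc_correct(pS) else pS
  dN <- if (correction == "jukes_cantor") jc_correct(pN) else pN
  se_pS <- se_pN <- var_dS <- var_dN <- NA_real_
  boot_dn_ds <- NULL
  if (boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    k <- length(st$S)
    reps <- vapply(seq_len(boot), function(r) {
      i <- sample.int(k, k, replace = TRUE)
      bS <- sum(st$S[i]); bN <- sum(st$N[i])
      ## resamples with no sites of a class carry no information on its rate
      c(if (bS > 0) sum(st$Sd[i]) / bS else NA_real_,
        if (bN > 0) sum(st$Nd[i]) / bN else NA_real_)
    }, numeric(2))
    se_pS <- stats::sd(reps[1, ], na.rm = TRUE)
    se_pN <- stats::sd(reps[2, ], na.rm = TRUE)
    if (correction == "jukes_cantor") {
      okS <- !is.na(reps[1, ]) & reps[1, ] < 3 / 4
      okN <- !is.na(reps[2, ]) & reps[2, ] < 3 / 4
      var_dS <- stats::var(-3 / 4 * log(1 - 4 * reps[1, okS] / 3))
      var_dN <- stats::var(-3 / 4 * log(1 - 4 * reps[2, okN] / 3))
    } else {
      var_dS <- se_pS^2; var_dN <- se_pN^2
    }
    boot_dn_ds <- reps
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, se_pS = se_pS, se_pN = se_pN,
                 var_dS = var_dS, var_dN = var_dN,
                 n_codons = length(st$S), correction = correction,
                 rows = row_names),
            class = "NGResult")
}

#' @export
print.NGResult <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori %s vs %s: %d codons | S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
    x$rows[1], x$rows[2], x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS=%.4f (se %.4f)  pN=%.4f (se %.4f)  correction=%s\n",
              x$pS, x$se_pS, x$pN, x$se_pN, x$correction))
  invisible(x)
}

#' Nei-Gojobori synonymous/nonsynonymous divergence
#'
#' Pathway-counting estimator: per-codon synonymous site counts are the
#' fraction of the nine single-nucleotide neighbors that are synonymous
#' (stop-codon neighbors excluded from the denominator), averaged over the
#' two rows; multi-difference codons are resolved by averaging over all
#' minimal substitution pathways with equal weights, excluding pathways that
#' pass through stop codons. `pS = Sd/S`, `pN = Nd/N`; the optional
#' Jukes-Cantor correction gives `dS`/`dN` (undefined for p >= 3/4).
#'
#' @param caln a [codon_alignment()].
#' @param row_a,row_b row indices or labels.
#' @param correction `"none"` or `"jukes_cantor"`.
#' @param boot number of codon-resampling bootstrap replicates for the
#'   standard errors of `pS`/`pN` (0 skips them).
#' @param seed RNG seed for the bootstrap.
#' @return an `NGResult`.
#' @export
nei_gojobori <- function(caln, row_a = 1L, row_b = 2L,
                         correction = c("none", "jukes_cantor"),
                         boot = 0L, seed = NULL) {
  correction <- match.arg(correction)
  st <- ng_codon_stats(caln, row_a, row_b)
  ng_from_stats(st, correction, boot, seed,
                row_names = c(row_label(caln, row_a), row_label(caln, row_b)))
}

row_label <- function(caln, row)
  if (is.character(row)) row else caln$ids[row]

#' Flag codon columns containing CpG dinucleotides
#'
#' A codon column is flagged when, in any row, the codon contains a CG
#' dinucleotide. Under `boundary_rule = "within_codon"` only CGs inside the
#' triplet count; under `"spanning"` a C ending one codon followed by a G
#' beginning the next flags both codons. Gapped codons never flag.
#'
#' @param caln a [codon_alignment()].
#' @param boundary_rule `"spanning"` (default) or `"within_codon"`.
#' @return the alignment with `cpg_flags` (logical per codon column) set;
#'   the flagged-column count is in `sum(x$cpg_flags)`.
#' @export
flag_cpg_codons <- function(caln, boundary_rule = c("spanning",
                                                    "within_codon")) {
  boundary_rule <- match.arg(boundary_rule)
  flags <- rep(FALSE, caln$n_codon)
  for (r in seq_len(nrow(caln$mat))) {
    cod <- row_codons(caln, r)
    ungapped <- !grepl("-", cod, fixed = TRUE)
    within <- ungapped & grepl("CG", cod, fixed = TRUE)
    flags <- flags | within
    if (boundary_rule == "spanning" && caln$n_codon > 1L) {
      last <- substr(cod, 3, 3); first <- substr(cod, 1, 1)
      span <- which(last[-caln$n_codon] == "C" & first[-1] == "G" &
                      ungapped[-caln$n_codon] & ungapped[-1])
      flags[span] <- TRUE
      flags[span + 1L] <- TRUE
    }
  }
  caln$cpg_flags <- flags
  caln$cpg_rule <- boundary_rule
  pa_log("flag_cpg_codons: ", sum(flags), "/", caln$n_codon,
         " codon columns flagged (", boundary_rule, ")")
  caln
}

#' Nei-Gojobori divergence excluding CpG-flagged codons
#'
#' Identical contract to [nei_gojobori()] restricted to codon columns not
#' flagged by [flag_cpg_codons()] under `boundary_rule`.
#'
#' @inheritParams nei_gojobori
#' @param boundary_rule passed to [flag_cpg_codons()].
#' @return an `NGResult` with extra fields `n_included`, `n_excluded`.
#' @export
ng_excluding_cpg <- function(caln, row_a = 1L, row_b = 2L,
                             boundary_rule = c("spanning", "within_codon"),
                             correction = c("none", "jukes_cantor"),
                             boot = 0L, seed = NULL) {
  correction <- match.arg(correction)
  caln <- flag_cpg_codons(caln, boundary_rule)
  st <- ng_codon_stats(caln, row_a, row_b)
  keep <- !caln$cpg_flags[st$codon]
  if (!any(keep)) stop("no unflagged comparable codons remain")
  st2 <- lapply(st, function(v) v[keep])
  out <- ng_from_stats(st2, correction, boot, seed,
                       row_names = c(row_label(caln, row_a),
                                     row_label(caln, row_b)))
  out$n_included <- sum(keep)
  out$n_excluded <- sum(!keep)
  out
}

#' Test of dN = dS from bootstrap variances
#'
#' `z = (dN - dS) / sqrt(var(dN) + var(dS))` with variances from the codon
#' bootstrap stored in the `NGResult`; normal-approximation p-values. When
#' `dN == dS` exactly, `z = 0` and the two-sided p is 1. With `dS = 0` the
#' dN/dS ratio is undefined but the test is still reported on the
#' difference scale.
#'
#' @param ng an `NGResult` computed with `boot > 0`.
#' @return list: `z`, `p_two_sided`, `p_dn_greater`, `p_dn_less`, `ratio`,
#'   `dN`, `dS`.
#' @export
dnds_z_test <- function(ng) {
  if (!inherits(ng, "NGResult")) stop("need an NGResult")
  if (is.na(ng$var_dS) || is.na(ng$var_dN))
    stop("NGResult lacks bootstrap variances; rerun with boot >= 500")
  diff <- ng$dN - ng$dS
  z <- if (diff == 0) 0 else diff / sqrt(ng$var_dN + ng$var_dS)
  list(z = z,
       p_two_sided = 2 * pnorm(-abs(z)),
       p_dn_greater = pnorm(-z),
       p_dn_less = pnorm(z),
       ratio = if (ng$dS > 0) ng$dN / ng$dS else NA_real_,
       dN = ng$dN, dS = ng$dS)
}

#' Compare substitution rates inside vs outside a CDS region
#'
#' Computes `Nd/N` (or `Sd/S`) between a test row and a reference row inside
#' and outside an interval on the ungapped CDS coordinate space of the
#' reference row, and tests equality of the two proportions by Fisher's
#' exact test on the 2x2 table of (differences, non-differing site mass),
#' site masses rounded half-up to integers.
#'
#' @param caln a [codon_alignment()].
#' @param row_ref,row_test row indices or labels.
#' @param region_start,region_end 0-based half-open interval in CDS
#'   nucleotide coordinates (reference row, ungapped); must lie strictly
#'   inside the CDS so both partitions contain codons.
#' @param metric `"nonsyn"` or `"syn"`.
#' @return list: per-partition rates and counts, `odds_ratio`, `p_value`.
#' @export
region_rate_compare <- function(caln, row_ref, row_test,
                                region_start, region_end,
                                metric = c("nonsyn", "syn")) {
  metric <- match.arg(metric)
  if (region_start < 0 || region_end <= region_start)
    stop("malformed region")
  st <- ng_codon_stats(caln, row_ref, row_test)
  cod_start <- (st$codon - 1L) * 3L  # CDS coords of comparable codons
  inside <- cod_start >= region_start & (cod_start + 3L) <= region_end
  if (!any(inside)) stop("no codons inside region")
  if (all(inside)) stop("region covers the whole compared CDS")
  take <- function(sel) {
    if (metric == "nonsyn")
      c(d = sum(st$Nd[sel]), s = sum(st$N[sel]))
    else
      c(d = sum(st$Sd[sel]), s = sum(st$S[sel]))
  }
  ins <- take(inside); outs <- take(!inside)
  tab <- matrix(c(round_half_up(ins[["d"]], 0),
                  round_half_up(ins[["s"]] - ins[["d"]], 0),
                  round_half_up(outs[["d"]], 0),
                  round_half_up(outs[["s"]] - outs[["d"]], 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("inside", "outside"),
                                c("diff", "same")))
  ft <- fisher.test(tab)
  list(metric = metric,
       rate_inside = ins[["d"]] / ins[["s"]],
       rate_outside = outs[["d"]] / outs[["s"]],
       diffs_inside = ins[["d"]], sites_inside = ins[["s"]],
       diffs_outside = outs[["d"]], sites_outside = outs[["s"]],
       table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Count amino-acid changes between two rows, split by region
#'
#' Counts comparable codon columns whose standard-code translations differ;
#' splits the count by membership in a CDS-coordinate region. Codon columns
#' translating to an internal stop in either row are skipped with a warning.
#'
#' @inheritParams region_rate_compare
#' @param row_a,row_b rows to compare.
#' @return list: `total_changes`, `in_region_changes`, `changed_codons`
#'   (1-based codon indices).
#' @export
count_amino_acid_changes <- function(caln, row_a = 1L, row_b = 2L,
                                     region_start = 0L, region_end = 0L) {
  cc <- comparable_codons(caln, row_a, row_b)
  idx <- which(cc$ok)
  stops <- idx[is_stop(cc$a[idx]) | is_stop(cc$b[idx])]
  if (length(stops)) {
    warning("internal stop codon at codon column(s) ",
            paste(stops, collapse = ","), "; skipped")
    idx <- setdiff(idx, stops)
  }
  changed <- idx[translate_codon(cc$a[idx]) != translate_codon(cc$b[idx])]
  cod_start <- (changed - 1L) * 3L
  in_region <- cod_start >= region_start & (cod_start + 3L) <= region_end
  list(total_changes = length(changed),
       in_region_changes = sum(in_region),
       changed_codons = changed)
}

#' One-row TSV summary of a divergence comparison
#'
#' @param ng an `NGResult`.
#' @return data.frame suitable for `write.table`.
#' @export
ng_as_row <- function(ng) {
  data.frame(id_a = ng$rows[1], id_b = ng$rows[2], n_codons = ng$n_codons,
             S = ng$S, N = ng$N, Sd = ng$Sd, Nd = ng$Nd,
             pS = ng$pS, pN = ng$pN, dS = ng$dS, dN = ng$dN,
             se_pS = ng$se_pS, se_pN = ng$se_pN,
             correction = ng$correction)
}
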