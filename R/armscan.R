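## Windowed divergence between palindrome arms and detection of
## conversion-resistant divergent islands.

#' Windowed divergence profile between two aligned arms
#'
#' The alignment is arm 1 against the reverse complement of arm 2 (so
#' homologous positions share columns). Windows of `window` alignment
#' columns are taken every `step` columns; mismatch proportions use pairwise
#' deletion (columns with a gap or `N` in either row are not compared).
#' Window coordinates are reported both as alignment-column starts (0-based)
#' and as signed positions relative to `center` (e.g. the loop midpoint,
#' matching profiles drawn with the loop center at position zero).
#'
#' @param aln a [pairwise_alignment()] of arm1 vs revcomp(arm2).
#' @param window window size in alignment columns (>= 50; 500 reproduces a
#'   standard non-overlapping 500-bp scan when `step = window`).
#' @param step distance between window starts (>= 1).
#' @param center alignment-coordinate position taken as zero for the signed
#'   axis; defaults to the alignment end (arms meet the loop there).
#' @return data.frame of class `WindowDivergenceProfile`: `start`,
#'   `signed_center_pos`, `sites`, `mismatches`, `d`; attributes carry the
#'   per-site comparable/mismatch positions used by [detect_islands()].
#' @export
arm_profile <- function(aln, window = 500L, step = window, center = NULL) {
  if (window < 50L) stop("window must be >= 50 bp")
  if (step < 1L) stop("step must be >= 1")
  L <- length(aln$a)
  if (window > L) {
    warning("window (", window, ") exceeds alignment length (", L,
            "); using a single truncated window")
    window <- L
  }
  if (is.null(center)) center <- L
  comparable <- aln$a %in% DNA_BASES & aln$b %in% DNA_BASES
  mismatch <- comparable & aln$a != aln$b
  starts <- seq(1L, L, by = step)
  starts <- starts[starts <= L - window + 1L | starts == 1L]
  ## when step == window the trailing partial window is kept so that window
  ## mismatch totals conserve the whole-alignment mismatch count
  if (step == window && max(starts) + window - 1L < L)
    starts <- c(starts, max(starts) + window)
  rows <- lapply(starts, function(st) {
    en <- min(st + window - 1L, L)
    idx <- st:en
    data.frame(start = st - 1L,
               signed_center_pos = (st - 1L) - center,
               sites = sum(comparable[idx]),
               mismatches = sum(mismatch[idx]))
  })
  prof <- do.call(rbind, rows)
  prof$d <- ifelse(prof$sites > 0, prof$mismatches / prof$sites, NA_real_)
  attr(prof, "window") <- window
  attr(prof, "step") <- step
  attr(prof, "center") <- center
  attr(prof, "aln_length") <- L
  attr(prof, "comparable_pos") <- which(comparable)  # 1-based columns
  attr(prof, "mismatch_pos") <- which(mismatch)
  class(prof) <- c("WindowDivergenceProfile", "data.frame")
  prof
}

#' Detect divergent islands in a window profile
#'
#' For each window the background mismatch rate is the pooled rate over all
#' other windows (leave-one-out); a one-sided exact binomial test asks
#' whether the window's mismatch count exceeds that background, with
#' Benjamini-Hochberg adjustment across windows. Significant adjacent
#' windows are merged and each merged span is refined to the maximal-scoring
#' run of mismatch-enriched sites under a two-state (background/island)
#' per-site log-odds score. An alternative permutation test (mismatch
#' positions shuffled across comparable sites) is available behind
#' `method = "permutation"`.
#'
#' @param profile a [arm_profile()] result (>= 3 windows).
#' @param alpha significance level on the adjusted p-values.
#' @param merge_adjacent merge neighboring significant windows into one
#'   island.
#' @param method `"binomial"` (default) or `"permutation"`.
#' @param n_perm,seed permutation settings when `method = "permutation"`.
#' @return data.frame of class `DivergentIsland`: refined `start`/`end`
#'   (0-based half-open alignment columns), `sites`, `mismatches`,
#'   `mean_divergence` (region mean over the refined span),
#'   `window_mean_divergence` (mean of member-window d), `background`,
#'   `p_value`, `p_adj`. Zero rows when nothing is significant (always,
#'   when all windows have zero mismatches).
#' @export
detect_islands <- function(profile, alpha = 0.01, merge_adjacent = TRUE,
                           method = c("binomial", "permutation"),
                           n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      sites = numeric(0), mismatches = numeric(0),
                      mean_divergence = numeric(0),
                      window_mean_divergence = numeric(0),
                      background = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0))
  class(empty) <- c("DivergentIsland", "data.frame")
  W <- nrow(profile)
  if (W < 3L) stop("need >= 3 windows to estimate a background")
  x <- profile$mismatches; n <- profile$sites
  if (sum(x) == 0L) return(empty)
  ## background estimated leave-one-out, then re-estimated with all
  ## currently significant windows masked (iterated to convergence), so a
  ## strong island does not inflate its own background
  masked <- integer(0)
  for (it in 1:10) {
    ## Jeffreys +1/2 pseudocount keeps the background estimate positive on
    ## near-identical arms (0 mismatches outside the island)
    bg_loo <- vapply(seq_len(W), function(w) {
      keep <- setdiff(seq_len(W), union(w, masked))
      (sum(x[keep]) + 0.5) / max(sum(n[keep]) + 1, 1)
    }, numeric(1))
    pv <- vapply(seq_len(W), function(w) {
      if (x[w] == 0L || n[w] == 0L) return(1)
      pbinom(x[w] - 1L, n[w], bg_loo[w], lower.tail = FALSE)
    }, numeric(1))
    new_masked <- which(p.adjust(pv, method = "BH") <= alpha &
                          x / pmax(n, 1) > bg_loo)
    if (identical(new_masked, masked)) break
    masked <- new_masked
  }
  if (method == "permutation") {
    set.seed(seed)
    comp <- attr(profile, "comparable_pos")
    m_tot <- sum(x)
    win_of <- findInterval(comp - 1L, profile$start)
    cnt <- matrix(0L, n_perm, W)
    for (r in seq_len(n_perm)) {
      hit <- sample(win_of, m_tot)
      tb <- tabulate(hit, nbins = W)
      cnt[r, ] <- tb
    }
    pv <- vapply(seq_len(W), function(w)
      (1 + sum(cnt[, w] >= x[w])) / (n_perm + 1), numeric(1))
    pv[x == 0L] <- 1
  }
  padj <- p.adjust(pv, method = "BH")
  enriched <- x / pmax(n, 1) > bg_loo
  sig <- which(padj <= alpha & enriched)
  if (!length(sig)) return(empty)
  runs <- if (merge_adjacent) split(sig, cumsum(c(1L, diff(sig) != 1L)))
          else as.list(sig)
  comp <- attr(profile, "comparable_pos")
  mism <- attr(profile, "mismatch_pos")
  window <- attr(profile, "window")
  L <- attr(profile, "aln_length")
  out <- lapply(runs, function(ws) {
    span0 <- profile$start[ws[1]]
    span1 <- min(profile$start[ws[length(ws)]] + window, L)
    in_run <- comp > span0 & comp <= span1
    p1 <- max(mean(comp[in_run] %in% mism), 1e-9)
    ## refinement may reach one window beyond the significant span, so an
    ## island edge falling in a non-significant neighbor window is captured
    ext0 <- max(0L, span0 - window)
    ext1 <- min(L, span1 + window)
    in_ext <- comp > ext0 & comp <= ext1
    sites_run <- comp[in_ext]
    is_mm <- sites_run %in% mism
    out_idx <- setdiff(seq_len(W), sig)   # mask all significant windows
    p0 <- (sum(x[out_idx]) + 0.5) / max(sum(n[out_idx]) + 1, 1)
    p0 <- min(max(p0, 1e-9), 1 - 1e-9)
    ## two-state log-odds segmentation: maximal-scoring subsegment, with
    ## the island rate re-estimated from the first-pass segment
    kadane <- function(p1) {
      sc <- ifelse(is_mm, log(p1 / p0), log((1 - p1) / (1 - p0)))
      cs <- cumsum(sc)
      pref <- c(0, cs[-length(cs)])
      gains <- cs - cummin(pref)
      jmax <- which.max(gains)
      imin <- which.min(pref[seq_len(jmax)])
      seq.int(imin, jmax)
    }
    seg <- kadane(max(p1, 2 * p0))
    ## island rate re-estimated from the first-pass segment; the segment
    ## spans first..last mismatch, so (m - 1)/span is the rate MLE
    p1b <- max(sum(is_mm[seg]) - 1, 1) / length(seg)
    seg <- kadane(max(p1b, 2 * p0))
    ## edge correction: the segment ends at observed mismatches, while the
    ## divergent region extends on average one inter-mismatch gap (1/p1)
    ## beyond the outermost mismatch on each side
    p1c <- max(sum(is_mm[seg]) - 1, 1) / length(seg)
    pad <- round(1 / max(p1c, 2 * p0))
    st <- max(ext0, sites_run[seg[1]] - 1L - pad)  # 0-based half-open
    en <- min(ext1, sites_run[seg[length(seg)]] + pad)
    in_isl <- sites_run > st & sites_run <= en
    mm_seg <- sum(is_mm[in_isl])
    n_seg <- sum(in_isl)
    ## pooled evidence over the refined span, Bonferroni across windows
    pval <- pbinom(mm_seg - 1L, n_seg, p0, lower.tail = FALSE)
    data.frame(start = st, end = en, sites = n_seg, mismatches = mm_seg,
               mean_divergence = mm_seg / n_seg,
               window_mean_divergence = mean(profile$d[ws], na.rm = TRUE),
               background = p0, p_value = pval,
               p_adj = min(1, pval * W))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("DivergentIsland", "data.frame")
  res
}

#' Overlap divergent islands with annotated features
#'
#' @param islands a [detect_islands()] result.
#' @param features `Interval` data.frame in the same coordinate space.
#' @return data.frame: one row per (island, overlapping feature) with
#'   `overlap_bp` and `fraction_of_island`; islands with no overlapping
#'   feature contribute a row with `feature = NA`.
#' @export
island_gene_overlap <- function(islands, features) {
  rows <- list()
  for (i in seq_len(nrow(islands))) {
    st <- islands$start[i]; en <- islands$end[i]
    ov_st <- pmax(st, features$start); ov_en <- pmin(en, features$end)
    ov <- pmax(0, ov_en - ov_st)
    hit <- which(ov > 0)
    if (!length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        island = i, island_start = st, island_end = en,
        feature = NA_character_, overlap_bp = 0,
        fraction_of_island = 0, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        island = i, island_start = st, island_end = en,
        feature = ifelse(nzchar(features$label[hit]), features$label[hit],
                         features$seq_id[hit]),
        overlap_bp = ov[hit],
        fraction_of_island = ov[hit] / (en - st), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
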