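## Divergence dating by linear scaling of substitution counts against a
## calibrated comparison of the same site class.

#' Date a divergence by substitution-count scaling
#'
#' `T = T_cal * k_obs / k_cal`: the focal substitution count is scaled by
#' the rate implied by a calibrated comparison of the same site class. The
#' headline estimate is reported to one decimal with round-half-up
#' (`35 * 4 / 22 = 6.3636... -> 6.4`). As a supplementary output, a 95%
#' interval treats `k_obs` as a Poisson count (exact interval scaled by
#' `T_cal / k_cal`).
#'
#' @param k_obs substitution count on the focal comparison (>= 0).
#' @param k_cal substitution count on the calibrated comparison (> 0).
#' @param t_cal calibration time in million years (> 0); always supplied by
#'   the caller.
#' @param conf confidence level of the supplementary interval.
#' @return list: `t_myr` (one-decimal headline value), `t_raw`, `ci_low`,
#'   `ci_high`, `k_obs`, `k_cal`, `t_cal`.
#' @export
scale_time <- function(k_obs, k_cal, t_cal, conf = 0.95) {
  if (k_cal <= 0) stop("undefined rate: calibration count k_cal must be > 0")
  if (t_cal <= 0) stop("calibration time t_cal must be > 0")
  if (k_obs < 0) stop("k_obs must be >= 0")
  t_raw <- t_cal * k_obs / k_cal
  ci <- stats::poisson.test(round(k_obs), conf.level = conf)$conf.int
  list(t_myr = round_half_up(t_raw, 1L), t_raw = t_raw,
       ci_low = ci[1] * t_cal / k_cal, ci_high = ci[2] * t_cal / k_cal,
       k_obs = k_obs, k_cal = k_cal, t_cal = t_cal)
}

#' Count substitutions of one site class between two rows
#'
#' Counts codon differences classified as synonymous or nonsynonymous by the
#' Nei-Gojobori pathway logic (multi-difference codons contribute their
#' pathway-averaged class counts). With `cpg_only = TRUE` only differences
#' inside CpG-flagged codon columns are counted; `non_cpg_only = TRUE`
#' restricts to unflagged columns.
#'
#' @param caln a [codon_alignment()].
#' @param row_a,row_b rows to compare.
#' @param site_class `"synonymous"` or `"nonsynonymous"`.
#' @param cpg_only count only differences in CpG-flagged codons.
#' @param non_cpg_only count only differences outside CpG-flagged codons.
#' @param boundary_rule passed to [flag_cpg_codons()] when flags are needed.
#' @return numeric substitution count (integer-valued unless multi-hit
#'   codons force pathway averaging).
#' @export
count_class_substitutions <- function(caln, row_a = 1L, row_b = 2L,
                                      site_class = c("synonymous",
                                                     "nonsynonymous"),
                                      cpg_only = FALSE, non_cpg_only = FALSE,
                                      boundary_rule = c("spanning",
                                                        "within_codon")) {
  site_class <- match.arg(site_class)
  if (cpg_only && non_cpg_only) stop("choose at most one CpG restriction")
  st <- ng_codon_stats(caln, row_a, row_b)
  keep <- rep(TRUE, length(st$codon))
  if (cpg_only || non_cpg_only) {
    if (is.null(caln$cpg_flags))
      caln <- flag_cpg_codons(caln, match.arg(boundary_rule))
    fl <- caln$cpg_flags[st$codon]
    keep <- if (cpg_only) fl else !fl
  }
  if (site_class == "synonymous") sum(st$Sd[keep]) else sum(st$Nd[keep])
}
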