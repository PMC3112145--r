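## End-to-end orchestration: synthetic (or user-supplied) locus ->
## self-comparison -> palindrome calls -> arm divergence profile -> island
## detection -> gene-conversion fragments -> codon divergence and dating,
## with a run manifest of parameters and output digests.

#' Pipeline configuration
#'
#' Defaults follow the standard analysis settings: 500-bp windows with no
#' overlap, spanning CpG rule, pairwise gap deletion.
#'
#' @param window,step window analysis settings in bp.
#' @param alpha island significance level (adjusted p).
#' @param bootstrap_reps codon-bootstrap replicates for dN/dS errors.
#' @param permutations permutations for the Sawyer fragment test.
#' @param seed master RNG seed (all stage seeds derive from it).
#' @param cpg_rule CpG boundary rule (see [flag_cpg_codons()]).
#' @param gap_policy `"pairwise"` or `"complete"` deletion.
#' @param t_cal,k_cal calibration (million years, substitution count) for
#'   the dating stage; user-supplied, never hard-coded downstream.
#' @param fasta,truth_bed optional paths to a pre-made locus FASTA (records
#'   `locus`, `arm1`, `arm2`) and truth/annotation BED; when `NULL` a locus
#'   is simulated.
#' @param out_dir output directory.
#' @param ... overrides for [simulate_palindrome_locus()] or
#'   [simulate_cds_pair()] parameters (`locus_args`, `cds_args` lists).
#' @return named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(window = 500L, step = 500L, alpha = 0.01,
                            bootstrap_reps = 500L, permutations = 1000L,
                            seed = 1L, cpg_rule = "spanning",
                            gap_policy = "pairwise",
                            t_cal = 35, k_cal = NULL,
                            fasta = NULL, truth_bed = NULL,
                            out_dir = tempfile("palinarm_run_"), ...) {
  cfg <- c(list(window = window, step = step, alpha = alpha,
                bootstrap_reps = bootstrap_reps,
                permutations = permutations, seed = seed,
                cpg_rule = cpg_rule, gap_policy = gap_policy,
                t_cal = t_cal, k_cal = k_cal,
                fasta = fasta, truth_bed = truth_bed, out_dir = out_dir),
           list(...))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a key-value config file
#'
#' Simple `key: value` text format (YAML-like scalars only); values override
#' [pipeline_config()] defaults and are coerced to numeric where possible.
#'
#' @param path config file.
#' @return `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  args <- list()
  for (g in kv) {
    if (length(g) < 3L) next
    val <- trimws(g[3])
    num <- suppressWarnings(as.numeric(val))
    args[[g[2]]] <- if (!is.na(num)) num else val
  }
  do.call(pipeline_config, args)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full palindrome-evolution analysis
#'
#' Orchestrates the analysis stages in order: locus input (simulated or
#' loaded), self-comparison, palindrome calling, arm divergence profile,
#' island detection, gene-conversion fragments, and codon
#' divergence/dating on a coding-pair simulation. Deterministic given the
#' config seed; writes each stage's table under `out_dir` together with a
#' JSON manifest of parameters and output digests.
#'
#' @param config a [pipeline_config()].
#' @return list of class `AnalysisBundle` with the per-stage results and the
#'   manifest, invisibly.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- path
    path
  }
  stages_done <- character(0)

  ## stage 1: locus
  sim <- stage_try("locus", {
    if (!is.null(cfg$fasta)) {
      if (!file.exists(cfg$fasta))
        stop("missing input file: ", cfg$fasta)
      seqs <- read_fasta(cfg$fasta)
      names(seqs) <- vapply(seqs, `[[`, "", "id")
      if (!all(c("locus", "arm1", "arm2") %in% names(seqs)))
        stop("FASTA must contain records 'locus', 'arm1', 'arm2'")
      list(locus = seqs[["locus"]], arm1 = seqs[["arm1"]]$seq,
           arm2 = seqs[["arm2"]]$seq, ancestor_arm = NULL, truth = NULL)
    } else {
      largs <- if (!is.null(cfg$locus_args)) cfg$locus_args else list()
      largs$seed <- cfg$seed
      do.call(simulate_palindrome_locus, largs)
    }
  })
  stages_done <- c(stages_done, "locus")

  ## stage 2: self-comparison + palindrome calls
  pal <- stage_try("palindrome", {
    segs <- self_compare(sim$locus)
    segs$color <- if (nrow(segs)) bin_similarity(segs$identity)
                  else character(0)
    emit(segs, "match_segments.tsv")
    calls <- detect_palindromes(segs, sim$locus)
    emit(calls, "palindrome_calls.tsv")
    list(segments = segs, calls = calls)
  })
  stages_done <- c(stages_done, "palindrome")

  ## stage 3: arm profile (arms are homologous ungapped copies here)
  prof <- stage_try("armscan", {
    aln <- pairwise_alignment(sim$arm1, sim$arm2, "arm1", "arm2")
    loop_len <- nchar(sim$locus$seq) - nchar(sim$arm1) - nchar(sim$arm2)
    p <- arm_profile(aln, window = cfg$window, step = cfg$step,
                     center = length(aln$a) + loop_len / 2)
    emit(as.data.frame(p), "arm_profile.tsv")
    p
  })
  stages_done <- c(stages_done, "armscan")

  ## stage 4: divergent islands
  islands <- stage_try("islands", {
    isl <- detect_islands(prof, alpha = cfg$alpha)
    emit(as.data.frame(isl), "islands.tsv")
    isl
  })
  stages_done <- c(stages_done, "islands")

  ## stage 5: gene conversion (arm1, arm2 and the ancestral arm when known)
  conv <- stage_try("geneconv", {
    seqs <- c(arm1 = sim$arm1, arm2 = sim$arm2)
    if (!is.null(sim$ancestor_arm))
      seqs <- c(seqs, ancestor = sim$ancestor_arm)
    if (length(seqs) < 3L) {
      NULL
    } else {
      tab <- build_site_table(seqs)
      fr <- sawyer_fragments(tab, n_permutations = cfg$permutations,
                             seed = cfg$seed + 1L)
      emit(fr, "conversion_fragments.tsv")
      fr
    }
  })
  stages_done <- c(stages_done, "geneconv")

  ## stage 6: codon divergence + dating on a coding-pair simulation
  dv <- stage_try("divergence_dating", {
    cargs <- if (!is.null(cfg$cds_args)) cfg$cds_args else list()
    cargs$seed <- cfg$seed + 2L
    cds <- do.call(simulate_cds_pair, cargs)
    caln <- codon_alignment(c(a = cds$cds_a, b = cds$cds_b))
    ng_all <- nei_gojobori(caln, boot = cfg$bootstrap_reps,
                           seed = cfg$seed + 3L)
    ng_nocpg <- ng_excluding_cpg(caln, boundary_rule = cfg$cpg_rule,
                                 boot = cfg$bootstrap_reps,
                                 seed = cfg$seed + 4L)
    test <- dnds_z_test(ng_all)
    k_obs <- count_class_substitutions(caln, site_class = "synonymous",
                                       cpg_only = TRUE,
                                       boundary_rule = cfg$cpg_rule)
    k_cal <- if (!is.null(cfg$k_cal)) cfg$k_cal
             else count_class_substitutions(caln, site_class = "synonymous")
    dating <- scale_time(k_obs, k_cal, cfg$t_cal)
    emit(rbind(cbind(set = "all_codons", ng_as_row(ng_all)),
               cbind(set = "cpg_excluded", ng_as_row(ng_nocpg))),
         "codon_divergence.tsv")
    emit(data.frame(k_obs = k_obs, k_cal = k_cal, t_cal = cfg$t_cal,
                    t_myr = dating$t_myr, ci_low = dating$ci_low,
                    ci_high = dating$ci_high), "dating.tsv")
    list(cds = cds, ng_all = ng_all, ng_nocpg = ng_nocpg,
         dnds_test = test, dating = dating)
  })
  stages_done <- c(stages_done, "divergence_dating")

  manifest <- list(
    package_version = as.character(utils::packageVersion("palinarm")),
    params = cfg[!vapply(cfg, is.null, TRUE) &
                   !names(cfg) %in% c("locus_args", "cds_args")],
    stages_completed = stages_done,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  bundle <- list(config = cfg, locus = sim, palindrome = pal,
                 profile = prof, islands = islands, conversion = conv,
                 divergence = dv, manifest = manifest,
                 manifest_path = manifest_path)
  class(bundle) <- "AnalysisBundle"
  invisible(bundle)
}
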