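## Ground-truthed sequence generators. Every generator is deterministic
## given (params, seed) and emits a truth record sufficient to re-derive the
## planted structure, so downstream detectors can be scored without external
## data.

## integer-coded base helpers (1=A, 2=C, 3=G, 4=T)
int2base <- function(v) DNA_BASES[v]
base2int <- function(ch) match(ch, DNA_BASES)

## codon index (1..64) from three base ints
codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

codon_tables <- function() {
  tb <- .pa_env$codon_tb
  if (!is.null(tb)) return(tb)
  gc <- Biostrings::GENETIC_CODE
  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)  # varies b3 fastest
  codons <- paste0(DNA_BASES[idx$b1], DNA_BASES[idx$b2], DNA_BASES[idx$b3])
  aa <- unname(gc[codons])
  ord <- order(codon_index(idx$b1, idx$b2, idx$b3))
  tb <- list(aa = aa[ord], codon = codons[ord])
  .pa_env$codon_tb <- tb
  tb
}

#' Random i.i.d. nucleotide sequence
#'
#' @param n length in bp.
#' @return nucleotide string.
#' @export
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

random_cds_int <- function(n_codons) {
  tb <- codon_tables()
  sense <- which(tb$aa != "*")
  picks <- sample(sense, n_codons, replace = TRUE)
  b1 <- (picks - 1L) %/% 16L + 1L
  b2 <- ((picks - 1L) %/% 4L) %% 4L + 1L
  b3 <- (picks - 1L) %% 4L + 1L
  as.integer(rbind(b1, b2, b3))
}

## is nucleotide site i of int-coded sequence s inside a CG dinucleotide?
in_cpg_context <- function(s, i) {
  n <- length(s)
  (s[i] == 2L && i < n && s[i + 1L] == 3L) ||
    (s[i] == 3L && i > 1L && s[i - 1L] == 2L)
}

site_rates <- function(s, cpg_mult) {
  n <- length(s)
  r <- rep(1, n)
  cg <- which(s[-n] == 2L & s[-1] == 3L)
  r[cg] <- cpg_mult
  r[cg + 1L] <- cpg_mult
  r
}

#' Simulate a pair of coding sequences with CpG-elevated substitution
#'
#' One sequence is a random stop-free CDS; the second evolves from it by a
#' continuous-time process for branch length `t` (expected proposals per
#' unit-rate site). Each nucleotide site proposes substitutions at rate 1,
#' multiplied by `cpg_mult` while the site sits in a CG dinucleotide
#' (context re-evaluated at every event, so CpG decay and creation are
#' dynamic). Proposed changes that create an internal stop codon are
#' rejected; nonsynonymous proposals are accepted with relative rate
#' `omega`; synonymous proposals are always accepted.
#'
#' @param n_codons number of codons (>= 10). Defaults reproduce the study
#'   regime of a ~315-codon gene pair whose synonymous divergence is
#'   strongly inflated by CpG sites.
#' @param t branch length: expected substitution proposals per unit-rate
#'   site (> 0, or 0 for an identical pair).
#' @param omega relative acceptance rate of nonsynonymous proposals.
#' @param cpg_mult rate multiplier at CpG-context sites (>= 1).
#' @param seed RNG seed; identical params + seed give identical output.
#' @return list of class `CdsPairSim`: `cds_a`, `cds_b` (strings), `truth`
#'   (class `CodonSimTruth`): params, the accepted-event log (`site`,
#'   `codon`, `from`, `to`, `class`, `cpg_context`), realized counts
#'   (`syn_changes`, `nonsyn_changes`, `syn_changes_cpg_codon`,
#'   `n_diff_sites`) where `*_cpg_codon` counts events whose codon column is
#'   CpG-flagged (spanning rule) in the emitted alignment.
#' @export
simulate_cds_pair <- function(n_codons = 315L, t = 0.08, omega = 0.9,
                              cpg_mult = 12, seed = 1L) {
  if (n_codons < 10L) stop("n_codons must be >= 10")
  if (t < 0) stop("t must be >= 0")
  if (cpg_mult < 1) stop("cpg_mult must be >= 1")
  set.seed(seed)
  tb <- codon_tables()
  anc <- random_cds_int(n_codons)
  s <- anc
  n <- length(s)
  rates <- site_rates(s, cpg_mult)
  total <- sum(rates)
  time <- 0
  ev <- list()
  ## unit-rate sites propose at rate 1, so over branch length t a plain site
  ## expects t proposals; waiting times are Exp(sum of site rates)
  repeat {
    if (t == 0) break
    time <- time + rexp(1L, total)
    if (time > t) break
    i <- sample.int(n, 1L, prob = rates)
    newb <- sample((1:4)[-s[i]], 1L)
    cpos <- (i - 1L) %/% 3L + 1L
    o <- (cpos - 1L) * 3L
    old_ci <- codon_index(s[o + 1L], s[o + 2L], s[o + 3L])
    sv <- s
    sv[i] <- newb
    new_ci <- codon_index(sv[o + 1L], sv[o + 2L], sv[o + 3L])
    if (tb$aa[new_ci] == "*") next
    cls <- if (tb$aa[new_ci] == tb$aa[old_ci]) "synonymous"
           else "nonsynonymous"
    if (cls == "nonsynonymous" && runif(1L) > omega) next
    ev[[length(ev) + 1L]] <- data.frame(
      site = i, codon = cpos, from = DNA_BASES[s[i]], to = DNA_BASES[newb],
      class = cls, cpg_context = in_cpg_context(s, i),
      stringsAsFactors = FALSE)
    s <- sv
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    for (j in lo:hi) {
      old_r <- rates[j]
      rates[j] <- if (in_cpg_context(s, j)) cpg_mult else 1
      total <- total + rates[j] - old_r
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(site = integer(0), codon = integer(0),
                            from = character(0), to = character(0),
                            class = character(0), cpg_context = logical(0))
  cds_a <- paste(int2base(anc), collapse = "")
  cds_b <- paste(int2base(s), collapse = "")
  caln <- flag_cpg_codons(codon_alignment(c(a = cds_a, b = cds_b)),
                          "spanning")
  syn_ev <- events$class == "synonymous"
  truth <- structure(list(
    n_codons = n_codons, t = t, omega = omega, cpg_mult = cpg_mult,
    seed = seed, events = events,
    syn_changes = sum(syn_ev),
    nonsyn_changes = sum(!syn_ev),
    syn_changes_cpg_codon = sum(syn_ev & caln$cpg_flags[events$codon]),
    nonsyn_changes_cpg_codon = sum(!syn_ev & caln$cpg_flags[events$codon]),
    cpg_flagged_codons = sum(caln$cpg_flags),
    n_diff_sites = sum(anc != s)), class = "CodonSimTruth")
  structure(list(cds_a = cds_a, cds_b = cds_b, truth = truth),
            class = "CdsPairSim")
}

## point-mutate arm positions (int vector) at per-site probability p;
## returns list(seq, n_mut, pos)
mutate_sites <- function(s, p, positions = seq_along(s)) {
  hit <- positions[runif(length(positions)) < p]
  for (i in hit) s[i] <- sample((1:4)[-s[i]], 1L)
  list(seq = s, pos = hit)
}

#' Point-mutate a nucleotide sequence
#'
#' Substitutes each position independently with probability `divergence`
#' (always to a different base). Useful for building diverged homologs and
#' outgroup contexts around the structured generators.
#'
#' @param seq a `NucSequence` or nucleotide string.
#' @param divergence per-site substitution probability.
#' @return mutated nucleotide string.
#' @export
mutate_sequence <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  s <- base2int(strsplit(as_seq_string(seq), "", fixed = TRUE)[[1]])
  keep_n <- is.na(s)
  s[keep_n] <- 1L
  out <- mutate_sites(s, divergence)$seq
  v <- int2base(out)
  v[keep_n] <- "N"
  paste(v, collapse = "")
}

#' Simulate a palindromic locus with conversion and a protected island
#'
#' Builds an ancestral arm of `arm_units` duplicated units (i.i.d. random
#' cores), evolves two descendant arms from it (each at
#' `background_div / 2`, so the arm-to-arm background divergence is
#' `background_div`), and assembles `arm1 + loop + revcomp(arm2)`.
#' `rpois(1, conversion_rate)` gene-conversion tracts (geometric lengths,
#' mean `tract_mean`) overwrite arm2 with the arm1 sequence -- restoring
#' identity -- everywhere except inside the protected island; finally the
#' island segment of arm2 is reset to the arm1 sequence and re-diverged at
#' `island$divergence`, so its true arm-to-arm divergence equals the island
#' parameter exactly. The ancestral arm is returned alongside the arms: it
#' is the third homolog a gene-conversion screen aligns against.
#'
#' @param unit_length bp per duplicated unit.
#' @param arm_units units per arm.
#' @param loop_units units in the loop spacer.
#' @param background_div arm-to-arm background divergence (0-0.25).
#' @param conversion_rate expected number of conversion tracts. The default
#'   (`NULL`) scales with the arm, `3 * arm_length / tract_mean`, so tracts
#'   cover ~95% of the arm regardless of geometry: arms are kept nearly
#'   identical by recurrent conversion and the residual background
#'   divergence outside the protected island is near zero.
#' @param tract_mean mean geometric tract length in bp.
#' @param island `NULL`, or list(`length`, `divergence`, `offset`) with
#'   `offset` the island start in arm coordinates (default: 100 bp into the
#'   second arm unit, emulating a divergent segment at the 5' end of a gene
#'   carried by that unit).
#' @param seed RNG seed.
#' @return list of class `LocusSim`: `locus` (`NucSequence`), `arm1`,
#'   `arm2`, `ancestor_arm` (strings, arm coordinates), and `truth`
#'   (class `LocusTruth`): unit/arm/loop/island intervals in locus
#'   coordinates (`Interval`), the island interval in arm coordinates,
#'   conversion tract log, and mutation positions.
#' @export
simulate_palindrome_locus <- function(unit_length = 15000L, arm_units = 3L,
                                      loop_units = 1L,
                                      background_div = 0.002,
                                      conversion_rate = NULL,
                                      tract_mean = 500,
                                      island = list(length = 673L,
                                                    divergence = 0.02,
                                                    offset = NULL),
                                      seed = 1L) {
  if (background_div < 0 || background_div > 0.25)
    stop("background_div must be in [0, 0.25]")
  set.seed(seed)
  A <- unit_length * arm_units
  if (is.null(conversion_rate)) conversion_rate <- 3 * A / tract_mean
  if (!is.null(island)) {
    if (is.null(island$offset))
      island$offset <- unit_length + 100L
    if (island$divergence < 0 || island$divergence > 0.25)
      stop("island divergence must be in [0, 0.25]")
    if (island$length >= A) stop("island longer than arm")
    if (island$offset + island$length > A)
      stop("island does not fit inside the arm")
  }
  anc <- sample.int(4L, A, replace = TRUE)
  loop <- sample.int(4L, unit_length * loop_units, replace = TRUE)
  isl_pos <- if (!is.null(island) && island$length > 0)
    (island$offset + 1L):(island$offset + island$length) else integer(0)
  ## both arms descend from the duplication ancestor, splitting the
  ## arm-to-arm background divergence between the two lineages; the
  ## ancestor is kept in the truth record as the outgroup context that
  ## conversion detection needs
  bg1 <- mutate_sites(anc, background_div / 2)
  arm1 <- bg1$seq
  bg <- mutate_sites(anc, background_div / 2)
  arm2 <- bg$seq
  ## conversion tracts: copy arm1 onto arm2, never inside the island
  n_tr <- stats::rpois(1L, conversion_rate)
  tracts <- list()
  for (r in seq_len(n_tr)) {
    len <- stats::rgeom(1L, 1 / tract_mean) + 1L
    st <- sample.int(A, 1L)
    en <- min(A, st + len - 1L)
    span <- setdiff(st:en, isl_pos)
    arm2[span] <- arm1[span]
    tracts[[r]] <- data.frame(start = st - 1L, end = en, length = en - st + 1L,
                              clipped_by_island = length(span) < en - st + 1L)
  }
  tract_log <- if (length(tracts)) do.call(rbind, tracts)
               else data.frame(start = numeric(0), end = numeric(0),
                               length = numeric(0),
                               clipped_by_island = logical(0))
  ## protected island: reset then re-diverge at the island rate
  if (length(isl_pos)) {
    arm2[isl_pos] <- arm1[isl_pos]
    isl <- mutate_sites(arm2, island$divergence, isl_pos)
    arm2 <- isl$seq
  }
  arm1_s <- paste(int2base(arm1), collapse = "")
  arm2_s <- paste(int2base(arm2), collapse = "")
  loop_s <- paste(int2base(loop), collapse = "")
  locus_s <- paste0(arm1_s, loop_s, revcomp(arm2_s))
  Lp <- nchar(loop_s)
  total <- 2L * A + Lp
  ## truth intervals, locus coordinates (0-based half-open)
  unit_iv <- list()
  for (u in seq_len(arm_units)) {
    unit_iv[[length(unit_iv) + 1L]] <-
      c((u - 1L) * unit_length, u * unit_length, paste0("u", u), "+")
  }
  for (u in seq_len(loop_units)) {
    unit_iv[[length(unit_iv) + 1L]] <-
      c(A + (u - 1L) * unit_length, A + u * unit_length,
        paste0("loop", u), "+")
  }
  for (u in seq_len(arm_units)) {
    ## arm2 unit u occupies arm coords [(u-1)U, uU) -> locus (reversed)
    st <- total - u * unit_length
    unit_iv[[length(unit_iv) + 1L]] <-
      c(st, st + unit_length, paste0("u", u, "p"), "-")
  }
  um <- do.call(rbind, unit_iv)
  units <- intervals("locus", as.numeric(um[, 1]), as.numeric(um[, 2]),
                     strand = um[, 4], label = um[, 3])
  arms <- intervals("locus", c(0, A + Lp), c(A, total),
                    strand = c("+", "-"), label = c("arm1", "arm2"))
  loop_iv <- intervals("locus", A, A + Lp, label = "loop")
  island_truth <- NULL
  if (length(isl_pos)) {
    island_truth <- list(
      arm_start = island$offset, arm_end = island$offset + island$length,
      divergence = island$divergence,
      realized_mismatches = sum(arm1[isl_pos] != arm2[isl_pos]),
      locus_arm1 = intervals("locus", island$offset,
                             island$offset + island$length,
                             label = "island"),
      locus_arm2 = intervals("locus",
                             total - (island$offset + island$length),
                             total - island$offset, strand = "-",
                             label = "island"))
  }
  truth <- structure(list(
    params = list(unit_length = unit_length, arm_units = arm_units,
                  loop_units = loop_units, background_div = background_div,
                  conversion_rate = conversion_rate, tract_mean = tract_mean,
                  island = island, seed = seed),
    units = units, arms = arms, loop = loop_iv,
    island = island_truth, tracts = tract_log,
    background_mut_pos = sort(unique(c(bg1$pos, bg$pos))),
    n_arm_mismatches = sum(arm1 != arm2)), class = "LocusTruth")
  structure(list(locus = nuc_sequence("locus", locus_s,
                                      "synthetic palindromic locus"),
                 arm1 = arm1_s, arm2 = arm2_s,
                 ancestor_arm = paste(int2base(anc), collapse = ""),
                 truth = truth),
            class = "LocusSim")
}

#' Simulate a gene-family alignment down a tree
#'
#' Evolves `n_sites` i.i.d. sites under a single-rate symmetric (JC69)
#' substitution model along a binary tree with branch lengths in expected
#' substitutions per site.
#'
#' @param tree a `phylo` tree (branch lengths >= 0).
#' @param n_sites alignment length.
#' @param seed RNG seed.
#' @return list: `alignment` (character matrix, rows = tips, uppercase),
#'   `tree` (the truth tree).
#' @export
simulate_family_alignment <- function(tree, n_sites = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have nonnegative branch lengths")
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = n_sites, type = "DNA", rate = 1)
  mat <- toupper(as.character(sim))
  list(alignment = mat, tree = tree)
}

#' Write a simulated locus with its truth record
#'
#' Emits `<prefix>.fasta` (locus plus both arms), `<prefix>_truth.bed`
#' (unit/arm/loop/island truth intervals) and `<prefix>_truth.json`
#' (parameters, seed, tract log, counts).
#'
#' @param sim a [simulate_palindrome_locus()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return named character vector of the files written, invisibly.
#' @export
write_locus_outputs <- function(sim, dir, prefix = "locus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  write_fasta(list(sim$locus,
                   nuc_sequence("arm1", sim$arm1),
                   nuc_sequence("arm2", sim$arm2),
                   nuc_sequence("ancestor", sim$ancestor_arm)), fa)
  tr <- sim$truth
  iv <- rbind(tr$units, tr$arms, tr$loop)
  if (!is.null(tr$island)) iv <- rbind(iv, tr$island$locus_arm1,
                                       tr$island$locus_arm2)
  bed <- file.path(dir, paste0(prefix, "_truth.bed"))
  write_bed(iv, bed)
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(
    params = tr$params,
    island = if (!is.null(tr$island))
      tr$island[c("arm_start", "arm_end", "divergence",
                  "realized_mismatches")] else NULL,
    tracts = tr$tracts,
    n_arm_mismatches = tr$n_arm_mismatches), js, auto_unbox = TRUE,
    digits = NA)
  invisible(c(fasta = fa, bed = bed, json = js))
}
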