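test_that("CDS-pair simulator honors degenerate parameters", {
  s0 <- simulate_cds_pair(n_codons = 50, t = 0, seed = 3)
  expect_identical(s0$cds_a, s0$cds_b)
  expect_equal(s0$truth$n_diff_sites, 0)

  s1 <- simulate_cds_pair(n_codons = 100, t = 0.3, omega = 0,
                          cpg_mult = 1, seed = 4)
  expect_equal(s1$truth$nonsyn_changes, 0)
  expect_gt(s1$truth$syn_changes, 0)
  ## and the emitted pair translates identically
  ca <- codon_alignment(c(a = s1$cds_a, b = s1$cds_b))
  expect_equal(count_amino_acid_changes(ca)$total_changes, 0)

  expect_error(simulate_cds_pair(n_codons = 5), ">= 10")
  expect_error(simulate_cds_pair(cpg_mult = 0.5), ">= 1")
})

test_that("CDS-pair simulator is seed-deterministic and self-consistent", {
  a <- simulate_cds_pair(n_codons = 80, t = 0.2, seed = 11)
  b <- simulate_cds_pair(n_codons = 80, t = 0.2, seed = 11)
  expect_identical(a$cds_a, b$cds_a)
  expect_identical(a$cds_b, b$cds_b)
  expect_identical(a$truth$events, b$truth$events)

  ## truth recount: logged difference count matches the emitted sequences
  va <- strsplit(a$cds_a, "")[[1]]; vb <- strsplit(a$cds_b, "")[[1]]
  expect_equal(a$truth$n_diff_sites, sum(va != vb))
  ## no internal stops in either sequence
  for (s in c(a$cds_a, a$cds_b)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  }
})

test_that("CpG sites accumulate more substitutions when the multiplier is on", {
  hot <- sapply(1:10, function(sd)
    simulate_cds_pair(n_codons = 300, t = 0.05, cpg_mult = 12,
                      seed = sd)$truth$syn_changes_cpg_codon)
  cold <- sapply(1:10, function(sd)
    simulate_cds_pair(n_codons = 300, t = 0.05, cpg_mult = 1,
                      seed = sd + 50)$truth$syn_changes_cpg_codon)
  expect_gt(mean(hot), mean(cold))
})

test_that("palindrome locus honors degenerate parameters exactly", {
  ## no divergence, no conversion, no island: arms are exact copies
  ls <- simulate_palindrome_locus(unit_length = 2000, arm_units = 2,
                                  loop_units = 1, background_div = 0,
                                  conversion_rate = 0, island = NULL,
                                  seed = 5)
  expect_identical(ls$arm1, ls$arm2)
  ## locus = arm1 + loop + revcomp(arm2)
  expect_identical(substr(ls$locus$seq, 1, 4000), ls$arm1)
  expect_identical(substr(ls$locus$seq, 6001, 10000), revcomp(ls$arm2))
  expect_equal(ls$truth$n_arm_mismatches, 0)

  ## saturating conversion, no island: arms nearly identical
  hi <- simulate_palindrome_locus(unit_length = 5000, arm_units = 2,
                                  loop_units = 1, background_div = 0.02,
                                  conversion_rate = 60, island = NULL,
                                  seed = 6)
  ident <- 1 - hi$truth$n_arm_mismatches / nchar(hi$arm1)
  expect_gt(ident, 0.99)
})

test_that("locus truth intervals are consistent and the island is protected", {
  ls <- simulate_palindrome_locus(unit_length = 3000, arm_units = 2,
                                  loop_units = 1, background_div = 0.002,
                                  conversion_rate = 40,
                                  island = list(length = 500,
                                                divergence = 0.02,
                                                offset = 3100), seed = 8)
  tr <- ls$truth
  L <- length(ls$locus)
  expect_true(all(tr$units$end <= L))
  expect_equal(nrow(tr$units), 5L)       # 2 arm + 1 loop + 2 arm
  expect_equal(tr$arms$end[1], 6000)
  expect_equal(tr$loop$start, 6000)

  ## island divergence is exactly the planted rate's realized mismatches
  a1 <- strsplit(ls$arm1, "")[[1]]; a2 <- strsplit(ls$arm2, "")[[1]]
  isl <- (tr$island$arm_start + 1):tr$island$arm_end
  expect_equal(sum(a1[isl] != a2[isl]), tr$island$realized_mismatches)
  ## conversion never reduced island divergence: tracts overlapping the
  ## island are flagged clipped and identity inside stays at ~2%
  expect_gt(tr$island$realized_mismatches, 0)
  ov <- tr$tracts$start < tr$island$arm_end &
        tr$tracts$end > tr$island$arm_start
  expect_true(all(tr$tracts$clipped_by_island[ov]))
  ## outside the island the arms are near-identical (conversion saturates)
  out <- setdiff(seq_along(a1), isl)
  expect_lt(mean(a1[out] != a2[out]), 0.004)

  ## geometry validation
  expect_error(simulate_palindrome_locus(unit_length = 1000, arm_units = 1,
                                         island = list(length = 2000,
                                                       divergence = 0.02,
                                                       offset = 0)),
               "island")
  expect_error(simulate_palindrome_locus(background_div = 0.5), "0.25")
})

test_that("locus outputs round-trip through FASTA/BED/JSON", {
  ls <- simulate_palindrome_locus(unit_length = 2000, arm_units = 2,
                                  loop_units = 1, seed = 9)
  dir <- tempfile("locus_out_")
  files <- write_locus_outputs(ls, dir)
  expect_true(all(file.exists(files)))
  back <- read_fasta(files[["fasta"]])
  expect_identical(back[[1]]$seq, ls$locus$seq)
  iv <- read_intervals(files[["bed"]], "bed")
  expect_true(all(c("u1", "u2", "loop1", "arm1", "arm2") %in% iv$label))
  js <- jsonlite::read_json(files[["json"]])
  expect_equal(js$params$seed, 9)
})

test_that("family alignments evolve by the truth tree", {
  tree0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  f0 <- simulate_family_alignment(tree0, n_sites = 200, seed = 2)
  expect_true(all(apply(f0$alignment, 2, function(col)
    length(unique(col)) == 1L)))

  ## 4-taxon tree with a long internal branch: NJ recovers the topology
  tree <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.15,(C:0.05,D:0.05):0.15);")
  wins <- vapply(1:40, function(sd) {
    f <- simulate_family_alignment(tree, n_sites = 2000, seed = sd)
    tr <- nj_tree(dist_matrix_p(f$alignment))
    identical(bipartitions(tr), bipartitions(tree))
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  ## p-distances converge to the Jukes-Cantor expectation of path lengths
  big <- simulate_family_alignment(tree, n_sites = 1e5, seed = 77)
  d <- dist_matrix_p(big$alignment)
  paths <- ape::cophenetic.phylo(tree)[rownames(d), rownames(d)]
  expected <- 3 / 4 * (1 - exp(-4 * paths / 3))
  se <- sqrt(expected * (1 - expected) / 1e5)
  off <- abs(unclass(d) - expected)[upper.tri(d)]
  expect_true(all(off <= 2.5 * se[upper.tri(se)]))

  noblen <- tree
  noblen$edge.length <- NULL
  expect_error(simulate_family_alignment(noblen), "branch lengths")
})
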