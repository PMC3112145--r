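test_that("window profile computes per-window divergence with signed coordinates", {
  set.seed(4)
  a <- random_dna(1500)
  v <- strsplit(a, "")[[1]]
  for (i in c(600, 700, 900)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  b <- paste(v, collapse = "")
  prof <- arm_profile(pairwise_alignment(a, b), window = 500, step = 500)
  expect_equal(prof$d, c(0, 0.006, 0))
  expect_equal(prof$start, c(0, 500, 1000))
  expect_equal(prof$signed_center_pos, c(-1500, -1000, -500))

  ## identical arms: all-zero profile
  p0 <- arm_profile(pairwise_alignment(a, a), 500, 500)
  expect_true(all(p0$d == 0))

  ## window larger than the alignment: one truncated window, with a warning
  expect_warning(p1 <- arm_profile(pairwise_alignment(a, b), 2000, 2000),
                 "truncated")
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$mismatches, 3)
})

test_that("window mismatch totals conserve the whole-alignment mismatch count", {
  set.seed(9)
  for (r in 1:10) {
    n <- sample(2000:6000, 1)
    a <- random_dna(n)
    b <- mutate_string(a, runif(1, 0, 0.05))
    aln <- pairwise_alignment(a, b)
    prof <- arm_profile(aln, 500, 500)
    expect_equal(sum(prof$mismatches),
                 sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
    ## windows are non-overlapping when step = size
    expect_true(all(diff(prof$start) == 500))
  }
})

test_that("gap and N columns are excluded from window site counts", {
  aln <- pairwise_alignment(paste0("AC-TN", strrep("A", 95)),
                            paste0("ACGTA", strrep("A", 95)))
  prof <- arm_profile(aln, window = 100, step = 100)
  expect_equal(prof$sites, 98)
  expect_equal(prof$mismatches, 0)
})

test_that("a planted divergent island is found where it was planted", {
  ls <- simulate_palindrome_locus(unit_length = 5000, arm_units = 2,
                                  loop_units = 1,
                                  island = list(length = 673,
                                                divergence = 0.02,
                                                offset = NULL), seed = 7)
  aln <- pairwise_alignment(ls$arm1, ls$arm2)
  prof <- arm_profile(aln, 500, 500)
  ## elevated d exactly in the windows overlapping the island (5100..5773)
  hot <- prof$start %in% c(5000, 5500)
  expect_gt(min(prof$d[hot]), max(prof$d[!hot]))

  isl <- detect_islands(prof, alpha = 0.01)
  expect_gte(nrow(isl), 1L)
  ## principal island: saturating conversion can leave minor residual
  ## pockets of divergence that are genuinely enriched vs the background
  top <- isl[which.max(isl$mismatches), ]
  expect_lt(top$p_adj, 0.001)
  expect_gt(top$mean_divergence, top$background)
  ## island overlaps the truth interval
  expect_lt(top$start, ls$truth$island$arm_end)
  expect_gt(top$end, ls$truth$island$arm_start)
})

test_that("island detection is quiet on homogeneous arms", {
  fp <- vapply(1:100, function(sd) {
    set.seed(sd + 700)
    a <- random_dna(10000)
    b <- mutate_string(a, 0.005)
    isl <- detect_islands(arm_profile(pairwise_alignment(a, b), 500, 500),
                          alpha = 0.01)
    nrow(isl) > 0
  }, logical(1))
  expect_gte(mean(!fp), 0.95)

  ## all-zero mismatch profile: empty result, no error
  a <- random_dna(3000)
  expect_equal(nrow(detect_islands(arm_profile(pairwise_alignment(a, a),
                                               500, 500))), 0L)
})

test_that("two distant islands are reported separately", {
  set.seed(66)
  a <- random_dna(12000)
  v <- strsplit(a, "")[[1]]
  w <- v
  plant <- function(w, from, to) {
    hit <- from + which(runif(to - from) < 0.03)
    for (i in hit) w[i] <- sample(setdiff(c("A", "C", "G", "T"), w[i]), 1)
    w
  }
  w <- plant(w, 2000, 2700)
  w <- plant(w, 8000, 8700)
  aln <- pairwise_alignment(a, paste(w, collapse = ""))
  isl <- detect_islands(arm_profile(aln, 500, 500), alpha = 0.01)
  expect_equal(nrow(isl), 2L)
  expect_true(any(isl$start < 3000) && any(isl$start > 7000))
})

test_that("permutation alternative agrees with the binomial test on a clear island", {
  ls <- simulate_palindrome_locus(unit_length = 5000, arm_units = 2,
                                  loop_units = 1,
                                  island = list(length = 673,
                                                divergence = 0.02,
                                                offset = NULL), seed = 19)
  prof <- arm_profile(pairwise_alignment(ls$arm1, ls$arm2), 500, 500)
  i1 <- detect_islands(prof, alpha = 0.05, method = "binomial")
  ## the permutation p floor is 1/(n_perm + 1), so resolution at small
  ## alpha needs enough permutations
  i2 <- detect_islands(prof, alpha = 0.05, method = "permutation",
                       n_perm = 1999, seed = 3)
  expect_gte(nrow(i1), 1L)
  expect_gte(nrow(i2), 1L)
  t1 <- i1[which.max(i1$mismatches), ]
  t2 <- i2[which.max(i2$mismatches), ]
  expect_lt(abs(t1$start - t2$start), 600)
})

test_that("island/feature overlap reports bp and fractions", {
  isl <- data.frame(start = c(100, 500), end = c(200, 700))
  feats <- intervals("arm", c(100, 650), c(200, 900),
                     label = c("geneA_5p", "geneB"))
  ov <- island_gene_overlap(isl, feats)
  expect_equal(ov$fraction_of_island[ov$island == 1], 1.0)
  expect_equal(ov$feature[ov$island == 1], "geneA_5p")
  ## island 2 half-covered by geneB
  expect_equal(ov$overlap_bp[ov$island == 2], 50)
  expect_equal(ov$fraction_of_island[ov$island == 2], 0.25)

  none <- island_gene_overlap(data.frame(start = 0, end = 10),
                              intervals("arm", 100, 200))
  expect_equal(none$overlap_bp, 0)
})
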