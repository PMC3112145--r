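test_that("self-comparison finds planted inverted and direct repeats exactly", {
  set.seed(14)
  u <- random_dna(5000)

  ## U + revcomp(U): one inverted segment pair covering both halves
  sp <- self_compare(paste0(u, revcomp(u)))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$orientation, "inverted")
  expect_equal(sp$q_start, 0)
  expect_equal(sp$q_end, 5000)
  expect_equal(sp$s_start, 5000)
  expect_equal(sp$s_end, 10000)
  expect_equal(sp$identity, 1.0)

  ## U + U: one direct segment
  sd <- self_compare(paste0(u, u))
  expect_equal(nrow(sd), 1L)
  expect_equal(sd$orientation, "direct")
  expect_equal(sd$identity, 1.0)

  expect_error(self_compare(u, k = 6), ">= 8")
})

test_that("i.i.d. random sequence yields no chained segments", {
  set.seed(55)
  for (r in 1:25) {
    expect_equal(nrow(self_compare(random_dna(20000), min_segment = 300)), 0L)
  }
})

test_that("similarity color bins follow the stated half-open boundaries", {
  expect_equal(bin_similarity(0.96), "red")
  expect_equal(bin_similarity(0.92), "orange")
  expect_equal(bin_similarity(0.85), "blue")
  expect_equal(bin_similarity(c(0.951, 0.95, 0.901, 0.90, 0.851, 0.3)),
               c("red", "orange", "orange", "green", "green", "blue"))
  expect_error(bin_similarity(1.2), "\\[0, 1\\]")
  expect_error(bin_similarity(-0.1), "\\[0, 1\\]")
})

test_that("palindrome calls recover a planted arm/loop structure", {
  ## 10 kb arms, 5 kb loop, ~1% arm-to-arm divergence
  ls <- simulate_palindrome_locus(unit_length = 5000, arm_units = 2,
                                  loop_units = 1, background_div = 0.01,
                                  conversion_rate = 0, island = NULL,
                                  seed = 77)
  segs <- self_compare(ls$locus)
  calls <- detect_palindromes(segs, ls$locus, min_arm = 5000)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$arm1_start - 0), 24)
  expect_lte(abs(calls$arm1_end - 10000), 24)
  expect_lte(abs(calls$arm2_start - 15000), 24)
  expect_lte(abs(calls$arm2_end - 25000), 24)
  expect_gte(calls$arm_identity, 0.985)
  expect_lte(calls$arm_identity, 0.995)
  expect_equal(calls$center, 12500, tolerance = 0.01)

  ## direct-only repeats give no palindrome call
  set.seed(15)
  u <- random_dna(4000)
  tand <- self_compare(paste0(u, u, random_dna(3000)))
  expect_equal(nrow(detect_palindromes(tand, paste0(u, u, random_dna(3000)),
                                       min_arm = 1000)), 0L)
})

test_that("a large deletion in one arm yields a shortened overlapping call", {
  set.seed(78)
  arm <- random_dna(10000)
  loop <- random_dna(3000)
  arm2 <- paste0(substr(arm, 1, 2000), substr(arm, 8001, 10000)) # 6 kb gone
  locus <- paste0(arm, loop, revcomp(arm2))
  calls <- detect_palindromes(self_compare(locus), locus, min_arm = 1000)
  expect_gte(nrow(calls), 1L)
  ## the principal call spans only part of the full arm
  expect_lt(calls$arm_length[1], 9000)
})

test_that("palindrome calls are mirror-symmetric under reverse complement", {
  ls <- simulate_palindrome_locus(unit_length = 4000, arm_units = 2,
                                  loop_units = 1, background_div = 0.005,
                                  conversion_rate = 0, island = NULL,
                                  seed = 101)
  L <- length(ls$locus)
  fwd <- detect_palindromes(self_compare(ls$locus), ls$locus, min_arm = 4000)
  rc <- revcomp(ls$locus$seq)
  rev <- detect_palindromes(self_compare(rc), rc, min_arm = 4000)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(L - c(fwd$arm2_end, fwd$arm2_start)),
               sort(c(fwd$arm1_start, fwd$arm1_end)), tolerance = 30)
  expect_equal(rev$arm1_start, L - fwd$arm2_end, tolerance = 30)
  ## segment counts match between strands
  expect_equal(nrow(self_compare(ls$locus)), nrow(self_compare(rc)))
})

test_that("planted palindromes are recovered across arm lengths and identities", {
  hits <- 0; total <- 0
  for (sd in 1:25) {
    set.seed(sd + 300)
    arm_len <- sample(5000:20000, 1)
    div <- runif(1, 0, 0.05)
    ls <- simulate_palindrome_locus(unit_length = arm_len, arm_units = 1,
                                    loop_units = 1, background_div = div,
                                    conversion_rate = 0, island = NULL,
                                    seed = sd)
    calls <- detect_palindromes(self_compare(ls$locus), ls$locus,
                                min_arm = 2000)
    total <- total + 1
    if (nrow(calls) == 1 &&
        abs(calls$arm1_start - 0) <= 24 &&
        abs(calls$arm1_end - arm_len) <= 24 &&
        abs(calls$arm_identity - (1 - div)) < 0.01)
      hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("marker-based unit orthology assigns by Jaccard score", {
  ua <- list(duplicated_unit("h1", 0, 10, c("a", "b", "c")),
             duplicated_unit("h2", 10, 20, c("d", "e", "f", "g",
                                             "h", "i", "j", "k")),
             duplicated_unit("h3", 20, 30, character(0)))
  ub <- list(duplicated_unit("m1", 0, 10, c("a", "b", "c")),
             duplicated_unit("m2", 10, 20, c("d", "e", "f", "g",
                                             "h", "i", "x", "y")),
             duplicated_unit("m3", 20, 30, c("z")))
  res <- unit_orthology_scores(ua, ub)
  expect_equal(res$scores["h1", "m1"], 1.0)
  expect_equal(res$scores["h2", "m2"], 6 / 10)
  asn <- res$assignment
  expect_equal(asn$unit_b[asn$unit_a == "h1"], "m1")
  expect_equal(asn$unit_b[asn$unit_a == "h2"], "m2")
  expect_true("h3" %in% res$empty_marker_units)
  expect_true("h3" %in% res$unassigned_a)

  ## disjoint marker sets: nothing assigned
  ud <- list(duplicated_unit("x1", 0, 5, c("p", "q")))
  ue <- list(duplicated_unit("y1", 0, 5, c("r", "s")))
  res2 <- unit_orthology_scores(ud, ue)
  expect_equal(nrow(res2$assignment), 0L)
  expect_equal(res2$unassigned_a, "x1")
})
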