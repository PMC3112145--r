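test_that("p-distance matches hand-worked values and the binomial SE", {
  d <- p_distance(pairwise_alignment("ACGTACGT", "ACGTACGA"))
  expect_equal(d$p, 0.125)
  expect_equal(d$n_sites, 8L)

  ## pairwise deletion drops gap columns from the denominator
  d2 <- p_distance(pairwise_alignment("AC-T", "ACGT"))
  expect_equal(d2$p, 0)
  expect_equal(d2$n_sites, 3L)

  ## 20 mismatches over a 2880-bp unit: 0.7% with SE ~0.15%
  a <- strrep("A", 2880)
  b <- paste0(strrep("C", 20), strrep("A", 2860))
  d3 <- p_distance(pairwise_alignment(a, b))
  expect_equal(d3$p, 20 / 2880)
  expect_equal(d3$se, sqrt(d3$p * (1 - d3$p) / 2880))
  expect_equal(d3$se, 0.001548, tolerance = 1e-3)

  expect_error(p_distance(pairwise_alignment("--A", "AA-")),
               "no comparable")
})

test_that("p-distance is symmetric, zero on self, monotone in mismatches", {
  set.seed(7)
  for (r in 1:20) {
    a <- random_dna(200)
    b <- mutate_string(a, 0.1)
    expect_equal(p_distance(pairwise_alignment(a, b))$p,
                 p_distance(pairwise_alignment(b, a))$p)
    expect_equal(p_distance(pairwise_alignment(a, a))$p, 0)
    ## appending one mismatching column never decreases p
    p1 <- p_distance(pairwise_alignment(a, b))$p
    p2 <- p_distance(pairwise_alignment(paste0(a, "A"), paste0(b, "C")))$p
    expect_gte(p2, p1)
  }
})

test_that("Nei-Gojobori reproduces worked single-codon examples", {
  ng <- nei_gojobori(codon_alignment(c(a = "GGGGGG", b = "GGAGGG")))
  expect_equal(ng$S, 2)
  expect_equal(ng$N, 4)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Nd, 0)
  expect_equal(ng$pS, 0.5)
  expect_equal(ng$pN, 0)

  ng2 <- nei_gojobori(codon_alignment(c(a = "ATG", b = "ATA")))
  expect_equal(ng2$S, 1 / 3)
  expect_equal(ng2$N, 8 / 3)
  expect_equal(ng2$Nd, 1)
  expect_equal(ng2$pN, 0.375)
  expect_equal(ng2$pS, 0)

  same <- nei_gojobori(codon_alignment(c(a = "ATGAAA", b = "ATGAAA")))
  expect_equal(same$Sd + same$Nd, 0)
  expect_equal(c(same$pS, same$pN), c(0, 0))
})

test_that("site counts always satisfy S + N = 3 x compared codons", {
  set.seed(3)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    a <- random_sense_cds(n)
    ca <- codon_alignment(c(a = a, b = mutate_string(a, 0.08)))
    ng <- nei_gojobori(ca)
    expect_equal(ng$S + ng$N, 3 * ng$n_codons)
    expect_lte(ng$Sd, ng$S)
    expect_lte(ng$Nd, ng$N)
  }
  ## S + N conservation holds even for saturated (independent) pairs
  for (r in 1:5) {
    n <- sample(2:40, 1)
    ng <- nei_gojobori(codon_alignment(c(a = random_sense_cds(n),
                                         b = random_sense_cds(n))))
    expect_equal(ng$S + ng$N, 3 * ng$n_codons)
  }
})

test_that("CpG codon flagging follows the boundary rule exactly", {
  ## CG inside codon 1 only
  ca <- flag_cpg_codons(codon_alignment(c(x = "ACGGGG")), "within_codon")
  expect_equal(ca$cpg_flags, c(TRUE, FALSE))

  ## CG spanning the codon boundary flags both codons under "spanning" only
  cb <- flag_cpg_codons(codon_alignment(c(x = "AACGTT")), "spanning")
  expect_equal(cb$cpg_flags, c(TRUE, TRUE))
  cc <- flag_cpg_codons(codon_alignment(c(x = "AACGTT")), "within_codon")
  expect_equal(cc$cpg_flags, c(FALSE, FALSE))

  ## any row can flag a column
  cd <- flag_cpg_codons(codon_alignment(c(a = "AAATTT", b = "ACGTTT")),
                        "within_codon")
  expect_equal(cd$cpg_flags, c(TRUE, FALSE))
})

test_that("CpG exclusion restricts the estimator without changing its contract", {
  ## zero flagged codons: identical to the unrestricted estimator
  ca <- codon_alignment(c(a = "ATGAAATTT", b = "ATGAAATTC"))
  full <- nei_gojobori(ca)
  excl <- ng_excluding_cpg(ca)
  expect_identical(full[c("S", "N", "Sd", "Nd", "pS", "pN")],
                   excl[c("S", "N", "Sd", "Nd", "pS", "pN")])
  expect_equal(excl$n_excluded, 0L)

  ## all differences inside CpG-flagged codons vanish after exclusion
  cb <- codon_alignment(c(a = "ACGAAA", b = "ACAAAA"))  # ACG->ACA syn, CpG
  e2 <- ng_excluding_cpg(cb, boundary_rule = "within_codon")
  expect_equal(e2$pS, 0)
  expect_equal(e2$pN, 0)
  expect_equal(e2$n_excluded, 1L)

  ## everything flagged -> no-data error
  expect_error(ng_excluding_cpg(codon_alignment(c(a = "ACG", b = "ACG"))),
               "no unflagged")

  ## masked identical alignment stays at zero divergence under either rule
  cc <- codon_alignment(c(a = "ACGCGTTTT", b = "ACGCGTTTT"))
  for (rule in c("spanning", "within_codon"))
    expect_equal(ng_excluding_cpg(cc, boundary_rule = rule)$pS, 0)
})

test_that("Jukes-Cantor correction applies below its domain boundary", {
  ca <- codon_alignment(c(a = "GGGGGG", b = "GGAGGG"))
  ng <- nei_gojobori(ca, correction = "jukes_cantor")
  expect_equal(ng$dS, -3 / 4 * log(1 - 4 * 0.5 / 3))
  ## pS = 1 >= 3/4 -> undefined
  cb <- codon_alignment(c(a = "TTATTA", b = "TTGTTG"))  # Leu<->Leu syn x2
  expect_error(nei_gojobori(cb, correction = "jukes_cantor"), "3/4")
})

test_that("dN = dS gives z = 0 and two-sided p = 1; bootstrap is seeded", {
  ca <- codon_alignment(c(a = random_sense_cds(50), b = random_sense_cds(50)))
  ng <- nei_gojobori(ca, boot = 200, seed = 5)
  ng2 <- nei_gojobori(ca, boot = 200, seed = 5)
  expect_identical(ng$se_pS, ng2$se_pS)

  same <- nei_gojobori(codon_alignment(c(a = "ATGAAA", b = "ATGAAA")),
                       boot = 100, seed = 1)
  zt <- dnds_z_test(same)
  expect_equal(zt$z, 0)
  expect_equal(zt$p_two_sided, 1)
  expect_true(is.na(zt$ratio))  # dS = 0: ratio undefined, test still reported
})

test_that("dN/dS z-test detects purifying selection and holds its size", {
  ## power: omega = 0.2, 500 codons
  pow <- vapply(1:60, function(sd) {
    s <- simulate_cds_pair(n_codons = 500, t = 0.15, omega = 0.2,
                           cpg_mult = 1, seed = sd)
    ng <- nei_gojobori(codon_alignment(c(a = s$cds_a, b = s$cds_b)),
                       boot = 300, seed = sd)
    dnds_z_test(ng)$p_two_sided
  }, numeric(1))
  expect_gte(mean(pow < 0.05), 0.8)

  ## type-I error under neutrality (omega = 1)
  t1 <- vapply(1:300, function(sd) {
    s <- simulate_cds_pair(n_codons = 500, t = 0.15, omega = 1,
                           cpg_mult = 1, seed = sd + 4000)
    ng <- nei_gojobori(codon_alignment(c(a = s$cds_a, b = s$cds_b)),
                       boot = 300, seed = sd)
    dnds_z_test(ng)$p_two_sided
  }, numeric(1))
  expect_lte(mean(t1 <= 0.05), 0.07)
})

test_that("regional rate comparison is calibrated and finds planted rate shifts", {
  ## calibration: same process inside and outside the region
  pn <- vapply(1:300, function(sd) {
    s <- simulate_cds_pair(n_codons = 600, t = 0.2, omega = 0.5,
                           cpg_mult = 1, seed = sd)
    region_rate_compare(codon_alignment(c(a = s$cds_a, b = s$cds_b)), 1, 2,
                        600, 1200, "nonsyn")$p_value
  }, numeric(1))
  expect_lte(mean(pn <= 0.05), 0.08)

  ## power: middle 200 codons of 600 carry a 2x nonsynonymous rate
  pw <- vapply(1:50, function(sd) {
    cold <- simulate_cds_pair(n_codons = 600, t = 0.3, omega = 0.4,
                              cpg_mult = 1, seed = sd)
    hot <- simulate_cds_pair(n_codons = 200, t = 0.3, omega = 0.8,
                             cpg_mult = 1, seed = sd + 900)
    splice <- function(x, y)
      paste0(substr(x, 1, 600), y, substr(x, 1201, 1800))
    ca <- codon_alignment(c(a = splice(cold$cds_a, hot$cds_a),
                            b = splice(cold$cds_b, hot$cds_b)))
    r <- region_rate_compare(ca, 1, 2, 600, 1200, "nonsyn")
    (r$p_value < 0.05) && (r$rate_inside > r$rate_outside)
  }, logical(1))
  expect_gte(mean(pw), 0.8)

  ## a region covering the whole CDS is rejected
  s <- simulate_cds_pair(n_codons = 60, t = 0.2, omega = 1, cpg_mult = 1,
                         seed = 1)
  ca <- codon_alignment(c(a = s$cds_a, b = s$cds_b))
  expect_error(region_rate_compare(ca, 1, 2, 0, 180), "whole")
})

test_that("amino-acid change counting splits by region", {
  ca <- codon_alignment(c(a = "ATGAAA", b = "ATGAAA"))
  expect_equal(count_amino_acid_changes(ca)$total_changes, 0)

  ## one nonsynonymous change inside the region
  cb <- codon_alignment(c(a = "ATGAAA", b = "ATGACA"))
  r <- count_amino_acid_changes(cb, region_start = 3, region_end = 6)
  expect_equal(r$total_changes, 1)
  expect_equal(r$in_region_changes, 1)

  ## 13 planted amino-acid changes, 10 concentrated in a marked region
  set.seed(21)
  base <- random_sense_cds(320)
  inreg <- plant_changes(base, 10, "nonsynonymous", codon_pool = 101:180)
  full <- plant_changes(inreg$cds, 3, "nonsynonymous",
                        codon_pool = c(1:100, 181:320))
  cc <- codon_alignment(c(a = base, b = full$cds))
  r2 <- count_amino_acid_changes(cc, region_start = 300, region_end = 540)
  expect_equal(r2$total_changes, 13)
  expect_equal(r2$in_region_changes, 10)

  ## internal stop columns are skipped with a warning
  cd <- codon_alignment(c(a = "TGAAAA", b = "TGCAAA"))
  expect_warning(r3 <- count_amino_acid_changes(cd), "stop")
  expect_equal(r3$total_changes, 0)
})
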