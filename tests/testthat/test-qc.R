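test_that("depth filter is inclusive at the threshold and vacuous without samples", {
  mk <- function(depths) {
    tibble::tibble(variant_key = "v1", sample = paste0("S", seq_along(depths)),
                   depth = depths, depth_missing = FALSE)
  }
  cfg <- family_qc_config()
  expect_true(depth_filter(mk(c(12, 30, 10)), paste0("S", 1:3), cfg)$pass_depth)
  expect_false(depth_filter(mk(c(12, 9)), paste0("S", 1:2), cfg)$pass_depth)
  expect_true(depth_filter(mk(c(5, 5)), character(0), cfg)$pass_depth)
  # strict mode fails a missing DP, permissive passes it
  g <- mk(c(0, 30)); g$depth_missing <- c(TRUE, FALSE)
  expect_false(depth_filter(g, paste0("S", 1:2), cfg)$pass_depth)
  expect_true(depth_filter(g, paste0("S", 1:2),
                           family_qc_config(missing_qc = "permissive"))$pass_depth)
})

test_that("homopolymer rule fails runs exceeding five, passes runs of five", {
  ref <- c(c6 = paste0("GC", strrep("A", 6), "T", strrep("CG", 10)),
           c5 = paste0("GCC", strrep("A", 5), "T", strrep("CG", 10)))
  # variant right after the run: left flank ends with the A-run
  sites6 <- tibble::tibble(variant_key = "v6", chrom = "c6", pos = 9L, ref = "T")
  sites5 <- tibble::tibble(variant_key = "v5", chrom = "c5", pos = 9L, ref = "T")
  expect_true(homopolymer_adjacent(sites6, ref)$homopolymer_adjacent)
  expect_false(homopolymer_adjacent(sites5, ref)$homopolymer_adjacent)
})

test_that("planted right-flank runs are detected, matching a brute-force scan", {
  brute_max_adjacent_run <- function(seq, pos, ref_len) {
    chars <- strsplit(seq, "")[[1]]
    runlen <- function(idx, dir) {
      if (idx < 1 || idx > length(chars)) return(0L)
      b <- chars[idx]; k <- 0L
      while (idx >= 1 && idx <= length(chars) && chars[idx] == b) {
        k <- k + 1L; idx <- idx + dir
      }
      k
    }
    max(runlen(pos - 1L, -1L), runlen(pos + ref_len, 1L))
  }
  withr::with_seed(99, {
    for (i in 1:30) {
      runlen <- sample(2:9, 1)
      left <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
      seq <- paste0(left, "G", strrep("T", runlen), "ACAC")
      ref <- c(ctg = seq)
      sites <- tibble::tibble(variant_key = "v", chrom = "ctg", pos = 9L, ref = "G")
      expect_equal(
        homopolymer_adjacent(sites, ref)$homopolymer_adjacent,
        brute_max_adjacent_run(seq, 9L, 1L) > 5,
        info = paste("planted run", runlen)
      )
    }
  })
})

test_that("internal-cohort filter is strictly below the threshold", {
  ann <- tibble::tibble(variant_key = c("a", "b", "c"), internal_count = c(4L, 5L, 0L))
  expect_equal(internal_cohort_filter(ann)$pass_internal_cohort, c(TRUE, FALSE, TRUE))
})

test_that("the Hardy-Weinberg exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_p(2, 0, 2), hwe_oracle(2, 0, 2), tolerance = 1e-12)
  expect_equal(hwe_exact_p(57, 14, 50), hwe_oracle(57, 14, 50), tolerance = 1e-12)
  # imbalanced configuration: the chi-square approximation does not exceed
  # the exact p (both are vanishingly small and agree to rounding here)
  expect_lte(hwe_exact_p(57, 14, 50, method = "chisq"),
             hwe_exact_p(57, 14, 50) + 1e-12)
  expect_error(hwe_exact_p(0, 0, 0), "zero")
})

test_that("exact HWE equals the oracle for every genotype table with n <= 50", {
  worst <- 0
  for (n in 1:50) {
    for (n_alt in 0:n) {  # minor-allele copies among 2n alleles, via hom/het split
      for (hom_alt in 0:floor(n_alt / 2)) {
        het <- n_alt - 2 * hom_alt
        hom_ref <- n - het - hom_alt
        if (hom_ref < 0) next
        d <- abs(hwe_exact_p(hom_ref, het, hom_alt) - hwe_oracle(hom_ref, het, hom_alt))
        worst <- max(worst, d)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the exact test is conservative under Hardy-Weinberg sampling", {
  withr::with_seed(2024, {
    n <- 500; reps <- 2000
    mafs <- stats::runif(reps, 0.05, 0.5)
    rej <- vapply(mafs, function(p) {
      g <- stats::rbinom(n, 2, p)
      hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.05
    }, logical(1))
    se <- sqrt(0.05 * 0.95 / reps)
    expect_lte(mean(rej), 0.05 + 3 * se)
  })
})

test_that("call rate uses GQ-masked calls and the boundary is strict", {
  hw <- withr::with_seed(41, stats::rbinom(1000, 2, 0.3))  # HW genotypes
  g <- cohort_gt_tbl(c(hw[1:950], rep(NA, 50)))
  expect_equal(site_call_rate(g)$call_rate, 0.95)
  cfg <- cohort_qc_config()
  expect_equal(cohort_site_qc(g, cfg)$keep, TRUE)  # exclusion is < 0.95
  g2 <- cohort_gt_tbl(c(hw[1:949], rep(NA, 51)))
  expect_equal(cohort_site_qc(g2, cfg)$reason, "call_rate")
  # all GQ below the mask threshold -> call rate 0
  g3 <- cohort_gt_tbl(rep(1, 100), gq = 10)
  expect_equal(site_call_rate(g3)$call_rate, 0)
})

test_that("GQ masking is idempotent", {
  g <- cohort_gt_tbl(c(0, 1, 2, NA), gq = c(5, 25, 15, 99))
  m1 <- gq_mask(g)
  m2 <- gq_mask(m1)
  expect_identical(m1, m2)
  expect_equal(m1$missing, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("cohort site QC applies FILTER, call-rate and HWE rules in order", {
  cfg <- cohort_qc_config()
  bad_filter <- cohort_gt_tbl(rep(1, 100), filter = "VQSRTrancheSNP99.90")
  expect_equal(cohort_site_qc(bad_filter, cfg)$reason, "filter")

  # planted extreme HWE violation: all 200 samples heterozygous
  all_het <- cohort_gt_tbl(rep(1, 200))
  expect_lt(hwe_oracle(0, 200, 0), 1e-8)
  res <- cohort_site_qc(all_het, cfg)
  expect_equal(res$reason, "hwe")

  withr::with_seed(7, {
    clean <- cohort_gt_tbl(stats::rbinom(500, 2, 0.3))
    expect_true(cohort_site_qc(clean, cfg)$keep)
  })
})
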