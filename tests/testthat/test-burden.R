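test_that("beta weights follow the closed-form density and its monotonicity", {
  expect_equal(beta_weights(0), 25 * (1 - 0)^24)  # b at maf 0, the maximum
  mafs <- sort(stats::runif(20, 0, 0.5))
  expect_true(all(diff(beta_weights(mafs)) < 0))
  expect_equal(beta_weights(c(0.1, 0.4), 1, 1), c(1, 1))  # uniform case
  expect_error(beta_weights(1.2), "MAF")
})

test_that("the intercept-only null model fits the case fraction", {
  sim <- simulate_cohort(n_cases = 500, n_controls = 500, seed = 1)
  nf <- null_model(sim$dataset)
  expect_equal(unique(round(nf$mu, 10)), 0.5)
  sim2 <- simulate_cohort(n_cases = 130, n_controls = 861, seed = 1)
  nf2 <- null_model(sim2$dataset)
  expect_equal(unique(round(nf2$mu, 10)), round(130 / 991, 10))
  all_case <- sim$dataset
  all_case$phenotype <- rep("case", length(all_case$phenotype))
  expect_error(null_model(all_case), "constant")
})

test_that("the SKAT statistic equals a brute-force double loop", {
  brute_q <- function(G, w, r) {
    m <- ncol(G); n <- nrow(G); q <- 0
    for (j in seq_len(m)) {
      s <- 0
      for (i in seq_len(n)) s <- s + G[i, j] * r[i]
      q <- q + (w[j] * s)^2
    }
    q
  }
  withr::with_seed(31, {
    for (rep in 1:100) {
      n <- 50; m <- 10
      G <- matrix(stats::rbinom(n * m, 2, stats::runif(1, 0.05, 0.4)), n, m)
      y <- stats::rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      ds <- cohort_dataset(G, ifelse(y == 1, "case", "control"))
      nf <- null_model(ds)
      w <- stats::runif(m, 0.5, 25)
      expect_equal(skat_statistic(G, w, nf),
                   brute_q(G, w, nf$residuals), tolerance = 1e-10)
    }
  })
  # zero residuals give Q = 0; one variant reduces to the squared score
  G <- matrix(stats::rbinom(40, 2, 0.3), 20, 2)
  ds <- cohort_dataset(G, rep(c("case", "control"), 10))
  nf <- null_model(ds)
  nf0 <- nf; nf0$residuals <- rep(0, 20)
  expect_equal(skat_statistic(G, c(1, 1), nf0), 0)
  expect_equal(skat_statistic(G[, 1, drop = FALSE], 2, nf),
               (2 * sum(G[, 1] * nf$residuals))^2)
  expect_error(skat_statistic(G[, 0], numeric(0), nf), "no qualifying")
})

test_that("quadform tail matches chi-square closed forms exactly in the limits", {
  expect_equal(quadform_pvalue(3.7, 2.1),
               stats::pchisq(3.7 / 2.1, df = 1, lower.tail = FALSE))
  expect_equal(quadform_pvalue(9.1, rep(0.8, 5)),
               stats::pchisq(9.1 / 0.8, df = 5, lower.tail = FALSE))
  expect_error(quadform_pvalue(-1, 1), "non-negative")
  expect_error(quadform_pvalue(1, c(0, 0)), "all be zero")
})

test_that("quadform tail agrees with a seeded Monte-Carlo oracle", {
  withr::with_seed(17, {
    for (rep in 1:6) {
      lam <- exp(stats::runif(8, log(0.1), log(4)))
      q <- sum(lam) * stats::runif(1, 0.4, 2.5)
      p <- quadform_pvalue(q, lam)
      draws <- colSums(lam * matrix(stats::rchisq(8 * 1e6, df = 1), nrow = 8))
      p_mc <- mean(draws > q)
      se <- sqrt(max(p_mc * (1 - p_mc), 1e-12) / 1e6)
      expect_lte(abs(p - p_mc), 3 * se + 1e-12)
    }
  })
})

test_that("SKAT-O reduces to the score test for a single variant", {
  sim <- simulate_cohort(n_cases = 100, n_controls = 100, n_genes = 1,
                         variants_per_gene = 3, maf_range = c(0.1, 0.3), seed = 4)
  fit <- skat_o(sim$dataset, 1)
  expect_equal(diff(range(fit$p_rho)), 0)
  expect_equal(fit$p_value, fit$p_rho[1])
  expect_equal(diff(range(fit$q_rho)), 0)
})

test_that("SKAT-O analytic p agrees with label permutation on small instances", {
  # 60-sample instances carry only common variants, so the cross-check runs
  # unweighted (the rare-variant weighting is exercised by the calibration
  # and power tests); the discrete permutation null is summarised by its
  # mid-p, the standard convention against a continuous approximation
  diffs <- vapply(1:3, function(sd) {
    sim <- simulate_cohort(n_cases = 30, n_controls = 30, n_genes = 1,
                           variants_per_gene = 5, maf_range = c(0.1, 0.4),
                           seed = sd)
    fit <- skat_o(sim$dataset, 1:5, weights = rep(1, 5),
                  n_permutations = 2e4, perm_seed = 8)
    abs(fit$p_value - fit$permutation_midp)
  }, numeric(1))
  expect_lte(mean(diffs), 0.02)
})

test_that("statistics are invariant under sample relabeling", {
  sim <- simulate_cohort(n_cases = 80, n_controls = 120, n_genes = 1,
                         variants_per_gene = 6, seed = 13)
  ds <- sim$dataset
  perm <- withr::with_seed(3, sample.int(nrow(ds$dosage)))
  ds2 <- cohort_dataset(ds$dosage[perm, ], ds$phenotype[perm],
                        ds$ancestry_fraction[perm], ds$annotations)
  f1 <- skat_o(ds, 1:6)
  f2 <- skat_o(ds2, 1:6)
  expect_equal(f1$q_skat, f2$q_skat)
  expect_equal(f1$q_burden, f2$q_burden)
  expect_equal(f1$p_value, f2$p_value)
})

test_that("carrier enrichment reports group frequencies, fold and Fisher p", {
  sim <- simulate_cohort(n_cases = 130, n_controls = 861, n_genes = 1,
                         variants_per_gene = 3, seed = 6)
  sim <- plant_carriers(sim, "G001", n_case_carriers = 13, n_control_carriers = 29)
  enr <- carrier_enrichment(sim$dataset, 1:3)
  expect_equal(enr$freq_cases, 13 / 130)           # 10%
  expect_equal(enr$freq_controls, 29 / 861)        # prints as 3.4%
  expect_equal(round(enr$fold), 3)
  expect_lt(enr$fisher_p, 0.05)
  # zero carriers anywhere: frequencies 0, fold undefined
  empty <- plant_carriers(sim, "G001", 0, 0)
  enr0 <- carrier_enrichment(empty$dataset, 1:3)
  expect_equal(enr0$freq_cases, 0)
  expect_true(is.na(enr0$fold))
})

test_that("ancestry subsetting is strictly above the threshold", {
  ds <- cohort_dataset(matrix(0:5, nrow = 3,
                              dimnames = list(c("a", "b", "c"), NULL)),
                       c("case", "case", "control"),
                       ancestry_fraction = c(0.85, 0.80, 0.79))
  expect_error(ancestry_subset(ds), "control")  # 0.80 and 0.79 drop -> no controls
  ds2 <- cohort_dataset(matrix(0:5, nrow = 3), c("case", "control", "control"),
                        ancestry_fraction = c(0.85, 0.9, 1))
  expect_equal(nrow(ancestry_subset(ds2)$dosage), 3)  # all above: identity
  ds3 <- cohort_dataset(matrix(0:5, nrow = 3), c("case", "case", "control"))
  expect_error(ancestry_subset(ds3), "ancestry")
})

test_that("the Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("missing dosages are mean-imputed per variant", {
  G <- matrix(c(0, 1, NA, 2, NA, NA, 0, 0), nrow = 4)
  Gi <- impute_dosage(G)
  expect_equal(Gi[3, 1], mean(c(0, 1, 2)))
  expect_equal(Gi[1:2, 2], c(0, 0))
  expect_false(anyNA(Gi))
})

test_that("tidy and glance expose the fitted grid and summary", {
  sim <- simulate_cohort(n_cases = 60, n_controls = 60, n_genes = 1,
                         variants_per_gene = 4, seed = 2)
  fit <- skat_o(sim$dataset, 1:4)
  td <- tidy(fit)
  expect_equal(names(td), c("rho", "q", "p"))
  expect_equal(nrow(td), 8)
  gl <- glance(fit)
  expect_equal(gl$n_variants, 4)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})

test_that("a cohort dataset can be built from a tidy genotype table", {
  gt <- dplyr::bind_rows(
    cohort_gt_tbl(c(0, 1, 2, 0), pos = 100L),
    cohort_gt_tbl(c(1, 0, NA, 2), pos = 200L)
  )
  pheno <- tibble::tibble(sample = sprintf("S%03d", 1:4),
                          phenotype = c("case", "case", "control", "control"),
                          ancestry_fraction = c(0.9, 0.95, 0.85, 0.99))
  ds <- cohort_from_genotypes(gt, pheno)
  expect_equal(dim(ds$dosage), c(4L, 2L))
  expect_equal(unname(ds$dosage["S003", ]), c(2, NA))
  expect_equal(ds$phenotype, pheno$phenotype)
  expect_error(cohort_from_genotypes(gt, pheno[-1, ]), "S001")
})
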