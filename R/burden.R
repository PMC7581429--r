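#' Beta-density variant weights
#'
#' The standard rare-variant weighting: variant j receives
#' `dbeta(maf_j, a, b)`. With the defaults (a = 1, b = 25) the density is
#' `b (1 - maf)^(b-1)`, strictly decreasing in the minor-allele frequency,
#' so the rarest variants carry the most weight; (1, 1) gives uniform
#' weights.
#'
#' @param mafs Observed minor-allele frequencies in \[0, 1\] (analysis code
#'   passes minor-allele-oriented values in \[0, 0.5\]).
#' @param beta_a,beta_b Beta density shape parameters, both positive.
#' @return Numeric weight vector.
#' @export
beta_weights <- function(mafs, beta_a = 1, beta_b = 25) {
  stopifnot(beta_a > 0, beta_b > 0)
  if (any(mafs < 0 | mafs > 1)) stop("MAF outside [0, 1]", call. = FALSE)
  stats::dbeta(mafs, beta_a, beta_b)
}

#' Case-control cohort container
#'
#' @param dosage Samples-by-variants matrix of alternate-allele dosages
#'   (0/1/2, `NA` missing), with sample and variant-key dimnames.
#' @param phenotype Character vector (`"case"`/`"control"`), one per sample.
#' @param ancestry_fraction Optional numeric in \[0, 1\] per sample.
#' @param annotations Annotation tibble covering the variant columns.
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(dosage, phenotype, ancestry_fraction = NULL,
                           annotations = NULL) {
  stopifnot(is.matrix(dosage), length(phenotype) == nrow(dosage))
  if (!all(phenotype %in% c("case", "control"))) {
    stop("phenotype must be 'case'/'control'", call. = FALSE)
  }
  if (!any(phenotype == "case") || !any(phenotype == "control")) {
    stop("Both cases and controls must be present", call. = FALSE)
  }
  if (!is.null(ancestry_fraction)) {
    stopifnot(length(ancestry_fraction) == nrow(dosage),
              all(ancestry_fraction >= 0 & ancestry_fraction <= 1, na.rm = TRUE))
  }
  structure(list(dosage = dosage, phenotype = phenotype,
                 ancestry_fraction = ancestry_fraction,
                 annotations = annotations),
            class = "cohort_dataset")
}

#' Build a cohort dataset from a tidy genotype table
#'
#' Pivots a [read_vcf()]-style genotype tibble (after any QC masking) into
#' the samples-by-variants dosage matrix of a [cohort_dataset()], joining a
#' per-sample phenotype table.
#'
#' @param gt_tbl Tidy genotype tibble.
#' @param phenotype_tbl Tibble with columns `sample`, `phenotype`
#'   (`"case"`/`"control"`) and optionally `ancestry_fraction`.
#' @param annotations Optional annotation tibble for the variants.
#' @return A [cohort_dataset()].
#' @export
cohort_from_genotypes <- function(gt_tbl, phenotype_tbl, annotations = NULL) {
  wide <- gt_tbl |>
    dplyr::select("variant_key", "sample", "dosage") |>
    tidyr::pivot_wider(names_from = "variant_key", values_from = "dosage")
  idx <- match(wide$sample, phenotype_tbl$sample)
  if (anyNA(idx)) {
    stop("Phenotype missing for sample(s): ",
         paste(wide$sample[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  G <- as.matrix(wide[, -1])
  rownames(G) <- wide$sample
  af <- if ("ancestry_fraction" %in% names(phenotype_tbl)) {
    phenotype_tbl$ancestry_fraction[idx]
  } else NULL
  cohort_dataset(G, phenotype_tbl$phenotype[idx], af, annotations)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Cohort:", sum(x$phenotype == "case"), "cases /",
      sum(x$phenotype == "control"), "controls;",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Subset a cohort by ancestry fraction
#'
#' Retains samples whose ancestry fraction is strictly above
#' `min_fraction` (default 0.80, the Caucasian-subset rule).
#'
#' @param dataset A [cohort_dataset()].
#' @param min_fraction Strict lower bound.
#' @return A filtered `cohort_dataset`.
#' @export
ancestry_subset <- function(dataset, min_fraction = 0.80) {
  if (is.null(dataset$ancestry_fraction)) {
    stop("Dataset has no ancestry_fraction column", call. = FALSE)
  }
  keep <- dataset$ancestry_fraction > min_fraction
  cohort_dataset(dataset$dosage[keep, , drop = FALSE],
                 dataset$phenotype[keep],
                 dataset$ancestry_fraction[keep],
                 dataset$annotations)
}

#' Fit the null disease model
#'
#' Logistic regression of case status on the covariates (intercept-only by
#' default; the burden analysis of the motivating design used none).
#' Returns the fitted case probabilities, residuals and the variance terms
#' needed by the score statistics.
#'
#' @param dataset A [cohort_dataset()].
#' @param covariates Optional numeric matrix of per-sample covariates.
#' @return Object of class `burden_null`: list with `y`, `mu`, `residuals`,
#'   `v` (mu(1-mu)), and the design matrix `X`.
#' @export
null_model <- function(dataset, covariates = NULL) {
  y <- as.integer(dataset$phenotype == "case")
  if (length(unique(y)) < 2) stop("Phenotype is constant", call. = FALSE)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- fit$fitted.values
  structure(list(y = y, mu = mu, residuals = y - mu, v = mu * (1 - mu), X = X),
            class = "burden_null")
}

#' Per-variant mean imputation of missing dosages
#'
#' @param G Dosage matrix.
#' @return The matrix with each variant's missing entries replaced by its
#'   observed mean dosage (0 for an all-missing variant).
#' @export
impute_dosage <- function(G) {
  mis <- is.na(G)
  if (!any(mis)) return(G)
  means <- colMeans(G, na.rm = TRUE)
  means[is.nan(means)] <- 0
  idx <- which(mis, arr.ind = TRUE)
  G[mis] <- means[idx[, 2]]
  G
}

#' Observed minor-allele frequency per variant
#'
#' @param G Dosage matrix (alternate-allele counts).
#' @return Minor-allele-oriented frequencies in \[0, 0.5\].
#' @export
observed_maf <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' SKAT variance-component statistic
#'
#' `Q = r' G W^2 G' r` with `r` the null-model residual vector, `G` the
#' (masked, mean-imputed) dosage matrix and `W = diag(weights)`; this is the
#' rho = 0 component of the optimal combined test.
#'
#' @param G Dosage matrix (samples x variants) after masking.
#' @param weights Per-variant weights.
#' @param null_fit A [null_model()] fit.
#' @return Non-negative scalar Q.
#' @export
skat_statistic <- function(G, weights, null_fit) {
  if (is.null(dim(G)) || ncol(G) == 0) stop("no qualifying variants", call. = FALSE)
  G <- impute_dosage(G)
  s <- crossprod(G, null_fit$residuals) * weights   # weighted scores
  sum(s^2)
}

#' Weighted burden statistic
#'
#' `Q = (sum_j w_j g_j' r)^2`, the rho = 1 component of the optimal test.
#'
#' @inheritParams skat_statistic
#' @return Non-negative scalar Q.
#' @export
burden_statistic <- function(G, weights, null_fit) {
  if (is.null(dim(G)) || ncol(G) == 0) stop("no qualifying variants", call. = FALSE)
  G <- impute_dosage(G)
  s <- crossprod(G, null_fit$residuals) * weights
  sum(s)^2
}

#' Tail probability of a weighted chi-square mixture
#'
#' `P(sum_k lambda_k X_k > q)` with independent 1-df chi-squares, the null
#' distribution of the variance-component statistics. Exact closed forms are
#' used when all eigenvalues are equal (a scaled chi-square); otherwise the
#' characteristic function is inverted numerically (Imhof's integral), with
#' a moment-matching fallback (Liu-type, matching mean, variance and
#' kurtosis) when the integration misbehaves and an optional seeded
#' Monte-Carlo fallback.
#'
#' @param q Observed statistic (non-negative).
#' @param eigenvalues Non-negative mixture weights, not all zero.
#' @param method `"auto"` (closed form / Imhof with Liu fallback),
#'   `"liu"`, or `"montecarlo"`.
#' @param mc_draws,mc_seed Monte-Carlo sample size and seed for
#'   `method = "montecarlo"`.
#' @return Tail probability in \[0, 1\].
#' @export
quadform_pvalue <- function(q, eigenvalues, method = c("auto", "liu", "montecarlo"),
                            mc_draws = 1e6, mc_seed = 1L) {
  method <- match.arg(method)
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  lambda <- eigenvalues[eigenvalues > 0]
  if (length(lambda) == 0) stop("eigenvalues must not all be zero", call. = FALSE)
  if (method == "montecarlo") {
    return(withr::with_seed(mc_seed, {
      draws <- colSums(lambda * matrix(stats::rchisq(length(lambda) * mc_draws, df = 1),
                                       nrow = length(lambda)))
      mean(draws > q)
    }))
  }
  if (method == "liu") return(liu_pvalue(q, lambda))
  # exact reduction: k equal eigenvalues => scaled chi-square with k df
  if (diff(range(lambda)) <= 1e-12 * max(lambda)) {
    return(stats::pchisq(q / lambda[1], df = length(lambda), lower.tail = FALSE))
  }
  p <- tryCatch(imhof_pvalue(q, lambda), error = function(e) NA_real_)
  if (is.na(p)) p <- liu_pvalue(q, lambda)
  # the inversion integral resolves absolute error ~1e-9; deeper tails come
  # from the saddlepoint approximation, accurate in relative terms
  if (p < 1e-7) p <- saddlepoint_pvalue(q, lambda)
  min(max(p, 0), 1)
}

# Imhof (1961) characteristic-function inversion,
# P(Q > q) = 1/2 + (1/pi) * int_0^Inf sin(theta(u)) / (u rho(u)) du,
# evaluated by composite Simpson on a fixed grid. The step resolves the
# oscillation (|theta'| <= (q + sum lambda)/2); the truncation point U comes
# from an integration-by-parts envelope bound ~ 4 env(U) / q.
imhof_pvalue <- function(q, lambda, eps = 1e-8) {
  sl <- sum(lambda)
  env <- function(u) 1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  U <- 2 / max(lambda)
  while (4 * env(U) / (max(q, 0.1 * sl) * pi) > eps && U < 1e7) U <- U * 1.4
  h <- pi / (16 * (q + sl))
  n <- ceiling(U / h)
  if (n > 8e6) stop("integration grid too large")
  if (n %% 2 == 1) n <- n + 1
  # Simpson weights over f(0), f(h), ..., f(nh); f(0) is the analytic limit
  f0 <- (sl - q) / 2
  total <- f0
  blk <- max(1, floor(2e6 / length(lambda)))
  i <- 1L
  while (i <= n) {
    j <- seq(i, min(i + blk - 1L, n))
    u <- j * h
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    f <- sin(theta) / (u * rho)
    w <- ifelse(j %% 2L == 1L, 4, 2)
    w[j == n] <- 1
    total <- total + sum(w * f)
    i <- i + blk
  }
  0.5 + (total * h / 3) / pi
}

# Lugannani-Rice saddlepoint tail approximation (excellent relative accuracy
# deep in the tail, where the inversion integral loses absolute precision)
saddlepoint_pvalue <- function(q, lambda) {
  if (q <= sum(lambda)) return(liu_pvalue(q, lambda))
  kprime <- function(s) sum(lambda / (1 - 2 * s * lambda))
  upper <- 1 / (2 * max(lambda))
  shat <- stats::uniroot(function(s) kprime(s) - q,
                         lower = 0, upper = upper * (1 - 1e-12),
                         tol = 1e-14)$root
  K <- -0.5 * sum(log1p(-2 * shat * lambda))
  K2 <- 2 * sum(lambda^2 / (1 - 2 * shat * lambda)^2)
  w <- sqrt(2 * (shat * q - K))
  v <- shat * sqrt(K2)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Liu-Tang-Zhang moment matching (mean/variance/kurtosis) to a
# (non)central chi-square.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_x <- l + d
  sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = d, lower.tail = FALSE)
}

# Liu-type quantile of a mixture at upper-tail probability p.
liu_quantile <- function(p_upper, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_x <- l + d
  sigma_x <- sqrt(2) * a
  q_x <- stats::qchisq(p_upper, df = l, ncp = d, lower.tail = FALSE)
  (q_x - mu_x) / sigma_x * sqrt(2 * c2) + c1
}

# Projected, variance-scaled genotype matrix whose Gram matrix gives the
# null covariance of the weighted score vector.
score_covariance_root <- function(G, weights, null_fit) {
  Z <- sweep(G, 2, weights, `*`)
  V <- null_fit$v
  X <- null_fit$X
  VX <- V * X
  XtVX_inv <- solve(crossprod(X, VX))
  # Z1 = V^{1/2} (I - X (X'VX)^{-1} X' V) Z
  adj <- X %*% (XtVX_inv %*% crossprod(VX, Z))
  sqrt(V) * (Z - adj)
}

#' Optimal combined burden / variance-component test (SKAT-O)
#'
#' Computes `Q(rho) = (1 - rho) Q_skat + rho Q_burden` over a grid of
#' mixing values, obtains each analytic p-value from the tail of the
#' rho-adjusted weighted chi-square mixture, and combines them through the
#' minimum-p statistic with the standard one-dimensional integration over
#' the common (burden-direction) chi-square component. Optionally also
#' reports a phenotype-label permutation p-value for the same minimum-p
#' statistic.
#'
#' @param dataset A [cohort_dataset()].
#' @param mask Logical or integer index of the variants to test.
#' @param weights Per-variant weights for the masked variants; defaults to
#'   beta(1, 25) of the observed cohort MAF.
#' @param null_fit A [null_model()] fit; defaults to intercept-only.
#' @param rho_grid Mixing grid in \[0, 1\], containing 0 and 1.
#' @param n_permutations Number of phenotype-label permutations (0 = none).
#' @param perm_seed Seed for the permutation path.
#' @return Object of class `skato_fit`.
#' @export
skat_o <- function(dataset, mask, weights = NULL, null_fit = NULL,
                   rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1),
                   n_permutations = 0, perm_seed = 1L) {
  G <- dataset$dosage[, mask, drop = FALSE]
  if (ncol(G) == 0) stop("no qualifying variants", call. = FALSE)
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1), 0 %in% rho_grid, 1 %in% rho_grid)
  G <- impute_dosage(G)
  if (is.null(null_fit)) null_fit <- null_model(dataset)
  if (is.null(weights)) weights <- beta_weights(observed_maf(G))
  m <- ncol(G)
  q_skat <- skat_statistic(G, weights, null_fit)
  q_burden <- burden_statistic(G, weights, null_fit)

  Z1 <- score_covariance_root(G, weights, null_fit)
  lambda_by_rho <- lapply(rho_grid, function(rho) rho_eigenvalues(Z1, rho))
  q_rho <- (1 - rho_grid) * q_skat + rho_grid * q_burden
  p_rho <- vapply(seq_along(rho_grid), function(i) {
    quadform_pvalue(q_rho[i], lambda_by_rho[[i]])
  }, numeric(1))
  t_min <- min(p_rho)
  rho_opt <- rho_grid[which.min(p_rho)]
  p_value <- if (m == 1) {
    # single variant: Q(rho) is rho-invariant and the test reduces to the
    # score test
    p_rho[1]
  } else {
    skato_combined_pvalue(t_min, Z1, rho_grid, lambda_by_rho)
  }

  perm_p <- perm_midp <- NA_real_
  if (n_permutations > 0) {
    pp <- skato_permutation_pvalue(G, weights, null_fit, rho_grid,
                                   lambda_by_rho, t_min,
                                   n_permutations, perm_seed)
    perm_p <- pp$p
    perm_midp <- pp$midp
  }

  carriers <- carrier_enrichment(dataset, mask)
  structure(list(
    n_variants = m, q_skat = q_skat, q_burden = q_burden,
    rho_grid = rho_grid, q_rho = q_rho, p_rho = p_rho,
    rho_optimal = rho_opt, min_p = t_min, p_value = p_value,
    permutation_p = perm_p, permutation_midp = perm_midp,
    carrier_freq_cases = carriers$freq_cases,
    carrier_freq_controls = carriers$freq_controls
  ), class = "skato_fit")
}

# Eigenvalues of R_rho^{1/2} (Z1'Z1) R_rho^{1/2} where
# R_rho = (1-rho) I + rho 11'; R^{1/2} = a I + b 11' in closed form.
rho_eigenvalues <- function(Z1, rho) {
  m <- ncol(Z1)
  K <- crossprod(Z1)
  if (m == 1) return(as.numeric(K))
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  Rh <- diag(a, m) + matrix(b, m, m)
  A <- Rh %*% K %*% Rh
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

# Minimum-p combination: decompose the score vector into the common
# burden direction and its orthogonal complement, then integrate the
# conditional acceptance probability over the 1-df chi-square of the
# common component.
skato_combined_pvalue <- function(t_min, Z1, rho_grid, lambda_by_rho) {
  m <- ncol(Z1)
  z_mean <- rowMeans(Z1)
  zmz <- sum(z_mean^2)
  if (zmz < .Machine$double.eps) {
    # degenerate common direction: fall back to a Bonferroni bound
    return(min(1, t_min * length(rho_grid)))
  }
  cof <- as.numeric(crossprod(z_mean, Z1)) / zmz
  Z_common <- outer(z_mean, cof)
  Z_resid <- Z1 - Z_common
  K_resid <- crossprod(Z_resid)
  lambda <- eigen(K_resid, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 1) * 1e-10]
  mu_q <- sum(lambda)
  var_zeta <- 4 * sum(crossprod(Z_common) * K_resid)
  var_q <- 2 * sum(lambda^2) + var_zeta
  tau <- (m^2 * rho_grid + (1 - rho_grid) * sum(cof^2)) * zmz
  rho_cap <- pmin(rho_grid, 0.999)
  q_min <- vapply(seq_along(rho_grid), function(i) {
    mixture_quantile(t_min, lambda_by_rho[[i]])
  }, numeric(1))

  # acceptance probability conditional on the common chi-square component x
  accept_prob <- function(xi) {
    delta <- min((q_min - tau * xi) / (1 - rho_cap))
    if (length(lambda) == 0) return(as.numeric(delta > 0))
    if (delta <= 0) return(0)
    # mean/variance adjustment for the unmodelled mixed term zeta; the
    # conditional tail uses the fast moment-matching form
    dadj <- (delta - mu_q) * sqrt(var_q - var_zeta) / sqrt(var_q) + mu_q
    if (dadj <= 0) 0 else 1 - liu_pvalue(dadj, lambda)
  }
  # substitute x = y^2: dchisq(x, 1) dx = 2 dnorm(y) dy, removing the 1/sqrt(x)
  # endpoint singularity; the integrand has support x < min(q_min / tau)
  x_max <- min(q_min / pmax(tau, .Machine$double.xmin))
  upper_y <- sqrt(min(max(x_max, 0), 1600))
  integrand_y <- function(y) {
    vapply(y, function(yi) accept_prob(yi^2) * 2 * stats::dnorm(yi), numeric(1))
  }
  int <- if (upper_y <= 0) 0 else tryCatch(
    stats::integrate(integrand_y, lower = 0, upper = upper_y,
                     subdivisions = 1000L, rel.tol = 1e-6, abs.tol = 1e-10)$value,
    error = function(e) NA_real_)
  p <- if (is.na(int)) NA_real_ else 1 - int
  if (is.na(p)) p <- min(1, t_min * length(rho_grid))
  # the minimum-p statistic bounds its own p-value on both sides
  min(max(p, t_min), min(1, t_min * length(rho_grid)))
}

# quantile of a chi-square mixture at upper-tail probability t: moment-matched
# starting value refined by secant steps on the accurate tail function
mixture_quantile <- function(t, lambda) {
  q0 <- max(liu_quantile(t, lambda), .Machine$double.eps)
  p0 <- quadform_pvalue(q0, lambda)
  if (abs(p0 - t) <= 0.002 * t) return(q0)
  q1 <- q0 * ifelse(p0 > t, 1.15, 0.85)
  p1 <- quadform_pvalue(q1, lambda)
  for (it in 1:6) {
    if (abs(p1 - t) <= 0.002 * t || abs(log(p1) - log(p0)) < 1e-12) break
    q2 <- exp(log(q1) + (log(t) - log(p1)) * (log(q1) - log(q0)) /
                (log(p1) - log(p0)))
    q0 <- q1; p0 <- p1
    q1 <- max(q2, .Machine$double.xmin)
    p1 <- quadform_pvalue(q1, lambda)
  }
  q1
}

# Permutation p of the minimum-p statistic: phenotype labels are permuted
# (equivalently, the fixed residual values are reassigned to samples) and
# the per-rho tail transforms — the moment-matching form, identical for the
# observed and the permuted statistics, monotone in Q per rho — convert each
# Q(rho) to a p before taking the minimum. Eigenvalue sets do not depend on
# the labels, so everything vectorizes over permutations.
skato_permutation_pvalue <- function(G, weights, null_fit, rho_grid,
                                     lambda_by_rho, t_obs, n_permutations,
                                     perm_seed) {
  n <- nrow(G)
  Z <- sweep(G, 2, weights, `*`)
  s_obs <- as.numeric(crossprod(Z, null_fit$residuals))
  q_obs <- (1 - rho_grid) * sum(s_obs^2) + rho_grid * sum(s_obs)^2
  withr::with_seed(perm_seed, {
    R <- vapply(seq_len(n_permutations),
                function(b) null_fit$residuals[sample.int(n)],
                numeric(n))
    S <- crossprod(Z, R)                      # m x B weighted score vectors
    qS <- colSums(S^2)
    qB <- colSums(S)^2
    p_perm <- matrix(NA_real_, n_permutations, length(rho_grid))
    p_obs <- numeric(length(rho_grid))
    for (i in seq_along(rho_grid)) {
      lam <- lambda_by_rho[[i]]
      q_all <- c(q_obs[i], (1 - rho_grid[i]) * qS + rho_grid[i] * qB)
      pv <- liu_pvalue_vec(q_all, lam)
      p_obs[i] <- pv[1]
      p_perm[, i] <- pv[-1]
    }
    t_perm <- do.call(pmin, as.data.frame(p_perm))
    t_o <- min(p_obs)
    # inclusive (+1) convention for inference; mid-p (atoms split evenly)
    # for comparing the discrete permutation null against a continuous
    # analytic approximation
    list(p = (sum(t_perm <= t_o) + 1) / (n_permutations + 1),
         midp = mean(t_perm < t_o - 1e-12) +
           0.5 * mean(abs(t_perm - t_o) <= 1e-12))
  })
}

# vectorized-over-q version of the moment-matching tail
liu_pvalue_vec <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * (sqrt(2) * a) + l + d, df = l, ncp = d, lower.tail = FALSE)
}

#' Carrier enrichment between cases and controls
#'
#' A carrier holds at least one alternate allele across the masked
#' variants. Reports the carrier frequency per phenotype group, the
#' case/control fold enrichment (`NA` when no control carriers) and a
#' two-sided Fisher exact p-value on the 2x2 carrier table — supplementary
#' to, and distinct from, the SKAT-O association p-value.
#'
#' @param dataset A [cohort_dataset()].
#' @param mask Logical or integer variant index.
#' @return List with `freq_cases`, `freq_controls`, `fold`, `fisher_p`,
#'   `n_carriers_cases`, `n_carriers_controls`.
#' @export
carrier_enrichment <- function(dataset, mask) {
  G <- dataset$dosage[, mask, drop = FALSE]
  if (ncol(G) == 0) stop("no qualifying variants", call. = FALSE)
  carrier <- rowSums(G >= 1, na.rm = TRUE) > 0
  case <- dataset$phenotype == "case"
  fc <- mean(carrier[case])
  fn <- mean(carrier[!case])
  tab <- matrix(c(sum(carrier & case), sum(!carrier & case),
                  sum(carrier & !case), sum(!carrier & !case)), nrow = 2)
  list(freq_cases = fc, freq_controls = fn,
       fold = if (fn > 0) fc / fn else NA_real_,
       fisher_p = stats::fisher.test(tab)$p.value,
       n_carriers_cases = sum(carrier & case),
       n_carriers_controls = sum(carrier & !case))
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests` (0.05 over 2 genes gives 0.025).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' @export
print.skato_fit <- function(x, ...) {
  cat("SKAT-O:", x$n_variants, "variant(s); p =", format(x$p_value, digits = 4),
      "(rho* =", x$rho_optimal, ")\n")
  cat("  carriers: cases", sprintf("%.1f%%", 100 * x$carrier_freq_cases),
      "vs controls", sprintf("%.1f%%", 100 * x$carrier_freq_controls), "\n")
  invisible(x)
}

#' Tidy the per-rho grid of a SKAT-O fit
#'
#' @param x A `skato_fit`.
#' @param ... Unused.
#' @return Tibble with `rho`, `q`, `p`.
#' @method tidy skato_fit
#' @export
tidy.skato_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho_grid, q = x$q_rho, p = x$p_rho)
}

#' One-row summary of a SKAT-O fit
#'
#' @param x A `skato_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance skato_fit
#' @export
glance.skato_fit <- function(x, ...) {
  tibble::tibble(n_variants = x$n_variants, q_skat = x$q_skat,
                 q_burden = x$q_burden, rho_optimal = x$rho_optimal,
                 p_value = x$p_value, permutation_p = x$permutation_p,
                 carrier_freq_cases = x$carrier_freq_cases,
                 carrier_freq_controls = x$carrier_freq_controls)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
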