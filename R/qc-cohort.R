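#' Cohort site-QC configuration
#'
#' Thresholds for case-control cohort site quality control: genotypes with
#' genotype quality below 20 are masked to missing, sites with call rate
#' below 0.95 or a Hardy-Weinberg exact p-value below 1e-8 are excluded,
#' and sites must carry a PASS FILTER label (variant quality score
#' recalibration is consumed as that label, never refit).
#'
#' @param min_gq Genotype-quality mask threshold; calls with GQ strictly
#'   below it are set missing.
#' @param min_call_rate Minimum fraction of non-missing calls (exclusion is
#'   strictly below the threshold).
#' @param min_hwe_p Minimum Hardy-Weinberg exact p-value (exclusion is
#'   strictly below).
#' @param require_pass_filter Require FILTER == "PASS".
#' @param hwe_samples Compute the HWE test on `"all"` samples or
#'   `"controls"` only.
#' @return A list of class `cohort_qc_config`.
#' @export
cohort_qc_config <- function(min_gq = 20, min_call_rate = 0.95,
                             min_hwe_p = 1e-8, require_pass_filter = TRUE,
                             hwe_samples = c("all", "controls")) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            min_hwe_p > 0, min_hwe_p < 1)
  structure(list(min_gq = min_gq, min_call_rate = min_call_rate,
                 min_hwe_p = min_hwe_p,
                 require_pass_filter = require_pass_filter,
                 hwe_samples = match.arg(hwe_samples)),
            class = "cohort_qc_config")
}

#' Mask low-quality genotypes to missing
#'
#' Sets calls with genotype quality strictly below `min_gq` to missing
#' (dosage and allele columns `NA`). Idempotent: masking a masked table is a
#' no-op.
#'
#' @param gt_tbl Tidy genotype tibble.
#' @param config A [cohort_qc_config()].
#' @return The genotype tibble with low-GQ calls set missing.
#' @export
gq_mask <- function(gt_tbl, config = cohort_qc_config()) {
  low <- !gt_tbl$missing &
    (ifelse(gt_tbl$gq_missing, TRUE, gt_tbl$gq < config$min_gq))
  gt_tbl$allele1[low] <- NA_integer_
  gt_tbl$allele2[low] <- NA_integer_
  gt_tbl$dosage[low] <- NA_integer_
  gt_tbl$missing[low] <- TRUE
  gt_tbl
}

#' Per-site call rate after GQ masking
#'
#' @param gt_tbl Tidy genotype tibble (GQ masking is applied first).
#' @param config A [cohort_qc_config()].
#' @return Tibble with `variant_key` and `call_rate` = non-missing / total.
#' @export
site_call_rate <- function(gt_tbl, config = cohort_qc_config()) {
  if (nrow(gt_tbl) == 0) stop("No samples: cannot compute a call rate", call. = FALSE)
  gq_mask(gt_tbl, config) |>
    dplyr::group_by(.data$variant_key) |>
    dplyr::summarise(call_rate = mean(!.data$missing), .groups = "drop")
}

#' Hardy-Weinberg exact test p-value
#'
#' Two-sided conditional exact test: conditioning on the observed allele
#' counts, the p-value is the sum of probabilities of all heterozygote
#' counts no more probable than the observed one. Probabilities are built by
#' the standard recurrence from the modal heterozygote count. A monomorphic
#' site has a single attainable configuration and p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @param method `"exact"` (default) or `"chisq"` for the 1-df chi-square
#'   approximation (no continuity correction), exposed for comparison.
#' @return p-value in \[0, 1\].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("All genotype counts are zero", call. = FALSE)
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2L * n - n_alt)
  if (n_minor == 0) return(1)
  if (method == "chisq") {
    p_alt <- n_alt / (2 * n)
    e <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
    o <- c(n_hom_ref, n_het, n_hom_alt)
    x2 <- sum((o - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # heterozygote counts compatible with the allele counts share the parity
  # of the minor-allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  # start from the modal het count and fill by the recurrence
  # P(h+2)/P(h) = 4 * n_rare_hom(h) * n_common_hom(h) / ((h+2)*(h+1))
  mode_h <- hets[which.min(abs(hets - round(n_alt * (2 * n - n_alt) / (2 * n))))]
  i_mode <- match(mode_h, hets)
  probs[i_mode] <- 1
  if (i_mode < length(hets)) {
    for (i in seq(i_mode, length(hets) - 1)) {
      h <- hets[i]
      rare_hom <- (n_minor - h) / 2
      common_hom <- n - h - rare_hom
      probs[i + 1] <- probs[i] * 4 * rare_hom * common_hom / ((h + 2) * (h + 1))
    }
  }
  if (i_mode > 1) {
    for (i in seq(i_mode, 2)) {
      h <- hets[i]
      rare_hom <- (n_minor - h) / 2
      common_hom <- n - h - rare_hom
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (rare_hom + 1) * (common_hom + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("Heterozygote count incompatible with allele counts", call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Genotype counts per site from a tidy genotype table
#'
#' Diploid calls only; hemizygous and missing calls are not counted.
#'
#' @param gt_tbl Tidy genotype tibble.
#' @return Tibble with `variant_key`, `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @export
genotype_counts <- function(gt_tbl) {
  gt_tbl |>
    dplyr::filter(!.data$missing, !.data$hemizygous) |>
    dplyr::group_by(.data$variant_key) |>
    dplyr::summarise(n_hom_ref = sum(.data$dosage == 0),
                     n_het = sum(.data$dosage == 1),
                     n_hom_alt = sum(.data$dosage == 2),
                     .groups = "drop")
}

#' Cohort site QC verdict
#'
#' Applies, in order: the PASS FILTER requirement, GQ masking, the
#' call-rate rule, and the Hardy-Weinberg exact test on the remaining
#' genotypes. The first failing rule is reported; the order is fixed so
#' verdicts are deterministic.
#'
#' @param gt_tbl Tidy genotype tibble for the cohort.
#' @param config A [cohort_qc_config()].
#' @param phenotype Optional named vector (`"case"`/`"control"` by sample)
#'   used when `hwe_samples = "controls"`.
#' @return Tibble with `variant_key`, `keep` (logical) and `reason`
#'   (`"filter"`, `"call_rate"`, `"hwe"` or `NA` when kept).
#' @export
cohort_site_qc <- function(gt_tbl, config = cohort_qc_config(), phenotype = NULL) {
  masked <- gq_mask(gt_tbl, config)
  site <- dplyr::distinct(masked, .data$variant_key, .data$filter)
  cr <- site_call_rate(gt_tbl, config)
  hwe_tbl <- masked
  if (config$hwe_samples == "controls") {
    if (is.null(phenotype)) stop("hwe_samples='controls' needs a phenotype vector", call. = FALSE)
    hwe_tbl <- masked[phenotype[masked$sample] == "control", ]
  }
  cnt <- genotype_counts(hwe_tbl)
  res <- site |>
    dplyr::left_join(cr, by = "variant_key") |>
    dplyr::left_join(cnt, by = "variant_key")
  res$hwe_p <- vapply(seq_len(nrow(res)), function(i) {
    if (is.na(res$n_hom_ref[i]) || res$n_hom_ref[i] + res$n_het[i] + res$n_hom_alt[i] == 0) {
      return(NA_real_)
    }
    hwe_exact_p(res$n_hom_ref[i], res$n_het[i], res$n_hom_alt[i])
  }, numeric(1))
  res |>
    dplyr::mutate(
      reason = dplyr::case_when(
        config$require_pass_filter & .data$filter != "PASS" ~ "filter",
        .data$call_rate < config$min_call_rate ~ "call_rate",
        !is.na(.data$hwe_p) & .data$hwe_p < config$min_hwe_p ~ "hwe",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    ) |>
    dplyr::select("variant_key", "keep", "reason", "call_rate", "hwe_p")
}
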