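#' Family-cascade QC configuration
#'
#' Thresholds for the family-quintet genotype/site quality rules: minimum
#' per-sample read depth (at least 10 reads), the maximal flanking
#' homopolymer run tolerated (runs exceeding five bases adjacent to the
#' variant fail), and the internal-cohort recurrence rule (seen in fewer
#' than 5 of 147 in-house exomes from individuals without the disease).
#'
#' @param min_depth Minimum read depth per evaluated sample (inclusive).
#' @param homopolymer_max_run Longest adjacent single-base run allowed;
#'   strictly longer runs fail the variant.
#' @param internal_cohort_max_count A variant must be seen in fewer than
#'   this many internal exomes (strict).
#' @param internal_cohort_size Size of the internal comparison cohort
#'   (documentation only).
#' @param missing_qc `"strict"` treats a missing DP/GQ field as failing the
#'   threshold; `"permissive"` treats it as passing.
#' @return A list of class `family_qc_config`.
#' @export
family_qc_config <- function(min_depth = 10, homopolymer_max_run = 5,
                             internal_cohort_max_count = 5,
                             internal_cohort_size = 147,
                             missing_qc = c("strict", "permissive")) {
  stopifnot(min_depth > 0, homopolymer_max_run > 0,
            internal_cohort_max_count > 0, internal_cohort_size > 0)
  missing_qc <- match.arg(missing_qc)
  structure(list(min_depth = min_depth,
                 homopolymer_max_run = homopolymer_max_run,
                 internal_cohort_max_count = internal_cohort_max_count,
                 internal_cohort_size = internal_cohort_size,
                 missing_qc = missing_qc),
            class = "family_qc_config")
}

#' Per-variant read-depth filter
#'
#' A variant passes when every listed sample has depth at or above the
#' configured minimum ("at least 10" is inclusive). An empty sample list
#' passes vacuously. In strict missing-QC mode a sample with an absent DP
#' field fails the threshold.
#'
#' @param gt_tbl Tidy genotype tibble from [read_vcf()].
#' @param samples Sample ids whose depth is checked.
#' @param config A [family_qc_config()].
#' @return Tibble with `variant_key` and logical `pass_depth`.
#' @export
depth_filter <- function(gt_tbl, samples, config = family_qc_config()) {
  if (length(samples) == 0) {
    return(tibble::tibble(variant_key = unique(gt_tbl$variant_key), pass_depth = TRUE))
  }
  gt_tbl |>
    dplyr::filter(.data$sample %in% samples) |>
    dplyr::mutate(depth_ok = dplyr::if_else(
      .data$depth_missing, config$missing_qc == "permissive",
      .data$depth >= config$min_depth)) |>
    dplyr::group_by(.data$variant_key) |>
    dplyr::summarise(pass_depth = all(.data$depth_ok), .groups = "drop")
}

#' Flag variants adjacent to a long homopolymer
#'
#' A variant fails (returns `TRUE`) when the maximal single-base run
#' starting at the base immediately left of its reference span, or
#' immediately right of it, exceeds `homopolymer_max_run` bases. The run
#' never includes the variant's own reference base(s): a run of exactly five
#' passes, six fails.
#'
#' @param sites Tibble with `variant_key`, `chrom`, `pos`, `ref` (one row
#'   per variant).
#' @param reference FASTA path or pre-loaded reference from
#'   [read_reference()].
#' @param config A [family_qc_config()].
#' @return Tibble with `variant_key` and logical `homopolymer_adjacent`.
#' @export
homopolymer_adjacent <- function(sites, reference, config = family_qc_config()) {
  seqs <- if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    read_reference(reference)
  } else reference
  window <- config$homopolymer_max_run + 2L
  sites <- dplyr::distinct(sites, .data$variant_key, .data$chrom, .data$pos, .data$ref)
  res <- vapply(seq_len(nrow(sites)), function(i) {
    fl <- fetch_flank(seqs, sites$chrom[i], sites$pos[i], window,
                      ref_len = nchar(sites$ref[i]))
    max(adjacent_run(fl$left, side = "left"),
        adjacent_run(fl$right, side = "right")) > config$homopolymer_max_run
  }, logical(1))
  tibble::tibble(variant_key = sites$variant_key, homopolymer_adjacent = res)
}

# Length of the single-base run anchored at the variant-adjacent end of a
# flank: the right end of the left flank, the left end of the right flank.
adjacent_run <- function(flank, side = c("left", "right")) {
  side <- match.arg(side)
  n <- nchar(flank)
  if (n == 0) return(0L)
  chars <- strsplit(flank, "")[[1]]
  if (side == "left") chars <- rev(chars)
  run <- 1L
  while (run < n && chars[run + 1L] == chars[1L]) run <- run + 1L
  run
}

#' Internal-cohort recurrence filter
#'
#' Passes variants observed in fewer than `internal_cohort_max_count`
#' datasets of the in-house comparison cohort (strict inequality).
#'
#' @param annotations Annotation tibble with `variant_key` and
#'   `internal_count`.
#' @param config A [family_qc_config()].
#' @return Tibble with `variant_key` and logical `pass_internal_cohort`.
#' @export
internal_cohort_filter <- function(annotations, config = family_qc_config()) {
  tibble::tibble(
    variant_key = annotations$variant_key,
    pass_internal_cohort = annotations$internal_count < config$internal_cohort_max_count
  )
}
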