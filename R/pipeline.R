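#' Run the full candidate-gene prioritization pipeline
#'
#' Orchestrates the family cascade end to end: reads the quintet VCF,
#' pedigree, annotation table, reference and the two differential-expression
#' tables, runs QC, rarity/function filtering and inheritance classification,
#' computes the concordant differential-expression gene sets at both
#' timepoints, and intersects. Final candidates are genes with an
#' inheritance call that are concordantly differentially expressed at both
#' timepoints.
#'
#' @param vcf,ped,annotations,reference,det_d0,det_d25 Input file paths
#'   (`reference` may be `NULL` to skip the homopolymer rule).
#' @param era Frequency era for the rarity policy (see [rarity_policy()]).
#' @param config A [family_qc_config()].
#' @param concordance A [concordance_config()].
#' @param proband_id Optional pedigree proband override.
#' @return Object of class `prioritize_result`: list with `candidates`
#'   (final call rows), `cascade` (the `cascade_result`), `det_d0`/`det_d25`
#'   gene sets and a `summary` tibble.
#' @export
run_prioritize <- function(vcf, ped, annotations, reference = NULL,
                           det_d0 = NULL, det_d25 = NULL,
                           era = c("study_initiation", "current"),
                           config = family_qc_config(),
                           concordance = concordance_config(),
                           proband_id = NULL) {
  era <- match.arg(era)
  for (p in c(vcf, ped, annotations, reference, det_d0, det_d25)) {
    if (!is.null(p) && !file.exists(p)) stop("Input file not found: ", p, call. = FALSE)
  }
  gt <- read_vcf(vcf)
  pedigree <- read_pedigree(ped, proband_id = proband_id)
  ann <- read_annotations(annotations)
  policy <- rarity_policy(frequency_era = era)
  cascade <- run_family_cascade(gt, pedigree, ann, reference = reference,
                                config = config, policy = policy)
  d0_set <- d25_set <- NULL
  candidates <- cascade$calls
  if (!is.null(det_d0) && !is.null(det_d25)) {
    d0_set <- concordant_dets(read_det_table(det_d0, "d0"), "d0", concordance)
    d25_set <- concordant_dets(read_det_table(det_d25, "d25"), "d25", concordance)
    candidates <- intersect_candidates(cascade$calls, d0_set, d25_set)
  }
  summary <- dplyr::bind_rows(
    cascade$summary,
    tibble::tibble(stage = "candidate_genes",
                   n_variants = length(unique(candidates$gene)))
  )
  structure(list(candidates = candidates, cascade = cascade,
                 det_d0 = d0_set, det_d25 = d25_set, summary = summary,
                 era = era),
            class = "prioritize_result")
}

#' @export
print.prioritize_result <- function(x, ...) {
  cat("Prioritization (", x$era, " frequencies): candidate_genes: ",
      length(unique(x$candidates$gene)), "\n", sep = "")
  if (nrow(x$candidates) > 0) {
    tab <- table(x$candidates$mode)
    cat("  modes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  genes:", paste(sort(unique(x$candidates$gene)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write prioritization outputs to disk
#'
#' Writes the candidate table (TSV), the per-variant audit table (TSV) and
#' a machine-readable summary (JSON).
#'
#' @param result A `prioritize_result`.
#' @param dir Output directory.
#' @return Invisible list of written paths.
#' @export
write_prioritize_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(candidates = file.path(dir, "candidates.tsv"),
                audit = file.path(dir, "audit.tsv"),
                summary = file.path(dir, "summary.json"))
  cand <- tidy(result$cascade)
  cand <- cand[cand$gene %in% result$candidates$gene, ]
  readr::write_tsv(cand, paths$candidates)
  readr::write_tsv(result$cascade$audit, paths$audit)
  jsonlite::write_json(
    list(candidate_genes = sort(unique(result$candidates$gene)),
         modes = as.list(table(result$candidates$mode)),
         stages = stats::setNames(as.list(result$summary$n_variants),
                                  result$summary$stage)),
    paths$summary, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Per-gene, per-category rare-variant burden scan
#'
#' Runs cohort site QC is assumed done upstream; for each requested gene
#' (and optionally each variant category) this selects qualifying variants
#' with [burden_variant_mask()], computes beta-weighted SKAT-O and carrier
#' enrichment, and reports the Bonferroni verdict at `alpha / n_tests`
#' (defaulting to the number of genes tested).
#'
#' @param dataset A [cohort_dataset()] with gene-annotated variants.
#' @param genes Genes to test (error when empty).
#' @param categories `NULL` for the default strict-impact mask, or a
#'   character vector of category names (see [burden_variant_mask()]).
#' @param policy A [burden_policy()].
#' @param weight_spec Length-2 numeric: beta density shape parameters.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param n_tests Number of tests for the threshold (default: genes x
#'   categories actually run).
#' @param relax_cadd Drop the CADD restriction (category runs).
#' @param rho_grid Mixing grid for [skat_o()].
#' @return A `burden_scan` tibble: one row per (gene, category) with
#'   `n_variants`, `p_value`, `rho_optimal`, carrier frequencies, Fisher p
#'   and `significant`; genes without qualifying variants keep a row with
#'   `n_variants = 0` and `NA` p.
#' @export
run_burden <- function(dataset, genes, categories = NULL,
                       policy = burden_policy(), weight_spec = c(1, 25),
                       alpha = 0.05, n_tests = NULL, relax_cadd = FALSE,
                       rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)) {
  if (length(genes) == 0) stop("Empty gene list", call. = FALSE)
  ann <- dataset$annotations
  if (is.null(ann)) stop("Dataset carries no variant annotations", call. = FALSE)
  cats <- if (is.null(categories)) NA_character_ else categories
  grid <- tidyr::expand_grid(gene = genes, category = cats)
  if (is.null(n_tests)) n_tests <- nrow(grid)
  thr <- bonferroni_threshold(alpha, n_tests)
  nf <- null_model(dataset)
  rows <- purrr::pmap_dfr(grid, function(gene, category) {
    cat_arg <- if (is.na(category)) NULL else category
    mask <- ann$gene == gene &
      burden_variant_mask(ann, policy, category = cat_arg, relax_cadd = relax_cadd)
    if (!any(mask)) {
      return(tibble::tibble(gene = gene,
                            category = ifelse(is.na(category), "default", category),
                            n_variants = 0L, p_value = NA_real_,
                            rho_optimal = NA_real_, q_skat = NA_real_,
                            q_burden = NA_real_, carrier_freq_cases = NA_real_,
                            carrier_freq_controls = NA_real_, fold = NA_real_,
                            fisher_p = NA_real_, significant = NA))
    }
    idx <- which(mask)
    G <- impute_dosage(dataset$dosage[, idx, drop = FALSE])
    w <- beta_weights(observed_maf(G), weight_spec[1], weight_spec[2])
    fit <- skat_o(dataset, idx, weights = w, null_fit = nf, rho_grid = rho_grid)
    enr <- carrier_enrichment(dataset, idx)
    tibble::tibble(gene = gene,
                   category = ifelse(is.na(category), "default", category),
                   n_variants = fit$n_variants, p_value = fit$p_value,
                   rho_optimal = fit$rho_optimal, q_skat = fit$q_skat,
                   q_burden = fit$q_burden,
                   carrier_freq_cases = enr$freq_cases,
                   carrier_freq_controls = enr$freq_controls,
                   fold = enr$fold, fisher_p = enr$fisher_p,
                   significant = fit$p_value < thr)
  })
  structure(rows, class = c("burden_scan", class(rows)),
            threshold = thr, alpha = alpha, n_tests = n_tests)
}

#' @export
print.burden_scan <- function(x, ...) {
  cat("Burden scan:", nrow(x), "test(s); significance threshold p <",
      format(attr(x, "threshold"), digits = 4),
      sprintf("(%g / %d tests)\n", attr(x, "alpha"), attr(x, "n_tests")))
  NextMethod()
}

#' Extract and write a first-neighbor subnetwork
#'
#' @param seeds Seed gene symbols.
#' @param edges_path Tab-separated edge list with columns `gene_a`,
#'   `gene_b` and optionally `type`.
#' @param dir Optional output directory for `nodes.tsv` / `edges.tsv`.
#' @return The [first_neighbor_network()] result.
#' @export
run_network <- function(seeds, edges_path, dir = NULL) {
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    stop("Edge list needs columns gene_a, gene_b", call. = FALSE)
  }
  net <- first_neighbor_network(seeds, edges)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(net$nodes, file.path(dir, "nodes.tsv"))
    readr::write_tsv(net$edges, file.path(dir, "edges.tsv"))
  }
  net
}
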