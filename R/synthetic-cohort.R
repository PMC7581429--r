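#' Simulate a random quintet with planted inheritance modes
#'
#' Builds an in-memory tidy genotype table (the schema of [read_vcf()]), a
#' matching annotation table and pedigree, with one planted configuration
#' per gene: `de_novo`, `homozygous_recessive`, `compound_heterozygous`,
#' `x_linked_recessive`, or one of three null configurations that must not
#' be called (`null_single_parent`: one paternal heterozygous variant;
#' `null_same_side`: two maternal variants, no paternal side;
#' `null_both_het`: a single variant heterozygous in both parents, which
#' cannot anchor a compound pair alone). Sibling genotypes are drawn
#' uniformly among the carrier states consistent with the planted call
#' (never reproducing the full causal configuration). Genotypes are
#' error-free; depth 30, GQ 99 throughout.
#'
#' @param modes Character vector, one planted mode per gene.
#' @param seed Integer seed.
#' @return List with `gt` (tidy genotype tibble), `annotations`, `pedigree`
#'   and `truth` (gene, planted mode).
#' @export
simulate_quintet <- function(modes, seed = 1L) {
  withr::with_seed(seed, {
    members <- tibble::tibble(
      sample_id = quintet_samples(),
      father_id = c(NA, NA, "I.1", "I.1", "I.1"),
      mother_id = c(NA, NA, "I.2", "I.2", "I.2"),
      sex = c("male", "female", "male", "female", "male"),
      affected = c("unaffected", "unaffected", "unaffected", "unaffected", "affected")
    )
    ped <- new_pedigree(members)
    genes <- sprintf("G%03d", seq_along(modes))
    rows <- list()
    x_offset <- 0L
    for (gi in seq_along(modes)) {
      mode <- modes[gi]
      gene <- genes[gi]
      two <- mode %in% c("compound_heterozygous", "null_same_side")
      n_var <- if (two) 2L else 1L
      chrom <- if (mode == "x_linked_recessive") "synX" else paste0("syn_", gene)
      if (mode == "x_linked_recessive") x_offset <- x_offset + 1L
      pos <- if (mode == "x_linked_recessive") 1000L + 500L * x_offset else 1001L
      pos <- pos + seq_len(n_var) * 10L
      for (vi in seq_len(n_var)) {
        g <- switch(mode,
          de_novo = c(fa = "0/0", mo = "0/0", pb = "0/1",
                      b = "0/0", s = "0/0"),
          homozygous_recessive = c(fa = "0/1", mo = "0/1", pb = "1/1",
                                   b = sample(c("0/0", "0/1"), 1),
                                   s = sample(c("0/0", "0/1"), 1)),
          compound_heterozygous = {
            side <- if (vi == 1) "maternal" else "paternal"
            # a sibling may carry variants of at most one side
            b_car <- sample(c(TRUE, FALSE), 1) && side == "paternal"
            s_car <- sample(c(TRUE, FALSE), 1) && side == "maternal"
            c(fa = if (side == "paternal") "0/1" else "0/0",
              mo = if (side == "maternal") "0/1" else "0/0",
              pb = "0/1",
              b = if (b_car) "0/1" else "0/0",
              s = if (s_car) "0/1" else "0/0")
          },
          x_linked_recessive = c(fa = "0", mo = "0/1", pb = "1",
                                 b = "0", s = sample(c("0/0", "0/1"), 1)),
          null_single_parent = c(fa = "0/1", mo = "0/0", pb = "0/1",
                                 b = "0/0", s = "0/0"),
          null_same_side = c(fa = "0/0", mo = "0/1", pb = "0/1",
                             b = "0/0", s = "0/0"),
          null_both_het = c(fa = "0/1", mo = "0/1", pb = "0/1",
                            b = "0/0", s = "0/0"),
          stop("unknown planted mode: ", mode)
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = chrom, pos = pos[vi], gene = gene,
          gt = list(c(`I.1` = unname(g["fa"]), `I.2` = unname(g["mo"]),
                      `II.1` = unname(g["b"]), `II.2` = unname(g["s"]),
                      `II.3` = unname(g["pb"])))
        )
      }
    }
    site <- dplyr::bind_rows(rows)
    site$ref <- sample(c("A", "C", "G", "T"), nrow(site), replace = TRUE)
    site$alt <- vapply(site$ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       character(1))
    gt_tbl <- tidy_gt_from_strings(site)
    ann <- tibble::tibble(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      gene = site$gene, transcript = NA_character_, consequence = "missense",
      maf_esp = 0.0001, maf_1kg = 0.0001, maf_gnomad = 0.0001,
      cadd = 25, internal_count = 0L, pli = NA_real_, regulatory = FALSE,
      variant_key = paste(site$chrom, site$pos, site$ref, site$alt, sep = ":")
    )
    list(gt = gt_tbl, annotations = ann, pedigree = ped,
         truth = tibble::tibble(gene = genes, mode = modes))
  })
}

# expand per-site GT string vectors into the tidy read_vcf() schema
tidy_gt_from_strings <- function(site, depth = 30, gq = 99) {
  samples <- names(site$gt[[1]])
  out <- tidyr::expand_grid(i = seq_len(nrow(site)), sample = samples)
  gts <- vapply(seq_len(nrow(out)), function(k) {
    site$gt[[out$i[k]]][[out$sample[k]]]
  }, character(1))
  parsed <- parse_gt(gts)
  tibble::tibble(
    chrom = site$chrom[out$i], pos = site$pos[out$i], id = ".",
    ref = site$ref[out$i], alt = site$alt[out$i], filter = "PASS",
    variant_key = paste(site$chrom[out$i], site$pos[out$i],
                        site$ref[out$i], site$alt[out$i], sep = ":"),
    sample = out$sample,
    allele1 = parsed$a1, allele2 = parsed$a2,
    dosage = ifelse(parsed$missing, NA_integer_,
                    as.integer((!is.na(parsed$a1) & parsed$a1 == 1L) +
                                 (!is.na(parsed$a2) & parsed$a2 == 1L))),
    missing = parsed$missing, hemizygous = parsed$hemi,
    other_alt = FALSE, phased = parsed$phased,
    depth = depth, depth_missing = FALSE, gq = gq, gq_missing = FALSE
  )
}

#' Simulate a case-control cohort with planted per-gene carrier effects
#'
#' Variant minor-allele frequencies are drawn uniformly on `maf_range` and
#' genotypes at Hardy-Weinberg proportions. Case labels are assigned by
#' weighted sampling without replacement with per-sample weights from a
#' logistic model on carrier state (`carrier_log_odds` per gene; all zeros
#' gives random labels), so the case/control split is exact. Missingness is
#' applied uniformly at `missing_rate`.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param n_genes Number of genes.
#' @param variants_per_gene Variants per gene.
#' @param maf_range Length-2 range within (0, 0.5).
#' @param carrier_log_odds Per-gene log odds ratio of case status per
#'   carrier (recycled; 0 = null).
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return List with `dataset` (a [cohort_dataset()]) and `truth` (per-gene
#'   effect table); the dataset's annotations carry `gene`, rare
#'   frequencies and a missense consequence so the default burden mask
#'   keeps every variant.
#' @export
simulate_cohort <- function(n_cases = 130, n_controls = 861, n_genes = 2,
                            variants_per_gene = 10, maf_range = c(0.002, 0.01),
                            carrier_log_odds = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0, n_genes > 0, variants_per_gene > 0,
            maf_range[1] > 0, maf_range[2] < 0.5)
  carrier_log_odds <- rep_len(carrier_log_odds, n_genes)
  withr::with_seed(seed, {
    n <- n_cases + n_controls
    m <- n_genes * variants_per_gene
    mafs <- stats::runif(m, maf_range[1], maf_range[2])
    G <- vapply(mafs, function(p) stats::rbinom(n, 2, p), numeric(n))
    genes <- rep(sprintf("G%03d", seq_len(n_genes)), each = variants_per_gene)
    colnames(G) <- paste0("syn_chr:", seq_len(m) * 100, ":A:G")
    # logistic carrier model -> exact-count case assignment
    logit <- rep(0, n)
    for (gi in seq_len(n_genes)) {
      if (carrier_log_odds[gi] != 0) {
        carrier <- rowSums(G[, genes == genes[(gi - 1) * variants_per_gene + 1],
                             drop = FALSE]) > 0
        logit <- logit + carrier_log_odds[gi] * carrier
      }
    }
    case_idx <- sample.int(n, n_cases, prob = exp(logit))
    phenotype <- rep("control", n)
    phenotype[case_idx] <- "case"
    if (missing_rate > 0) {
      G[stats::runif(length(G)) < missing_rate] <- NA
    }
    rownames(G) <- sprintf("S%04d", seq_len(n))
    keys <- colnames(G)
    ann <- tibble::tibble(
      chrom = "syn_chr", pos = seq_len(m) * 100, ref = "A", alt = "G",
      gene = genes, transcript = NA_character_, consequence = "missense",
      maf_esp = mafs, maf_1kg = mafs, maf_gnomad = mafs,
      cadd = 25, internal_count = 0L, pli = NA_real_, regulatory = FALSE,
      variant_key = keys
    )
    ds <- cohort_dataset(G, phenotype,
                         ancestry_fraction = stats::runif(n, 0.81, 1),
                         annotations = ann)
    list(dataset = ds,
         truth = tibble::tibble(gene = unique(genes),
                                carrier_log_odds = carrier_log_odds))
  })
}

#' Plant exact carrier counts for one gene in a cohort
#'
#' Overwrites the first variant of `gene` so that exactly
#' `n_case_carriers` cases and `n_control_carriers` controls carry one
#' alternate allele (all other samples non-carriers at that gene). Useful
#' for reproducing printed carrier frequencies on a realized fixture.
#'
#' @param sim Output of [simulate_cohort()].
#' @param gene Gene symbol.
#' @param n_case_carriers,n_control_carriers Exact carrier counts.
#' @return The modified simulation list.
#' @export
plant_carriers <- function(sim, gene, n_case_carriers, n_control_carriers) {
  ds <- sim$dataset
  cols <- which(ds$annotations$gene == gene)
  ds$dosage[, cols] <- 0
  cases <- which(ds$phenotype == "case")
  controls <- which(ds$phenotype == "control")
  stopifnot(n_case_carriers <= length(cases),
            n_control_carriers <= length(controls))
  ds$dosage[cases[seq_len(n_case_carriers)], cols[1]] <- 1
  ds$dosage[controls[seq_len(n_control_carriers)], cols[1]] <- 1
  sim$dataset <- ds
  sim
}

#' Simulate differential-expression tables with planted concordance
#'
#' Concordant genes receive same-sign log2 fold changes versus both parents
#' with adjusted p below threshold; discordant genes opposite signs (both
#' significant); the remainder are null. The same truth is emitted at both
#' timepoints.
#'
#' @param n_genes Total genes.
#' @param n_concordant,n_discordant Planted counts
#'   (`n_concordant + n_discordant <= n_genes`).
#' @param effect_log2fc Mean absolute planted log2 fold change.
#' @param noise_sd Gaussian noise on the fold changes.
#' @param seed Integer seed.
#' @return List with `d0`, `d25` (DET tibbles) and `truth`.
#' @export
simulate_det_tables <- function(n_genes = 100, n_concordant = 40,
                                n_discordant = 30, effect_log2fc = 2,
                                noise_sd = 0.2, seed = 1L) {
  stopifnot(n_concordant + n_discordant <= n_genes)
  withr::with_seed(seed, {
    genes <- sprintf("T%04d", seq_len(n_genes))
    status <- rep("null", n_genes)
    status[seq_len(n_concordant)] <- "concordant"
    status[n_concordant + seq_len(n_discordant)] <- "discordant"
    one_tp <- function(tp) {
      purrr::map_dfr(seq_len(n_genes), function(i) {
        sgn <- sample(c(-1, 1), 1)
        lfc <- switch(status[i],
          concordant = sgn * (effect_log2fc + stats::rnorm(2, 0, noise_sd)),
          discordant = c(1, -1) * sgn * (effect_log2fc + stats::rnorm(2, 0, noise_sd)),
          null = stats::rnorm(2, 0, noise_sd / 2))
        p <- if (status[i] == "null") stats::runif(2, 0.2, 1) else stats::runif(2, 1e-6, 0.01)
        tibble::tibble(gene = genes[i],
                       comparison = c("proband_vs_mother", "proband_vs_father"),
                       log2fc = lfc, adjusted_p = p, timepoint = tp)
      })
    }
    list(d0 = one_tp("d0"), d25 = one_tp("d25"),
         truth = tibble::tibble(gene = genes, status = status))
  })
}
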