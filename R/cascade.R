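#' Run the family variant-prioritization cascade
#'
#' Applies, in order: site/genotype QC (read depth over proband and parents,
#' adjacency to a long homopolymer, internal-cohort recurrence), rarity and
#' functional-impact filtering, then per-gene inheritance classification
#' (de novo, homozygous recessive, compound heterozygous with transmission
#' phasing, X-linked recessive) with unaffected-sibling exclusion, plus
#' retention of inherited loss-of-function variants in pLI-constrained
#' genes. Every input variant is accounted for exactly once in the audit
#' table: either it supports a surviving call or it records the stage that
#' removed it.
#'
#' @param gt_tbl Tidy genotype tibble from [read_vcf()].
#' @param pedigree A [new_pedigree()] object.
#' @param annotations Annotation tibble from [read_annotations()].
#' @param reference FASTA path or loaded reference for the homopolymer rule;
#'   `NULL` skips that rule.
#' @param config A [family_qc_config()].
#' @param policy A [rarity_policy()].
#' @return Object of class `cascade_result`: list with `calls` (one row per
#'   inheritance call), `audit` (one row per input variant) and `summary`
#'   (variants surviving each stage).
#' @export
run_family_cascade <- function(gt_tbl, pedigree, annotations, reference = NULL,
                               config = family_qc_config(),
                               policy = rarity_policy()) {
  fam <- family_genotypes(gt_tbl, pedigree)
  audit <- tibble::tibble(variant_key = fam$variant_key,
                          gene = annotations$gene[match(fam$variant_key, annotations$variant_key)],
                          stage_removed = NA_character_)

  mark <- function(audit, keys, stage) {
    sel <- audit$variant_key %in% keys & is.na(audit$stage_removed)
    audit$stage_removed[sel] <- stage
    audit
  }

  # unannotated variants are reported, never silently dropped
  unann <- fam$variant_key[!fam$variant_key %in% annotations$variant_key]
  audit <- mark(audit, unann, "unannotated")
  active <- setdiff(fam$variant_key, unann)

  # QC: trio depth (proband and both parents); sibling depth additionally
  # gates inherited modes but shares the audit label
  trio <- c(pedigree$proband_id, pedigree$father_id, pedigree$mother_id)
  dep <- depth_filter(gt_tbl, trio, config)
  fail_depth <- dep$variant_key[!dep$pass_depth]
  audit <- mark(audit, intersect(active, fail_depth), "qc_depth")
  active <- setdiff(active, fail_depth)

  if (!is.null(reference)) {
    hp <- homopolymer_adjacent(fam[fam$variant_key %in% active, ], reference, config)
    fail_hp <- hp$variant_key[hp$homopolymer_adjacent]
    audit <- mark(audit, fail_hp, "qc_homopolymer")
    active <- setdiff(active, fail_hp)
  }

  ann_active <- annotations[annotations$variant_key %in% active, ]
  ic <- internal_cohort_filter(ann_active, config)
  fail_ic <- ic$variant_key[!ic$pass_internal_cohort]
  audit <- mark(audit, fail_ic, "qc_internal_cohort")
  active <- setdiff(active, fail_ic)

  # rarity at the recessive (wider) threshold; the de novo path re-checks the
  # dominant threshold during classification
  ann_active <- annotations[annotations$variant_key %in% active, ]
  rare <- is_rare(ann_active, "recessive", policy)
  audit <- mark(audit, ann_active$variant_key[!rare], "not_rare")
  active <- ann_active$variant_key[rare]

  ann_active <- annotations[annotations$variant_key %in% active, ]
  fun <- is_functional(ann_active)
  audit <- mark(audit, ann_active$variant_key[!fun], "not_functional")
  active <- ann_active$variant_key[fun]

  fam_active <- fam[fam$variant_key %in% active, ]
  ann_active <- annotations[match(fam_active$variant_key, annotations$variant_key), ]
  fam_active$gene <- ann_active$gene

  calls <- list()
  supported <- character(0)
  excluded_genes <- character(0)

  # de novo calls (per variant)
  if (nrow(fam_active) > 0) {
    dn <- classify_de_novo(fam_active, ann_active, config, policy)
    for (k in dn$variant_key[dn$de_novo]) {
      g <- fam_active$gene[fam_active$variant_key == k]
      calls[[length(calls) + 1]] <- call_row(g, "de_novo", k, "de_novo", FALSE,
                                             sib_verdict(pedigree$sibling_ids,
                                                         rep(FALSE, length(pedigree$sibling_ids))))
      supported <- c(supported, k)
    }
  }

  # per-gene recessive / X-linked classification on inherited variants
  sib_ok <- vapply(seq_len(nrow(fam_active)), function(i) {
    so <- fam_active$sib_depth_ok[[i]]
    length(so) == 0 || all(is.na(so) | so)
  }, logical(1))
  fam_inh <- fam_active[sib_ok & !fam_active$variant_key %in% supported, ]
  for (g in unique(fam_inh$gene)) {
    gene_fam <- fam_inh[fam_inh$gene == g, ]
    res <- classify_gene_recessive(gene_fam, pedigree, gene = g)
    if (is_call(res)) {
      calls[[length(calls) + 1]] <- res
      supported <- c(supported, res$variant_keys[[1]])
    } else if (res$sibling_excluded) {
      excluded_genes <- c(excluded_genes, g)
    }
  }

  # inherited loss-of-function retention in constrained genes
  inh_lof <- inherited_lof_retention(ann_active) &
    !is.na(fam_active$d_pro) & fam_active$d_pro >= 1 &
    !(!is.na(fam_active$d_fat) & fam_active$d_fat == 0 &
        !is.na(fam_active$d_mot) & fam_active$d_mot == 0) &
    !fam_active$variant_key %in% supported
  for (i in which(inh_lof)) {
    origin <- variant_origin(fam_active$d_fat[i], fam_active$d_mot[i])
    calls[[length(calls) + 1]] <- call_row(fam_active$gene[i], "inherited_lof",
                                           fam_active$variant_key[i], origin, FALSE,
                                           sib_verdict(pedigree$sibling_ids,
                                                       rep(FALSE, length(pedigree$sibling_ids))))
    supported <- c(supported, fam_active$variant_key[i])
  }

  leftover <- setdiff(active, supported)
  leftover_genes <- annotations$gene[match(leftover, annotations$variant_key)]
  audit <- mark(audit, leftover[leftover_genes %in% excluded_genes], "sibling_excluded")
  audit <- mark(audit, leftover, "no_inheritance")
  audit$stage_removed[is.na(audit$stage_removed) &
                        audit$variant_key %in% supported] <- "survived"

  calls_tbl <- if (length(calls) > 0) dplyr::bind_rows(calls) else
    call_row(character(0), character(0), character(0), character(0),
             logical(0), character(0))[0, ]
  stages <- c("input", "unannotated", "qc_depth", "qc_homopolymer",
              "qc_internal_cohort", "not_rare", "not_functional",
              "sibling_excluded", "no_inheritance", "survived")
  summary <- tibble::tibble(
    stage = stages,
    n_variants = unname(c(nrow(audit),
                          vapply(stages[-1],
                                 function(s) sum(audit$stage_removed == s, na.rm = TRUE),
                                 numeric(1))))
  )
  structure(list(calls = calls_tbl, audit = audit, summary = summary,
                 pedigree = pedigree),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Family variant cascade:", nrow(x$audit), "input variants,",
      nrow(x$calls), "inheritance call(s) in",
      length(unique(x$calls$gene)), "gene(s)\n")
  if (nrow(x$calls) > 0) {
    tab <- table(x$calls$mode)
    cat("  modes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an inheritance-call table
#'
#' One row per supporting variant, with its gene, mode and parental origin.
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) {
  if (nrow(x$calls) == 0) {
    return(tibble::tibble(gene = character(0), mode = character(0),
                          variant_key = character(0), origin = character(0)))
  }
  purrr::pmap_dfr(x$calls, function(gene, mode, variant_keys, origins, ...) {
    tibble::tibble(gene = gene, mode = mode, variant_key = variant_keys,
                   origin = unname(origins))
  })
}

#' One-line cascade summary
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return A one-row tibble with stage counts and the candidate-gene count.
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  s <- stats::setNames(as.list(x$summary$n_variants), x$summary$stage)
  tibble::as_tibble(s) |>
    dplyr::mutate(n_calls = nrow(x$calls),
                  n_genes = length(unique(x$calls$gene)))
}
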