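#' Collapse a tidy genotype table to one row per variant with family roles
#'
#' Produces, per variant, the proband/father/mother dosages and flags plus
#' list-columns of unaffected-sibling dosages, keyed by sibling id. Dosage is
#' the count of the record's alternate allele (0/1/2 diploid, 0/1
#' hemizygous, `NA` missing).
#'
#' @param gt_tbl Tidy genotype tibble from [read_vcf()].
#' @param pedigree A [new_pedigree()] object.
#' @return Tibble with one row per `variant_key`.
#' @export
family_genotypes <- function(gt_tbl, pedigree) {
  roles <- c(pro = pedigree$proband_id, fat = pedigree$father_id,
             mot = pedigree$mother_id)
  site <- dplyr::distinct(gt_tbl, .data$variant_key, .data$chrom, .data$pos,
                          .data$ref, .data$alt, .data$filter)
  pick <- function(id, col) {
    sub <- gt_tbl[gt_tbl$sample == id, c("variant_key", col)]
    sub[[col]][match(site$variant_key, sub$variant_key)]
  }
  out <- site
  for (r in names(roles)) {
    out[[paste0("d_", r)]] <- pick(roles[[r]], "dosage")
    out[[paste0("hemi_", r)]] <- pick(roles[[r]], "hemizygous")
    out[[paste0("depth_", r)]] <- pick(roles[[r]], "depth")
    out[[paste0("depthmiss_", r)]] <- pick(roles[[r]], "depth_missing")
  }
  sibs <- pedigree$sibling_ids
  out$sib_dosage <- lapply(seq_len(nrow(site)), function(i) {
    stats::setNames(vapply(sibs, function(s) {
      v <- gt_tbl$dosage[gt_tbl$sample == s & gt_tbl$variant_key == site$variant_key[i]]
      if (length(v) == 0) NA_integer_ else v[1]
    }, integer(1)), sibs)
  })
  out$sib_hemi <- lapply(seq_len(nrow(site)), function(i) {
    stats::setNames(vapply(sibs, function(s) {
      v <- gt_tbl$hemizygous[gt_tbl$sample == s & gt_tbl$variant_key == site$variant_key[i]]
      if (length(v) == 0) NA else v[1]
    }, logical(1)), sibs)
  })
  out$sib_depth_ok <- lapply(seq_len(nrow(site)), function(i) {
    stats::setNames(vapply(sibs, function(s) {
      rows <- gt_tbl$sample == s & gt_tbl$variant_key == site$variant_key[i]
      if (!any(rows)) return(NA)
      !gt_tbl$depth_missing[rows][1] || gt_tbl$depth[rows][1] > 0
    }, logical(1)), sibs)
  })
  out
}

is_x_chrom <- function(chrom) {
  toupper(chrom) %in% c("X", "CHRX", "SYNX")
}

# Parent-of-origin from parental genotypes (transmission, not read phasing).
variant_origin <- function(d_fat, d_mot) {
  dplyr::case_when(
    is.na(d_fat) | is.na(d_mot) ~ NA_character_,
    d_mot >= 1 & d_fat == 0 ~ "maternal",
    d_fat >= 1 & d_mot == 0 ~ "paternal",
    d_mot >= 1 & d_fat >= 1 ~ "both",
    TRUE ~ "de_novo"
  )
}

#' Classify de novo candidate variants
#'
#' A variant is de novo when the proband carries at least one alternate
#' allele while both parents are explicitly homozygous reference with
#' adequate depth (guarding against allele dropout), and the variant is rare
#' at the dominant (<1%) threshold. A missing parental genotype is never de
#' novo; such variants are flagged in the `note` column.
#'
#' @param fam_tbl Output of [family_genotypes()].
#' @param annotations Annotation tibble (matched by `variant_key`).
#' @param config A [family_qc_config()].
#' @param policy A [rarity_policy()].
#' @return Tibble with `variant_key`, logical `de_novo`, and `note`.
#' @export
classify_de_novo <- function(fam_tbl, annotations, config = family_qc_config(),
                             policy = rarity_policy()) {
  ann <- annotations[match(fam_tbl$variant_key, annotations$variant_key), ]
  rare_dom <- is_rare(ann, "dominant", policy)
  depth_ok <- fam_tbl$depth_pro >= config$min_depth &
    fam_tbl$depth_fat >= config$min_depth &
    fam_tbl$depth_mot >= config$min_depth
  parent_missing <- is.na(fam_tbl$d_fat) | is.na(fam_tbl$d_mot)
  dn <- !is.na(fam_tbl$d_pro) & fam_tbl$d_pro >= 1 &
    !parent_missing & fam_tbl$d_fat == 0 & fam_tbl$d_mot == 0 &
    depth_ok & rare_dom
  note <- dplyr::case_when(
    parent_missing & !is.na(fam_tbl$d_pro) & fam_tbl$d_pro >= 1 ~ "parent genotype missing",
    TRUE ~ NA_character_
  )
  tibble::tibble(variant_key = fam_tbl$variant_key, de_novo = dn, note = note)
}

# Can a compound-heterozygous configuration be assembled from origin labels?
# Needs two distinct variants covering both parental sides; a both-parent-het
# variant can fill either side but a single one cannot anchor a pair alone.
ch_feasible <- function(origins) {
  m <- sum(origins == "maternal", na.rm = TRUE)
  p <- sum(origins == "paternal", na.rm = TRUE)
  b <- sum(origins == "both", na.rm = TRUE)
  (m >= 1 && p >= 1) || (m >= 1 && b >= 1) || (p >= 1 && b >= 1) || b >= 2
}

#' Classify one gene's qualifying variants into a recessive mode
#'
#' Applies, in order: homozygous recessive (proband homozygous alternate
#' with both parents heterozygous), compound heterozygous (at least one
#' maternally- and one paternally-transmitted heterozygous variant, origin
#' inferred by transmission; a variant heterozygous in both parents is
#' ambiguous and may fill either side but two distinct variants are always
#' required), then X-linked recessive for genes on the X chromosome. A call
#' is voided when any unaffected sibling's genotypes reproduce the proband's
#' full causal configuration: both alleles of the homozygous call, at least
#' one maternal-side plus one paternal-side variant of the compound set, or
#' the hemizygous/homozygous state for X-linked calls. Siblings carrying a
#' single variant of a compound pair are consistent carriers and do not void
#' the call.
#'
#' @param gene_fam One gene's rows of [family_genotypes()], already
#'   restricted to rare (recessive threshold) functional variants.
#' @param pedigree A [new_pedigree()] object.
#' @param gene Gene symbol for the call record.
#' @return A one-row call tibble (`gene`, `mode`, `variant_keys`, `origins`,
#'   `ambiguous`, `sibling_exclusion` list-columns) or `NULL`; a voided call
#'   returns `NULL` with attribute `"sibling_excluded"` carried via the
#'   `excluded` field of the attached audit attribute.
#' @export
classify_gene_recessive <- function(gene_fam, pedigree, gene = gene_fam$gene[1]) {
  sibs <- pedigree$sibling_ids
  voided <- FALSE

  # --- homozygous recessive -------------------------------------------------
  hom_idx <- which(!is.na(gene_fam$d_pro) & gene_fam$d_pro == 2 &
                     !gene_fam$hemi_pro &
                     !is.na(gene_fam$d_fat) & gene_fam$d_fat == 1 &
                     !is.na(gene_fam$d_mot) & gene_fam$d_mot == 1)
  for (i in hom_idx) {
    sib_d <- gene_fam$sib_dosage[[i]]
    excl <- !is.na(sib_d) & sib_d == 2
    if (!any(excl)) {
      return(call_row(gene, "homozygous_recessive",
                      gene_fam$variant_key[i], "both", FALSE,
                      sib_verdict(sibs, rep(FALSE, length(sibs)))))
    }
    voided <- TRUE
  }

  # --- compound heterozygous ------------------------------------------------
  het_idx <- which(!is.na(gene_fam$d_pro) & gene_fam$d_pro == 1 & !gene_fam$hemi_pro)
  if (length(het_idx) >= 2) {
    origins <- variant_origin(gene_fam$d_fat[het_idx], gene_fam$d_mot[het_idx])
    usable <- !is.na(origins) & origins %in% c("maternal", "paternal", "both")
    het_idx <- het_idx[usable]
    origins <- origins[usable]
    if (ch_feasible(origins)) {
      sib_excl <- vapply(sibs, function(s) {
        carried <- vapply(het_idx, function(i) {
          d <- gene_fam$sib_dosage[[i]][[s]]
          !is.na(d) && d >= 1
        }, logical(1))
        sum(carried) >= 2 && ch_feasible(origins[carried])
      }, logical(1))
      if (!any(sib_excl)) {
        return(call_row(gene, "compound_heterozygous",
                        gene_fam$variant_key[het_idx], origins,
                        any(origins == "both"),
                        sib_verdict(sibs, sib_excl)))
      }
      voided <- TRUE
    }
  }

  # --- X-linked recessive ---------------------------------------------------
  if (any(is_x_chrom(gene_fam$chrom))) {
    xcall <- classify_x_linked(gene_fam, pedigree, gene = gene)
    if (is_call(xcall)) return(xcall)
    if (xcall$sibling_excluded) voided <- TRUE
  }

  no_call(voided)
}

no_call <- function(sibling_excluded) {
  structure(list(sibling_excluded = sibling_excluded), class = "vc_no_call")
}

is_call <- function(x) inherits(x, "tbl_df")

#' Classify an X-chromosome gene for X-linked recessive inheritance
#'
#' Male proband: call when hemizygous for the alternate allele with a
#' carrier mother and non-carrier father; voided when an unaffected brother
#' is hemizygous alternate (unaffected sisters may be heterozygous carriers,
#' but a homozygous sister reproduces the causal configuration and voids).
#' Female proband: homozygous alternate with both parents carriers; a
#' hemizygous-alternate brother or homozygous sister voids. A diploid-coded
#' heterozygous male X call is inconsistent and is dropped from the
#' analysis.
#'
#' @inheritParams classify_gene_recessive
#' @return A one-row call tibble or `NULL` (with attribute
#'   `sibling_excluded` when a qualifying configuration was voided).
#' @export
classify_x_linked <- function(gene_fam, pedigree, gene = gene_fam$gene[1]) {
  sex <- proband_sex(pedigree)
  if (sex == "unknown") {
    stop("Proband sex unknown: cannot run X-linked analysis for gene ", gene, call. = FALSE)
  }
  sibs <- pedigree$sibling_ids
  members <- pedigree$members
  sib_sex <- stats::setNames(members$sex[match(sibs, members$sample_id)], sibs)
  voided <- FALSE
  for (i in seq_len(nrow(gene_fam))) {
    row <- gene_fam[i, ]
    if (!is_x_chrom(row$chrom)) next
    if (sex == "male") {
      # diploid-coded male X het is inconsistent: drop from X-linked analysis
      if (!is.na(row$d_pro) && !row$hemi_pro && row$d_pro == 1) next
      qualifies <- !is.na(row$d_pro) && row$d_pro >= 1 &&
        !is.na(row$d_mot) && row$d_mot >= 1 &&
        !is.na(row$d_fat) && row$d_fat == 0
    } else {
      qualifies <- !is.na(row$d_pro) && row$d_pro == 2 &&
        !is.na(row$d_mot) && row$d_mot >= 1 &&
        !is.na(row$d_fat) && row$d_fat >= 1
    }
    if (!qualifies) next
    sib_d <- row$sib_dosage[[1]]
    sib_excl <- vapply(sibs, function(s) {
      d <- sib_d[[s]]
      if (is.na(d)) return(FALSE)
      if (identical(sib_sex[[s]], "male")) d >= 1 else d == 2
    }, logical(1))
    if (!any(sib_excl)) {
      return(call_row(gene, "x_linked_recessive", row$variant_key, "maternal",
                      FALSE, sib_verdict(sibs, sib_excl),
                      hemizygous = identical(sex, "male")))
    }
    voided <- TRUE
  }
  no_call(voided)
}

call_row <- function(gene, mode, variant_keys, origins, ambiguous, sib_verdicts,
                     hemizygous = FALSE) {
  named_origins <- stats::setNames(origins, variant_keys)
  tibble::tibble(
    gene = gene, mode = mode, n_variants = length(variant_keys),
    variant_keys = list(variant_keys),
    origins = list(named_origins),
    ambiguous = ambiguous, hemizygous = hemizygous,
    sibling_exclusion = list(sib_verdicts)
  )
}

sib_verdict <- function(sibs, excluded) {
  stats::setNames(ifelse(excluded, "excluded_by", "consistent"), sibs)
}

#' Retain inherited loss-of-function variants in constrained genes
#'
#' Inherited frameshift and start/stop-codon variants are retained when the
#' gene is intolerant of loss of function (pLI strictly above 0.75). A
#' missing pLI retains nothing and warns.
#'
#' @param annotations Annotation tibble rows for inherited
#'   frameshift/stop-gain/stop-loss variants.
#' @param pli_min Strict pLI threshold.
#' @return Logical vector.
#' @export
inherited_lof_retention <- function(annotations, pli_min = 0.75) {
  lof <- annotations$consequence %in% c("frameshift", "stop_gain", "stop_loss")
  if (any(lof & is.na(annotations$pli))) {
    warning("pLI missing for ", sum(lof & is.na(annotations$pli)),
            " loss-of-function variant(s); not retained")
  }
  lof & !is.na(annotations$pli) & annotations$pli > pli_min
}
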