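#' Consequence classes, ranked by severity
#'
#' One primary class per variant per transcript; when several apply the most
#' severe is kept. The order is: frameshift > stop_gain > stop_loss >
#' essential_splice > missense > splice_region > synonymous > UTR >
#' upstream/promoter/regulatory > intronic > other.
#'
#' @return Character vector of class names, most severe first.
#' @export
consequence_levels <- function() {
  c("frameshift", "stop_gain", "stop_loss", "essential_splice", "missense",
    "splice_region", "synonymous", "utr5", "utr3", "upstream_1kb", "promoter",
    "encode_tfbs", "mirna_site", "enhancer", "intronic", "other")
}

functional_consequences <- function() {
  c("frameshift", "stop_gain", "stop_loss", "missense", "essential_splice",
    "mirna_site", "enhancer", "encode_tfbs", "promoter")
}

#' Read a variant annotation table
#'
#' Tab-separated with a one-line header; required columns are CHROM, POS,
#' REF, ALT, GENE, CONSEQUENCE plus the population-frequency columns
#' (MAF_ESP, MAF_1KG, MAF_GNOMAD as fractions), CADD, INTERNAL_COUNT, PLI
#' and REGULATORY. Missing frequencies are read as `NA` and treated as 0
#' (novel variant) by [is_rare()].
#'
#' @param path Path to the annotation TSV.
#' @return Tibble keyed by `variant_key` with lower-case column names.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    stop("Annotation table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tbl$consequence), consequence_levels())
  if (length(bad) > 0) {
    stop("Unknown consequence class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (col in c("maf_esp", "maf_1kg", "maf_gnomad", "cadd", "pli")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  }
  if (!"internal_count" %in% names(tbl)) tbl$internal_count <- 0L
  if (!"regulatory" %in% names(tbl)) tbl$regulatory <- FALSE
  tbl$variant_key <- paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")
  dplyr::relocate(tbl, "variant_key")
}

#' Rarity policy for the family cascade
#'
#' Rare means the maximum frequency over the configured databases is
#' strictly below the mode's threshold: under 1% for de novo,
#' loss-of-function and panel-gene screening (dominant-acting candidates),
#' under 3% for compound-heterozygous, hemizygous or homozygous-recessive
#' candidates. The frequency era selects which database columns the maximum
#' runs over: `"study_initiation"` emulates the exome-server-era lookup
#' (ESP column only), `"current"` uses all columns including gnomAD.
#'
#' @param maf_threshold_dominant Strict upper bound for dominant-acting
#'   modes.
#' @param maf_threshold_recessive Strict upper bound for recessive modes.
#' @param frequency_era `"study_initiation"` or `"current"`.
#' @param databases Frequency columns to maximise over; defaults depend on
#'   the era.
#' @return A list of class `rarity_policy`.
#' @export
rarity_policy <- function(maf_threshold_dominant = 0.01,
                          maf_threshold_recessive = 0.03,
                          frequency_era = c("study_initiation", "current"),
                          databases = NULL) {
  frequency_era <- match.arg(frequency_era)
  stopifnot(maf_threshold_dominant > 0, maf_threshold_dominant < 1,
            maf_threshold_recessive > 0, maf_threshold_recessive < 1)
  if (is.null(databases)) {
    databases <- if (frequency_era == "study_initiation") {
      c("maf_esp", "maf_1kg")
    } else {
      c("maf_esp", "maf_1kg", "maf_gnomad")
    }
  }
  structure(list(maf_threshold_dominant = maf_threshold_dominant,
                 maf_threshold_recessive = maf_threshold_recessive,
                 frequency_era = frequency_era,
                 databases = databases),
            class = "rarity_policy")
}

max_database_maf <- function(annotations, policy) {
  cols <- intersect(policy$databases, names(annotations))
  if (length(cols) == 0) return(rep(0, nrow(annotations)))
  m <- as.matrix(annotations[, cols])
  m[is.na(m)] <- 0   # absent frequency = novel variant
  apply(m, 1, max)
}

#' Is a variant rare under a mode's threshold?
#'
#' @param annotations Annotation tibble.
#' @param mode `"dominant"` (<1% default) or `"recessive"` (<3% default).
#' @param policy A [rarity_policy()].
#' @return Logical vector, one element per annotation row; `TRUE` when the
#'   maximum database frequency is strictly below the mode's threshold.
#' @export
is_rare <- function(annotations, mode = c("dominant", "recessive"),
                    policy = rarity_policy()) {
  mode <- match.arg(mode)
  thr <- if (mode == "dominant") policy$maf_threshold_dominant else policy$maf_threshold_recessive
  max_database_maf(annotations, policy) < thr
}

#' Is a variant functional?
#'
#' Functional variants impact a protein sequence, a canonical splice site, a
#' microRNA coding sequence or binding site, an enhancer region, or a
#' transcription-factor binding site within an ENCODE-validated promoter.
#'
#' @param annotations Annotation tibble with a `consequence` column.
#' @return Logical vector.
#' @export
is_functional <- function(annotations) {
  annotations$consequence %in% functional_consequences()
}

#' Screen a gene panel for rare functional variants
#'
#' Reports rare (dominant threshold, <1%) functional variants in a supplied
#' clinical panel gene list for manual review. The report never removes
#' variants from the cascade. The panel membership is user-supplied
#' configuration (an empty panel yields a warning and an empty report).
#'
#' @param annotations Annotation tibble.
#' @param panel_genes Character vector of panel gene symbols.
#' @param policy A [rarity_policy()].
#' @return Tibble of reportable panel-gene variants.
#' @export
panel_screen <- function(annotations, panel_genes, policy = rarity_policy()) {
  if (length(panel_genes) == 0) {
    warning("Empty panel gene list: nothing to screen")
    return(annotations[0, ])
  }
  annotations[annotations$gene %in% panel_genes &
                is_rare(annotations, "dominant", policy) &
                is_functional(annotations), ]
}

#' Burden-analysis variant inclusion policy
#'
#' Default mode restricts to strong predicted functional impact: frameshift,
#' missense, stop-gain, stop-loss and essential-splice variants, with
#' missense additionally required to have CADD strictly above 24, and all
#' variants required to be rare (MAF < 0.01 across all populations, maximum
#' over databases).
#'
#' @param maf_threshold Strict rarity bound (max across databases).
#' @param consequence_whitelist Consequence classes included in default
#'   mode.
#' @param cadd_min_for_missense CADD threshold applied to missense only
#'   (strictly above).
#' @return A list of class `burden_policy`.
#' @export
burden_policy <- function(maf_threshold = 0.01,
                          consequence_whitelist = c("frameshift", "missense",
                                                    "stop_gain", "stop_loss",
                                                    "essential_splice"),
                          cadd_min_for_missense = 24) {
  stopifnot(maf_threshold > 0, cadd_min_for_missense > 0)
  structure(list(maf_threshold = maf_threshold,
                 consequence_whitelist = consequence_whitelist,
                 cadd_min_for_missense = cadd_min_for_missense),
            class = "burden_policy")
}

burden_categories <- function() {
  c("all_gene_body", "missense", "intronic", "splice_region", "synonymous",
    "utr3", "utr5", "upstream_1kb", "regulatory_fetal_heart", "tfbs_clusters")
}

#' Variant inclusion mask for burden testing
#'
#' Default mode (`category = NULL`) applies the strict-impact whitelist, the
#' CADD-on-missense rule and the rarity rule. Category mode selects by
#' consequence class (or regulatory-region flag for the two regulatory
#' categories) together with rarity; `relax_cadd = TRUE` drops the CADD
#' restriction, as in the relaxed-constraint gene-body analyses.
#'
#' @param annotations Annotation tibble.
#' @param policy A [burden_policy()].
#' @param category `NULL` for default mode, or one of
#'   `r paste(burden_categories(), collapse = ", ")`.
#' @param relax_cadd Drop the CADD restriction on missense.
#' @param regulatory_regions Optional tibble of BED-style intervals
#'   (`chrom`, `start` 0-based, `end`) for the regulatory categories.
#' @return Logical inclusion mask, one element per annotation row.
#' @export
burden_variant_mask <- function(annotations, policy = burden_policy(),
                                category = NULL, relax_cadd = FALSE,
                                regulatory_regions = NULL) {
  rare <- max_database_maf(annotations,
                           list(databases = c("maf_esp", "maf_1kg", "maf_gnomad"))) <
    policy$maf_threshold
  cadd_ok <- annotations$consequence != "missense" |
    (!is.na(annotations$cadd) & annotations$cadd > policy$cadd_min_for_missense)
  if (relax_cadd) cadd_ok <- rep(TRUE, nrow(annotations))
  if (is.null(category)) {
    return(rare & annotations$consequence %in% policy$consequence_whitelist & cadd_ok)
  }
  if (!category %in% burden_categories()) {
    stop("Unknown burden category: ", category, call. = FALSE)
  }
  sel <- switch(category,
    all_gene_body = rep(TRUE, nrow(annotations)),
    missense = annotations$consequence == "missense",
    intronic = annotations$consequence == "intronic",
    splice_region = annotations$consequence == "splice_region",
    synonymous = annotations$consequence == "synonymous",
    utr3 = annotations$consequence == "utr3",
    utr5 = annotations$consequence == "utr5",
    upstream_1kb = annotations$consequence == "upstream_1kb",
    regulatory_fetal_heart = ,
    tfbs_clusters = region_overlap_mask(annotations, regulatory_regions)
  )
  # category mode selects by class only (plus rarity); the CADD rule belongs
  # to the default strict-impact mode
  rare & sel
}

# Overlap of variant positions with BED-style half-open intervals.
region_overlap_mask <- function(annotations, regions) {
  if (is.null(regions)) {
    if (!"regulatory" %in% names(annotations)) {
      stop("Regulatory category needs regulatory_regions intervals or a ",
           "'regulatory' annotation column", call. = FALSE)
    }
    return(as.logical(annotations$regulatory))
  }
  vapply(seq_len(nrow(annotations)), function(i) {
    any(regions$chrom == annotations$chrom[i] &
          regions$start < annotations$pos[i] &
          regions$end >= annotations$pos[i])
  }, logical(1))
}
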