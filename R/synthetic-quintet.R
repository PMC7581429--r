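#' The published worked-example variant table
#'
#' The 22 distinct recessive variants reported for the index family's ten
#' candidate genes, transcribed with their printed consequence class,
#' parental origin, unaffected-sibling genotypes, population
#' minor-allele frequency (percent; blank = not observed, a novel variant)
#' and dbSNP id. `origin = "both"` encodes the homozygous-recessive variant
#' heterozygous in each parent. The two X-linked genes are placed on the
#' synthetic X contig.
#'
#' @return A tibble, one row per variant.
#' @export
worked_example_variants <- function() {
  tibble::tribble(
    ~gene,     ~mode,      ~consequence,  ~cdna,          ~protein,   ~origin,    ~brother, ~sister, ~maf_pct, ~rsid,
    "HSPG2",   "cmpd_het", "missense",    "c.2074G>A",    "p.V692M",  "maternal", "WT",     "WT",    0.288,    "rs143669458",
    "HSPG2",   "cmpd_het", "missense",    "c.326G>A",     "p.R109Q",  "paternal", "Het",    "Het",   0,        "rs773796176",
    "HSPG2",   "cmpd_het", "promoter",    "c.-227C>A",    NA,         "paternal", "WT",     "WT",    1.392,    "rs566166086",
    "SLC9A1",  "cmpd_het", "promoter",    "c.-906T>C",    NA,         "paternal", "Het",    "Het",   1.227,    "rs114101904",
    "SLC9A1",  "cmpd_het", "promoter",    "c.-947T>G",    NA,         "maternal", "WT",     "WT",    27.175,   "rs11588974",
    "SLC9A1",  "cmpd_het", "promoter",    "c.-1085A>G",   NA,         "paternal", "Het",    "Het",   0.841,    "rs116299278",
    "SLC9A1",  "cmpd_het", "encode_tfbs", "c.-1138C>T",   NA,         "paternal", "Het",    "Het",   0.93,     "rs75089536",
    "SLC9A1",  "cmpd_het", "promoter",    "c.-1311G>A",   NA,         "paternal", "Het",    "Het",   0.93,     "rs77414471",
    "APOB",    "cmpd_het", "missense",    "c.13441G>A",   "p.A4481T", "maternal", "WT",     "Het",   2.475,    "rs1801695",
    "APOB",    "cmpd_het", "missense",    "c.751G>A",     "p.A251T",  "paternal", "Het",    "WT",    0.071,    "rs61741625",
    "LRP2",    "cmpd_het", "missense",    "c.9613A>G",    "p.N3205D", "maternal", "WT",     "WT",    0.407,    "rs35734447",
    "LRP2",    "cmpd_het", "missense",    "c.170C>T",     "p.A57V",   "paternal", "WT",     "WT",    0.032,    "rs115350461",
    "SDHD",    "cmpd_het", "promoter",    "c.-815G>C",    NA,         "maternal", "Het",    "WT",    0.573,    "rs117661257",
    "SDHD",    "cmpd_het", "encode_tfbs", "c.-205G>A",    "p.A22A",   "paternal", "WT",     "WT",    0.241,    "rs61734353",
    "SDHD",    "cmpd_het", "missense",    "c.34G>A",      "p.G12S",   "maternal", "Het",    "WT",    0.729,    "rs34677591",
    "PRTG",    "cmpd_het", "mirna_site",  "c.*3501T>G",   NA,         "paternal", "Het",    "WT",    0.739,    "rs77181316",
    "PRTG",    "cmpd_het", "mirna_site",  "c.*2678A>G",   NA,         "maternal", "WT",     "Het",   0.019,    "rs756136447",
    "HN1",     "cmpd_het", "encode_tfbs", "c.56+617C>T",  NA,         "maternal", "Het",    "WT",    3.764,    "rs117213586",
    "HN1",     "cmpd_het", "promoter",    "c.-1748A>C",   NA,         "paternal", "WT",     "Het",   0.816,    "rs73995795",
    "SIK1",    "hom_rec",  "missense",    "c.2087C>T",    "p.P696L",  "both",     "WT",     "Het",   NA,       "rs1256991707",
    "ELF4",    "x_linked", "missense",    "c.1144G>A",    "p.V382I",  "maternal", "WT",     "Het",   0.025,    "rs148953158",
    "HS6ST2",  "x_linked", "missense",    "c.948-40041G>A", "p.R349Q", "maternal", "WT",    "Het",   0.146,    "rs201239951"
  )
}

quintet_samples <- function() c("I.1", "I.2", "II.1", "II.2", "II.3")

decoy_rules <- function() {
  c("depth", "homopolymer", "internal_cohort", "common_maf", "nonfunctional",
    "sibling_match", "det_discordant", "det_missing")
}

# random DNA with no single-base run longer than 3 (so only planted runs can
# trip the homopolymer rule)
random_contig <- function(len) {
  bases <- c("A", "C", "G", "T")
  out <- character(len)
  out[1] <- sample(bases, 1)
  run <- 1L
  for (i in 2:len) {
    pool <- if (run >= 3L) setdiff(bases, out[i - 1]) else bases
    out[i] <- sample(pool, 1)
    run <- if (out[i] == out[i - 1]) run + 1L else 1L
  }
  paste(out, collapse = "")
}

#' Generate the packaged quintet worked-example fixture
#'
#' Emits a five-sample VCF encoding every published worked-example variant
#' with its printed proband/parent/sibling genotypes (synthetic positions on
#' synthetic contigs, one contig per autosomal gene, a shared X contig for
#' the X-linked genes), a matching PED file, an annotation table carrying
#' the printed population frequencies, a reference FASTA fragment for the
#' homopolymer rule, and two differential-expression tables marking the ten
#' candidate genes concordant at both timepoints.
#'
#' Decoy variants are added, `n_decoys_per_rule` for each filter rule, each
#' violating exactly one rule (read depth 9, adjacency to a seven-base
#' homopolymer run, internal-cohort count above threshold, common
#' population frequency, non-functional consequence, a sibling matching the
#' full causal configuration, discordant differential expression, and
#' differential expression at a single timepoint). Apart from its one
#' violation every decoy is a valid homozygous-recessive configuration, so
#' the cascade stage that removes it is exactly the rule it violates.
#'
#' The frequency-era behaviour lives in the analysis policy, not the files:
#' the annotation table carries both the exome-server-era emulated columns
#' (capped below the 3% threshold) and the printed gnomAD column, and
#' [rarity_policy()]'s `frequency_era` selects which are consulted.
#'
#' @param dir Output directory (created if needed).
#' @param n_decoys_per_rule Decoys per filter rule.
#' @param genotype_error_rate Per-call probability of replacing a quintet
#'   genotype with a random diploid genotype (0 = the printed genotypes).
#' @param seed Integer seed; all randomness is derived from it.
#' @return Invisibly, a list of file paths (`vcf`, `ped`, `annotations`,
#'   `reference`, `det_d0`, `det_d25`) plus the `truth` tibble (one row per
#'   variant with its expected removal stage).
#' @export
make_quintet_fixture <- function(dir = tempfile("quintet_fixture_"),
                                n_decoys_per_rule = 3,
                                genotype_error_rate = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    t1 <- worked_example_variants()
    t1$chrom <- ifelse(t1$mode == "x_linked", "synX", paste0("syn_", t1$gene))

    decoys <- tidyr::expand_grid(rule = decoy_rules(),
                                 i = seq_len(n_decoys_per_rule))
    decoys$gene <- toupper(paste0("DECOY_", decoys$rule, "_", decoys$i))
    decoys$chrom <- paste0("syn_", decoys$gene)

    rows <- dplyr::bind_rows(
      dplyr::mutate(t1, rule = "worked_example"),
      tibble::tibble(gene = decoys$gene, mode = "hom_rec",
                     consequence = ifelse(decoys$rule == "nonfunctional",
                                          "intronic", "missense"),
                     cdna = NA, protein = NA, origin = "both",
                     brother = ifelse(decoys$rule == "sibling_match", "Hom", "WT"),
                     sister = "WT", maf_pct = NA, rsid = ".",
                     chrom = decoys$chrom, rule = decoys$rule)
    )
    # positions: rows spaced within each contig (the X contig is shared by
    # the X-linked genes)
    rows <- rows |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(pos = 1001L + 500L * (dplyr::row_number() - 1L)) |>
      dplyr::ungroup()

    contig_len <- vapply(unique(rows$chrom), function(cc) {
      max(rows$pos[rows$chrom == cc]) + 1000L
    }, integer(1))
    seqs <- vapply(contig_len, random_contig, character(1))

    # plant homopolymer runs immediately right of the decoy positions
    for (j in which(rows$rule == "homopolymer")) {
      cc <- rows$chrom[j]; p <- rows$pos[j]
      run_base <- sample(c("A", "C", "G", "T"), 1)
      substr(seqs[[cc]], p + 1, p + 7) <- strrep(run_base, 7)
    }
    rows$ref <- toupper(substr(seqs[rows$chrom], rows$pos, rows$pos))
    rows$alt <- vapply(rows$ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       character(1))
    rows$variant_key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":")

    gt <- quintet_genotype_strings(rows)
    if (genotype_error_rate > 0) {
      flip <- matrix(stats::runif(length(gt)) < genotype_error_rate,
                     nrow = nrow(gt), dimnames = dimnames(gt))
      gt[flip] <- sample(c("0/0", "0/1", "1/1"), sum(flip), replace = TRUE)
    }
    dp <- matrix(30, nrow(rows), 5, dimnames = list(NULL, quintet_samples()))
    dp[rows$rule == "depth", "II.3"] <- 9
    gq <- matrix(99, nrow(rows), 5, dimnames = list(NULL, quintet_samples()))

    paths <- list(
      vcf = file.path(dir, "quintet.vcf"),
      ped = file.path(dir, "quintet.ped"),
      annotations = file.path(dir, "annotations.tsv"),
      reference = file.path(dir, "reference.fa"),
      det_d0 = file.path(dir, "det_d0.tsv"),
      det_d25 = file.path(dir, "det_d25.tsv")
    )

    write_reference(seqs, paths$reference)
    write_fixture_vcf(rows, gt, dp, gq, contig_len, paths$vcf)
    writeLines(c("5H\tI.1\t0\t0\t1\t1",
                 "5H\tI.2\t0\t0\t2\t1",
                 "5H\tII.1\tI.1\tI.2\t1\t1",
                 "5H\tII.2\tI.1\tI.2\t2\t1",
                 "5H\tII.3\tI.1\tI.2\t1\t2"), paths$ped)

    maf <- ifelse(is.na(rows$maf_pct), 0, rows$maf_pct / 100)
    maf[rows$rule == "common_maf"] <- 0.05
    ann <- tibble::tibble(
      CHROM = rows$chrom, POS = rows$pos, REF = rows$ref, ALT = rows$alt,
      GENE = rows$gene, TRANSCRIPT = NA_character_,
      CONSEQUENCE = rows$consequence,
      # exome-server-era emulation for the printed variants only: capped
      # below the recessive threshold; decoys keep their true frequency
      MAF_ESP = ifelse(rows$rule == "worked_example", pmin(maf, 0.029), maf),
      MAF_1KG = ifelse(rows$rule == "worked_example", pmin(maf, 0.029), maf),
      MAF_GNOMAD = maf,
      CADD = ifelse(rows$consequence == "missense", 25.0, NA_real_),
      INTERNAL_COUNT = ifelse(rows$rule == "internal_cohort", 6L, 0L),
      PLI = NA_real_, REGULATORY = rows$consequence %in%
        c("promoter", "encode_tfbs", "enhancer")
    )
    readr::write_tsv(ann, paths$annotations, na = "")

    det <- fixture_det_tables(unique(t1$gene), decoys)
    readr::write_tsv(det$d0, paths$det_d0)
    readr::write_tsv(det$d25, paths$det_d25)

    expected_stage <- dplyr::case_when(
      rows$rule == "worked_example" ~ "survived",
      rows$rule == "depth" ~ "qc_depth",
      rows$rule == "homopolymer" ~ "qc_homopolymer",
      rows$rule == "internal_cohort" ~ "qc_internal_cohort",
      rows$rule == "common_maf" ~ "not_rare",
      rows$rule == "nonfunctional" ~ "not_functional",
      rows$rule == "sibling_match" ~ "sibling_excluded",
      TRUE ~ "survived"  # DET decoys survive the genetic cascade
    )
    truth <- tibble::tibble(variant_key = rows$variant_key, gene = rows$gene,
                            rule = rows$rule, expected_stage = expected_stage)
    invisible(c(paths, list(truth = truth)))
  })
}

# printed genotypes -> GT strings for the five quintet members
quintet_genotype_strings <- function(rows) {
  n <- nrow(rows)
  gt <- matrix("0/0", n, 5, dimnames = list(NULL, quintet_samples()))
  for (i in seq_len(n)) {
    xlinked <- rows$mode[i] == "x_linked"
    sib_code <- function(code, male) {
      switch(code,
             WT = if (male && xlinked) "0" else "0/0",
             Het = "0/1",
             Hom = if (male && xlinked) "1" else "1/1")
    }
    gt[i, "II.1"] <- sib_code(rows$brother[i], male = TRUE)
    gt[i, "II.2"] <- sib_code(rows$sister[i], male = FALSE)
    if (xlinked) {
      gt[i, "II.3"] <- "1"
      gt[i, "I.1"] <- "0"
      gt[i, "I.2"] <- "0/1"
    } else if (rows$origin[i] == "both") {
      gt[i, "II.3"] <- "1/1"
      gt[i, "I.1"] <- "0/1"
      gt[i, "I.2"] <- "0/1"
    } else {
      gt[i, "II.3"] <- "0/1"
      gt[i, "I.1"] <- if (rows$origin[i] == "paternal") "0/1" else "0/0"
      gt[i, "I.2"] <- if (rows$origin[i] == "maternal") "0/1" else "0/0"
    }
  }
  gt
}

write_fixture_vcf <- function(rows, gt, dp, gq, contig_len, path) {
  samples <- quintet_samples()
  ord <- order(rows$chrom, rows$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_len), contig_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(ord, function(i) {
    cells <- paste(gt[i, samples], dp[i, samples], gq[i, samples], sep = ":")
    paste(c(rows$chrom[i], rows$pos[i], rows$rsid[i], rows$ref[i], rows$alt[i],
            "100", "PASS", ".", "GT:DP:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

fixture_det_tables <- function(candidate_genes, decoys) {
  concordant_rows <- function(genes, lfc = -1.5) {
    tidyr::expand_grid(gene = genes,
                       comparison = c("proband_vs_mother", "proband_vs_father")) |>
      dplyr::mutate(log2fc = lfc, adjusted_p = 0.001)
  }
  discordant_genes <- unique(decoys$gene[decoys$rule == "det_discordant"])
  onetp_genes <- unique(decoys$gene[decoys$rule == "det_missing"])
  discordant_rows <- tidyr::expand_grid(
    gene = discordant_genes,
    comparison = c("proband_vs_mother", "proband_vs_father")) |>
    dplyr::mutate(log2fc = ifelse(.data$comparison == "proband_vs_mother", -1.5, 1.5),
                  adjusted_p = 0.001)
  null_rows <- tidyr::expand_grid(
    gene = paste0("NULLGENE_", 1:5),
    comparison = c("proband_vs_mother", "proband_vs_father")) |>
    dplyr::mutate(log2fc = 0.1, adjusted_p = 0.8)
  d0 <- dplyr::bind_rows(concordant_rows(candidate_genes),
                         concordant_rows(onetp_genes),
                         discordant_rows, null_rows)
  d25 <- dplyr::bind_rows(concordant_rows(candidate_genes),
                          discordant_rows, null_rows)
  list(d0 = d0, d25 = d25)
}
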