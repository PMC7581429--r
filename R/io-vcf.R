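#' Read a multi-sample VCF into a tidy genotype table
#'
#' Parses a VCF (v4.x, plain or gzipped) and returns one row per
#' (variant, sample) pair. Multi-allelic records are split into biallelic
#' records before anything else, because every downstream threshold
#' (population frequency, CADD, genotype class) is defined per alternate
#' allele. For a sample whose genotype carries a different alternate allele
#' than the one a split record represents, the dosage for that record is the
#' count of the represented allele only and `other_alt` is set, so the sample
#' is treated as a non-carrier of the split allele.
#'
#' Haploid calls (e.g. male X) are kept as single-allele genotypes:
#' `allele2` is `NA` while `allele1` is observed, and `hemizygous` is `TRUE`.
#' A fully missing call has both allele columns `NA` and `missing = TRUE`.
#'
#' @param path Path to a VCF file with a GT FORMAT field; DP and GQ are
#'   optional and stored as 0 with `depth_missing`/`gq_missing` flags when
#'   absent.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples returned. Requesting an absent sample is an error that lists the
#'   samples present.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `filter`, `variant_key`, `sample`, `allele1`, `allele2`, `dosage`,
#'   `missing`, `hemizygous`, `other_alt`, `phased`, `depth`,
#'   `depth_missing`, `gq`, `gq_missing`.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) {
    samples <- all_samples
  } else {
    absent <- setdiff(samples, all_samples)
    if (length(absent) > 0) {
      stop("Sample(s) not in VCF: ", paste(absent, collapse = ", "),
           ". Available: ", paste(all_samples, collapse = ", "), call. = FALSE)
    }
  }
  n_rec <- nrow(fix)
  gt_raw <- extract_format(v, "GT")
  has_dp <- any(grepl("\\bDP\\b", v@gt[, "FORMAT"]))
  has_gq <- any(grepl("\\bGQ\\b", v@gt[, "FORMAT"]))
  dp_raw <- if (has_dp) extract_format(v, "DP") else NULL
  gq_raw <- if (has_gq) extract_format(v, "GQ") else NULL

  out <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    gts <- unname(gt_raw[i, samples])
    parsed <- parse_gt(gts)
    dp <- if (has_dp) unname(suppressWarnings(as.numeric(dp_raw[i, samples]))) else rep(NA_real_, length(samples))
    gq <- if (has_gq) unname(suppressWarnings(as.numeric(gq_raw[i, samples]))) else rep(NA_real_, length(samples))
    dp_miss <- is.na(dp)
    gq_miss <- is.na(gq)
    per_alt <- lapply(seq_along(alts), function(a) {
      d1 <- as.integer(!is.na(parsed$a1) & parsed$a1 == a)
      d2 <- as.integer(!is.na(parsed$a2) & parsed$a2 == a)
      tibble::tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
        ref = ref,
        alt = alts[a],
        filter = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
        sample = samples,
        allele1 = parsed$a1,
        allele2 = parsed$a2,
        dosage = ifelse(parsed$missing, NA_integer_, d1 + d2),
        missing = parsed$missing,
        hemizygous = parsed$hemi,
        other_alt = !parsed$missing &
          ((!is.na(parsed$a1) & parsed$a1 != 0L & parsed$a1 != a) |
             (!is.na(parsed$a2) & parsed$a2 != 0L & parsed$a2 != a)),
        phased = parsed$phased,
        depth = ifelse(dp_miss, 0, dp),
        depth_missing = dp_miss,
        gq = ifelse(gq_miss, 0, gq),
        gq_missing = gq_miss
      )
    })
    out[[i]] <- dplyr::bind_rows(per_alt)
  }
  res <- dplyr::bind_rows(out)
  res$variant_key <- paste(res$chrom, res$pos, res$ref, res$alt, sep = ":")
  dplyr::relocate(res, "variant_key", .after = "filter")
}

# FORMAT-field extraction via vcfR; returns a records x samples character matrix
extract_format <- function(v, element) {
  m <- vcfR::extract.gt(v, element = element, as.numeric = FALSE, convertNA = FALSE)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  rownames(m) <- NULL
  m
}

# Parse GT strings ("0/1", "0|1", "1", ".", "./.") into allele indices.
parse_gt <- function(gts) {
  gts[is.na(gts)] <- "."
  phased <- grepl("|", gts, fixed = TRUE)
  parts <- strsplit(gts, "[/|]")
  a1 <- vapply(parts, function(p) if (length(p) >= 1 && p[1] != ".") suppressWarnings(as.integer(p[1])) else NA_integer_, integer(1))
  a2 <- vapply(parts, function(p) if (length(p) >= 2 && p[2] != ".") suppressWarnings(as.integer(p[2])) else NA_integer_, integer(1))
  hemi <- vapply(parts, function(p) length(p) == 1 && p[1] != ".", logical(1))
  missing <- is.na(a1) & is.na(a2)
  list(a1 = a1, a2 = a2, hemi = hemi, missing = missing, phased = phased)
}

#' Write a tidy genotype table back to a VCF file
#'
#' Formats the biallelic subset produced by [read_vcf()] as VCF v4.2 text with
#' GT:DP:GQ genotype fields. Records already split from multi-allelic sites
#' are written as separate biallelic records (the original record is not
#' reassembled). Genotypes, DP, GQ and FILTER round-trip bit-exactly through
#' [read_vcf()] on this subset.
#'
#' @param gt_tbl Tidy genotype tibble as returned by [read_vcf()].
#' @param path Output path (plain text).
#' @param contig_lengths Optional named integer vector of contig lengths for
#'   the header; inferred from maximum positions when absent.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt_tbl, path, contig_lengths = NULL) {
  samples <- unique(gt_tbl$sample)
  site <- dplyr::distinct(gt_tbl, .data$chrom, .data$pos, .data$id, .data$ref,
                          .data$alt, .data$filter, .data$variant_key)
  site <- dplyr::arrange(site, .data$chrom, .data$pos, .data$alt)
  if (is.null(contig_lengths)) {
    cl <- tapply(site$pos, site$chrom, max)
    contig_lengths <- stats::setNames(as.integer(cl) + 1000L, names(cl))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths), contig_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
  fmt_one <- function(a1, a2, hemi, phased, dp, gq) {
    sep <- ifelse(phased, "|", "/")
    gt <- ifelse(is.na(a1) & is.na(a2), ifelse(hemi, ".", "./."),
          ifelse(hemi | is.na(a2), as.character(a1),
                 paste0(a1, sep, a2)))
    paste(gt, as.integer(round(dp)), as.integer(round(gq)), sep = ":")
  }
  body <- vapply(seq_len(nrow(site)), function(i) {
    rows <- gt_tbl[gt_tbl$variant_key == site$variant_key[i], ]
    rows <- rows[match(samples, rows$sample), ]
    cells <- fmt_one(rows$allele1, rows$allele2, rows$hemizygous, rows$phased,
                     rows$depth, rows$gq)
    paste(c(site$chrom[i], site$pos[i], site$id[i], site$ref[i], site$alt[i],
            ".", site$filter[i], ".", "GT:DP:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
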