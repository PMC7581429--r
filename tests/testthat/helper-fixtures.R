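# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# the packaged worked-example quintet fixture (decoys included)
get_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    .fixture_env$fx <- make_quintet_fixture(seed = 42)
  }
  .fixture_env$fx
}

get_fixture_gt <- function() {
  if (is.null(.fixture_env$gt)) {
    .fixture_env$gt <- read_vcf(get_fixture()$vcf)
  }
  .fixture_env$gt
}

get_fixture_ped <- function() {
  if (is.null(.fixture_env$ped)) {
    .fixture_env$ped <- read_pedigree(get_fixture()$ped)
  }
  .fixture_env$ped
}

get_fixture_ann <- function() {
  if (is.null(.fixture_env$ann)) {
    .fixture_env$ann <- read_annotations(get_fixture()$annotations)
  }
  .fixture_env$ann
}

# independent brute-force enumeration oracle for the Hardy-Weinberg exact
# test: probabilities of every attainable heterozygote count conditional on
# the allele counts, from the closed-form factorial expression
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    rare_hom <- (n_minor - h) / 2
    common_hom <- n - h - rare_hom
    lgamma(n + 1) - lgamma(rare_hom + 1) - lgamma(h + 1) - lgamma(common_hom + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# writes a small VCF from header+body strings for degenerate-input tests
write_mini_vcf <- function(body_lines, samples = c("S1", "S2"),
                           contigs = c(ctg1 = 5000L)) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

# genotype tibble for one cohort variant from explicit dosages
cohort_gt_tbl <- function(dosages, gq = 99, filter = "PASS", chrom = "c1",
                          pos = 100L) {
  n <- length(dosages)
  tibble::tibble(
    chrom = chrom, pos = pos, id = ".", ref = "A", alt = "G", filter = filter,
    variant_key = paste(chrom, pos, "A", "G", sep = ":"),
    sample = sprintf("S%03d", seq_len(n)),
    allele1 = ifelse(is.na(dosages), NA_integer_, as.integer(dosages >= 1)),
    allele2 = ifelse(is.na(dosages), NA_integer_, as.integer(dosages == 2)),
    dosage = as.integer(dosages),
    missing = is.na(dosages), hemizygous = FALSE, other_alt = FALSE,
    phased = FALSE, depth = 30, depth_missing = FALSE,
    gq = rep_len(gq, n), gq_missing = FALSE
  )
}
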