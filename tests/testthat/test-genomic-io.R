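test_that("a plain multi-sample VCF round-trips through read and write", {
  path <- write_mini_vcf(c(
    "ctg1\t100\trs1\tA\tG\t50\tPASS\t.\tGT:DP:GQ\t0/1:30:99\t0/0:12:80",
    "ctg1\t200\t.\tC\tT\t50\tq10\t.\tGT:DP:GQ\t1/1:25:60\t./.:0:0"
  ))
  gt <- read_vcf(path)
  expect_equal(nrow(gt), 4)  # 2 records x 2 samples
  expect_equal(sort(unique(gt$variant_key)), c("ctg1:100:A:G", "ctg1:200:C:T"))
  expect_equal(gt$dosage[gt$variant_key == "ctg1:100:A:G"], c(1L, 0L))
  expect_true(gt$missing[gt$sample == "S2" & gt$pos == 200])
  expect_equal(unique(gt$filter[gt$pos == 200]), "q10")

  out <- tempfile(fileext = ".vcf")
  write_vcf(gt, out)
  gt2 <- read_vcf(out)
  cols <- c("chrom", "pos", "ref", "alt", "filter", "variant_key", "sample",
            "allele1", "allele2", "dosage", "missing", "depth", "gq")
  expect_equal(as.data.frame(gt2[cols]), as.data.frame(gt[cols]))
})

test_that("multi-allelic records split per alt with the full diploid GT remap", {
  # enumeration oracle: every diploid GT over two alts, dosage of each alt
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  oracle <- function(gt, alt_idx) {
    a <- as.integer(strsplit(gt, "/")[[1]])
    sum(a == alt_idx)
  }
  body <- paste0("ctg1\t100\t.\tA\tG,T\t50\tPASS\t.\tGT:DP:GQ\t",
                 paste(paste0(gts, ":30:99"), collapse = "\t"))
  path <- write_mini_vcf(body, samples = paste0("S", 1:6))
  gt <- read_vcf(path)
  expect_equal(nrow(gt), 12)  # 2 split records x 6 samples
  for (alt_i in 1:2) {
    alt_base <- c("G", "T")[alt_i]
    sub <- gt[gt$alt == alt_base, ]
    sub <- sub[match(paste0("S", 1:6), sub$sample), ]
    expect_equal(sub$dosage, vapply(gts, oracle, integer(1), alt_idx = alt_i),
                 ignore_attr = TRUE)
  }
  # conservation: per-sample total alt dosage across split records equals
  # the total alt-allele count of the original genotype
  tot <- tapply(gt$dosage, gt$sample, sum)
  expect_equal(as.integer(tot[paste0("S", 1:6)]),
               vapply(gts, function(g) sum(as.integer(strsplit(g, "/")[[1]]) > 0),
                      integer(1)),
               ignore_attr = TRUE)
  # the het-alt genotype 1/2 is flagged as carrying the other alt
  expect_true(all(gt$other_alt[gt$sample == "S5"]))
})

test_that("records lacking DP store depth 0 and flag it unavailable", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "ctg1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"
  ), path)
  gt <- read_vcf(path)
  expect_equal(gt$depth, 0)
  expect_true(gt$depth_missing)
  expect_true(gt$gq_missing)
})

test_that("requesting an absent sample names the available ones", {
  path <- write_mini_vcf("ctg1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP:GQ\t0/1:30:99\t0/0:12:80")
  expect_error(read_vcf(path, samples = c("S1", "NOPE")), "S2")
})

test_that("the quintet PED yields the proband and two unaffected siblings", {
  ped <- get_fixture_ped()
  expect_equal(ped$proband_id, "II.3")
  expect_equal(ped$father_id, "I.1")
  expect_equal(ped$mother_id, "I.2")
  expect_setequal(ped$sibling_ids, c("II.1", "II.2"))
  expect_equal(proband_sex(ped), "male")
})

test_that("degenerate pedigrees error or come back sibling-free", {
  single <- tempfile()
  writeLines("F1\tP1\t0\t0\t1\t2", single)
  expect_error(read_pedigree(single), "both parents")

  trio <- tempfile()
  writeLines(c("F1\tF\t0\t0\t1\t1", "F1\tM\t0\t0\t2\t1",
               "F1\tC\tF\tM\t1\t2"), trio)
  ped <- read_pedigree(trio)
  expect_equal(ped$proband_id, "C")
  expect_length(ped$sibling_ids, 0)

  # two affected offspring need an explicit override
  duo <- tempfile()
  writeLines(c("F1\tF\t0\t0\t1\t1", "F1\tM\t0\t0\t2\t1",
               "F1\tC1\tF\tM\t1\t2", "F1\tC2\tF\tM\t2\t2"), duo)
  expect_error(read_pedigree(duo), "proband_id")
  expect_equal(read_pedigree(duo, proband_id = "C2")$proband_id, "C2")
})

test_that("DET tables collapse duplicates to the smallest adjusted p and validate", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcomparison\tlog2fc\tadjusted_p",
               "A\tproband_vs_mother\t-2.0\t0.01",
               "A\tproband_vs_mother\t-1.5\t0.2",
               "B\tproband_vs_father\t1.1\t0.03"), path)
  det <- read_det_table(path, "d25")
  expect_equal(nrow(det), 2)
  expect_equal(det$adjusted_p[det$gene == "A"], 0.01)
  expect_equal(unique(det$timepoint), "d25")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcomparison\tlog2fc\tadjusted_p",
               "A\tproband_vs_mother\t-2.0\t1.5"), bad)
  expect_error(read_det_table(bad, "d0"), "adjusted_p")

  nocol <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tadjusted_p", "A\t1\t0.1"), nocol)
  expect_error(read_det_table(nocol, "d0"), "comparison")
})

test_that("reference flanks respect contig boundaries and match the sequence", {
  fa <- tempfile(fileext = ".fa")
  write_reference(c(ctgA = "ACGTACGTACGT"), fa)
  fl <- fetch_flank(fa, "ctgA", 1, 6)
  expect_equal(fl$left, "")
  expect_equal(fl$right, "CGTACG")
  fl <- fetch_flank(fa, "ctgA", 7, 3)
  expect_equal(fl$left, "TAC")   # positions 4-6
  expect_equal(fl$right, "TAC")  # positions 8-10
  expect_error(fetch_flank(fa, "nope", 1, 5), "not found")
  expect_error(fetch_flank(fa, "ctgA", 99, 5), "outside contig")
})
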