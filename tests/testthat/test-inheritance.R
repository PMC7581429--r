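# builds a family_genotypes()-shaped tibble directly from dosage vectors
fam_row <- function(key, chrom, d_pro, d_fat, d_mot, sibs = list(),
                    hemi_pro = FALSE, gene = "G") {
  tibble::tibble(
    variant_key = key, chrom = chrom, pos = 1L, ref = "A", alt = "G",
    filter = "PASS",
    d_pro = d_pro, hemi_pro = hemi_pro, depth_pro = 30, depthmiss_pro = FALSE,
    d_fat = d_fat, hemi_fat = FALSE, depth_fat = 30, depthmiss_fat = FALSE,
    d_mot = d_mot, hemi_mot = FALSE, depth_mot = 30, depthmiss_mot = FALSE,
    sib_dosage = list(unlist(sibs)),
    sib_hemi = list(stats::setNames(rep(FALSE, length(sibs)), names(sibs))),
    sib_depth_ok = list(stats::setNames(rep(TRUE, length(sibs)), names(sibs))),
    gene = gene
  )
}

quintet_ped <- function() {
  new_pedigree(tibble::tibble(
    sample_id = c("I.1", "I.2", "II.1", "II.2", "II.3"),
    father_id = c(NA, NA, "I.1", "I.1", "I.1"),
    mother_id = c(NA, NA, "I.2", "I.2", "I.2"),
    sex = c("male", "female", "male", "female", "male"),
    affected = c("unaffected", "unaffected", "unaffected", "unaffected", "affected")
  ))
}

test_that("de novo calls need carrier proband, hom-ref parents and depth", {
  ped <- quintet_ped()
  ann <- tibble::tibble(variant_key = "v1", maf_esp = 0, maf_1kg = 0,
                        maf_gnomad = 0)
  dn <- function(fam) classify_de_novo(fam, ann)$de_novo
  expect_true(dn(fam_row("v1", "c1", 1, 0, 0)))
  expect_false(dn(fam_row("v1", "c1", 1, 0, 1)))  # mother carries it
  # a missing parental genotype is never de novo, and is logged
  res <- classify_de_novo(fam_row("v1", "c1", 1, NA, 0), ann)
  expect_false(res$de_novo)
  expect_equal(res$note, "parent genotype missing")
  # parental depth below threshold blocks the call (dropout guard)
  low <- fam_row("v1", "c1", 1, 0, 0); low$depth_fat <- 9
  expect_false(dn(low))
})

test_that("the three-variant compound-het worked example is retained", {
  # maternal missense (sibs WT), paternal missense (both sibs het),
  # paternal promoter (sibs WT): no sibling carries a maternal variant
  ped <- quintet_ped()
  fam <- dplyr::bind_rows(
    fam_row("m1", "c1", 1, 0, 1, list(`II.1` = 0, `II.2` = 0), gene = "HSPG2"),
    fam_row("p1", "c1", 1, 1, 0, list(`II.1` = 1, `II.2` = 1), gene = "HSPG2"),
    fam_row("p2", "c1", 1, 1, 0, list(`II.1` = 0, `II.2` = 0), gene = "HSPG2")
  )
  call <- classify_gene_recessive(fam, ped)
  expect_equal(call$mode, "compound_heterozygous")
  expect_setequal(call$variant_keys[[1]], c("m1", "p1", "p2"))
  expect_equal(unname(call$origins[[1]][c("m1", "p1")]), c("maternal", "paternal"))
})

test_that("homozygous recessive is retained when siblings are at most het", {
  ped <- quintet_ped()
  fam <- fam_row("v", "c21", 2, 1, 1, list(`II.1` = 0, `II.2` = 1), gene = "SIK1")
  call <- classify_gene_recessive(fam, ped)
  expect_equal(call$mode, "homozygous_recessive")
  # a homozygous sibling reproduces the configuration and voids the call
  fam2 <- fam_row("v", "c21", 2, 1, 1, list(`II.1` = 2, `II.2` = 0), gene = "SIK1")
  res <- classify_gene_recessive(fam2, ped)
  expect_false(varcascade:::is_call(res))
  expect_true(res$sibling_excluded)
})

test_that("X-linked calls follow the hemizygous worked examples", {
  ped <- quintet_ped()
  # hemizygous proband, carrier mother, non-carrier father, brother WT,
  # sister het carrier
  for (g in c("ELF4", "HS6ST2")) {
    fam <- fam_row(paste0(g, ":v"), "synX", 1, 0, 1,
                   list(`II.1` = 0, `II.2` = 1), hemi_pro = TRUE, gene = g)
    call <- classify_gene_recessive(fam, ped)
    expect_equal(call$mode, "x_linked_recessive")
    expect_true(call$hemizygous)
  }
  # a hemizygous-alternate unaffected brother voids the call
  fam <- fam_row("v", "synX", 1, 0, 1, list(`II.1` = 1, `II.2` = 0),
                 hemi_pro = TRUE)
  res <- classify_gene_recessive(fam, ped)
  expect_false(varcascade:::is_call(res))
  expect_true(res$sibling_excluded)
  # a diploid-coded male X het is inconsistent and dropped
  fam <- fam_row("v", "synX", 1, 0, 1, list(`II.1` = 0, `II.2` = 0),
                 hemi_pro = FALSE)
  expect_false(varcascade:::is_call(classify_gene_recessive(fam, ped)))
})

test_that("sibling exclusion requires the full compound configuration", {
  # brute force over all 3^k sibling genotype combinations: the call is
  # voided iff the sibling could assemble a maternal+paternal pair from the
  # variants it carries (two distinct variants, both-het variants fill
  # either side)
  ped_one_sib <- new_pedigree(tibble::tibble(
    sample_id = c("F", "M", "S", "P"),
    father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "female", "male"),
    affected = c("unaffected", "unaffected", "unaffected", "affected")
  ))
  origins <- list(
    c("maternal", "paternal"),
    c("maternal", "paternal", "both"),
    c("maternal", "maternal", "paternal")
  )
  oracle_voids <- function(org, carried) {
    idx <- which(carried)
    if (length(idx) < 2) return(FALSE)
    for (i in idx) for (j in idx) {
      if (i == j) next
      if (org[i] %in% c("maternal", "both") && org[j] %in% c("paternal", "both")) {
        return(TRUE)
      }
    }
    FALSE
  }
  for (org in origins) {
    k <- length(org)
    combos <- expand.grid(rep(list(0:2), k))
    for (r in seq_len(nrow(combos))) {
      sib <- as.integer(combos[r, ])
      fam <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
        fam_row(paste0("v", i), "c1", 1,
                d_fat = ifelse(org[i] %in% c("paternal", "both"), 1, 0),
                d_mot = ifelse(org[i] %in% c("maternal", "both"), 1, 0),
                sibs = list(S = sib[i]))
      }))
      res <- classify_gene_recessive(fam, ped_one_sib)
      if (oracle_voids(org, sib >= 1)) {
        expect_false(varcascade:::is_call(res))
      } else {
        expect_equal(res$mode, "compound_heterozygous")
      }
    }
  }
})

test_that("a both-parent-het variant cannot anchor a compound pair alone", {
  ped <- quintet_ped()
  fam <- fam_row("v", "c1", 1, 1, 1, list(`II.1` = 0, `II.2` = 0))
  expect_false(varcascade:::is_call(classify_gene_recessive(fam, ped)))
  # but two both-het variants can pair
  fam2 <- dplyr::bind_rows(
    fam_row("v1", "c1", 1, 1, 1, list(`II.1` = 0, `II.2` = 0)),
    fam_row("v2", "c1", 1, 1, 1, list(`II.1` = 0, `II.2` = 0))
  )
  call <- classify_gene_recessive(fam2, ped)
  expect_equal(call$mode, "compound_heterozygous")
  expect_true(call$ambiguous)
})

test_that("inherited LoF retention needs pLI strictly above 0.75", {
  ann <- tibble::tibble(consequence = c("frameshift", "frameshift", "stop_gain",
                                        "missense"),
                        pli = c(0.99, 0.75, 0.2, 0.99))
  expect_equal(inherited_lof_retention(ann), c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(inherited_lof_retention(tibble::tibble(consequence = "frameshift",
                                                        pli = NA_real_)),
                 "pLI missing")
})

test_that("planted modes are recovered exactly on random quintets", {
  modes_pool <- c("de_novo", "homozygous_recessive", "compound_heterozygous",
                  "x_linked_recessive", "null_single_parent", "null_same_side",
                  "null_both_het")
  for (s in 1:25) {
    modes <- withr::with_seed(3000 + s, sample(modes_pool, 8, replace = TRUE))
    sim <- simulate_quintet(modes, seed = 3000 + s)
    res <- run_family_cascade(sim$gt, sim$pedigree, sim$annotations)
    called <- stats::setNames(res$calls$mode, res$calls$gene)
    for (i in seq_len(nrow(sim$truth))) {
      g <- sim$truth$gene[i]; m <- sim$truth$mode[i]
      if (startsWith(m, "null")) {
        expect_false(g %in% names(called), info = paste(s, g, m))
      } else {
        expect_equal(unname(called[g]), m, info = paste(s, g, m))
      }
    }
  }
})

test_that("adding an unaffected sibling can only remove calls, never add them", {
  withr::with_seed(77, {
    for (rep in 1:30) {
      org <- sample(c("maternal", "paternal", "both"), sample(2:4, 1), replace = TRUE)
      k <- length(org)
      sib1 <- sample(0:2, k, replace = TRUE)
      ped0 <- new_pedigree(tibble::tibble(
        sample_id = c("F", "M", "P"), father_id = c(NA, NA, "F"),
        mother_id = c(NA, NA, "M"), sex = c("male", "female", "male"),
        affected = c("unaffected", "unaffected", "affected")))
      ped1 <- new_pedigree(tibble::tibble(
        sample_id = c("F", "M", "S", "P"), father_id = c(NA, NA, "F", "F"),
        mother_id = c(NA, NA, "M", "M"), sex = c("male", "female", "female", "male"),
        affected = c("unaffected", "unaffected", "unaffected", "affected")))
      mk <- function(sibs) dplyr::bind_rows(lapply(seq_len(k), function(i) {
        fam_row(paste0("v", i), "c1", 1,
                d_fat = ifelse(org[i] %in% c("paternal", "both"), 1, 0),
                d_mot = ifelse(org[i] %in% c("maternal", "both"), 1, 0),
                sibs = sibs[[i]])
      }))
      fam0 <- mk(rep(list(list()), k))
      fam1 <- mk(lapply(seq_len(k), function(i) list(S = sib1[i])))
      r0 <- classify_gene_recessive(fam0, ped0)
      r1 <- classify_gene_recessive(fam1, ped1)
      if (varcascade:::is_call(r1)) expect_true(varcascade:::is_call(r0))
    }
  })
})
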