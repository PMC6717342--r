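test_that("genotype complement is an involution with the stated fixed points", {
  expect_identical(gt_complement(c("0_0", "0_1", "1_1")),
                   c("1_1", "0_1", "0_0"))
  set.seed(1)
  for (i in 1:20) {
    x <- sample(c("0_0", "0_1", "1_1"), 50, replace = TRUE)
    expect_identical(gt_complement(gt_complement(x)), x)
  }
  expect_error(gt_complement("0/1"), "invalid genotype")
})

test_that("genotype_matrix enforces its invariants", {
  gm <- th_tiny_gm(list(c("0_0", "0_1", "1_1", "0_0"),
                        c("0_1", "0_1", "0_0", "1_1")), 2, 2)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm), c(2L, 4L))

  # out-of-vocabulary cell named in the error
  calls <- gm$calls
  calls["v2", "R1"] <- "0/1"
  expect_error(genotype_matrix(calls, gm$variants, gm$samples),
               "invalid genotype '0/1' for variant v2, sample R1")
  calls["v2", "R1"] <- NA
  expect_error(genotype_matrix(calls, gm$variants, gm$samples),
               "missing genotype call")

  # duplicate keys / samples
  v2 <- gm$variants; v2$key <- c("v1", "v1")
  calls2 <- gm$calls; rownames(calls2) <- c("v1", "v1")
  expect_error(genotype_matrix(calls2, v2, gm$samples), "duplicate variant key")
  s2 <- gm$samples; s2$sample_id <- c("a", "a", "b", "c")
  expect_error(genotype_matrix(gm$calls, gm$variants, s2), "dimnames|duplicate")
})

test_that("matrix_csv loading parses calls and demands full group coverage", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "matrix.csv")
  writeLines(c("key,s1,s2",
               "v1,0_0,0_1",
               "v2,1_1,0_0",
               "v3,0_1,0_1"), path)
  gm <- read_genotype_matrix(path, "matrix_csv",
                             groups = c(s1 = "sensitive", s2 = "resistant"))
  expect_equal(dim(gm), c(3L, 2L))
  expect_identical(gm$calls["v2", "s1"], "1_1")
  expect_error(
    read_genotype_matrix(path, "matrix_csv", groups = c(s1 = "sensitive")),
    "without group assignment: s2")

  writeLines(c("key,s1,s2", "v1,0_0,?"), path)
  expect_error(
    read_genotype_matrix(path, "matrix_csv",
                         groups = c(s1 = "sensitive", s2 = "resistant")),
    "invalid genotype '\\?' for variant v1, sample s2")
})

test_that("VCF GT fields map phase-insensitively and multiallelics split", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "calls.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/2\t0/2"
  ), path)
  gm <- read_genotype_matrix(path, "vcf",
                             groups = c(s1 = "sensitive", s2 = "resistant"))
  expect_equal(nrow(gm$calls), 3L)  # multiallelic row split in two
  expect_identical(unname(gm$calls["chr1:100:A:G", ]), c("0_1", "1_1"))
  # per-alternate-allele dosage on the split records
  expect_identical(unname(gm$calls["chr1:200:C:T", ]), c("0_1", "0_0"))
  expect_identical(unname(gm$calls["chr1:200:C:G", ]), c("0_1", "0_1"))
  expect_identical(gm$variants$rsid[gm$variants$key == "chr1:100:A:G"], "rs1")
})

test_that("population frequencies load, range-check and report absences", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "popfreq.csv")
  writeLines(c("key,alt_af", "v1,0.25", "rs99,0.4"), path)
  freqs <- read_population_frequencies(path)
  expect_equal(unname(freqs["v1"]), 0.25)
  expect_true(is.na(lookup_alt_af(freqs, "v2")))
  # rsID alias fallback after the canonical key misses
  expect_equal(lookup_alt_af(freqs, c("v1", "vX"), rsids = c(NA, "rs99")),
               c(0.25, 0.4))

  writeLines(c("key,alt_af", "v1,1.25"), path)
  expect_error(read_population_frequencies(path), "outside \\[0, 1\\]")
})

test_that("tables round-trip through their writer/reader pairs", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    ct <- th_random_ct(10, seed)
    p <- file.path(dir, sprintf("ct%d.csv", seed))
    write_table(ct, p)
    back <- read_contingency_table(p)
    expect_equal(as.data.frame(back), as.data.frame(ct), tolerance = 1e-12)
  }
  # gene rank table with the published column roles
  grt <- data.frame(gene = c("A", "B", "C"), rank = 1:3,
                    rp = c(1, 2.5, 3), fc = c(0.2, 0.5, 0.8),
                    pfp = c(1e-4, 5e-3, 0.04), p_value = c(1e-6, 1e-4, 4e-3))
  p <- file.path(dir, "grt.csv")
  write_table(grt, p)
  expect_equal(as.data.frame(read_gene_rank_table(p))[-1],
               grt[-1], tolerance = 1e-12)
  # empty table -> header-only file
  write_table(grt[0, ], p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(nrow(read_gene_rank_table(p)), 0L)
})
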