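test_that("theoretical MAF imputation fills only absent frequencies", {
  gm <- th_tiny_gm(list(c("0_1", "0_0"), c("0_0", "0_1"), c("1_1", "0_1")), 1, 1)
  gm$variants$alt_af <- c(NA, 0.30, NA)
  out <- impute_theoretical_maf(gm, 503)
  expect_equal(out$variants$alt_af, c(1 / 503, 0.30, 1 / 503))
  expect_equal(out$variants$alt_af_imputed, c(TRUE, FALSE, TRUE))
  expect_equal(impute_theoretical_maf(gm, 1000)$variants$alt_af[1], 0.001)
  expect_error(impute_theoretical_maf(gm, 0), "positive integer")
  # imputed values are already MAFs: 1/n < 0.5 never triggers inversion
  oriented <- orient_to_minor_allele(out)
  expect_false(any(oriented$variants$inverted[c(1, 3)]))
})

test_that("minor-allele orientation complements calls at AltAF >= 0.5", {
  gm <- th_tiny_gm(list(c("0_0", "0_1", "1_1"),
                        c("0_0", "0_1", "1_1"),
                        c("0_1", "0_1", "0_0")), 2, 1)
  gm$variants$alt_af <- c(0.7, 0.2, 0.5)
  gm$variants$ref <- c("A", "C", "G")
  gm$variants$alt <- c("G", "T", "A")
  out <- orient_to_minor_allele(gm)
  expect_equal(out$variants$maf, c(0.3, 0.2, 0.5))
  expect_identical(unname(out$calls[1, ]), c("1_1", "0_1", "0_0"))
  expect_identical(unname(out$calls[2, ]), c("0_0", "0_1", "1_1"))
  expect_equal(out$variants$inverted, c(TRUE, FALSE, TRUE))  # 0.5 boundary inverts
  expect_identical(out$variants$ref[1], "G")  # labels swapped
  expect_true(all(out$variants$maf <= 0.5))
  # idempotence
  twice <- orient_to_minor_allele(out)
  expect_identical(twice$calls, out$calls)
  expect_equal(twice$variants$maf, out$variants$maf)
  expect_equal(twice$variants$inverted, out$variants$inverted)

  gm$variants$alt_af <- c(NA, 0.2, 0.5)
  expect_error(orient_to_minor_allele(gm), "need alt_af")
})

test_that("monomorphic pruning removes all-reference rows, keeping order", {
  gm <- th_tiny_gm(list(c("0_1", "0_0"), c("0_0", "0_0"), c("1_1", "0_1")), 1, 1)
  out <- drop_monomorphic(gm)
  expect_identical(out$removed, "v2")
  expect_identical(out$matrix$variants$key, c("v1", "v3"))
  # no monomorphic rows -> identity
  again <- drop_monomorphic(out$matrix)
  expect_length(again$removed, 0)
  expect_identical(again$matrix$calls, out$matrix$calls)
})

test_that("VAF is the minor-allele count over sequenced alleles", {
  # 5 heterozygous carriers among 12 patients -> 5/24, printed as 21%
  calls <- c(rep("0_1", 5), rep("0_0", 7))
  expect_equal(compute_vaf(calls), 5 / 24)
  expect_equal(round(100 * compute_vaf(calls)), 21)
  expect_equal(compute_vaf(rep("0_0", 4)), 0)
  expect_equal(compute_vaf(rep("1_1", 4)), 1)
  expect_error(compute_vaf(character(0)), "empty")
  # in [0,1]; 0 iff all ref-hom, 1 iff all var-hom
  set.seed(42)
  for (i in 1:50) {
    x <- sample(c("0_0", "0_1", "1_1"), 8, replace = TRUE)
    v <- compute_vaf(x)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v == 0, all(x == "0_0"))
    expect_equal(v == 1, all(x == "1_1"))
  }
})

test_that("contingency table rows match hand-enumerated allele counts", {
  # 2 variants, 2 sensitive + 2 resistant, counted by hand:
  # v1: sensitive {0_1, 0_0} -> 1/4; resistant {1_1, 0_1} -> 3/4
  # v2: sensitive {0_0, 0_0} -> 0;   resistant {0_1, 0_0} -> 1/4
  gm <- th_tiny_gm(list(c("0_1", "0_0", "1_1", "0_1"),
                        c("0_0", "0_0", "0_1", "0_0")), 2, 2)
  gm$variants$maf <- c(0.1, 0.2)
  built <- build_contingency_table(gm)
  expect_equal(built$table$vaf_sensitive, c(1 / 4, 0))
  expect_equal(built$table$vaf_resistant, c(3 / 4, 1 / 4))
  expect_equal(built$table$maf_population, c(0.1, 0.2))

  # variant heterozygous in every resistant sample, ref-hom elsewhere
  gm2 <- th_tiny_gm(list(c("0_0", "0_0", "0_1", "0_1")), 2, 2)
  gm2$variants$maf <- 0.05
  row <- build_contingency_table(gm2)$table
  expect_equal(c(row$vaf_sensitive, row$vaf_resistant), c(0, 0.5))

  # 8 and 2 minor alleles over 24 chromosomes: 0.33 vs 0.08
  gm3 <- th_tiny_gm(list(c(rep("0_1", 2), rep("0_0", 10),
                           rep("0_1", 8), rep("0_0", 4))), 12, 12)
  gm3$variants$maf <- 0.25
  row <- build_contingency_table(gm3)$table
  expect_equal(round(row$vaf_resistant, 2), 0.33)
  expect_equal(round(row$vaf_sensitive, 2), 0.08)

  # a group missing entirely is a configuration error
  gm4 <- th_tiny_gm(list(c("0_1", "0_0")), 2, 0)
  gm4$samples$group <- c("sensitive", "sensitive")
  gm4$variants$maf <- 0.1
  expect_error(build_contingency_table(gm4), "group 'resistant' absent")
})

test_that("adjustment workflow counts stay arithmetically consistent", {
  set.seed(99)
  for (i in 1:10) {
    nv <- sample(20:60, 1)
    v <- data.frame(gene = "G1", functional_class = "intronic",
                    exonic_subtype = NA, maf = th_maf_spectrum(nv), or = 1,
                    altaf_missing = runif(nv) < 0.2,
                    altaf_major = runif(nv) < 0.25)
    v$altaf_major <- v$altaf_major & !v$altaf_missing
    b <- simulate_cohort(simulation_spec(v, 6, 6, 503, seed = i))
    adj <- th_adjust(b)
    r <- adj$report
    expect_equal(r$n_output, r$n_input - r$n_removed_monomorphic)
    expect_equal(r$n_output, nrow(adj$table))
    expect_equal(r$n_imputed_maf, sum(v$altaf_missing))
    expect_equal(r$n_inverted, sum(v$altaf_major))
    expect_true(all(adj$table$maf_population <= 0.5))
    # every retained row has a variant allele somewhere
    expect_true(all(adj$table$vaf_sensitive + adj$table$vaf_resistant > 0))
  }
})

test_that("drop_missing_af mirrors the no-imputation alternative", {
  gm <- th_tiny_gm(list(c("0_1", "0_0"), c("0_1", "1_1"), c("0_0", "0_1")), 1, 1)
  gm$variants$alt_af <- c(NA, 0.3, NA)
  adj <- adjust_genotype_matrix(gm, drop_missing_af = TRUE)
  expect_equal(adj$removed_missing_af, c("v1", "v3"))
  expect_equal(adj$table$key, "v2")
  expect_equal(adj$report$n_imputed_maf, 0L)
})
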