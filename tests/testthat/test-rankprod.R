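test_that("the protein-altering filter keeps exactly the altering exonic classes", {
  v <- data.frame(
    key = sprintf("v%d", 1:7),
    gene = "G",
    functional_class = c("exonic", "exonic", "intronic", "UTR5",
                         "exonic_splicing", "exonic", "exonic"),
    exonic_subtype = c("synonymous", "frameshift", NA, NA,
                       "non-synonymous", "stop-gain", "non-frameshift"),
    stringsAsFactors = FALSE)
  keep <- filter_protein_altering(v, "protein_altering")
  expect_equal(keep, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(all(filter_protein_altering(v, "all")))
  # exonic record with no subtype is a validation error
  v$exonic_subtype[2] <- NA
  expect_error(filter_protein_altering(v, "protein_altering"),
               "missing exonic_subtype: v2")
  # with_altaf_only keeps observed (non-imputed) AltAF records
  v$exonic_subtype[2] <- "frameshift"
  v$alt_af <- c(0.1, NA, 0.2, 0.3, NA, 0.4, 0.5)
  v$alt_af_imputed <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(filter_protein_altering(v, "with_altaf_only"),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("bootstrap experiments resample patients with replacement, reproducibly", {
  b <- th_rp_cohort(1, planted_or = 5)
  gm <- th_adjust(b)$matrix
  exps <- bootstrap_experiments(gm, "resistant", n_experiments = 2, k = 200,
                                seed = 42)
  expect_length(exps, 2)
  expect_equal(dim(exps[[1]]), c(nrow(gm$calls), 200))
  expect_true(all(exps[[1]] >= 0 & exps[[1]] <= 1))
  # same seed -> identical resample streams
  again <- bootstrap_experiments(gm, "resistant", n_experiments = 2, k = 200,
                                 seed = 42)
  expect_identical(exps, again)
  # mean resampled VAF matches the observed VAF within 3 exact standard
  # errors (each resample VAF is a mean of n draws from the empirical
  # patient-dosage distribution; SE of the k-resample mean follows)
  calls <- gm$calls[, gm$samples$group == "resistant", drop = FALSE]
  dos <- matrix(gt_dosage(calls) / 2, nrow(calls))
  n <- ncol(dos); k <- 200
  obs <- rowMeans(dos)
  v_pop <- rowMeans(dos^2) - obs^2        # population variance over patients
  se <- sqrt(v_pop / (n * k * 2))          # two pooled experiments
  got <- (rowMeans(exps[[1]]) + rowMeans(exps[[2]])) / 2
  poly <- v_pop > 0
  # per-variant 3-SE check; a ~0.3% Gaussian tail leaves room for the
  # occasional excursion across ~100 variants
  expect_gte(mean((abs(got - obs) <= 3 * se + 1e-12)[poly]), 0.97)
  expect_true(all(got[!poly] == obs[!poly]))
})

test_that("gene aggregation implements mean and size-normalized sum", {
  vafs <- c(0.2, 0.4, 0.1)
  genes <- c("A", "A", "B")
  expect_equal(gene_aggregate(vafs, genes, "mean"),
               c(A = 0.3, B = 0.1))
  sizes <- c(A = 1000, B = 500)
  expect_equal(gene_aggregate(vafs, genes, "sum_over_size", sizes),
               c(A = 0.0006, B = 0.0002))
  expect_error(gene_aggregate(vafs, genes, "sum_over_size", c(A = 1000)),
               "missing gene size for: B")
  # matrix input aggregates per resample column
  M <- cbind(c(0.2, 0.4, 0.1), c(0, 0.2, 0.3))
  out <- gene_aggregate(M, genes, "mean")
  expect_equal(out["A", ], c(0.3, 0.1), ignore_attr = TRUE)
})

test_that("the ODDS plug-in estimator matches direct arithmetic and guards", {
  expect_equal(odds_estimator(rep(0.3, 10), 0.3, eps = 1e-6), 1)
  expect_equal(odds_estimator(0.2, 0.01, eps = 1e-6),
               (0.2 * 0.99) / (0.01 * 0.8))  # 24.75
  eps <- 1 / (2 * 12 + 1)
  expect_equal(odds_estimator(rep(0, 5), 0.1, eps = eps),
               eps * 0.9 / (0.1 * (1 - eps)))
  expect_error(odds_estimator(0.2, 0), "strictly inside")
  expect_error(odds_estimator(0.2, 1), "strictly inside")
})

test_that("rank product and permutation p match exhaustive enumeration on a toy", {
  odds1 <- matrix(c(1, 2, 3, 1, 2, 3), 3,
                  dimnames = list(c("g1", "g2", "g3"), NULL))
  odds1[, 2] <- c(2, 1, 3)
  odds2 <- matrix(c(2, 1, 1), 3, 1, dimnames = list(c("g1", "g2", "g3"), NULL))
  got <- rank_product_two_class(odds1, odds2, exhaustive = TRUE)

  # independent oracle: direct loops over both pairings' fold changes
  fc1 <- odds1[, 1] / odds2[, 1]
  fc2 <- odds1[, 2] / odds2[, 1]
  r1 <- rank(fc1); r2 <- rank(fc2)
  rp_obs <- sqrt(r1 * r2)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  null_rp <- c()
  for (a in perms) for (b in perms) null_rp <- c(null_rp, sqrt(a * b))
  x <- vapply(rp_obs, function(r) sum(null_rp <= r + 1e-12), numeric(1))
  p_oracle <- (x + 1) / (36 * 3 + 1)
  pos <- rank(rp_obs, ties.method = "first")
  ord <- order(pos)
  expect_equal(got$gene, names(rp_obs)[ord])
  expect_equal(got$rp, unname(rp_obs[ord]), tolerance = 1e-12)
  expect_equal(got$p_value, unname(p_oracle[ord]), tolerance = 1e-12)
  expect_equal(got$pfp, got$p_value * 3 / got$rank, tolerance = 1e-12)

  # identical values in every pairing: all ranks tie at (G+1)/2
  same1 <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  same2 <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  tied <- rank_product_two_class(same1, same2, n_permutations = 10, seed = 1)
  expect_true(all(tied$rp == 2))
})

test_that("rank product is invariant to experiment order within a class", {
  b <- th_rp_cohort(2, planted_or = 5)
  adj <- th_adjust(b)
  keep <- filter_protein_altering(adj$matrix$variants, "protein_altering")
  sub <- adj$matrix
  sub$calls <- sub$calls[keep, ]; sub$variants <- sub$variants[keep, ]
  genes <- sub$variants$gene
  p_gene <- pmin(pmax(gene_aggregate(sub$variants$maf, genes, "mean"),
                      1 / 503), 0.5)
  exp_s <- bootstrap_experiments(sub, "sensitive", 4, k = 99, seed = 5)
  exp_r <- bootstrap_experiments(sub, "resistant", 4, k = 99, seed = 6)
  odds_s <- experiment_odds(exp_s, genes, p_gene, "mean", eps = 1 / 25)
  odds_r <- experiment_odds(exp_r, genes, p_gene, "mean", eps = 1 / 25)
  a <- rank_product_two_class(odds_s, odds_r, n_permutations = 50, seed = 9)
  bb <- rank_product_two_class(odds_s[, c(3, 1, 4, 2)], odds_r[, c(2, 4, 1, 3)],
                               n_permutations = 50, seed = 9)
  expect_equal(a$rp, bb$rp)
  expect_equal(a$gene, bb$gene)
})

test_that("mean and size-normalized aggregation agree on the top genes", {
  b <- th_rp_cohort(3, planted_or = 10)
  adj <- th_adjust(b)
  r_mean <- rank_genes(adj$matrix, sizes = b$gene_sizes, filter = "protein_altering",
                       agg = "mean", k = 299, n_permutations = 100, seed = 11)
  r_size <- rank_genes(adj$matrix, sizes = b$gene_sizes, filter = "protein_altering",
                       agg = "sum_over_size", k = 299, n_permutations = 100,
                       seed = 11)
  expect_gte(length(intersect(r_mean$gene[1:3], r_size$gene[1:3])), 2)
  expect_equal(r_mean$gene[1], "G01")
  expect_equal(r_size$gene[1], "G01")
})
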