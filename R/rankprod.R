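#' Filter variants entering the gene-ranking test
#'
#' Three modes mirror the selectable inputs of the gene-ranking branch:
#' `protein_altering` (default) keeps exonic / exonic-splicing records
#' whose subtype alters the protein (non-synonymous, frameshift,
#' non-frameshift, stop-gain, stop-loss) and drops synonymous and all
#' non-exonic classes; `all` keeps everything; `with_altaf_only` keeps
#' variants whose reference-panel AltAF was observed rather than imputed.
#'
#' @param variants variant data.frame (from a [genotype_matrix()]).
#' @param mode filter mode.
#' @return logical vector marking retained variants.
#' @export
filter_protein_altering <- function(variants,
                                    mode = c("protein_altering", "all",
                                             "with_altaf_only")) {
  mode <- match.arg(mode)
  if (mode == "all") return(rep(TRUE, nrow(variants)))
  if (mode == "with_altaf_only") {
    imp <- variants$alt_af_imputed
    if (is.null(imp)) imp <- rep(FALSE, nrow(variants))
    return(!is.na(variants$alt_af) & !imp)
  }
  fc <- variants$functional_class
  exonic <- !is.na(fc) & fc %in% c("exonic", "exonic_splicing")
  sub <- variants$exonic_subtype
  if (any(exonic & is.na(sub))) {
    stop("exonic variant(s) missing exonic_subtype: ",
         paste(utils::head(variants$key[exonic & is.na(sub)], 5), collapse = ", "),
         call. = FALSE)
  }
  altering <- c("non-synonymous", "frameshift", "non-frameshift",
                "stop-gain", "stop-loss")
  exonic & sub %in% altering
}

dosage_matrix <- function(gm) {
  D <- matrix(gt_dosage(gm$calls), nrow(gm$calls),
              dimnames = dimnames(gm$calls))
  D
}

#' Naive-bootstrap replicate experiments of one patient group
#'
#' Simulated experiments are fabricated by resampling the group's
#' patients with replacement: each experiment holds `k` resamples of the
#' full group size, and each resample yields a per-variant VAF.  No
#' distributional assumption is made (the VAF distribution in a
#' 12-patient group is decidedly non-Gaussian).
#'
#' @param gm a [genotype_matrix()] (oriented; any variant subset).
#' @param group `"sensitive"` or `"resistant"`.
#' @param n_experiments number of replicate experiments (default 4).
#' @param k resamples per experiment (default 999).
#' @param seed RNG seed; the experiments consume one common stream, so a
#'   fixed seed reproduces every resample.
#' @return list of `n_experiments` numeric matrices (variants x k) of
#'   resampled VAFs.
#' @export
bootstrap_experiments <- function(gm, group, n_experiments = 4, k = 999,
                                  seed = NULL) {
  calls <- group_calls(gm, group)
  n <- ncol(calls)
  if (n < 2) stop("group needs at least 2 samples to bootstrap", call. = FALSE)
  D <- matrix(gt_dosage(calls), nrow(calls), dimnames = dimnames(calls))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_experiments), function(e) {
    # multiplicity of each patient in each of the k resamples
    M <- vapply(seq_len(k), function(j) {
      tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    }, integer(n))
    vaf <- (D %*% M) / (2 * n)
    rownames(vaf) <- rownames(calls)
    vaf
  })
}

#' Aggregate per-variant frequencies to one value per gene
#'
#' Either the arithmetic mean of the gene's variant frequencies
#' (`mean`), or their sum divided by the captured gene size in base
#' pairs (`sum_over_size`) to correct for the variant count scaling with
#' gene size.  Genes with no variant in the input are absent from the
#' output.
#'
#' @param vafs numeric vector or matrix (variants x resamples) of
#'   frequencies.
#' @param genes gene symbol per variant.
#' @param method `"mean"` or `"sum_over_size"`.
#' @param sizes named vector gene -> size in bp (required for
#'   `sum_over_size`).
#' @return matrix (genes x resamples) or named vector when the input was
#'   a vector.
#' @export
gene_aggregate <- function(vafs, genes, method = c("mean", "sum_over_size"),
                           sizes = NULL) {
  method <- match.arg(method)
  vec <- is.null(dim(vafs))
  V <- if (vec) matrix(vafs, ncol = 1) else as.matrix(vafs)
  stopifnot(length(genes) == nrow(V))
  sums <- rowsum(V, genes)
  if (method == "mean") {
    counts <- as.vector(table(genes)[rownames(sums)])
    out <- sums / counts
  } else {
    if (is.null(sizes)) stop("sum_over_size needs a gene size table", call. = FALSE)
    sz <- sizes[rownames(sums)]
    if (anyNA(sz)) {
      stop("missing gene size for: ",
           paste(rownames(sums)[is.na(sz)], collapse = ", "), call. = FALSE)
    }
    out <- sums / as.numeric(sz)
  }
  if (vec) stats::setNames(out[, 1], rownames(out)) else out
}

#' Bootstrap-averaged odds-ratio ("ODDS") plug-in estimator
#'
#' For one gene, with `q_k` the gene-level patient frequency in resample
#' `k` and `p` the gene-level population frequency, the estimator is the
#' average over resamples of the odds ratio `q_k (1-p) / (p (1-q_k))`.
#' `q_k` values are clamped to `[eps, 1-eps]` before use: a resample with
#' no minor allele would otherwise give odds 0, and one with only minor
#' alleles infinite odds.  `p` must already lie strictly inside (0, 1)
#' (floor it at the theoretical MAF, cap it at 0.5 via orientation).
#'
#' @param q numeric vector of resampled gene-level frequencies.
#' @param p population gene-level frequency, in (0, 1).
#' @param eps clamp width for `q`; the default `1/(2 n + 1)` with `n`
#'   inferred is not possible here, so pass it explicitly (e.g.
#'   `1/(2*12 + 1)` for 12 patients).
#' @return positive scalar.
#' @export
odds_estimator <- function(q, p, eps = 1 / (2 * 12 + 1)) {
  if (length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    stop("population frequency p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (length(q) < 1) stop("need at least one resample", call. = FALSE)
  q <- pmin(pmax(q, eps), 1 - eps)
  mean((q * (1 - p)) / (p * (1 - q)))
}

#' Per-gene ODDS values for a set of replicate experiments
#'
#' The zero-frequency guard is applied at the variant level, before
#' aggregation: each resampled variant VAF is clamped into
#' `[eps, 1 - eps]` so that a resample carrying no (or only) minor
#' alleles cannot produce a zero or infinite odds ratio.  Clamping
#' before aggregation keeps both aggregation methods on their own
#' natural scale (`sum_over_size` gene values are far below any
#' allele-scale clamp and must not be floored there).
#'
#' @param experiments list of variants x k VAF matrices from
#'   [bootstrap_experiments()] (already restricted to the filtered
#'   variants).
#' @param genes gene per variant.
#' @param p_gene named vector of gene-level population frequencies
#'   (same aggregation method as `q`), strictly inside (0, 1).
#' @param method,sizes passed to [gene_aggregate()].
#' @param eps variant-level clamp width (use `1/(2 n + 1)` for an
#'   n-patient group).
#' @return matrix genes x experiments of ODDS values.
#' @export
experiment_odds <- function(experiments, genes, p_gene,
                            method = c("mean", "sum_over_size"),
                            sizes = NULL, eps = 1 / (2 * 12 + 1)) {
  method <- match.arg(method)
  mats <- lapply(experiments, function(vafs) {
    gene_aggregate(pmin(pmax(vafs, eps), 1 - eps), genes, method, sizes)
  })
  gene_ids <- rownames(mats[[1]])
  p <- p_gene[gene_ids]
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("population frequency missing or outside (0, 1) for some gene",
         call. = FALSE)
  }
  out <- vapply(mats, function(Q) {
    rowMeans((Q * (1 - p)) / (p * (1 - Q)))   # p recycles along rows
  }, numeric(length(gene_ids)))
  out <- matrix(out, nrow = length(gene_ids),
                dimnames = list(gene_ids, paste0("exp", seq_along(mats))))
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Two-class rank-product test on replicate ODDS values
#'
#' For each of the `E1 x E2` between-class pairings of replicate
#' experiments, the per-gene fold change `FC = ODDS_class1 / ODDS_class2`
#' is ranked ascending (with class 1 = sensitive, a small FC marks
#' resistant enrichment, which is ranked toward position 1; ties get
#' average ranks).  The rank product `RP_g` is the geometric mean of the
#' gene's ranks over all pairings.  Significance is assessed by
#' permutation: in each of `n_permutations` rounds every pairing's rank
#' vector is replaced by a random permutation of `1..G`, the null RPs
#' are pooled, and for each gene `p = (count of null RP <= observed RP
#' + 1) / (n_permutations * G + 1)`.  The percentage of false prediction
#' is `pfp = p * G / rank position` (expected false positives at or
#' above the gene's position, divided by the position).
#'
#' @param odds1 matrix genes x experiments for class 1 (sensitive).
#' @param odds2 matrix genes x experiments for class 2 (resistant); same
#'   gene universe, same order.
#' @param n_permutations permutation rounds (default 1000).
#' @param seed RNG seed for the permutations.
#' @param direction `"resistant"` (default): genes enriched in class 2
#'   rank first; `"sensitive"` reverses the one-sided ordering.
#' @param exhaustive if `TRUE`, enumerate every combination of rank
#'   permutations across pairings instead of sampling (feasible only for
#'   toy problems; `n_permutations`/`seed` are then ignored).
#' @return a `gene_rank_table` data.frame sorted by ascending RP:
#'   columns `gene`, `rank`, `rp`, `fc` (mean class-1 ODDS / mean
#'   class-2 ODDS), `pfp`, `p_value`.
#' @export
rank_product_two_class <- function(odds1, odds2, n_permutations = 1000,
                                   seed = NULL,
                                   direction = c("resistant", "sensitive"),
                                   exhaustive = FALSE) {
  direction <- match.arg(direction)
  odds1 <- as.matrix(odds1); odds2 <- as.matrix(odds2)
  if (!identical(rownames(odds1), rownames(odds2))) {
    stop("both classes must share one gene universe in the same order",
         call. = FALSE)
  }
  G <- nrow(odds1)
  if (G < 1 || ncol(odds1) < 1 || ncol(odds2) < 1) {
    stop("both classes need at least one experiment and one gene", call. = FALSE)
  }
  ranks <- matrix(NA_real_, G, ncol(odds1) * ncol(odds2))
  pair <- 0L
  for (i in seq_len(ncol(odds1))) {
    for (j in seq_len(ncol(odds2))) {
      pair <- pair + 1L
      fc <- odds1[, i] / odds2[, j]
      if (direction == "sensitive") fc <- 1 / fc
      ranks[, pair] <- rank(fc, ties.method = "average")
    }
  }
  P <- ncol(ranks)
  log_rp <- rowMeans(log(ranks))
  rp <- exp(log_rp)
  # null distribution of log RP under independent rank permutations
  if (exhaustive) {
    perms <- all_permutations(G)
    combos <- nrow(perms)^P
    idx <- rep(1L, P)
    null_log <- numeric(0)
    for (cmb in seq_len(combos)) {
      R <- vapply(seq_len(P), function(p) as.numeric(perms[idx[p], ]), numeric(G))
      null_log <- c(null_log, rowMeans(matrix(log(R), G)))
      # odometer increment
      for (p in seq_len(P)) {
        idx[p] <- idx[p] + 1L
        if (idx[p] <= nrow(perms)) break
        idx[p] <- 1L
      }
    }
    n_eff <- combos
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_log <- numeric(n_permutations * G)
    for (b in seq_len(n_permutations)) {
      R <- vapply(seq_len(P), function(p) sample.int(G), integer(G))
      null_log[((b - 1) * G + 1):(b * G)] <-
        rowMeans(matrix(log(R), G))
    }
    n_eff <- n_permutations
  }
  null_sorted <- sort(null_log)
  x <- findInterval(log_rp + 1e-12, null_sorted)
  p_value <- (x + 1) / (n_eff * G + 1)
  pos <- rank(rp, ties.method = "first")
  pfp <- p_value * G / pos
  fc_mean <- rowMeans(odds1) / rowMeans(odds2)
  out <- data.frame(gene = rownames(odds1), rank = pos, rp = rp, fc = fc_mean,
                    pfp = pfp, p_value = p_value, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("gene_rank_table", class(out)))
  out
}

#' Rank genes by resistant-group variant enrichment
#'
#' End-to-end gene-ranking branch: filter variants, fabricate replicate
#' experiments for each patient group by naive bootstrap, aggregate
#' resampled VAFs per gene, compute the bootstrap-averaged ODDS against
#' the population frequency, and run the two-class rank-product test.
#'
#' @param gm an adjusted (oriented, pruned) [genotype_matrix()] whose
#'   variants carry `maf`, `gene` and functional annotations.
#' @param sizes named gene-size vector (needed for
#'   `agg = "sum_over_size"`).
#' @param filter variant filter mode (see [filter_protein_altering()]).
#' @param agg gene aggregation method.
#' @param k resamples per experiment (default 999).
#' @param n_experiments replicate experiments per class (default 4).
#' @param n_permutations rank-product permutation rounds (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_reference_individuals reference-panel size; floors the
#'   gene-level population frequency at the theoretical MAF.
#' @return a `gene_rank_table` (see [rank_product_two_class()]) with
#'   attributes `n_variants` and `n_genes`.
#' @export
rank_genes <- function(gm, sizes = NULL,
                       filter = c("protein_altering", "all", "with_altaf_only"),
                       agg = c("mean", "sum_over_size"),
                       k = 999, n_experiments = 4, n_permutations = 1000,
                       seed, n_reference_individuals = 503) {
  filter <- match.arg(filter)
  agg <- match.arg(agg)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(gm$variants$maf)) {
    stop("matrix is not adjusted (no `maf`); run adjust_genotype_matrix() first",
         call. = FALSE)
  }
  keep <- filter_protein_altering(gm$variants, filter)
  keep <- keep & !is.na(gm$variants$gene)
  if (!any(keep)) stop("no variants pass the chosen filter", call. = FALSE)
  sub <- subset_variants(gm, keep)
  genes <- sub$variants$gene
  # population frequency: variant-level theoretical-MAF floor (the same
  # floor the adjustment uses), then the same aggregation method as q
  maf_v <- pmin(pmax(sub$variants$maf, 1 / n_reference_individuals), 0.5)
  p_gene <- gene_aggregate(maf_v, genes, agg, sizes)
  n_sens <- sum(sub$samples$group == "sensitive")
  n_res <- sum(sub$samples$group == "resistant")
  exp_s <- bootstrap_experiments(sub, "sensitive", n_experiments, k,
                                 seed = seed)
  exp_r <- bootstrap_experiments(sub, "resistant", n_experiments, k,
                                 seed = seed + 1L)
  odds_s <- experiment_odds(exp_s, genes, p_gene, agg, sizes,
                            eps = 1 / (2 * n_sens + 1))
  odds_r <- experiment_odds(exp_r, genes, p_gene, agg, sizes,
                            eps = 1 / (2 * n_res + 1))
  out <- rank_product_two_class(odds_s, odds_r,
                                n_permutations = n_permutations,
                                seed = seed + 2L)
  attr(out, "n_variants") <- nrow(sub$calls)
  attr(out, "n_genes") <- nrow(out)
  out
}
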