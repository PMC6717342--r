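# Shared fixture builders.  All cohorts are generated in code at test time;
# the worlds (sample sizes, MAF spectrum, odds ratios) are fixed once and
# shared between module tests and the acceptance suite.

# Tiny hand-enumerable genotype matrix: `spec` is a list of character
# vectors (one per variant, sensitive samples first).
th_tiny_gm <- function(spec, n_sensitive, n_resistant,
                       variants = NULL) {
  calls <- do.call(rbind, spec)
  keys <- if (is.null(variants)) sprintf("v%d", seq_along(spec)) else variants$key
  rownames(calls) <- keys
  samples <- data.frame(
    sample_id = c(sprintf("S%d", seq_len(n_sensitive)),
                  sprintf("R%d", seq_len(n_resistant))),
    group = c(rep("sensitive", n_sensitive), rep("resistant", n_resistant)),
    stringsAsFactors = FALSE
  )
  colnames(calls) <- samples$sample_id
  if (is.null(variants)) {
    variants <- data.frame(key = keys, stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, variants, samples)
}

# Background MAF spectrum used by every synthetic world: a rare-skewed
# site-frequency spectrum truncated to (0.001, 0.5].
th_maf_spectrum <- function(n) pmax(0.5 * stats::rbeta(n, 0.4, 2.5), 1e-3)

# Paper-scale rank-product world: 105 protein-altering variants in 30
# genes, 12 + 12 patients.  `planted_or` > 1 plants gene G01 with three
# variants at MAF 0.05; `planted_or = NULL` gives the complete null.
th_rp_cohort <- function(seed, planted_or = NULL) {
  set.seed(seed * 1000L)
  genes <- sprintf("G%02d", 1:30)
  n_bg <- if (is.null(planted_or)) 105L else 102L
  bg_genes <- if (is.null(planted_or)) genes else genes[-1]
  v <- data.frame(gene = sample(rep(bg_genes, length.out = n_bg)),
                  functional_class = "exonic",
                  exonic_subtype = "non-synonymous",
                  maf = th_maf_spectrum(n_bg), or = 1,
                  stringsAsFactors = FALSE)
  if (!is.null(planted_or)) {
    pl <- data.frame(gene = genes[1], functional_class = "exonic",
                     exonic_subtype = "non-synonymous",
                     maf = 0.05, or = planted_or, stringsAsFactors = FALSE)
    v <- rbind(v, pl, pl, pl)
  }
  v$altaf_missing <- FALSE
  v$altaf_major <- FALSE
  spec <- simulation_spec(v, n_sensitive = 12, n_resistant = 12,
                          n_reference_individuals = 503,
                          seed = seed * 1000L + 1L)
  simulate_cohort(spec)
}

# Clustering world: 150 neutral intronic variants plus 20 variants
# enriched in the resistant group at allele OR 5, MAF in [0.02, 0.05].
th_cluster_cohort <- function(seed) {
  set.seed(seed * 77L)
  n_bg <- 150L
  bg <- data.frame(gene = sample(sprintf("G%02d", 1:20), n_bg, replace = TRUE),
                   functional_class = "intronic",
                   exonic_subtype = NA_character_,
                   maf = th_maf_spectrum(n_bg), or = 1,
                   stringsAsFactors = FALSE)
  en <- data.frame(gene = "GEN", functional_class = "exonic",
                   exonic_subtype = "non-synonymous",
                   maf = stats::runif(20, 0.02, 0.05), or = 5,
                   stringsAsFactors = FALSE)
  v <- rbind(bg, en)
  v$altaf_missing <- FALSE
  v$altaf_major <- FALSE
  spec <- simulation_spec(v, 12, 12, 503, seed = seed * 77L + 1L)
  simulate_cohort(spec)
}

th_adjust <- function(bundle, ...) {
  adjust_genotype_matrix(
    bundle$matrix,
    stats::setNames(bundle$popfreq$alt_af, bundle$popfreq$key), ...)
}

# Three well-separated planar Gaussian blobs (or fewer) for choose_k.
th_blobs <- function(seed, centers, n_each = 30, sigma = 0.01) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(stats::rnorm(n_each, centers[i, 1], sigma),
          stats::rnorm(n_each, centers[i, 2], sigma))
  }))
  rownames(pts) <- sprintf("p%d", seq_len(nrow(pts)))
  pts
}

# Random valid contingency table for property tests.
th_random_ct <- function(n, seed) {
  set.seed(seed)
  contingency_table(
    key = sprintf("v%d", seq_len(n)),
    vaf_sensitive = stats::runif(n, 0.01, 0.9),
    vaf_resistant = stats::runif(n, 0.01, 0.9),
    maf_population = stats::runif(n, 0.001, 0.5)
  )
}
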