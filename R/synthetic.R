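#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort the simulator can draw: sample counts per group, a
#' per-variant table (gene, functional class, population MAF,
#' resistant-group enrichment odds ratio, and flags controlling how the
#' reference panel records the variant), and the reference-panel size.
#'
#' @param variants data.frame with columns `gene`, `functional_class`,
#'   `exonic_subtype` (NA for non-exonic), `maf` in (0, 0.5], `or` > 0
#'   (allele-level odds ratio of the resistant group versus the
#'   population), `altaf_missing` (variant absent from the panel) and
#'   `altaf_major` (panel records the major allele as alternate, so the
#'   emitted AltAF is `1 - maf` and emitted genotypes are complemented).
#' @param n_sensitive,n_resistant samples per group (default 12 + 12).
#' @param n_reference_individuals reference-panel size (default 503).
#' @param seed RNG seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(variants, n_sensitive = 12, n_resistant = 12,
                            n_reference_individuals = 503, seed = 1) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("gene", "functional_class", "maf", "or")
  if (!all(need %in% names(variants))) {
    stop("variant table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(variants$exonic_subtype)) variants$exonic_subtype <- NA_character_
  if (is.null(variants$altaf_missing)) variants$altaf_missing <- FALSE
  if (is.null(variants$altaf_major)) variants$altaf_major <- FALSE
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    stop("population MAFs must lie in (0, 0.5]", call. = FALSE)
  }
  if (any(variants$or <= 0)) stop("odds ratios must be positive", call. = FALSE)
  if (n_sensitive < 1 || n_resistant < 1 || n_reference_individuals < 1) {
    stop("sample counts must be >= 1", call. = FALSE)
  }
  structure(list(variants = variants, n_sensitive = n_sensitive,
                 n_resistant = n_resistant,
                 n_reference_individuals = n_reference_individuals,
                 seed = seed),
            class = "simulation_spec")
}

#' Resistant-group allele frequency implied by an enrichment odds ratio
#'
#' Solves `odds(q) = or * odds(maf)` for `q`, i.e.
#' `q = or*m/(1-m) / (1 + or*m/(1-m))`.
#'
#' @param maf population minor-allele frequency.
#' @param or allele-level odds ratio.
#' @return frequency in (0, 1).
#' @export
enriched_frequency <- function(maf, or) {
  odds <- or * maf / (1 - maf)
  q <- odds / (1 + odds)
  if (any(q <= 0 | q >= 1)) stop("implied frequency outside (0, 1)", call. = FALSE)
  q
}

hw_genotypes <- function(n, q) {
  sample(GT_CODES, n, replace = TRUE,
         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Draw a synthetic cohort
#'
#' Sensitive-group genotypes are drawn under Hardy-Weinberg equilibrium
#' at each variant's population MAF; resistant-group genotypes at the
#' frequency implied by the variant's enrichment odds ratio
#' ([enriched_frequency()]).  Variants flagged `altaf_major` are emitted
#' the way a reference panel anchored on the opposite allele would
#' record them: AltAF `= 1 - maf` and complemented genotype codes, so the
#' adjustment workflow must invert them back.  Variants flagged
#' `altaf_missing` are left out of the frequency table.  Variants are
#' simulated independently (no linkage disequilibrium).
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (a raw [genotype_matrix()]),
#'   `annotations`, `popfreq` (data.frame key/alt_af), `gene_sizes`
#'   (named vector), and `truth` (per-variant data.frame with the
#'   planted enrichment: `enriched = or > 1`, the implied resistant
#'   frequency `q_resistant`, and the emission flags).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  v <- spec$variants
  nv <- nrow(v)
  key <- sprintf("chr%d:%d:%s:%s",
                 rep_len(1:22, nv), seq_len(nv) * 1000L,
                 rep_len(c("A", "C", "G", "T"), nv),
                 rep_len(c("G", "T", "A", "C"), nv))
  q_res <- enriched_frequency(v$maf, v$or)
  samples <- data.frame(
    sample_id = c(sprintf("S%02d", seq_len(spec$n_sensitive)),
                  sprintf("R%02d", seq_len(spec$n_resistant))),
    group = c(rep("sensitive", spec$n_sensitive),
              rep("resistant", spec$n_resistant)),
    stringsAsFactors = FALSE
  )
  calls <- matrix(NA_character_, nv, nrow(samples),
                  dimnames = list(key, samples$sample_id))
  for (i in seq_len(nv)) {
    # variants are "identified" in the cohort: condition each draw on at
    # least one non-reference call in the emitted orientation (rejection
    # sampling), as a variant caller would only report such sites.
    # Monomorphism can then only arise after allele inversion.
    for (try in seq_len(10000L)) {
      g <- c(hw_genotypes(spec$n_sensitive, v$maf[i]),
             hw_genotypes(spec$n_resistant, q_res[i]))
      if (v$altaf_major[i]) g <- gt_complement(g)
      if (any(g != GT_REF_HOM)) break
    }
    if (all(g == GT_REF_HOM)) g[1] <- GT_HET
    calls[i, ] <- g
  }
  annotations <- data.frame(key = key, gene = v$gene,
                            functional_class = v$functional_class,
                            exonic_subtype = v$exonic_subtype,
                            stringsAsFactors = FALSE)
  emit_af <- ifelse(v$altaf_major, 1 - v$maf, v$maf)
  popfreq <- data.frame(key = key[!v$altaf_missing],
                        alt_af = emit_af[!v$altaf_missing],
                        stringsAsFactors = FALSE)
  genes <- sort(unique(v$gene))
  gene_sizes <- stats::setNames(
    sample(2000:20000, length(genes), replace = TRUE), genes)
  truth <- data.frame(key = key, gene = v$gene, maf = v$maf, or = v$or,
                      q_resistant = q_res, enriched = v$or > 1,
                      altaf_missing = v$altaf_missing,
                      altaf_major = v$altaf_major,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, annotations, samples)
  list(matrix = gm, annotations = annotations, popfreq = popfreq,
       gene_sizes = gene_sizes, truth = truth)
}

# 48-gene panel used for the bundled fixture (pharmacokinetics panel:
# transporters, CYP enzymes, cell cycle, DNA repair, cytokine signalling,
# kinases/phosphatases).
PANEL_GENES <- c(
  "ABCB1", "ABCC2", "ABCG2", "HFE", "HIF1A", "ORM1", "SLC22A1", "SLC22A4",
  "SLCO1A2", "SLCO1B1", "CYP1A1", "CYP1A2", "CYP2C19", "CYP2C8", "CYP2C9",
  "CYP2D6", "CYP3A4", "CYP3A5", "NR1I2", "NR1I3", "UGT1A1", "UGT1A9",
  "CCND1", "PPP2R2A", "RPA1", "RPA2", "RPA3", "ERCC2", "ERCC3", "ERCC4",
  "ERCC5", "ERCC6", "ERCC8", "LIG1", "RAD23B", "XPA", "XPC", "CXCL8",
  "IFNG", "IFNGR1", "IFNGR2", "SOCS1", "SOCS2", "AKT1", "ULK3", "PTPN1",
  "PTPN2", "PTPN22"
)

#' Deterministic mid-size demonstration cohort
#'
#' A fixed-seed synthetic cohort shaped like a targeted-panel study:
#' about 700 variants over the 48-gene pharmacokinetics panel, 12
#' sensitive + 12 resistant patients, roughly 18% of variants absent
#' from the reference panel (theoretical-MAF candidates), roughly 24% of
#' the recorded AltAFs anchored on the major allele (inversion
#' candidates), and three genes planted with resistant-group enrichment
#' (three protein-altering variants each at allele odds ratio 10).
#'
#' @param n_variants approximate cohort size (default 708).
#' @param seed fixture seed (default 4801; change it only to study
#'   seed-sensitivity, the bundled fixture is the default).
#' @return the [simulate_cohort()] bundle, with the planted gene symbols
#'   in `enriched_genes`.
#' @export
paperlike_fixture <- function(n_variants = 708, seed = 4801) {
  set.seed(seed)
  classes <- c("intronic", "exonic", "UTR5", "UTR3", "upstream",
               "downstream", "splicing", "intergenic", "ncRNA_exonic",
               "exonic_splicing")
  class_prob <- c(0.609, 0.240, 0.079, 0.045, 0.008, 0.004, 0.002, 0.004,
                  0.002, 0.007)
  enriched_genes <- c("UGT1A9", "PTPN22", "ERCC5")
  n_planted <- 3L * length(enriched_genes)
  n_bg <- n_variants - n_planted
  fclass <- sample(classes, n_bg, replace = TRUE, prob = class_prob)
  subtype <- rep(NA_character_, n_bg)
  exonic <- fclass %in% c("exonic", "exonic_splicing")
  subtype[exonic] <- sample(
    c("non-synonymous", "synonymous", "frameshift", "non-frameshift",
      "stop-gain", "stop-loss"),
    sum(exonic), replace = TRUE,
    prob = c(0.594, 0.366, 0.017, 0.011, 0.006, 0.006))
  bg <- data.frame(
    gene = sample(PANEL_GENES, n_bg, replace = TRUE),
    functional_class = fclass,
    exonic_subtype = subtype,
    maf = pmax(0.5 * stats::rbeta(n_bg, 0.4, 2.5), 1e-3),
    or = 1,
    stringsAsFactors = FALSE
  )
  planted <- data.frame(
    gene = rep(enriched_genes, each = 3),
    functional_class = "exonic",
    exonic_subtype = "non-synonymous",
    maf = stats::runif(n_planted, 0.02, 0.05),
    or = 10,
    stringsAsFactors = FALSE
  )
  v <- rbind(bg, planted)
  v <- v[sample(nrow(v)), , drop = FALSE]
  rownames(v) <- NULL
  v$altaf_missing <- stats::runif(nrow(v)) < 0.184
  v$altaf_major <- !v$altaf_missing & stats::runif(nrow(v)) < 0.24
  spec <- simulation_spec(v, n_sensitive = 12, n_resistant = 12,
                          n_reference_individuals = 503, seed = seed + 1L)
  out <- simulate_cohort(spec)
  out$enriched_genes <- enriched_genes
  out
}
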