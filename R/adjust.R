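#' Attach population alternate-allele frequencies to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param freqs named numeric vector from [read_population_frequencies()].
#' @return `gm` with `variants$alt_af` filled where a lookup succeeded
#'   (canonical key, then rsID alias).
#' @export
set_population_frequencies <- function(gm, freqs) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$variants$alt_af <- lookup_alt_af(freqs, gm$variants$key, gm$variants$rsid)
  validate_genotype_matrix(gm)
}

#' Impute the theoretical MAF for variants absent from the reference panel
#'
#' A variant never observed in a reference panel of `n` individuals is
#' treated as rarer than one carrier in the panel, i.e. its minor allele
#' frequency is set to `1/n` (for a 503-individual panel, 1/503, about
#' 2e-3).  Present frequencies are untouched.  Imputed values are already
#' minor-allele frequencies and can never trigger allele inversion
#' (`1/n < 0.5` for `n >= 3`).
#'
#' @param gm a [genotype_matrix()] (possibly with `NA` alt_af values).
#' @param n_reference_individuals size of the reference panel (default
#'   503, the European reference sub-population used throughout).
#' @return `gm` with all `alt_af` present and a logical
#'   `variants$alt_af_imputed` column.
#' @export
impute_theoretical_maf <- function(gm, n_reference_individuals = 503) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_reference_individuals
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("n_reference_individuals must be a positive integer", call. = FALSE)
  }
  miss <- is.na(gm$variants$alt_af)
  gm$variants$alt_af[miss] <- 1 / n
  gm$variants$alt_af_imputed <- miss
  gm
}

#' Drop variants with no reference-panel frequency
#'
#' Alternative to [impute_theoretical_maf()]: remove variants whose AltAF
#' is absent instead of assigning a theoretical floor.
#'
#' @param gm a [genotype_matrix()].
#' @return list with the pruned matrix (`matrix`) and the removed keys
#'   (`removed`).
#' @export
drop_missing_af <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  miss <- is.na(gm$variants$alt_af)
  out <- subset_variants(gm, !miss)
  out$variants$alt_af_imputed <- FALSE
  list(matrix = out, removed = gm$variants$key[miss])
}

subset_variants <- function(gm, keep) {
  gm$calls <- gm$calls[keep, , drop = FALSE]
  gm$variants <- gm$variants[keep, , drop = FALSE]
  rownames(gm$variants) <- NULL
  gm
}

#' Orient every variant to the population minor allele
#'
#' The reference panel records the frequency of the alternate allele,
#' which may be the *major* allele in the population.  For variants with
#' `AltAF >= 0.5` the minor allele frequency is `1 - AltAF`, the recorded
#' ref/alt labels are swapped and every genotype call is complemented
#' (`0_0 <-> 1_1`); otherwise MAF = AltAF and calls are untouched.  After
#' orientation every population MAF is `<= 0.5`.
#'
#' @param gm a [genotype_matrix()] whose variants all carry an `alt_af`
#'   (run [impute_theoretical_maf()] or [drop_missing_af()] first).
#' @return `gm` with new variant columns `maf` and `inverted`, genotypes
#'   complemented where needed.
#' @export
orient_to_minor_allele <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  af <- gm$variants$alt_af
  if (anyNA(af)) {
    stop("all variants need alt_af before orientation (impute or drop first)",
         call. = FALSE)
  }
  already <- isTRUE_vec(gm$variants$inverted)
  invert <- af >= 0.5 & !already
  maf_prev <- gm$variants$maf
  if (is.null(maf_prev)) maf_prev <- rep(NA_real_, length(af))
  maf <- ifelse(invert, 1 - af, af)
  maf[already] <- maf_prev[already]
  gm$variants$maf <- maf
  if (any(invert)) {
    gm$calls[invert, ] <- gt_complement(gm$calls[invert, , drop = FALSE])
    if (!is.null(gm$variants$ref)) {
      ref <- gm$variants$ref[invert]
      gm$variants$ref[invert] <- gm$variants$alt[invert]
      gm$variants$alt[invert] <- ref
    }
    gm$variants$alt_af[invert] <- 1 - af[invert]
  }
  gm$variants$inverted <- invert | already
  gm
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Remove variants with no minor allele in any patient
#'
#' After orientation, a variant whose calls are reference-homozygous in
#' every sample carries no information and is removed.
#'
#' @param gm an oriented [genotype_matrix()].
#' @return list with the pruned matrix (`matrix`) and removed keys
#'   (`removed`); input variant order is preserved.
#' @export
drop_monomorphic <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mono <- apply(gm$calls == GT_REF_HOM, 1, all)
  list(matrix = subset_variants(gm, !mono), removed = gm$variants$key[mono])
}

#' Variant allele frequency of a group of genotype calls
#'
#' Allele-counting definition: `(n_het + 2 n_hom) / (2 n_samples)`, the
#' fraction of minor alleles among all sequenced alleles.  Five
#' heterozygous carriers among 12 patients give 5/24, i.e. 21%.
#'
#' @param calls character vector (or matrix row) of genotype codes.
#' @return fraction in \[0, 1\].
#' @export
compute_vaf <- function(calls) {
  if (length(calls) == 0) stop("empty genotype group", call. = FALSE)
  mean(gt_dosage(calls)) / 2
}

#' Assemble the three-group contingency table
#'
#' One row per retained variant: VAF in the sensitive group, VAF in the
#' resistant group and the population MAF.  Also returns the adjustment
#' report with the counts of the preceding workflow steps.
#'
#' @param gm oriented, pruned [genotype_matrix()] with `maf` present.
#' @param report optional partial report counts (see
#'   [adjust_genotype_matrix()]); filled in for the output count.
#' @return list with `table` (a [contingency_table()]) and `report` (an
#'   `adjustment_report`).
#' @export
build_contingency_table <- function(gm, report = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$variants$maf)) {
    stop("variants carry no `maf`; run orient_to_minor_allele() first", call. = FALSE)
  }
  for (g in c("sensitive", "resistant")) {
    if (!any(gm$samples$group == g)) {
      stop(sprintf("group '%s' absent from matrix", g), call. = FALSE)
    }
  }
  vaf_s <- apply(group_calls(gm, "sensitive"), 1, compute_vaf)
  vaf_r <- apply(group_calls(gm, "resistant"), 1, compute_vaf)
  tab <- contingency_table(gm$variants$key, vaf_s, vaf_r, gm$variants$maf)
  if (is.null(report)) {
    report <- adjustment_report(n_input = nrow(gm$calls), n_imputed_maf = 0L,
                                n_inverted = 0L, n_removed_monomorphic = 0L)
  }
  report$n_output <- nrow(tab)
  list(table = tab, report = validate_adjustment_report(report))
}

adjustment_report <- function(n_input, n_imputed_maf, n_inverted,
                              n_removed_monomorphic, n_output = NULL) {
  structure(list(
    n_input = as.integer(n_input),
    n_imputed_maf = as.integer(n_imputed_maf),
    n_inverted = as.integer(n_inverted),
    n_removed_monomorphic = as.integer(n_removed_monomorphic),
    n_output = if (is.null(n_output)) NA_integer_ else as.integer(n_output)
  ), class = "adjustment_report")
}

validate_adjustment_report <- function(r) {
  counts <- unlist(r[c("n_input", "n_imputed_maf", "n_inverted",
                       "n_removed_monomorphic", "n_output")])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("adjustment report counts must be nonnegative and complete", call. = FALSE)
  }
  if (r$n_output != r$n_input - r$n_removed_monomorphic) {
    stop("adjustment report inconsistent: n_output != n_input - n_removed_monomorphic",
         call. = FALSE)
  }
  r
}

#' @export
print.adjustment_report <- function(x, ...) {
  cat(sprintf(paste0(
    "adjustment report:\n",
    "  input variants:        %d\n",
    "  theoretical MAF added: %d\n",
    "  allele-inverted:       %d\n",
    "  monomorphic removed:   %d\n",
    "  retained:              %d\n"),
    x$n_input, x$n_imputed_maf, x$n_inverted,
    x$n_removed_monomorphic, x$n_output))
  invisible(x)
}

#' Run the full genotype-adjustment workflow
#'
#' The four-step adjustment: (1) theoretical-MAF imputation for variants
#' absent from the reference panel (or removal, with
#' `drop_missing_af = TRUE`); (2) minor-allele orientation, inverting
#' genotypes where `AltAF >= 0.5`; (3) removal of variants left with no
#' minor allele in any patient; (4) VAF computation into the three-group
#' contingency table.
#'
#' @param gm a raw [genotype_matrix()].
#' @param freqs optional population frequency vector to attach first.
#' @param n_reference_individuals reference-panel size for the
#'   theoretical MAF (default 503).
#' @param drop_missing_af if `TRUE`, drop variants without AltAF instead
#'   of imputing.
#' @return list with `matrix` (adjusted genotype matrix), `table`
#'   (contingency table), `report` (adjustment report) and
#'   `removed_monomorphic` / `removed_missing_af` key vectors.
#' @export
adjust_genotype_matrix <- function(gm, freqs = NULL,
                                   n_reference_individuals = 503,
                                   drop_missing_af = FALSE) {
  if (!is.null(freqs)) gm <- set_population_frequencies(gm, freqs)
  n_input_raw <- nrow(gm$calls)
  removed_af <- character(0)
  if (drop_missing_af) {
    dropped <- drop_missing_af(gm)
    gm <- dropped$matrix
    removed_af <- dropped$removed
    n_imputed <- 0L
  } else {
    n_imputed <- sum(is.na(gm$variants$alt_af))
    gm <- impute_theoretical_maf(gm, n_reference_individuals)
  }
  gm <- orient_to_minor_allele(gm)
  n_inverted <- sum(gm$variants$inverted)
  pruned <- drop_monomorphic(gm)
  report <- adjustment_report(
    n_input = nrow(gm$calls),
    n_imputed_maf = n_imputed,
    n_inverted = n_inverted,
    n_removed_monomorphic = length(pruned$removed)
  )
  built <- build_contingency_table(pruned$matrix, report)
  list(matrix = pruned$matrix, table = built$table, report = built$report,
       removed_monomorphic = pruned$removed, removed_missing_af = removed_af,
       n_input_raw = n_input_raw)
}
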