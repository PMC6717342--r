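#' Construct a genotype matrix
#'
#' The central container of the pipeline: a complete variants x samples
#' table of categorical genotype calls, together with per-variant metadata
#' (gene, functional class, optional reference-population alternate allele
#' frequency) and per-sample group labels (sensitive / resistant).
#'
#' @param calls character matrix (variants x samples) of genotype codes
#'   `"0_0"`, `"0_1"`, `"1_1"`; rownames are variant keys, colnames sample
#'   ids.
#' @param variants data.frame with at least a `key` column matching
#'   `rownames(calls)`; optional columns `gene`, `functional_class`,
#'   `exonic_subtype`, `rsid`, `ref`, `alt`, `alt_af`.
#' @param samples data.frame with columns `sample_id` (matching
#'   `colnames(calls)`) and `group` (each `"sensitive"` or `"resistant"`).
#' @return an object of class `genotype_matrix`.
#' @details Missing genotype calls are rejected: upstream depth filtering
#'   is assumed to have produced a complete matrix, and no imputation
#'   scheme is implemented.  Duplicate variant keys or sample ids are
#'   errors.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("`calls` must be a character matrix", call. = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(variants$key)) stop("`variants` needs a `key` column", call. = FALSE)
  if (is.null(samples$sample_id) || is.null(samples$group)) {
    stop("`samples` needs `sample_id` and `group` columns", call. = FALSE)
  }
  for (col in c("gene", "functional_class", "exonic_subtype", "rsid")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
  }
  if (is.null(variants$alt_af)) variants$alt_af <- NA_real_
  rownames(calls) <- if (is.null(rownames(calls))) variants$key else rownames(calls)
  colnames(calls) <- if (is.null(colnames(calls))) samples$sample_id else colnames(calls)
  obj <- structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  v <- x$variants
  s <- x$samples
  if (anyDuplicated(v$key)) {
    stop("duplicate variant key(s): ",
         paste(unique(v$key[duplicated(v$key)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(s$group %in% c("sensitive", "resistant"))) {
    stop("sample groups must be 'sensitive' or 'resistant'", call. = FALSE)
  }
  if (nrow(x$calls) != nrow(v) || ncol(x$calls) != nrow(s)) {
    stop("calls dimensions do not match variants/samples tables", call. = FALSE)
  }
  if (!identical(rownames(x$calls), as.character(v$key)) ||
      !identical(colnames(x$calls), as.character(s$sample_id))) {
    stop("calls dimnames must match variant keys and sample ids", call. = FALSE)
  }
  if (anyNA(x$calls)) {
    idx <- which(is.na(x$calls), arr.ind = TRUE)[1, ]
    stop(sprintf("missing genotype call for variant %s, sample %s",
                 rownames(x$calls)[idx[1]], colnames(x$calls)[idx[2]]),
         call. = FALSE)
  }
  bad <- !(x$calls %in% GT_CODES)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(x$calls)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype '%s' for variant %s, sample %s",
                 x$calls[idx[1], idx[2]],
                 rownames(x$calls)[idx[1]], colnames(x$calls)[idx[2]]),
         call. = FALSE)
  }
  af <- v$alt_af
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("alt_af outside [0, 1]", call. = FALSE)
  }
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(x$samples$group)
  cat(sprintf(
    "genotype_matrix: %d variants x %d samples (%s)\n",
    nrow(x$calls), ncol(x$calls),
    paste(sprintf("%d %s", grp, names(grp)), collapse = ", ")
  ))
  n_af <- sum(!is.na(x$variants$alt_af))
  cat(sprintf("  population AltAF present for %d/%d variants\n",
              n_af, nrow(x$calls)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Extract calls for one sample group
#' @param x a `genotype_matrix`.
#' @param group `"sensitive"` or `"resistant"`.
#' @return character matrix restricted to that group's samples.
#' @keywords internal
group_calls <- function(x, group) {
  keep <- x$samples$group == group
  if (!any(keep)) stop(sprintf("no samples in group '%s'", group), call. = FALSE)
  x$calls[, keep, drop = FALSE]
}

#' Construct a three-group contingency table
#'
#' One row per variant, with the variant-allele frequency observed in the
#' sensitive and resistant patient groups and the population minor allele
#' frequency.  This is the table consumed by correspondence analysis and
#' by the odds-ratio estimator (patient-group frequency q versus
#' population frequency p).
#'
#' @param key variant keys.
#' @param vaf_sensitive,vaf_resistant,maf_population numeric fractions.
#' @return data.frame of class `contingency_table`.
#' @export
contingency_table <- function(key, vaf_sensitive, vaf_resistant, maf_population) {
  tab <- data.frame(
    key = as.character(key),
    vaf_sensitive = as.numeric(vaf_sensitive),
    vaf_resistant = as.numeric(vaf_resistant),
    maf_population = as.numeric(maf_population),
    stringsAsFactors = FALSE
  )
  validate_contingency_table(tab)
}

#' @rdname contingency_table
#' @param tab a candidate table.
#' @export
validate_contingency_table <- function(tab) {
  need <- c("key", "vaf_sensitive", "vaf_resistant", "maf_population")
  if (!all(need %in% names(tab))) {
    stop("contingency table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num <- as.matrix(tab[, need[-1]])
  if (any(is.na(num)) || any(num < 0) || any(num > 1)) {
    stop("contingency table entries must be fractions in [0, 1]", call. = FALSE)
  }
  if (any(tab$maf_population > 0.5 + 1e-12)) {
    stop("maf_population exceeds 0.5; orient variants to the minor allele first",
         call. = FALSE)
  }
  if (anyDuplicated(tab$key)) stop("duplicate keys in contingency table", call. = FALSE)
  class(tab) <- unique(c("contingency_table", class(tab)))
  tab
}
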