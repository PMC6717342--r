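#' Genotype vocabulary
#'
#' Genotype calls are stored as the three categorical codes `"0_0"`
#' (reference homozygous), `"0_1"` (heterozygous) and `"1_1"` (variant
#' homozygous).  All genotype matrices in the package are complete: a cell
#' outside this vocabulary (including `NA`) is rejected at load time.
#'
#' @name genotype-codes
#' @keywords internal
NULL

GT_REF_HOM <- "0_0"
GT_HET <- "0_1"
GT_VAR_HOM <- "1_1"
GT_CODES <- c(GT_REF_HOM, GT_HET, GT_VAR_HOM)

#' Complement genotype calls
#'
#' Swaps the roles of the two alleles: `0_0` becomes `1_1`, `1_1` becomes
#' `0_0` and `0_1` is its own complement.  Used when a variant is oriented
#' to the population minor allele and the recorded alternate allele turns
#' out to be the major allele.  The operation is an involution.
#'
#' @param x character vector of genotype codes.
#' @return character vector of complemented codes.
#' @examples
#' gt_complement(c("0_0", "0_1", "1_1"))
#' @export
gt_complement <- function(x) {
  validate_gt_codes(x)
  out <- x
  out[x == GT_REF_HOM] <- GT_VAR_HOM
  out[x == GT_VAR_HOM] <- GT_REF_HOM
  out
}

#' Minor-allele dosage of genotype calls
#'
#' @param x character vector of genotype codes.
#' @return integer vector in \{0, 1, 2\}: copies of the variant allele.
#' @export
gt_dosage <- function(x) {
  validate_gt_codes(x)
  match(x, GT_CODES) - 1L
}

validate_gt_codes <- function(x, context = NULL) {
  bad <- !(x %in% GT_CODES)
  if (any(bad)) {
    stop(sprintf(
      "invalid genotype code(s)%s: %s (expected one of %s)",
      if (is.null(context)) "" else paste0(" in ", context),
      paste(unique(x[bad]), collapse = ", "),
      paste(GT_CODES, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}
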