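#' Read a genotype matrix from disk
#'
#' Two dialects are supported.  `matrix_csv` is a delimited table whose
#' first column holds variant keys, whose header row holds sample ids and
#' whose cells are the genotype codes `0_0` / `0_1` / `1_1`.  `vcf` is a
#' multi-sample VCF; GT fields `0/0`, `0/1`, `1/1` (phased `0|0` etc.) are
#' mapped to the three codes and multiallelic rows are split into
#' biallelic records (one per alternate allele, counting copies of that
#' allele).
#'
#' @param path path to the genotype file.
#' @param dialect `"matrix_csv"` or `"vcf"`.
#' @param groups sample-to-group assignment: a data.frame with columns
#'   `sample_id` and `group`, a named character vector, or the path of a
#'   delimited side-car file with those two columns.  Every sample in the
#'   file must be assigned.
#' @param annotations optional variant annotation table (data.frame or
#'   path, see [read_annotations()]) merged onto the variants by key.
#' @param sep field separator for `matrix_csv` (default comma; pass
#'   `"\t"` for tab-delimited input).
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("matrix_csv", "vcf"),
                                 groups, annotations = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  groups <- as_group_table(groups)
  parsed <- switch(dialect,
    matrix_csv = parse_matrix_csv(path, sep),
    vcf = parse_vcf_genotypes(path)
  )
  sample_ids <- colnames(parsed$calls)
  missing_grp <- setdiff(sample_ids, groups$sample_id)
  if (length(missing_grp)) {
    stop("sample(s) without group assignment: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  samples <- groups[match(sample_ids, groups$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  variants <- parsed$variants
  if (!is.null(annotations)) {
    if (is.character(annotations)) annotations <- read_annotations(annotations)
    variants <- merge_annotations(variants, annotations)
  }
  genotype_matrix(parsed$calls, variants, samples)
}

as_group_table <- function(groups) {
  if (is.character(groups) && length(groups) == 1 && is.null(names(groups)) &&
      file.exists(groups)) {
    groups <- utils::read.csv(groups, stringsAsFactors = FALSE)
  }
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- data.frame(sample_id = names(groups), group = unname(groups),
                         stringsAsFactors = FALSE)
  }
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    stop("groups need `sample_id` and `group` columns", call. = FALSE)
  }
  groups$group <- tolower(groups$group)
  groups
}

parse_matrix_csv <- function(path, sep) {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs a key column and >= 1 sample", call. = FALSE)
  keys <- raw[[1]]
  calls <- as.matrix(raw[, -1, drop = FALSE])
  rownames(calls) <- keys
  list(calls = calls,
       variants = data.frame(key = keys, stringsAsFactors = FALSE))
}

# VCF parsing is delegated to VariantAnnotation; only the GT-string to
# three-state mapping (and the multiallelic split) is done here.
parse_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the 'vcf' dialect requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alts <- VariantAnnotation::alt(vcf)
  ids <- names(rr)
  keys <- character(0); rsids <- character(0)
  refs <- character(0); alt_out <- character(0)
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    allele_lists <- strsplit(gt[i, ], "[/|]")
    n_alt <- length(alts[[i]])
    for (a in seq_len(n_alt)) {
      calls <- vapply(allele_lists, function(al) {
        if (any(al == ".")) return(NA_character_)
        GT_CODES[sum(al == as.character(a)) + 1L]
      }, character(1))
      alt_a <- as.character(alts[[i]][a])
      keys <- c(keys, sprintf("%s:%d:%s:%s", chrom[i], pos[i], ref[i], alt_a))
      rsid <- ids[i]
      rsids <- c(rsids, if (!is.null(rsid) && grepl("^rs", rsid)) rsid else NA_character_)
      refs <- c(refs, ref[i]); alt_out <- c(alt_out, alt_a)
      rows[[length(rows) + 1L]] <- calls
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- keys
  colnames(calls) <- colnames(gt)
  if (anyNA(calls)) {
    idx <- which(is.na(calls), arr.ind = TRUE)[1, ]
    stop(sprintf("missing GT call for variant %s, sample %s",
                 keys[idx[1]], colnames(calls)[idx[2]]), call. = FALSE)
  }
  list(calls = calls,
       variants = data.frame(key = keys, rsid = rsids, ref = refs,
                             alt = alt_out, stringsAsFactors = FALSE))
}

merge_annotations <- function(variants, annotations) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (is.null(ann$key)) stop("annotations need a `key` column", call. = FALSE)
  idx <- match(variants$key, ann$key)
  for (col in setdiff(names(ann), "key")) {
    new <- ann[[col]][idx]
    if (col %in% names(variants)) {
      keep <- !is.na(new)
      variants[[col]][keep] <- new[keep]
    } else {
      variants[[col]] <- new
    }
  }
  variants
}

#' Read a variant annotation table
#'
#' Delimited file with columns `key`, `gene`, `functional_class` and
#' `exonic_subtype` (subtype may be empty for non-exonic records);
#' optional `rsid` column.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame.
#' @export
read_annotations <- function(path, sep = ",") {
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("key", "gene", "functional_class") %in% names(ann))) {
    stop("annotation table needs key, gene, functional_class columns", call. = FALSE)
  }
  if (!is.null(ann$exonic_subtype)) {
    ann$exonic_subtype[ann$exonic_subtype == ""] <- NA_character_
  }
  ann
}

#' Read a reference-population allele-frequency table
#'
#' Delimited file with columns `key` and `alt_af`.  Keys absent from the
#' table are reported as absent (`NA`) on lookup; frequencies outside
#' \[0, 1\] are a load error.
#'
#' @param path file path.
#' @param sep field separator.
#' @return named numeric vector (key -> AltAF).
#' @export
read_population_frequencies <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("key", "alt_af") %in% names(tab))) {
    stop("population frequency table needs key and alt_af columns", call. = FALSE)
  }
  af <- as.numeric(tab$alt_af)
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop("alt_af outside [0, 1] in population frequency table", call. = FALSE)
  }
  stats::setNames(af, tab$key)
}

#' Look up population alternate-allele frequencies
#'
#' Tries the canonical `chrom:pos:ref:alt` key first, then the rsID alias
#' when one is available.  Unmatched variants get `NA` (absent).
#'
#' @param freqs named numeric vector from [read_population_frequencies()].
#' @param keys canonical variant keys.
#' @param rsids optional rsID aliases (same length as `keys`).
#' @return numeric vector of AltAFs with `NA` for absent variants.
#' @export
lookup_alt_af <- function(freqs, keys, rsids = NULL) {
  out <- unname(freqs[keys])
  if (!is.null(rsids)) {
    miss <- is.na(out) & !is.na(rsids)
    out[miss] <- unname(freqs[rsids[miss]])
  }
  out
}

#' Read a gene-size table
#'
#' Delimited file with columns `gene` and `size_bp` (captured size of each
#' gene in base pairs, as defined at probe design).
#'
#' @param path file path.
#' @param sep field separator.
#' @return named numeric vector (gene -> size in bp).
#' @export
read_gene_sizes <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "size_bp") %in% names(tab))) {
    stop("gene size table needs gene and size_bp columns", call. = FALSE)
  }
  sz <- as.numeric(tab$size_bp)
  if (any(is.na(sz) | sz <= 0)) stop("gene sizes must be positive", call. = FALSE)
  stats::setNames(sz, tab$gene)
}

#' Write a pipeline table to a delimited file
#'
#' Contingency tables, gene rank tables and cluster assignments are
#' written as plain CSV with a header so that the matching `read_*`
#' function round-trips them losslessly.
#'
#' @param obj object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  utils::write.csv(as.data.frame(obj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_contingency_table <- function(path) {
  validate_contingency_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_table
#' @export
read_gene_rank_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "rank", "rp", "fc", "pfp", "p_value")
  if (!all(need %in% names(tab))) {
    stop("gene rank table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  class(tab) <- unique(c("gene_rank_table", class(tab)))
  tab
}

#' @rdname write_table
#' @export
read_cluster_assignment <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "cluster") %in% names(tab))) {
    stop("cluster assignment needs key and cluster columns", call. = FALSE)
  }
  tab
}
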