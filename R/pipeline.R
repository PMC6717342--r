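#' Configuration for a full pipeline run
#'
#' @param matrix,groups,annotations,popfreq,gene_sizes input file paths
#'   (`annotations`, `popfreq`, `gene_sizes` may be `NULL` when the
#'   corresponding information is unavailable; `gene_sizes` is only
#'   required for `agg = "sum_over_size"`).
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed (required).
#' @param dialect genotype input dialect (`"matrix_csv"` or `"vcf"`).
#' @param n_reference_individuals reference-panel size (default 503).
#' @param drop_missing_af drop variants without AltAF instead of
#'   imputing the theoretical MAF.
#' @param filter,agg,k,n_experiments,n_permutations gene-ranking
#'   parameters (see [rank_genes()]).
#' @param K cluster count: `"auto"` or an integer.
#' @param sep field separator of the delimited inputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(matrix, groups, out_dir, seed,
                       annotations = NULL, popfreq = NULL, gene_sizes = NULL,
                       dialect = "matrix_csv", n_reference_individuals = 503,
                       drop_missing_af = FALSE,
                       filter = "protein_altering", agg = "mean",
                       k = 999, n_experiments = 4, n_permutations = 1000,
                       K = "auto", sep = ",") {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  cfg <- list(matrix = matrix, groups = groups, annotations = annotations,
              popfreq = popfreq, gene_sizes = gene_sizes, out_dir = out_dir,
              dialect = dialect,
              n_reference_individuals = n_reference_individuals,
              drop_missing_af = drop_missing_af, filter = filter, agg = agg,
              k = k, n_experiments = n_experiments,
              n_permutations = n_permutations, K = K, seed = seed, sep = sep)
  class(cfg) <- "run_config"
  cfg
}

#' Run both analysis branches end to end
#'
#' Reads the inputs, runs the genotype-adjustment workflow, then both
#' branches: the variant-level branch (correspondence analysis + HCPC
#' cluster labelling) and the gene-level branch (bootstrap ODDS +
#' two-class rank product).  All outputs are written to
#' `config$out_dir` as delimited text with headers, plus a JSON
#' adjustment report and a plain-text run log.  Re-running with an
#' identical config and seed reproduces every output byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `table`, `report`, `solution`,
#'   `clusters`, `gene_ranks` and the output paths.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- "load"
  res <- tryCatch({
    gm <- read_genotype_matrix(config$matrix, config$dialect, config$groups,
                               annotations = config$annotations,
                               sep = config$sep)
    say("loaded %d variants x %d samples", nrow(gm$calls), ncol(gm$calls))
    freqs <- NULL
    if (!is.null(config$popfreq)) {
      freqs <- read_population_frequencies(config$popfreq, sep = config$sep)
      say("population frequencies for %d keys", length(freqs))
    }
    sizes <- NULL
    if (!is.null(config$gene_sizes)) {
      sizes <- read_gene_sizes(config$gene_sizes, sep = config$sep)
    }

    stage <- "adjust"
    adj <- adjust_genotype_matrix(gm, freqs,
                                  config$n_reference_individuals,
                                  config$drop_missing_af)
    r <- adj$report
    say(paste0("adjustment: input=%d imputed=%d inverted=%d ",
               "removed_monomorphic=%d retained=%d"),
        r$n_input, r$n_imputed_maf, r$n_inverted,
        r$n_removed_monomorphic, r$n_output)
    paths <- list(
      contingency = file.path(config$out_dir, "contingency_table.csv"),
      report = file.path(config$out_dir, "adjustment_report.json"),
      coords = file.path(config$out_dir, "ca_coordinates.csv"),
      ca_summary = file.path(config$out_dir, "ca_summary.csv"),
      assignments = file.path(config$out_dir, "cluster_assignments.csv"),
      cluster_summary = file.path(config$out_dir, "cluster_summary.csv"),
      gene_ranks = file.path(config$out_dir, "gene_rank_table.csv"),
      log = file.path(config$out_dir, "run_log.txt")
    )
    write_table(adj$table, paths$contingency)
    jsonlite::write_json(unclass(r), paths$report, auto_unbox = TRUE)

    stage <- "fca"
    sol <- correspondence_analysis(adj$table)
    say("CA: %d dimensions, total inertia %.6g",
        length(sol$singular_values), sol$total_inertia)
    coords <- ca_project(sol, 2)
    write_table(data.frame(key = rownames(coords), coords,
                           check.names = FALSE), paths$coords)
    write_table(data.frame(dimension = seq_along(sol$singular_values),
                           singular_value = sol$singular_values,
                           eigenvalue = sol$eigenvalues,
                           explained = sol$explained), paths$ca_summary)

    stage <- "cluster"
    clus <- hcpc(adj$table, k = config$K, solution = sol)
    say("HCPC: K=%d (%d consolidation moves)", clus$K,
        clus$consolidation_moves)
    lab <- merge(clus$assignment,
                 clus$clusters[, c("cluster", "label")], by = "cluster")
    lab <- lab[match(clus$assignment$key, lab$key), c("key", "cluster", "label")]
    write_table(lab, paths$assignments)
    write_table(clus$clusters, paths$cluster_summary)

    stage <- "rankgenes"
    ranks <- rank_genes(adj$matrix, sizes = sizes, filter = config$filter,
                        agg = config$agg, k = config$k,
                        n_experiments = config$n_experiments,
                        n_permutations = config$n_permutations,
                        seed = config$seed,
                        n_reference_individuals = config$n_reference_individuals)
    say("rank product: %d variants in %d genes; top gene %s (RP %.3f)",
        attr(ranks, "n_variants"), attr(ranks, "n_genes"),
        ranks$gene[1], ranks$rp[1])
    write_table(ranks, paths$gene_ranks)

    writeLines(log_lines, paths$log)
    list(table = adj$table, report = adj$report, solution = sol,
         clusters = clus, gene_ranks = ranks, paths = paths)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}

#' Write a simulated cohort bundle to disk
#'
#' Serializes a [simulate_cohort()] bundle into the delimited files the
#' pipeline readers expect: `matrix.csv`, `groups.csv`,
#' `annotations.csv`, `popfreq.csv`, `gene_sizes.csv`, `truth.csv`.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory.
#' @return named list of file paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- bundle$matrix
  paths <- list(
    matrix = file.path(dir, "matrix.csv"),
    groups = file.path(dir, "groups.csv"),
    annotations = file.path(dir, "annotations.csv"),
    popfreq = file.path(dir, "popfreq.csv"),
    gene_sizes = file.path(dir, "gene_sizes.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_table(data.frame(key = rownames(gm$calls), gm$calls,
                         check.names = FALSE), paths$matrix)
  write_table(gm$samples, paths$groups)
  write_table(bundle$annotations, paths$annotations)
  write_table(bundle$popfreq, paths$popfreq)
  write_table(data.frame(gene = names(bundle$gene_sizes),
                         size_bp = as.numeric(bundle$gene_sizes)),
              paths$gene_sizes)
  write_table(bundle$truth, paths$truth)
  paths
}
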