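#' Factorial correspondence analysis of the three-group VAF table
#'
#' Standard correspondence analysis via the SVD of the matrix of
#' standardized chi-square residuals.  With `P` the table divided by its
#' grand total, row masses `r = rowSums(P)` and column masses
#' `c = colSums(P)`, the residual matrix is
#' `S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)`.  Row principal coordinates
#' are `diag(1/sqrt(r)) U D` and column principal coordinates
#' `diag(1/sqrt(c)) V D`, where `S = U D V'`.  Total inertia equals the
#' sum of squared singular values, which is the Pearson chi-square
#' statistic of the table divided by its grand total.
#'
#' The table holds frequencies (VAF fractions), not counts; CA is
#' scale-invariant, so this only enters through the masses, which are
#' defined by the raw column sums of the VAF table.
#'
#' @param tab a [contingency_table()] or a nonnegative numeric matrix
#'   with row/column names.  No all-zero row or column is allowed.
#' @return object of class `ca_solution` with elements `row_coords`,
#'   `col_coords` (principal coordinates), `singular_values`,
#'   `eigenvalues`, `total_inertia`, `explained`, `row_masses`,
#'   `col_masses`.  Dimensions with singular value below 1e-12 are
#'   dropped; axis signs are fixed so the `resistant` column (or, absent
#'   that name, the first column) loads nonnegatively on every axis.
#' @export
correspondence_analysis <- function(tab) {
  X <- as_ca_matrix(tab)
  if (any(X < 0)) stop("contingency table entries must be nonnegative", call. = FALSE)
  n <- sum(X)
  if (n <= 0) stop("contingency table grand total must be positive", call. = FALSE)
  zr <- rowSums(X) == 0
  if (any(zr)) {
    stop("all-zero row(s): ", paste(rownames(X)[zr], collapse = ", "), call. = FALSE)
  }
  zc <- colSums(X) == 0
  if (any(zc)) {
    stop("all-zero column(s): ", paste(colnames(X)[zc], collapse = ", "), call. = FALSE)
  }
  P <- X / n
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- (P - outer(r, c_)) / sqrt(outer(r, c_))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  k <- min(sum(keep), min(nrow(X), ncol(X)) - 1L)
  if (k == 0) {
    d <- numeric(0)
    row_coords <- matrix(0, nrow(X), 0, dimnames = list(rownames(X), NULL))
    col_coords <- matrix(0, ncol(X), 0, dimnames = list(colnames(X), NULL))
  } else {
    d <- sv$d[seq_len(k)]
    U <- sv$u[, seq_len(k), drop = FALSE]
    V <- sv$v[, seq_len(k), drop = FALSE]
    # SVD signs are arbitrary; anchor each axis on the resistant column.
    anchor <- if ("vaf_resistant" %in% colnames(X)) {
      which(colnames(X) == "vaf_resistant")
    } else 1L
    flip <- sign(V[anchor, ])
    flip[flip == 0] <- 1
    U <- sweep(U, 2, flip, `*`)
    V <- sweep(V, 2, flip, `*`)
    row_coords <- sweep(U, 1, sqrt(r), `/`) %*% diag(d, k)
    col_coords <- sweep(V, 1, sqrt(c_), `/`) %*% diag(d, k)
    dimnames(row_coords) <- list(rownames(X), paste0("Dim", seq_len(k)))
    dimnames(col_coords) <- list(colnames(X), paste0("Dim", seq_len(k)))
  }
  total <- sum(sv$d^2)
  structure(list(
    row_coords = row_coords,
    col_coords = col_coords,
    singular_values = d,
    eigenvalues = d^2,
    total_inertia = total,
    explained = if (total > 0) d^2 / total else d^2,
    row_masses = r,
    col_masses = c_
  ), class = "ca_solution")
}

as_ca_matrix <- function(tab) {
  if (inherits(tab, "contingency_table") ||
      (is.data.frame(tab) && all(c("key", "vaf_sensitive", "vaf_resistant",
                                   "maf_population") %in% names(tab)))) {
    X <- as.matrix(tab[, c("vaf_sensitive", "vaf_resistant", "maf_population")])
    rownames(X) <- tab$key
    return(X)
  }
  X <- as.matrix(tab)
  if (!is.numeric(X)) stop("cannot interpret table as numeric matrix", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("r", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  X
}

#' @export
print.ca_solution <- function(x, ...) {
  cat(sprintf("ca_solution: %d rows, %d dimensions, total inertia %.6g\n",
              nrow(x$row_coords), length(x$singular_values), x$total_inertia))
  if (length(x$explained)) {
    cat("  explained inertia:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Planar projection of the row (variant) cloud
#'
#' Returns the first `dims` principal coordinates per variant, padding
#' with zero columns when the table rank is below `dims`, with the
#' explained-inertia fractions attached.
#'
#' @param solution a `ca_solution`.
#' @param dims number of dimensions (default 2).
#' @return numeric matrix (variants x dims) with attribute `explained`.
#' @export
ca_project <- function(solution, dims = 2) {
  stopifnot(inherits(solution, "ca_solution"))
  have <- ncol(solution$row_coords)
  out <- matrix(0, nrow(solution$row_coords), dims,
                dimnames = list(rownames(solution$row_coords),
                                paste0("Dim", seq_len(dims))))
  use <- min(have, dims)
  if (use > 0) out[, seq_len(use)] <- solution$row_coords[, seq_len(use)]
  expl <- rep(0, dims)
  expl[seq_len(use)] <- solution$explained[seq_len(use)]
  attr(out, "explained") <- expl
  out
}
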