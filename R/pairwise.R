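#' Symmetric pairwise distance / similarity matrix
#'
#' Tags a symmetric matrix with the kind of quantity it holds and an optional
#' symmetric pair mask (TRUE = pair included in downstream statistics). The
#' diagonal is undefined and ignored everywhere.
#'
#' @param ids ordered unit labels (individuals or groups).
#' @param values symmetric numeric matrix.
#' @param kind one of `rousset_a`, `morans_i`, `euclidean`, `least_cost`,
#'   `resistance`, `fst`.
#' @param mask optional symmetric logical matrix; diagonal is forced FALSE.
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(ids, values,
                            kind = c("rousset_a", "morans_i", "euclidean",
                                     "least_cost", "resistance", "fst"),
                            mask = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- length(ids)
  .check(nrow(values) == n && ncol(values) == n,
         "values must be %d x %d", n, n)
  off <- row(values) != col(values)
  tv <- t(values)
  fin <- off & is.finite(values)
  sym_ok <- identical(is.na(values[off]), is.na(tv[off])) &&
    all(is.finite(values[off]) == is.finite(tv[off])) &&
    all(abs(values[fin] - tv[fin]) <=
          1e-9 * pmax(1, abs(values[fin])))
  .check(sym_ok, "values must be symmetric off the diagonal")
  values[fin] <- (values[fin] + tv[fin]) / 2  # remove solver float jitter
  diag(values) <- NA_real_
  dimnames(values) <- list(ids, ids)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    .check(all(dim(mask) == n), "mask must be %d x %d", n, n)
    .check(identical(mask, t(mask)), "mask must be symmetric")
    diag(mask) <- FALSE
    dimnames(mask) <- list(ids, ids)
  }
  structure(list(ids = as.character(ids), values = values, kind = kind,
                 mask = mask),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  v <- upper_pairs(x)
  cat(sprintf("pairwise_matrix [%s]: %d units, %d usable pairs\n",
              x$kind, length(x$ids), sum(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Upper-triangle values of a pairwise matrix
#'
#' Returns the off-diagonal upper-triangle entries, with masked-out pairs set
#' to `NA`.
#' @param pm a [pairwise_matrix()].
#' @return numeric vector of length `n*(n-1)/2`.
#' @export
upper_pairs <- function(pm) {
  ut <- upper.tri(pm$values)
  v <- pm$values[ut]
  if (!is.null(pm$mask)) v[!pm$mask[ut]] <- NA_real_
  v
}

#' Read / write a pairwise matrix as CSV (ids in first row and column)
#' @param path file path.
#' @param kind matrix kind (see [pairwise_matrix()]).
#' @return a [pairwise_matrix()].
#' @export
read_pairwise_csv <- function(path, kind) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  pairwise_matrix(rownames(df), as.matrix(df), kind = kind)
}

#' @rdname read_pairwise_csv
#' @param pm a [pairwise_matrix()] to write.
#' @export
write_pairwise_csv <- function(pm, path) {
  utils::write.csv(as.data.frame(pm$values), path)
  invisible(path)
}
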