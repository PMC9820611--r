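#' Expression matrix with time-course sample metadata
#'
#' The substrate of all correlation computations: a genes x samples matrix
#' of log-scale expression values together with the (time point, replicate)
#' identity of every column.  Samples are named `t<hours>h_r<rep>`, e.g.
#' `t0h_r1` for the first replicate of the unstressed control.
#'
#' @param values Numeric matrix, one row per gene, one column per sample.
#'   Row names are the gene IDs.  All values must be finite.
#' @param time_point Numeric vector of sampling times in hours, one per
#'   column of `values`.
#' @param replicate Integer vector of replicate indices, one per column.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, columns renamed canonically) and `sample_meta`
#'   (data frame with columns `sample`, `time_point`, `replicate`).
#'
#' @details Invariants enforced: no duplicate gene IDs, no duplicate
#'   (time point, replicate) pairs, every time point carries the same
#'   number of replicates, and all values are finite.
#'
#' @examples
#' m <- matrix(rnorm(12), nrow = 2,
#'             dimnames = list(c("g1", "g2"), NULL))
#' em <- expression_matrix(m, time_point = rep(c(0, 1, 3), each = 2),
#'                         replicate = rep(1:2, times = 3))
#' n_genes(em)
#' sample_names(em)
#' @export
expression_matrix <- function(values, time_point, replicate) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_hiergrn("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values))) {
    stop_hiergrn("`values` must have gene IDs as row names")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_hiergrn("duplicate gene IDs: ", paste(dup, collapse = ", "))
  }
  if (length(time_point) != ncol(values) ||
      length(replicate) != ncol(values)) {
    stop_hiergrn("`time_point` and `replicate` must have one entry per column")
  }
  if (!all(is.finite(values))) {
    stop_hiergrn("all expression values must be finite")
  }
  time_point <- as.numeric(time_point)
  replicate <- as.integer(replicate)
  if (any(time_point < 0)) stop_hiergrn("time points must be non-negative")
  key <- paste(time_point, replicate)
  if (anyDuplicated(key)) {
    stop_hiergrn("duplicate (time_point, replicate) pairs: ",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  reps_per_tp <- table(time_point)
  if (length(unique(as.integer(reps_per_tp))) > 1L) {
    stop_hiergrn("every time point must have the same replicate count")
  }
  ord <- order(time_point, replicate)
  values <- values[, ord, drop = FALSE]
  time_point <- time_point[ord]
  replicate <- replicate[ord]
  sample <- sample_id(time_point, replicate)
  colnames(values) <- sample
  structure(
    list(values = values,
         sample_meta = data.frame(sample = sample,
                                  time_point = time_point,
                                  replicate = replicate,
                                  stringsAsFactors = FALSE)),
    class = "ExpressionMatrix")
}

sample_id <- function(time_point, replicate) {
  # per-element formatting so c(0, 0.5) renders as "0" and "0.5", not "0.0"
  hours <- vapply(time_point,
                  function(t) format(t, trim = TRUE, scientific = FALSE),
                  character(1))
  sprintf("t%sh_r%d", hours, as.integer(replicate))
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_names <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
time_points <- function(x) sort(unique(x$sample_meta$time_point))

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tp <- time_points(x)
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (%d time points x %d replicates)\n",
    n_genes(x), n_samples(x), length(tp),
    n_samples(x) / max(1L, length(tp))))
  cat("time points (h):", paste(tp, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix to a set of genes
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Character vector of gene IDs; all must be present.
#' @return An `ExpressionMatrix` restricted to `genes`, in the given order.
#' @export
subset_genes <- function(x, genes) {
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing) > 0) {
    stop_hiergrn("genes absent from matrix: ",
                 paste(missing, collapse = ", "))
  }
  expression_matrix(x$values[genes, , drop = FALSE],
                    x$sample_meta$time_point, x$sample_meta$replicate)
}
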