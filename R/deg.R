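#' Fold change between treated and control replicate groups
#'
#' Values are expected on the log2 scale, so the log2 fold change is simply
#' the difference of group means and the linear fold change its power of
#' two.
#'
#' @param treated_values,control_values Numeric vectors of log2 expression,
#'   one entry per replicate; at least one each, all finite.
#' @return List with elements `fold_change` and `log2_fold_change`.
#' @examples
#' fold_change(c(3, 3.1), c(2, 1.9))   # ~2-fold induction
#' @export
fold_change <- function(treated_values, control_values) {
  if (length(treated_values) == 0 || length(control_values) == 0) {
    stop_hiergrn("both replicate vectors must be non-empty")
  }
  if (!all(is.finite(treated_values)) || !all(is.finite(control_values))) {
    stop_hiergrn("replicate values must be finite")
  }
  lfc <- mean(treated_values) - mean(control_values)
  list(fold_change = 2^lfc, log2_fold_change = lfc)
}

#' Two-sided Welch t-test p-value between replicate groups
#'
#' The default differential-expression test on log2 values.  It is a
#' deliberate simplification of count-based negative-binomial testing;
#' callers with externally computed p-values (e.g. from a dedicated
#' count-model package) can inject them through the `p_values` argument of
#' [call_degs()].
#'
#' Degenerate case: when both groups have zero within-group variance, the
#' test statistic is undefined; equal means then return p = 1 (no evidence
#' of change) and unequal means p = 0 (deterministic separation).
#'
#' @param treated_values,control_values Numeric vectors, >= 2 replicates
#'   each.
#' @return Two-sided p-value.
#' @export
de_test <- function(treated_values, control_values) {
  if (length(treated_values) < 2 || length(control_values) < 2) {
    stop_hiergrn(
      "need >= 2 replicates per group for the default Welch test; ",
      "supply external p-values to call_degs() otherwise")
  }
  if (stats::var(treated_values) == 0 && stats::var(control_values) == 0) {
    return(if (mean(treated_values) == mean(control_values)) 1 else 0)
  }
  stats::t.test(treated_values, control_values, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, clipped to 1, returned in the input
#' order.  Shared by the differential-expression and enrichment modules.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_hiergrn("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes against the 0 h control
#'
#' For every gene and every non-control time point, computes the fold
#' change and a p-value of treated vs control replicates, adjusts p-values
#' within each time point across all genes (Benjamini-Hochberg), and flags
#' a gene as differentially expressed when `fdr < fdr_max` and the fold
#' change is `> fc_up` or `< fc_down` (both strict).  A gene's global DEG
#' status is DEG at at least one time point: that union is the gene
#' universe entering network construction.
#'
#' Genes with zero variance and identical values across all samples
#' (flat zero profiles after log transform) are dropped before testing,
#' with a message reporting the count.
#'
#' @param matrix An [expression_matrix()] of log2 values.
#' @param control_time Hours of the control time point (default 0).
#' @param fdr_max,fc_up,fc_down DEG thresholds.
#' @param p_values Optional externally computed p-value matrix
#'   (genes x non-control time points, dimnames required) overriding the
#'   built-in Welch test.
#' @return Data frame of class `DEGTable` with columns `gene_id`,
#'   `time_point`, `log2_fold_change`, `fold_change`, `p_value`, `fdr`,
#'   `is_deg`, plus attribute `deg_genes`: the union described above.
#' @examples
#' g <- generate_planted_grn(2, 3, 10, mean_out_degree = 2, seed = 1)
#' em <- simulate_time_course(g, simulation_config(seed = 1))
#' tab <- call_degs(em)
#' head(tab)
#' @export
call_degs <- function(matrix, control_time = 0, fdr_max = 0.05,
                      fc_up = 1.5, fc_down = 0.66, p_values = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  meta <- matrix$sample_meta
  tps <- sort(unique(meta$time_point))
  if (!control_time %in% tps) {
    stop_hiergrn("control time ", control_time,
                 " not present; available time points: ",
                 paste(tps, collapse = ", "))
  }
  treat_tps <- setdiff(tps, control_time)
  if (length(treat_tps) == 0) stop_hiergrn("no non-control time points")

  vals <- matrix$values
  constant <- apply(vals, 1, function(v) all(v == v[1]) && v[1] == 0)
  if (any(constant)) {
    message(sum(constant), " all-zero gene(s) dropped before DE testing")
    vals <- vals[!constant, , drop = FALSE]
  }
  genes <- rownames(vals)
  ctrl_cols <- meta$sample[meta$time_point == control_time]

  rows <- lapply(treat_tps, function(tp) {
    trt_cols <- meta$sample[meta$time_point == tp]
    lfc <- rowMeans(vals[, trt_cols, drop = FALSE]) -
      rowMeans(vals[, ctrl_cols, drop = FALSE])
    if (is.null(p_values)) {
      p <- vapply(genes, function(g)
        de_test(vals[g, trt_cols], vals[g, ctrl_cols]), numeric(1))
    } else {
      tp_col <- as.character(tp)
      if (!all(genes %in% rownames(p_values)) ||
          !tp_col %in% colnames(p_values)) {
        stop_hiergrn("external p-value matrix must cover all genes and ",
                     "time points (column '", tp_col, "')")
      }
      p <- p_values[genes, tp_col]
    }
    data.frame(gene_id = genes, time_point = tp, log2_fold_change = lfc,
               fold_change = 2^lfc, p_value = p, fdr = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$is_deg <- tab$fdr < fdr_max &
    (tab$fold_change > fc_up | tab$fold_change < fc_down)
  tab <- tab[order(tab$time_point, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("DEGTable", "data.frame")
  attr(tab, "deg_genes") <- sort(unique(tab$gene_id[tab$is_deg]))
  tab
}

#' Union of genes flagged DEG at any time point
#'
#' @param deg_table A table from [call_degs()].
#' @return Character vector of gene IDs, sorted.
#' @export
deg_genes <- function(deg_table) {
  stopifnot(inherits(deg_table, "DEGTable"))
  attr(deg_table, "deg_genes")
}

#' Write a DEG table as TSV
#' @param deg_table A table from [call_degs()].
#' @param path Output file path.
#' @export
write_deg_table <- function(deg_table, path) {
  utils::write.table(as.data.frame(deg_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
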