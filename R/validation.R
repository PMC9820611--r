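#' Classify one tested TF -> target interaction
#'
#' The bench-validation decision rule: an interaction is `direct` when the
#' TF binds any of the four 500-bp quarters of the target's 2000-bp
#' promoter in ChIP-PCR (any number of bound fragments counts the same);
#' `indirect` when no fragment is bound but overexpressing the TF changes
#' the target's expression (qRT-PCR fold change strictly > 2 with
#' p < 0.05); `none` when qRT data are present but fail those gates; and
#' `untested` when no fragment is bound and no qRT data exist.
#'
#' @param chip_fragments Logical vector of length 4: binding outcome of
#'   promoter quarters I-IV.
#' @param qrt_fold_change Positive fold change from the overexpression
#'   qRT-PCR assay, or `NA` when not assayed.
#' @param qrt_p Its p-value in \[0, 1\], or `NA`.
#' @return One of `"direct"`, `"indirect"`, `"none"`, `"untested"`.
#' @examples
#' classify_interaction(c(FALSE, FALSE, TRUE, FALSE))        # direct
#' classify_interaction(rep(FALSE, 4), 2.5, 0.01)            # indirect
#' classify_interaction(rep(FALSE, 4), 1.2, 0.01)            # none
#' @export
classify_interaction <- function(chip_fragments, qrt_fold_change = NA_real_,
                                 qrt_p = NA_real_) {
  if (!is.logical(chip_fragments) || length(chip_fragments) != 4 ||
      anyNA(chip_fragments)) {
    stop_hiergrn("`chip_fragments` must be 4 non-missing booleans")
  }
  has_qrt <- !is.na(qrt_fold_change) || !is.na(qrt_p)
  if (has_qrt) {
    if (is.na(qrt_fold_change) || is.na(qrt_p)) {
      stop_hiergrn("qRT fold change and p-value must be given together")
    }
    if (qrt_fold_change <= 0) stop_hiergrn("qRT fold change must be positive")
    if (qrt_p < 0 || qrt_p > 1) stop_hiergrn("qRT p-value must be in [0, 1]")
  }
  if (any(chip_fragments)) return("direct")
  if (!has_qrt) return("untested")
  if (qrt_fold_change > 2 && qrt_p < 0.05) "indirect" else "none"
}

#' Build labelled validation records from an assay table
#'
#' @param records Data frame with columns `tf_id`, `target_id`,
#'   `layer_pair`, `frag1`..`frag4` (logical), and optional `qrt_fc`,
#'   `qrt_p`.
#' @return The same data frame with a `label` column appended.
#' @export
label_validation_records <- function(records) {
  frag_cols <- paste0("frag", 1:4)
  needed <- c("tf_id", "target_id", frag_cols)
  if (!all(needed %in% names(records))) {
    stop_hiergrn("records need columns ", paste(needed, collapse = ", "))
  }
  if (!"qrt_fc" %in% names(records)) records$qrt_fc <- NA_real_
  if (!"qrt_p" %in% names(records)) records$qrt_p <- NA_real_
  records$label <- vapply(seq_len(nrow(records)), function(i) {
    classify_interaction(as.logical(unlist(records[i, frag_cols])),
                         records$qrt_fc[i], records$qrt_p[i])
  }, character(1))
  records
}

#' Summarise labelled validation records
#'
#' Counts and one-decimal (half-up) percentages of direct, indirect and
#' unsupported interactions among the tested set; `pct_true` combines
#' direct and indirect as experimentally supported.
#'
#' @param records Data frame with a `label` column (from
#'   [label_validation_records()] or built directly); every record must be
#'   labelled `direct`, `indirect` or `none`.
#' @return List of class `ValidationSummary` with `n_tested`, `n_direct`,
#'   `n_indirect`, `n_none`, `pct_direct`, `pct_indirect`, `pct_none`,
#'   `pct_true`.
#' @examples
#' recs <- data.frame(label = c(rep("direct", 18), rep("indirect", 4),
#'                              rep("none", 3)))
#' summarize_validation(recs)
#' @export
summarize_validation <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_hiergrn("no validation records to summarise")
  }
  if (!"label" %in% names(records)) {
    stop_hiergrn("records must carry a `label` column")
  }
  untested <- which(records$label == "untested")
  if (length(untested) > 0) {
    stop_hiergrn("untested record(s) at row(s): ",
                 paste(untested, collapse = ", "))
  }
  bad <- setdiff(unique(records$label), c("direct", "indirect", "none"))
  if (length(bad) > 0) {
    stop_hiergrn("unknown label(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(records)
  n_direct <- sum(records$label == "direct")
  n_indirect <- sum(records$label == "indirect")
  n_none <- sum(records$label == "none")
  structure(list(
    n_tested = n, n_direct = n_direct, n_indirect = n_indirect,
    n_none = n_none,
    pct_direct = round_half_up(100 * n_direct / n, 1),
    pct_indirect = round_half_up(100 * n_indirect / n, 1),
    pct_none = round_half_up(100 * n_none / n, 1),
    pct_true = round_half_up(100 * (n_direct + n_indirect) / n, 1)),
    class = "ValidationSummary")
}

#' @export
print.ValidationSummary <- function(x, ...) {
  cat(sprintf("%d interactions tested: %d direct (%.1f%%), %d indirect ",
              x$n_tested, x$n_direct, x$pct_direct, x$n_indirect),
      sprintf("(%.1f%%), %d unsupported\n", x$pct_indirect, x$n_none),
      sep = "")
  cat(sprintf("%.1f%% of tested interactions are supported\n", x$pct_true))
  invisible(x)
}

#' Relative expression by the comparative CT method
#'
#' Computes `2^(-ddCt)` from qPCR cycle thresholds of a target gene and an
#' internal reference gene (e.g. TUBULIN2) under treated and control
#' conditions.  Replicate Ct vectors are averaged first;
#' `dCt = Ct_target - Ct_reference` per condition and
#' `ddCt = dCt_treated - dCt_control`.
#'
#' @param ct_target_treated,ct_reference_treated Ct values (scalar or
#'   replicate vector) under treatment.
#' @param ct_target_control,ct_reference_control Ct values under the
#'   control condition.
#' @return The relative expression `2^(-ddCt)`.
#' @examples
#' ddct_fold_change(20, 22, 21, 22)   # one cycle earlier: 2-fold
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- list(ct_target_treated, ct_reference_treated,
              ct_target_control, ct_reference_control)
  for (v in cts) {
    if (length(v) == 0 || !all(is.finite(v)) || any(v <= 0)) {
      stop_hiergrn("all Ct values must be positive finite numbers")
    }
  }
  d_treated <- mean(ct_target_treated) - mean(ct_reference_treated)
  d_control <- mean(ct_target_control) - mean(ct_reference_control)
  2^(-(d_treated - d_control))
}

#' Convenience two-sample t-test on replicate delta-Ct values
#'
#' The significance test for the qRT-PCR gate is in principle an input;
#' this helper provides a two-sided Welch test on per-replicate
#' `Ct_target - Ct_reference` differences for callers working from raw Ct
#' tables.
#'
#' @param dct_treated,dct_control Numeric vectors of replicate delta-Ct
#'   values, >= 2 each.
#' @return Two-sided p-value.
#' @export
qrt_p_value <- function(dct_treated, dct_control) {
  de_test(dct_treated, dct_control)
}

#' Read a validation assay table
#'
#' TSV with columns `tf_id`, `target_id`, `layer_pair`, `frag1`..`frag4`
#' (TRUE/FALSE), `qrt_fc`, `qrt_p` (empty or NA when not assayed).
#'
#' @param path Path to the TSV file.
#' @return Data frame ready for [label_validation_records()].
#' @export
read_validation_tsv <- function(path) {
  if (!file.exists(path)) stop_hiergrn("validation file not found: ", path)
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  for (col in paste0("frag", 1:4)) {
    if (!col %in% names(rec)) stop_hiergrn("missing column ", col)
    rec[[col]] <- as.logical(rec[[col]])
  }
  rec
}
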