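#' Thresholds for network construction
#'
#' The three gates of the triple-gene attribution scheme: a gene pair
#' (x, y) is co-expressed when their Pearson correlation passes
#' `r_xy >= r_min` with `p < p_max`, and a TF z explains the pair when the
#' first-order partial correlation satisfies `|r_xy|z| <= partial_max`.
#'
#' @param r_min Minimum pair correlation (default 0.8).  With
#'   `use_absolute_r = TRUE` the gate is `|r_xy| >= r_min`, admitting
#'   strongly anti-correlated pairs (repression-aware mode); the default
#'   screens positive correlations only.
#' @param p_max Maximum raw correlation p-value (default 0.001; not
#'   multiplicity-adjusted).
#' @param partial_max Maximum absolute partial correlation for attribution
#'   (default 0.3); must be smaller than `r_min`.
#' @param use_absolute_r Screen pairs on `|r|` instead of signed `r`.
#' @return A list of class `GRNParams`.
#' @export
grn_params <- function(r_min = 0.8, p_max = 0.001, partial_max = 0.3,
                       use_absolute_r = FALSE) {
  if (!is_scalar_number(r_min) || r_min <= 0 || r_min > 1) {
    stop_hiergrn("`r_min` must be in (0, 1]")
  }
  if (!is_scalar_number(p_max) || p_max <= 0 || p_max >= 1) {
    stop_hiergrn("`p_max` must be in (0, 1)")
  }
  if (!is_scalar_number(partial_max) || partial_max < 0 ||
      partial_max >= r_min) {
    stop_hiergrn("`partial_max` must satisfy 0 <= partial_max < r_min")
  }
  check_flag(use_absolute_r, "use_absolute_r")
  structure(list(r_min = r_min, p_max = p_max, partial_max = partial_max,
                 use_absolute_r = use_absolute_r),
            class = "GRNParams")
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample correlation plus the p-value of the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom; perfectly
#' correlated vectors (|r| = 1) return p = 0.
#'
#' @param x_values,y_values Numeric vectors of equal length n >= 3, each
#'   with nonzero variance.
#' @param x_name,y_name Optional labels used in error messages.
#' @return List with elements `r` and `p`.
#' @export
pearson_with_p <- function(x_values, y_values, x_name = "x", y_name = "y") {
  n <- length(x_values)
  if (length(y_values) != n) stop_hiergrn("vectors must have equal length")
  if (n < 3) stop_hiergrn("need n >= 3 samples for a correlation p-value")
  if (stats::sd(x_values) == 0) {
    stop_hiergrn("zero-variance profile for gene '", x_name, "'")
  }
  if (stats::sd(y_values) == 0) {
    stop_hiergrn("zero-variance profile for gene '", y_name, "'")
  }
  r <- stats::cor(x_values, y_values)
  list(r = r, p = cor_p_value(r, n))
}

# two-sided p for a Pearson r at sample size n (vectorised; keeps dim)
cor_p_value <- function(r, n) {
  rc <- pmin(1, pmax(-1, r))   # pmin/pmax drop dim attributes
  p <- 2 * stats::pt(abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, 0)),
                     df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  if (!is.null(dim(r))) dim(p) <- dim(r)
  p
}

#' First-order partial correlation from three pairwise correlations
#'
#' The correlation between x and y after removing the linear effect of the
#' conditioning gene z:
#' \deqn{r_{xy|z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'                      {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' It equals the correlation of the residuals of x and y after regressing
#' each on z, and is near zero when z fully explains the pair's
#' co-expression.  The result is clipped to \[-1, 1\] against
#' floating-point overshoot.
#'
#' @param r_xy Pair correlation in \[-1, 1\].
#' @param r_xz,r_yz Correlations with the conditioning gene, strictly
#'   inside (-1, 1).
#' @return The partial correlation `r_xy|z`.
#' @examples
#' partial_correlation(0.64, 0.8, 0.8)   # z explains the pair: 0
#' partial_correlation(0.9, 0, 0)        # independent conditioner: 0.9
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  for (v in list(r_xy, r_xz, r_yz)) {
    if (!is_scalar_number(v) || abs(v) > 1) {
      stop_hiergrn("correlations must be finite values in [-1, 1]")
    }
  }
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1) {
    stop_hiergrn("degenerate conditioning variable (|r| = 1 with z)")
  }
  res <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  min(1, max(-1, res))
}

# correlation matrix of the given genes across samples
gene_cor <- function(matrix, genes) {
  vals <- matrix$values[genes, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    stop_hiergrn("zero-variance profile for gene(s): ",
                 paste(genes[sds == 0], collapse = ", "))
  }
  stats::cor(t(vals))
}

#' Find co-expressed gene pairs
#'
#' All unordered pairs within `gene_set` whose Pearson correlation passes
#' the `r_min` and `p_max` gates of `params`.  Each pair is reported once
#' with `x < y` lexicographically.
#'
#' @param matrix An [expression_matrix()].
#' @param gene_set Character vector of gene IDs present in `matrix`.
#' @param params A [grn_params()].
#' @return Data frame with columns `x`, `y`, `r_xy`, `p_xy`, sorted by
#'   (`x`, `y`).
#' @export
find_coexpressed_pairs <- function(matrix, gene_set, params = grn_params()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(params, "GRNParams"))
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, gene_ids(matrix))
  if (length(missing) > 0) {
    stop_hiergrn("genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  if (length(gene_set) < 2) stop_hiergrn("need at least 2 genes")
  gene_set <- sort(unique(gene_set))
  C <- gene_cor(matrix, gene_set)
  n <- n_samples(matrix)
  P <- cor_p_value(C, n)
  keep <- upper.tri(C) & P < params$p_max &
    (if (params$use_absolute_r) abs(C) else C) >= params$r_min
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(x = gene_set[idx[, 1]], y = gene_set[idx[, 2]],
                    r_xy = C[idx], p_xy = P[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test candidate regulators against co-expressed pairs
#'
#' For every (pair, TF) combination with the TF z outside the pair,
#' computes `r_xz`, `r_yz` and the partial correlation `r_xy|z`, and flags
#' the triple as passing when `|r_xy|z| <= partial_max`.  All passing
#' triples are retained: a pair may be explained by several TFs and no
#' best-z selection is performed.  Triples with a degenerate conditioning
#' TF (|r_xz| = 1 or |r_yz| = 1) are skipped with a warning.
#'
#' @param pairs Data frame from [find_coexpressed_pairs()].
#' @param tf_ids Candidate regulator gene IDs.
#' @param matrix The [expression_matrix()] the pairs came from.
#' @param params A [grn_params()].
#' @return Data frame of triple tests with columns `x`, `y`, `z`, `r_xy`,
#'   `p_xy`, `r_xz`, `r_yz`, `r_xy_given_z`, `passes` (all computed
#'   triples, passing or not).
#' @export
attribute_pairs_to_regulators <- function(pairs, tf_ids, matrix,
                                          params = grn_params()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(params, "GRNParams"))
  tf_ids <- sort(unique(as.character(tf_ids)))
  empty <- data.frame(x = character(0), y = character(0), z = character(0),
                      r_xy = numeric(0), p_xy = numeric(0),
                      r_xz = numeric(0), r_yz = numeric(0),
                      r_xy_given_z = numeric(0), passes = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || length(tf_ids) == 0) return(empty)
  genes <- sort(unique(c(pairs$x, pairs$y, tf_ids)))
  C <- gene_cor(matrix, genes)
  n_pair <- nrow(pairs)
  n_tf <- length(tf_ids)
  # n_pair x n_tf correlation blocks
  Rxz <- C[pairs$x, tf_ids, drop = FALSE]
  Ryz <- C[pairs$y, tf_ids, drop = FALSE]
  Rxy <- matrix(pairs$r_xy, nrow = n_pair, ncol = n_tf)
  self <- outer(pairs$x, tf_ids, "==") | outer(pairs$y, tf_ids, "==")
  num <- Rxy - Rxz * Ryz
  # A conditioning TF perfectly collinear with a pair member makes the
  # formula 0/0.  When the numerator cancels exactly (the noiseless
  # single-parent limit, r_xy = r_xz r_yz) the partial correlation is 0 by
  # continuity; otherwise the triple is genuinely degenerate and skipped.
  collinear <- !self & (abs(Rxz) >= 1 | abs(Ryz) >= 1)
  cancelled <- collinear & num == 0
  degen <- collinear & num != 0
  if (any(degen)) {
    warning(sum(degen), " triple(s) skipped: degenerate conditioning TF ",
            "(|r| = 1 with a pair member)", call. = FALSE)
  }
  ok <- !self & !degen
  pc <- matrix(NA_real_, n_pair, n_tf)
  regular <- ok & !cancelled
  pc[regular] <- num[regular] /
    sqrt((1 - Rxz[regular]^2) * (1 - Ryz[regular]^2))
  pc[cancelled] <- 0
  pc[ok] <- pmin(1, pmax(-1, pc[ok]))
  idx <- which(ok, arr.ind = TRUE)
  out <- data.frame(
    x = pairs$x[idx[, 1]], y = pairs$y[idx[, 1]], z = tf_ids[idx[, 2]],
    r_xy = pairs$r_xy[idx[, 1]], p_xy = pairs$p_xy[idx[, 1]],
    r_xz = Rxz[ok], r_yz = Ryz[ok], r_xy_given_z = pc[ok],
    stringsAsFactors = FALSE)
  out$passes <- abs(out$r_xy_given_z) <= params$partial_max
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Materialise directed edges from passing triples
#'
#' Each passing triple (x, y, z) asserts co-regulation of the pair by z and
#' contributes both edges z -> x and z -> y; duplicates are merged,
#' accumulating the number of supporting triples.  Per merged edge the
#' strongest supporting triple (smallest `|r_xy|z|`) provides the reported
#' `r_xy` and `partial_r` provenance values.
#'
#' @param triples Data frame from [attribute_pairs_to_regulators()]; every
#'   row must have `passes = TRUE`.
#' @return Data frame with columns `source`, `target`, `n_support`,
#'   `r_xy`, `partial_r`, sorted by (source, target).
#' @export
edges_from_triples <- function(triples) {
  if (nrow(triples) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      n_support = integer(0), r_xy = numeric(0),
                      partial_r = numeric(0), stringsAsFactors = FALSE))
  }
  if (!all(triples$passes)) {
    stop_hiergrn("edges_from_triples() requires passing triples only")
  }
  long <- rbind(
    data.frame(source = triples$z, target = triples$x,
               r_xy = triples$r_xy, partial_r = triples$r_xy_given_z,
               stringsAsFactors = FALSE),
    data.frame(source = triples$z, target = triples$y,
               r_xy = triples$r_xy, partial_r = triples$r_xy_given_z,
               stringsAsFactors = FALSE))
  long <- long[order(long$source, long$target, abs(long$partial_r)), ]
  key <- paste(long$source, long$target, sep = "\r")
  first <- !duplicated(key)
  out <- long[first, , drop = FALSE]
  out$n_support <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out[, c("source", "target", "n_support", "r_xy", "partial_r")]
}

#' Three-layer hierarchical network container
#'
#' @param layer1,layer2,layer3 Character vectors of gene IDs, pairwise
#'   disjoint (layers may be empty for degenerate inputs).
#' @param edges Data frame with columns `source`, `target`, `layer_pair`
#'   (`"1->2"` or `"2->3"`), `n_support` (>= 1 supporting triples) and
#'   optionally `r_xy`, `partial_r`.
#' @param triples Optional data frame of all supporting triple tests.
#' @param two_layer_warning TRUE when the top layer could not be built
#'   (fewer than two middle-layer TFs to pair).
#' @return An object of class `HierarchicalGRN`.
#' @export
hierarchical_grn <- function(layer1, layer2, layer3, edges,
                             triples = NULL, two_layer_warning = FALSE) {
  layer1 <- sort(unique(as.character(layer1)))
  layer2 <- sort(unique(as.character(layer2)))
  layer3 <- sort(unique(as.character(layer3)))
  if (anyDuplicated(c(layer1, layer2, layer3))) {
    stop_hiergrn("layers must be pairwise disjoint")
  }
  required <- c("source", "target", "layer_pair", "n_support")
  if (!is.data.frame(edges) || !all(required %in% names(edges))) {
    stop_hiergrn("`edges` must have columns source, target, layer_pair, ",
                 "n_support")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (!all(edges$layer_pair %in% c("1->2", "2->3"))) {
      stop_hiergrn("layer_pair must be '1->2' or '2->3'")
    }
    if (any(edges$n_support < 1)) {
      stop_hiergrn("every edge needs >= 1 supporting triple")
    }
    is12 <- edges$layer_pair == "1->2"
    bad <- (is12 & !(edges$source %in% layer1 & edges$target %in% layer2)) |
      (!is12 & !(edges$source %in% layer2 & edges$target %in% layer3))
    if (any(bad)) {
      stop_hiergrn("edge endpoints inconsistent with their layer_pair")
    }
    edges <- edges[order(edges$layer_pair, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(layer1 = layer1, layer2 = layer2, layer3 = layer3,
                 edges = edges, triples = triples,
                 two_layer_warning = isTRUE(two_layer_warning)),
            class = "HierarchicalGRN")
}

#' @export
print.HierarchicalGRN <- function(x, ...) {
  cat(sprintf(
    "HierarchicalGRN: layers %d/%d/%d; edges %d (1->2) + %d (2->3) = %d\n",
    length(x$layer1), length(x$layer2), length(x$layer3),
    sum(x$edges$layer_pair == "1->2"), sum(x$edges$layer_pair == "2->3"),
    nrow(x$edges)))
  if (x$two_layer_warning) {
    cat("note: top layer could not be built (two-layer result)\n")
  }
  invisible(x)
}

#' Assemble a three-layer hierarchical network
#'
#' The two-pass construction at the heart of the package.  PASS A screens
#' co-expressed pairs among the structural DEGs and attributes them to TF
#' regulators: TFs acquiring at least one structural target form layer 2
#' and their edges the 2->3 set; structural genes with at least one
#' incoming edge form layer 3.  PASS B then screens pairs among the
#' layer-2 TFs and attributes them to the remaining TFs (`tf_degs` minus
#' layer 2): TFs acquiring at least one layer-2 target form layer 1, their
#' edges the 1->2 set.  A TF placed in layer 2 by PASS A is never eligible
#' for layer 1 (the passes condition on disjoint candidate sets), keeping
#' the layers disjoint.
#'
#' Layer-2 TFs without an upstream regulator are retained; TFs landing in
#' neither layer are dropped.  When PASS A leaves fewer than two layer-2
#' TFs, no pair can be formed and a two-layer result is returned with
#' `two_layer_warning = TRUE` and a warning.
#'
#' @param matrix An [expression_matrix()] covering all genes involved.
#' @param tf_degs Differentially expressed TF gene IDs (regulator
#'   candidates).
#' @param structural_degs Differentially expressed structural gene IDs;
#'   must be disjoint from `tf_degs`.
#' @param params A [grn_params()].
#' @return A [hierarchical_grn()] whose `triples` element carries every
#'   passing triple test with its `layer_pair`.
#' @examples
#' g <- generate_planted_grn(2, 4, 20, mean_out_degree = 4, seed = 3)
#' em <- simulate_time_course(g, simulation_config(seed = 3))
#' grn <- assemble_three_layer_grn(em, c(g$layer1_ids, g$layer2_ids),
#'                                 g$layer3_ids)
#' grn
#' @export
assemble_three_layer_grn <- function(matrix, tf_degs, structural_degs,
                                     params = grn_params()) {
  tf_degs <- sort(unique(as.character(tf_degs)))
  structural_degs <- sort(unique(as.character(structural_degs)))
  if (length(tf_degs) == 0 || length(structural_degs) == 0) {
    stop_hiergrn("`tf_degs` and `structural_degs` must both be non-empty")
  }
  if (length(intersect(tf_degs, structural_degs)) > 0) {
    stop_hiergrn("`tf_degs` and `structural_degs` must be disjoint: ",
                 paste(intersect(tf_degs, structural_degs), collapse = ", "))
  }

  # PASS A: structural pairs explained by any TF
  pairs_a <- find_coexpressed_pairs(matrix, structural_degs, params)
  triples_a <- attribute_pairs_to_regulators(pairs_a, tf_degs, matrix, params)
  passing_a <- triples_a[triples_a$passes, , drop = FALSE]
  edges_23 <- edges_from_triples(passing_a)
  layer2 <- sort(unique(edges_23$source))
  layer3 <- sort(unique(edges_23$target))

  # PASS B: pairs among layer-2 TFs explained by the remaining TFs
  upper_candidates <- setdiff(tf_degs, layer2)
  passing_b <- edges_from_triples(
    data.frame(x = character(0), y = character(0), z = character(0),
               r_xy = numeric(0), p_xy = numeric(0), r_xz = numeric(0),
               r_yz = numeric(0), r_xy_given_z = numeric(0),
               passes = logical(0)))
  edges_12 <- passing_b
  triples_b <- NULL
  two_layer <- FALSE
  if (length(layer2) >= 2 && length(upper_candidates) > 0) {
    pairs_b <- find_coexpressed_pairs(matrix, layer2, params)
    triples_b <- attribute_pairs_to_regulators(pairs_b, upper_candidates,
                                               matrix, params)
    edges_12 <- edges_from_triples(triples_b[triples_b$passes, , drop = FALSE])
  } else if (length(layer2) < 2 && length(layer2) > 0) {
    two_layer <- TRUE
    warning("fewer than 2 middle-layer TFs: top layer cannot be built; ",
            "returning a two-layer network", call. = FALSE)
  }
  layer1 <- sort(unique(edges_12$source))

  dropped <- setdiff(tf_degs, c(layer1, layer2))
  if (length(dropped) > 0) {
    message(length(dropped), " TF(s) entered neither layer and were dropped")
  }
  orphans <- setdiff(layer2, unique(edges_12$target))
  if (length(orphans) > 0 && length(layer1) > 0) {
    message(length(orphans), " middle-layer TF(s) kept without an ",
            "upstream regulator")
  }

  triples <- rbind(
    if (nrow(passing_a) > 0) cbind(passing_a, layer_pair = "2->3"),
    if (!is.null(triples_b) && any(triples_b$passes))
      cbind(triples_b[triples_b$passes, , drop = FALSE], layer_pair = "1->2"))
  edges <- rbind(
    if (nrow(edges_12) > 0) cbind(edges_12, layer_pair = "1->2"),
    if (nrow(edges_23) > 0) cbind(edges_23, layer_pair = "2->3"))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        n_support = integer(0), r_xy = numeric(0),
                        partial_r = numeric(0), layer_pair = character(0),
                        stringsAsFactors = FALSE)
  }
  hierarchical_grn(layer1, layer2, layer3, edges, triples = triples,
                   two_layer_warning = two_layer)
}

#' Summarise a hierarchical network
#'
#' Layer sizes, edge counts per layer pair, the total edge count, and the
#' GO-term composition of the bottom layer: for each term the number and
#' percentage (one decimal, half-up) of layer-3 genes annotated to it, plus
#' the percentage annotated to any term of an optional caller-specified
#' subset.
#'
#' @param grn A [hierarchical_grn()].
#' @param annotation Optional annotation data frame with columns `gene_id`,
#'   `term_id` (see [read_annotation_tsv()]).
#' @param go_terms Optional ordered character vector of term IDs to report;
#'   defaults to all terms annotating at least one layer-3 gene.
#' @param subset_terms Optional term subset for the combined percentage.
#' @return List of class `GRNSummary` with elements `layer_sizes`,
#'   `n_edges_12`, `n_edges_23`, `n_edges_total`, `go_composition` (data
#'   frame `term_id`, `count`, `pct`), and `subset_pct` (NA when no subset
#'   given; NaN sentinel when layer 3 is empty).
#' @export
summarize_grn <- function(grn, annotation = NULL, go_terms = NULL,
                          subset_terms = NULL) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  n3 <- length(grn$layer3)
  pct_of_layer3 <- function(k) {
    if (n3 == 0) NaN else round_half_up(100 * k / n3, 1)
  }
  go_composition <- NULL
  subset_pct <- NA_real_
  if (!is.null(annotation)) {
    ann <- annotation[annotation$gene_id %in% grn$layer3, , drop = FALSE]
    if (is.null(go_terms)) go_terms <- sort(unique(ann$term_id))
    counts <- vapply(go_terms, function(term)
      length(unique(ann$gene_id[ann$term_id == term])), integer(1))
    go_composition <- data.frame(term_id = go_terms, count = counts,
                                 pct = pct_of_layer3(counts),
                                 stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(subset_terms)) {
      k <- length(unique(ann$gene_id[ann$term_id %in% subset_terms]))
      subset_pct <- pct_of_layer3(k)
    }
  }
  structure(list(
    layer_sizes = c(layer1 = length(grn$layer1), layer2 = length(grn$layer2),
                    layer3 = n3),
    n_edges_12 = sum(grn$edges$layer_pair == "1->2"),
    n_edges_23 = sum(grn$edges$layer_pair == "2->3"),
    n_edges_total = nrow(grn$edges),
    go_composition = go_composition,
    subset_pct = subset_pct), class = "GRNSummary")
}

#' @export
print.GRNSummary <- function(x, ...) {
  cat(sprintf("layers: %d / %d / %d genes\n",
              x$layer_sizes[1], x$layer_sizes[2], x$layer_sizes[3]))
  cat(sprintf("edges: %d (1->2) + %d (2->3) = %d total\n",
              x$n_edges_12, x$n_edges_23, x$n_edges_total))
  if (!is.null(x$go_composition)) {
    cat("bottom-layer GO composition:\n")
    print(x$go_composition, row.names = FALSE)
    if (!is.na(x$subset_pct)) {
      cat(sprintf("subset terms cover %.1f%% of the bottom layer\n",
                  x$subset_pct))
    }
  }
  invisible(x)
}
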