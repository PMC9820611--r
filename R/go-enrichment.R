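#' Upper-tail hypergeometric p-value for term enrichment
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the term: `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Annotated genes among the drawn set (0 <= k <= min(K, n)).
#' @param K Annotated genes in the universe.
#' @param n Drawn set size (e.g. number of DEGs).
#' @param N Universe size.
#' @return The exact upper tail probability.
#' @examples
#' hypergeom_pvalue(3, 4, 5, 20)
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) {
    if (!is_scalar_number(v) || v < 0 || v != round(v)) {
      stop_hiergrn("k, K, n, N must be non-negative integers")
    }
  }
  if (k > min(K, n) || K > N || n > N) {
    stop_hiergrn("need k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

# Wallenius non-central hypergeometric PMF over the full support, by
# numerical integration of
#   P(X = x) = C(K, x) C(N-K, n-x) \int_0^1 (1-t^{w/D})^x (1-t^{1/D})^{n-x} dt
# with D = w (K - x) + (N - K - (n - x)).  The vector is renormalised to
# absorb quadrature error; with w = 1 it reduces to the central PMF.
wallenius_pmf <- function(K, n, N, odds) {
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- vapply(support, function(x) {
    D <- odds * (K - x) + (N - K - (n - x))
    if (D <= 0) return(if (length(support) == 1) 1 else 0)
    integrand <- function(t) {
      exp(x * log1p(-t^(odds / D)) + (n - x) * log1p(-t^(1 / D)))
    }
    val <- stats::integrate(integrand, 0, 1, rel.tol = 1e-10,
                            subdivisions = 500L)$value
    exp(lchoose(K, x) + lchoose(N - K, n - x)) * val
  }, numeric(1))
  list(support = support, pmf = pmf / sum(pmf))
}

wallenius_pvalue <- function(k, K, n, N, odds) {
  d <- wallenius_pmf(K, n, N, odds)
  sum(d$pmf[d$support >= k])
}

#' Read a gene -> GO term annotation table
#'
#' Two-column TSV (`gene_id`, `term_id`), one row per (gene, term)
#' membership; repeated gene rows carry multiple terms.  An optional third
#' column `term_name` provides human-readable labels.  Term IDs may be
#' `GO:` + 7 digits or free-text labels; both are accepted.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `gene_id`, `term_id` (and `term_name`
#'   when present).
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop_hiergrn("annotation file not found: ", path)
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("gene_id", "term_id") %in% names(ann))) {
    stop_hiergrn("annotation TSV needs columns gene_id, term_id")
  }
  ann
}

#' Test GO term enrichment of a gene set against a universe
#'
#' One test per term with at least one universe gene: central
#' hypergeometric by default, or the Wallenius non-central variant in
#' which per-gene bias weights reweight the sampling odds (a term's odds
#' ratio is the mean weight of its universe genes over the mean weight of
#' the remaining universe genes, and the tail probability is computed by
#' numerical integration).  With equal weights the Wallenius mode reduces
#' exactly to the central one.  P-values are Benjamini-Hochberg adjusted
#' across terms.
#'
#' @param deg_ids Genes of interest; must all be in `universe_ids`.
#' @param universe_ids The enrichment universe (stated explicitly by the
#'   caller; it is never inferred).
#' @param annotation Data frame with columns `gene_id`, `term_id`.
#' @param fdr_max Threshold on the adjusted p-value for the `enriched`
#'   flag.
#' @param mode `"central"` or `"wallenius"`.
#' @param bias_weights Named positive numeric vector covering the universe
#'   (required in wallenius mode).
#' @return Data frame with one row per term: `term_id`, `k` (DEGs in
#'   term), `K` (universe genes in term), `n` (DEG count), `N` (universe
#'   size), `p_value`, `fdr`, `enriched`, sorted by p-value.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
#'                   term_id = c("GO:0000001", "GO:0000001",
#'                               "GO:0000002", "GO:0000002"))
#' enrich(c("g1", "g2"), paste0("g", 1:10), ann)
#' @export
enrich <- function(deg_ids, universe_ids, annotation, fdr_max = 0.05,
                   mode = c("central", "wallenius"), bias_weights = NULL) {
  mode <- match.arg(mode)
  deg_ids <- unique(as.character(deg_ids))
  universe_ids <- unique(as.character(universe_ids))
  outside <- setdiff(deg_ids, universe_ids)
  if (length(outside) > 0) {
    stop_hiergrn("genes of interest not in the universe: ",
                 paste(outside, collapse = ", "))
  }
  ann <- annotation[annotation$gene_id %in% universe_ids, , drop = FALSE]
  if (nrow(ann) == 0) {
    stop_hiergrn("annotation is empty on the given universe")
  }
  if (mode == "wallenius") {
    if (is.null(bias_weights)) {
      stop_hiergrn("wallenius mode requires `bias_weights`")
    }
    if (!all(universe_ids %in% names(bias_weights)) ||
        any(bias_weights[universe_ids] <= 0)) {
      stop_hiergrn("`bias_weights` must be positive and cover the universe")
    }
  }
  N <- length(universe_ids)
  n <- length(deg_ids)
  terms <- sort(unique(ann$term_id))
  rows <- lapply(terms, function(term) {
    members <- unique(ann$gene_id[ann$term_id == term])
    K <- length(members)
    k <- length(intersect(members, deg_ids))
    p <- if (mode == "central") {
      hypergeom_pvalue(k, K, n, N)
    } else {
      w_in <- mean(bias_weights[members])
      w_out_genes <- setdiff(universe_ids, members)
      odds <- if (length(w_out_genes) == 0) 1 else
        w_in / mean(bias_weights[w_out_genes])
      wallenius_pvalue(k, K, n, N, odds)
    }
    data.frame(term_id = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$enriched <- out$fdr < fdr_max
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
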