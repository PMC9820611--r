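#' Read an expression matrix from TSV
#'
#' The canonical dialect: tab-separated, UTF-8, no quoting; first column
#' `gene_id`, remaining columns one sample each with header IDs formatted
#' `t<hours>h_r<rep>` (e.g. `t0h_r1`, `t24h_r3`).
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_hiergrn("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop_hiergrn("expression file must have a header and >= 1 gene row")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "gene_id") {
    stop_hiergrn("line 1: header must start with 'gene_id' followed by ",
                 "sample IDs")
  }
  sample_ids <- header[-1]
  m <- regmatches(sample_ids,
                  regexec("^t([0-9]+(?:\\.[0-9]+)?)h_r([0-9]+)$", sample_ids))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop_hiergrn("line 1: unparseable sample ID(s): ",
                 paste(sample_ids[bad], collapse = ", "),
                 " (expected t<hours>h_r<rep>)")
  }
  time_point <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  replicate <- vapply(m, function(x) as.integer(x[3]), integer(1))

  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- vapply(body, length, integer(1))
  if (any(widths != length(header))) {
    stop_hiergrn("ragged row at line ",
                 which(widths != length(header))[1] + 1L)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stop_hiergrn("duplicate gene ID '", dup, "' at line ",
                 which(genes == dup)[2] + 1L)
  }
  values <- do.call(rbind, lapply(body, function(row) {
    v <- suppressWarnings(as.numeric(row[-1]))
    v
  }))
  if (anyNA(values)) {
    stop_hiergrn("non-numeric value at line ",
                 which(rowSums(is.na(values)) > 0)[1] + 1L)
  }
  rownames(values) <- genes
  expression_matrix(values, time_point, replicate)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; writing and re-reading reproduces
#' the same text.
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  header <- paste(c("gene_id", sample_names(x)), collapse = "\t")
  rows <- vapply(seq_len(n_genes(x)), function(i) {
    paste(c(gene_ids(x)[i],
            sprintf("%.10g", x$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a TF gene list (one ID per line)
#'
#' @param path Path to the list file; blank lines are skipped.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_hiergrn("gene list not found: ", path)
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

#' Write a hierarchical network to disk
#'
#' Three formats: `sif` (one `source regulates target` line per edge),
#' `graphml` (with a `layer` node attribute and `r_xy`/`partial_r`/
#' `layer_pair` edge attributes, via igraph), and `tsv` (full edge
#' provenance: source, target, layer_pair, n_support, r_xy, partial_r).
#' Edge ordering is deterministic (sorted by layer pair, source, target).
#'
#' @param grn A [hierarchical_grn()].
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param path Output file path.
#' @export
write_network <- function(grn, format, path) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  if (!format %in% c("sif", "graphml", "tsv")) {
    stop_hiergrn("unknown format '", format,
                 "'; available: sif, graphml, tsv")
  }
  e <- grn$edges
  if (format == "sif") {
    writeLines(if (nrow(e) == 0) character(0) else
      paste(e$source, "regulates", e$target, sep = "\t"), path)
  } else if (format == "tsv") {
    cols <- intersect(c("source", "target", "layer_pair", "n_support",
                        "r_xy", "partial_r"), names(e))
    utils::write.table(e[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- grn_to_igraph(grn)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a hierarchical network to an igraph object
#'
#' Nodes carry a `layer` attribute (1, 2 or 3); edges carry `layer_pair`,
#' `n_support`, `r_xy` and `partial_r`.
#'
#' @param grn A [hierarchical_grn()].
#' @return An igraph directed graph.
#' @export
grn_to_igraph <- function(grn) {
  stopifnot(inherits(grn, "HierarchicalGRN"))
  nodes <- data.frame(
    name = c(grn$layer1, grn$layer2, grn$layer3),
    layer = rep(1:3, c(length(grn$layer1), length(grn$layer2),
                       length(grn$layer3))),
    stringsAsFactors = FALSE)
  e <- grn$edges
  col_or_na <- function(col) {
    if (col %in% names(e)) e[[col]] else rep(NA_real_, nrow(e))
  }
  edge_df <- data.frame(from = e$source, to = e$target,
                        layer_pair = e$layer_pair,
                        n_support = e$n_support,
                        r_xy = col_or_na("r_xy"),
                        partial_r = col_or_na("partial_r"),
                        stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edge_df, directed = TRUE, vertices = nodes)
}
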