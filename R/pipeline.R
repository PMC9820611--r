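#' Read and validate a pipeline configuration
#'
#' Configuration is a YAML document with the blocks below; unknown keys at
#' any level are rejected, and threshold ranges are validated before any
#' computation runs.
#'
#' ```yaml
#' seed: 1
#' out_dir: results/run1
#' simulate:            # either this block or `expression:`/`tf_list:`
#'   n1: 11
#'   n2: 19
#'   n3: 158
#'   mean_out_degree: 8
#'   time_points: [0, 1, 3, 5, 9, 12, 24]
#'   n_replicates: 3
#'   noise_sd: 0.05
#'   driver_smoothness: 3
#' deg:
#'   control_time: 0
#'   fdr_max: 0.05
#'   fc_up: 1.5
#'   fc_down: 0.66
#' grn:
#'   r_min: 0.8
#'   p_max: 0.001
#'   partial_max: 0.3
#'   use_absolute_r: false
#' enrichment:          # optional
#'   annotation: annotation.tsv
#'   fdr_max: 0.05
#'   mode: central
#' ```
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_hiergrn("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A raw config list (as parsed from YAML).
#' @export
validate_pipeline_config <- function(config) {
  check_keys <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown) > 0) {
      stop_hiergrn("unknown config key(s) in ", where, ": ",
                   paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, c("seed", "out_dir", "simulate", "expression",
                       "tf_list", "deg", "grn", "enrichment"), "top level")
  if (is.null(config$seed) || !is_scalar_number(config$seed)) {
    stop_hiergrn("config needs an integer `seed`")
  }
  if (is.null(config$out_dir)) stop_hiergrn("config needs `out_dir`")
  has_sim <- !is.null(config$simulate)
  has_expr <- !is.null(config$expression)
  if (has_sim == has_expr) {
    stop_hiergrn("config needs exactly one of `simulate` or `expression`")
  }
  if (has_expr && is.null(config$tf_list)) {
    stop_hiergrn("`expression` input requires a `tf_list` file")
  }
  if (has_sim) {
    check_keys(config$simulate,
               c("n1", "n2", "n3", "mean_out_degree", "time_points",
                 "n_replicates", "noise_sd", "driver_smoothness"),
               "simulate")
    sim <- config$simulate
    # constructor-level validation, before anything runs
    simulation_config(
      time_points = unlist(sim$time_points %||% c(0, 1, 3, 5, 9, 12, 24)),
      n_replicates = sim$n_replicates %||% 3,
      noise_sd = sim$noise_sd %||% 0.05,
      driver_smoothness = sim$driver_smoothness %||% 3,
      seed = config$seed)
    if (is.null(sim$n1) || is.null(sim$n2) || is.null(sim$n3)) {
      stop_hiergrn("simulate block needs n1, n2, n3")
    }
  }
  check_keys(config$deg %||% list(),
             c("control_time", "fdr_max", "fc_up", "fc_down"), "deg")
  check_keys(config$grn %||% list(),
             c("r_min", "p_max", "partial_max", "use_absolute_r"), "grn")
  grn <- config$grn %||% list()
  do.call(grn_params, grn)   # range checks
  if (!is.null(config$enrichment)) {
    check_keys(config$enrichment, c("annotation", "fdr_max", "mode"),
               "enrichment")
    if (!is.null(config$enrichment$mode) &&
        !config$enrichment$mode %in% c("central", "wallenius")) {
      stop_hiergrn("enrichment mode must be 'central' or 'wallenius'")
    }
  }
  structure(config, class = c("PipelineConfig", "list"))
}

#' Run the pipeline end to end
#'
#' Orchestrates simulate (or load) -> DEG calling -> network assembly ->
#' enrichment -> summary.  All stage outputs land in `out_dir`:
#' `expression.tsv`, `planted_edges.tsv` and `recovery.tsv` (simulated
#' runs), `deg_table.tsv`, `grn.sif`, `grn.graphml`, `grn_edges.tsv`,
#' `enrichment.tsv` (when an annotation is configured), `summary.json` and
#' `pipeline.log`.  Outputs are deterministic for a fixed config; the log
#' records every threshold and the gene/pair/triple/edge counts at each
#' filtering stage.
#'
#' @param config A config list (validated with
#'   [validate_pipeline_config()] if not already).
#' @return Invisibly, a list with the main in-memory artifacts
#'   (`expression`, `deg_table`, `grn`, `summary`, plus `planted` and
#'   `recovery` for simulated runs) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) {
    config <- validate_pipeline_config(config)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e) {
    stop_hiergrn("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e))
  }

  seed <- as.integer(config$seed)
  planted <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    em <- tryCatch({
      planted <- generate_planted_grn(sim$n1, sim$n2, sim$n3,
                                      sim$mean_out_degree %||% 8,
                                      seed = seed)
      cfg <- simulation_config(
        time_points = unlist(sim$time_points %||% c(0, 1, 3, 5, 9, 12, 24)),
        n_replicates = sim$n_replicates %||% 3,
        noise_sd = sim$noise_sd %||% 0.05,
        driver_smoothness = sim$driver_smoothness %||% 3,
        seed = seed)
      simulate_time_course(planted, cfg)
    }, error = function(e) fail("simulate", e))
    write_planted_grn(planted, file.path(out_dir, "planted_edges.tsv"))
    write_expression_tsv(em, file.path(out_dir, "expression.tsv"))
    tf_ids <- c(planted$layer1_ids, planted$layer2_ids)
    log("simulate: planted %d/%d/%d genes, %d edges, noise_sd %.3g",
        length(planted$layer1_ids), length(planted$layer2_ids),
        length(planted$layer3_ids), nrow(planted$edges),
        sim$noise_sd %||% 0.05)
  } else {
    em <- tryCatch(read_expression_tsv(config$expression),
                   error = function(e) fail("read-expression", e))
    tf_ids <- tryCatch(read_gene_list(config$tf_list),
                       error = function(e) fail("read-tf-list", e))
  }
  log("input: %d genes x %d samples; %d TF candidates",
      n_genes(em), n_samples(em), length(tf_ids))

  dg <- config$deg %||% list()
  deg_table <- tryCatch(
    call_degs(em, control_time = dg$control_time %||% 0,
              fdr_max = dg$fdr_max %||% 0.05,
              fc_up = dg$fc_up %||% 1.5, fc_down = dg$fc_down %||% 0.66),
    error = function(e) fail("deg", e))
  write_deg_table(deg_table, file.path(out_dir, "deg_table.tsv"))
  degs <- deg_genes(deg_table)
  log("deg: thresholds fdr < %.3g, fc > %.3g or < %.3g; %d of %d genes DEG",
      dg$fdr_max %||% 0.05, dg$fc_up %||% 1.5, dg$fc_down %||% 0.66,
      length(degs), n_genes(em))

  tf_degs <- intersect(degs, tf_ids)
  structural_degs <- setdiff(degs, tf_ids)
  log("deg split: %d TF DEGs, %d structural DEGs",
      length(tf_degs), length(structural_degs))

  params <- do.call(grn_params, config$grn %||% list())
  grn <- tryCatch(
    assemble_three_layer_grn(em, tf_degs, structural_degs, params),
    error = function(e) fail("build-grn", e))
  log("grn: thresholds r >= %.3g, p < %.3g, |partial r| <= %.3g",
      params$r_min, params$p_max, params$partial_max)
  n_pairs <- if (is.null(grn$triples)) 0 else
    nrow(unique(grn$triples[, c("x", "y")]))
  log("grn: %d explained pairs, %d passing triples, layers %d/%d/%d, %d + %d edges",
      n_pairs, if (is.null(grn$triples)) 0 else nrow(grn$triples),
      length(grn$layer1), length(grn$layer2), length(grn$layer3),
      sum(grn$edges$layer_pair == "1->2"),
      sum(grn$edges$layer_pair == "2->3"))
  write_network(grn, "sif", file.path(out_dir, "grn.sif"))
  write_network(grn, "graphml", file.path(out_dir, "grn.graphml"))
  write_network(grn, "tsv", file.path(out_dir, "grn_edges.tsv"))

  enr_tab <- NULL
  enr <- config$enrichment
  if (!is.null(enr) && !is.null(enr$annotation)) {
    enr_tab <- tryCatch({
      ann <- read_annotation_tsv(enr$annotation)
      enrich(degs, gene_ids(em), ann, fdr_max = enr$fdr_max %||% 0.05,
             mode = enr$mode %||% "central")
    }, error = function(e) fail("enrich", e))
    utils::write.table(enr_tab, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("enrichment: %d terms tested, %d enriched at fdr < %.3g",
        nrow(enr_tab), sum(enr_tab$enriched), enr$fdr_max %||% 0.05)
  }

  recovery <- NULL
  if (!is.null(planted)) {
    recovery <- score_recovery(planted, grn)
    utils::write.table(recovery, file.path(out_dir, "recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("recovery 2->3: precision %.3f, recall %.3f",
        recovery$precision[recovery$layer_pair == "2->3"],
        recovery$recall[recovery$layer_pair == "2->3"])
  }

  summary <- list(
    seed = seed,
    n_genes = n_genes(em),
    n_samples = n_samples(em),
    n_degs = length(degs),
    n_tf_degs = length(tf_degs),
    n_structural_degs = length(structural_degs),
    layer_sizes = list(layer1 = length(grn$layer1),
                       layer2 = length(grn$layer2),
                       layer3 = length(grn$layer3)),
    n_edges_12 = sum(grn$edges$layer_pair == "1->2"),
    n_edges_23 = sum(grn$edges$layer_pair == "2->3"),
    n_edges_total = nrow(grn$edges),
    n_enriched_terms = if (is.null(enr_tab)) NULL else sum(enr_tab$enriched))
  summary <- summary[!vapply(summary, is.null, logical(1))]
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(expression = em, deg_table = deg_table, grn = grn,
                 summary = summary, planted = planted, recovery = recovery,
                 out_dir = out_dir))
}
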