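#' Planted three-layer regulatory hierarchy
#'
#' Constructor and validator for the synthetic ground truth used to
#' benchmark network recovery: three disjoint gene layers and signed,
#' weighted regulator->target edges restricted to layer1->layer2 and
#' layer2->layer3.
#'
#' @param layer1_ids,layer2_ids,layer3_ids Character vectors of gene IDs,
#'   pairwise disjoint and non-empty.
#' @param edges Data frame with columns `regulator`, `target`, `weight`
#'   (signed, nonzero).  Every edge must run layer1->layer2 or
#'   layer2->layer3; every layer-2/3 gene needs an incoming edge and every
#'   layer-1/2 gene an outgoing edge.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `PlantedGRN`.
#' @seealso [generate_planted_grn()] to sample one at random.
#' @export
planted_grn <- function(layer1_ids, layer2_ids, layer3_ids, edges,
                        seed = NA_integer_) {
  layer1_ids <- as.character(layer1_ids)
  layer2_ids <- as.character(layer2_ids)
  layer3_ids <- as.character(layer3_ids)
  if (length(layer1_ids) == 0 || length(layer2_ids) == 0 ||
      length(layer3_ids) == 0) {
    stop_hiergrn("all three layers must be non-empty")
  }
  all_ids <- c(layer1_ids, layer2_ids, layer3_ids)
  if (anyDuplicated(all_ids)) {
    stop_hiergrn("layers must be pairwise disjoint with unique gene IDs")
  }
  required <- c("regulator", "target", "weight")
  if (!is.data.frame(edges) || !all(required %in% names(edges))) {
    stop_hiergrn("`edges` must have columns regulator, target, weight")
  }
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(edges$weight)) || any(edges$weight == 0)) {
    stop_hiergrn("edge weights must be finite and nonzero")
  }
  is_12 <- edges$regulator %in% layer1_ids & edges$target %in% layer2_ids
  is_23 <- edges$regulator %in% layer2_ids & edges$target %in% layer3_ids
  if (!all(is_12 | is_23)) {
    stop_hiergrn("edges must run layer1->layer2 or layer2->layer3 only")
  }
  if (anyDuplicated(edges[, c("regulator", "target")])) {
    stop_hiergrn("duplicate edges")
  }
  edges$layer_pair <- ifelse(is_12, "1->2", "2->3")
  if (!all(layer2_ids %in% edges$target[is_12]) ||
      !all(layer3_ids %in% edges$target[is_23])) {
    stop_hiergrn("every layer-2 and layer-3 gene needs >= 1 incoming edge")
  }
  if (!all(layer1_ids %in% edges$regulator[is_12]) ||
      !all(layer2_ids %in% edges$regulator[is_23])) {
    stop_hiergrn("every layer-1 and layer-2 gene needs >= 1 outgoing edge")
  }
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(layer1_ids = layer1_ids, layer2_ids = layer2_ids,
                 layer3_ids = layer3_ids, edges = edges,
                 seed = as.integer(seed)),
            class = "PlantedGRN")
}

#' @export
print.PlantedGRN <- function(x, ...) {
  cat(sprintf("PlantedGRN: %d/%d/%d genes, %d + %d edges (seed %s)\n",
              length(x$layer1_ids), length(x$layer2_ids),
              length(x$layer3_ids),
              sum(x$edges$layer_pair == "1->2"),
              sum(x$edges$layer_pair == "2->3"),
              x$seed))
  invisible(x)
}

#' Sample a random planted three-layer hierarchy
#'
#' Generates a ground-truth regulatory hierarchy of the shape used
#' throughout the package's benchmarks: `n1` top-layer TFs, `n2`
#' middle-layer TFs and `n3` bottom-layer structural genes.  Every layer-2
#' gene first receives `min(3, n1)` distinct uniformly chosen layer-1
#' parents and every layer-3 gene one layer-2 parent (guaranteeing
#' connectivity), then extra edges are added by repeatedly picking a
#' regulator uniformly among all layer-1/2 genes and giving it one new
#' permissible target, until the mean out-degree over regulators reaches
#' `mean_out_degree`.  Sampling regulators (rather than free
#' regulator-target slots) keeps the expected out-degree homogeneous
#' across the two regulator layers.
#'
#' Middle-layer TFs are multiply regulated by construction because a
#' single-parent middle TF would be an exact noiseless copy of its driver
#' and hence statistically indistinguishable from it — an unidentifiable
#' planted truth; real layered stress networks likewise show several
#' upstream regulators per middle-layer TF.
#'
#' Edge weights are drawn uniformly from ±\[0.5, 1.5\] (sign chosen by fair
#' coin), so no weight can be zero or negligibly small.
#'
#' @param n1,n2,n3 Layer sizes; `n1`, `n2` >= 1 and `n3` >= 2.
#' @param mean_out_degree Target mean number of outgoing edges per
#'   regulator (layer-1 and layer-2 genes combined); must be >= 1 and
#'   cannot exceed the maximum `(n1*n2 + n2*n3) / (n1 + n2)`.
#' @param seed Integer seed; the result is a pure function of the
#'   arguments.
#' @return A [planted_grn()] object.
#' @examples
#' g <- generate_planted_grn(3, 5, 20, mean_out_degree = 3, seed = 1)
#' g
#' @export
generate_planted_grn <- function(n1, n2, n3, mean_out_degree, seed) {
  if (!is_scalar_number(n1) || !is_scalar_number(n2) ||
      !is_scalar_number(n3) || n1 < 1 || n2 < 1 || n3 < 2) {
    stop_hiergrn("need n1 >= 1, n2 >= 1, n3 >= 2")
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2); n3 <- as.integer(n3)
  n_reg <- n1 + n2
  max_edges <- n1 * n2 + n2 * n3
  if (!is_scalar_number(mean_out_degree) || mean_out_degree < 1) {
    stop_hiergrn("`mean_out_degree` must be >= 1")
  }
  if (mean_out_degree * n_reg > max_edges) {
    stop_hiergrn(sprintf(
      "mean_out_degree %.2f exceeds the maximum possible %.2f",
      mean_out_degree, max_edges / n_reg))
  }
  l1 <- sprintf("TF1_%02d", seq_len(n1))
  l2 <- sprintf("TF2_%02d", seq_len(n2))
  l3 <- sprintf("SG_%03d", seq_len(n3))

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # forced connectivity: min(2, n1) layer-1 parents per layer-2 gene,
  # one layer-2 parent per layer-3 gene
  k12 <- min(3L, n1)
  parents_12 <- lapply(seq_len(n2), function(i) l1[sample.int(n1, k12)])
  reg <- c(unlist(parents_12), l2[sample.int(n2, n3, replace = TRUE)])
  tgt <- c(rep(l2, each = k12), l3)
  # coverage: every regulator must have at least one outgoing edge
  idle_l1 <- setdiff(l1, reg)
  if (length(idle_l1) > 0) {
    reg <- c(reg, idle_l1)
    tgt <- c(tgt, l2[sample.int(n2, length(idle_l1), replace = TRUE)])
  }
  idle_l2 <- setdiff(l2, reg)
  if (length(idle_l2) > 0) {
    reg <- c(reg, idle_l2)
    tgt <- c(tgt, l3[sample.int(n3, length(idle_l2), replace = TRUE)])
  }
  dup <- duplicated(paste(reg, tgt))
  reg <- reg[!dup]; tgt <- tgt[!dup]
  has_edge <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(reg)) assign(paste0(reg[i], "\r", tgt[i]), TRUE,
                                   envir = has_edge)
  n_target_edges <- max(length(reg), round(mean_out_degree * n_reg))
  regulators <- c(l1, l2)
  targets_of <- function(r) if (r %in% l1) l2 else l3
  n_now <- length(reg)
  while (n_now < n_target_edges) {
    r <- regulators[sample.int(n_reg, 1L)]
    pool <- targets_of(r)
    free <- pool[!vapply(pool, function(t)
      exists(paste0(r, "\r", t), envir = has_edge), logical(1))]
    if (length(free) == 0) next   # regulator saturated; resample
    t <- free[sample.int(length(free), 1L)]
    assign(paste0(r, "\r", t), TRUE, envir = has_edge)
    reg <- c(reg, r); tgt <- c(tgt, t)
    n_now <- n_now + 1L
  }
  weight <- stats::runif(n_now, 0.5, 1.5) *
    sample(c(-1, 1), n_now, replace = TRUE)
  planted_grn(l1, l2, l3,
              data.frame(regulator = reg, target = tgt, weight = weight,
                         stringsAsFactors = FALSE),
              seed = seed)
}

#' Simulation settings for the synthetic stress time course
#'
#' @param time_points Strictly increasing sampling times in hours; the
#'   first must be the unstressed control at 0 h.  At least 3 time points
#'   are required (pair correlation p-values are undefined below n = 3).
#' @param n_replicates Biological replicates per time point (>= 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   log-expression scale.  Layer profiles are standardised to unit
#'   variance over time, so `noise_sd` is directly the noise-to-signal
#'   ratio.
#' @param driver_smoothness Number of random sinusoid components summed to
#'   form each top-layer temporal profile; small values give smooth,
#'   slowly varying drivers.
#' @param seed Integer seed for profile and noise draws.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(time_points = c(0, 1, 3, 5, 9, 12, 24),
                              n_replicates = 3, noise_sd = 0.05,
                              driver_smoothness = 3, seed = 1) {
  time_points <- as.numeric(time_points)
  if (length(time_points) < 3) {
    stop_hiergrn("need at least 3 time points")
  }
  if (is.unsorted(time_points, strictly = TRUE) || time_points[1] != 0) {
    stop_hiergrn("time points must be strictly increasing and start at 0 h")
  }
  if (!is_scalar_number(n_replicates) || n_replicates < 1) {
    stop_hiergrn("`n_replicates` must be >= 1")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_hiergrn("`noise_sd` must be non-negative")
  }
  if (!is_scalar_number(driver_smoothness) || driver_smoothness < 1) {
    stop_hiergrn("`driver_smoothness` must be a positive integer")
  }
  structure(list(time_points = time_points,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd,
                 driver_smoothness = as.integer(driver_smoothness),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a noisy stress time course from a planted hierarchy
#'
#' Top-layer genes receive smooth random temporal profiles (sums of
#' `driver_smoothness` random sinusoids, standardised to zero mean and unit
#' variance over the time grid).  Each downstream gene's noiseless profile
#' is the weighted sum of its parents' noiseless profiles (weights from the
#' planted edges), re-standardised to unit variance.  Observed
#' log-expression is the noiseless profile plus independent Gaussian noise
#' per replicate.  Deterministic for a fixed config seed.
#'
#' With `pattern_drivers = TRUE` and a 3-gene (or larger) top layer,
#' the first three drivers are fixed stress-response archetypes instead of
#' random curves: early induction with late repression, early repression
#' with late induction, and an oscillating profile.
#'
#' @param grn A [planted_grn()] object.
#' @param config A [simulation_config()].
#' @param pattern_drivers Use archetype profiles for the first (up to)
#'   three top-layer genes instead of random smooth curves.
#' @return An [expression_matrix()] with one row per gene in `grn` and one
#'   column per (time point, replicate).
#' @examples
#' g <- generate_planted_grn(2, 3, 10, mean_out_degree = 2, seed = 1)
#' em <- simulate_time_course(g, simulation_config(seed = 1))
#' dim(em$values)
#' @export
simulate_time_course <- function(grn, config, pattern_drivers = FALSE) {
  stopifnot(inherits(grn, "PlantedGRN"), inherits(config, "SimulationConfig"))
  tp <- config$time_points
  n_tp <- length(tp)
  n_rep <- config$n_replicates

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  standardize <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop_hiergrn("degenerate constant profile; increase driver_smoothness")
    (v - mean(v)) / s
  }
  span <- max(tp) - min(tp)
  random_driver <- function() {
    v <- rep(0, n_tp)
    for (j in seq_len(config$driver_smoothness)) {
      amp <- stats::rnorm(1)
      freq <- stats::runif(1, 0.25, 1.5)   # cycles over the sampled span
      phase <- stats::runif(1, 0, 2 * pi)
      v <- v + amp * sin(2 * pi * freq * tp / span + phase)
    }
    standardize(v)
  }
  archetypes <- list(
    up_early_down_late = standardize(sin(pi * tp / span) - tp / span),
    down_early_up_late = standardize(tp / span - sin(pi * tp / span)),
    oscillating = standardize(sin(4 * pi * tp / span)))

  l1 <- grn$layer1_ids
  # Drivers are distinct temporal programs: a candidate too collinear with
  # an already accepted driver (|r| > 0.75) is redrawn, because with few
  # time points near-duplicate drivers would make the planted regulators
  # statistically indistinguishable.  Bounded retries keep this a total,
  # seed-deterministic function; after the retry budget the least
  # collinear candidate seen is kept.
  max_driver_cor <- 0.75
  driver_profiles <- matrix(NA_real_, nrow = length(l1), ncol = n_tp,
                            dimnames = list(l1, NULL))
  for (i in seq_along(l1)) {
    if (pattern_drivers && i <= 3) {
      driver_profiles[i, ] <- archetypes[[i]]
      next
    }
    best <- NULL
    best_cor <- Inf
    for (try in seq_len(200L)) {
      cand <- random_driver()
      worst <- if (i == 1) 0 else
        max(abs(stats::cor(cand, t(driver_profiles[seq_len(i - 1), ,
                                                   drop = FALSE]))))
      if (worst < best_cor) {
        best <- cand
        best_cor <- worst
      }
      if (worst <= max_driver_cor) break
    }
    driver_profiles[i, ] <- best
  }

  noiseless <- matrix(NA_real_, nrow = length(l1) + length(grn$layer2_ids) +
                        length(grn$layer3_ids), ncol = n_tp)
  ids <- c(l1, grn$layer2_ids, grn$layer3_ids)
  rownames(noiseless) <- ids
  noiseless[l1, ] <- driver_profiles
  mix_children <- function(child_ids) {
    for (g in child_ids) {
      e <- grn$edges[grn$edges$target == g, , drop = FALSE]
      prof <- colSums(e$weight * noiseless[e$regulator, , drop = FALSE])
      noiseless[g, ] <<- standardize(prof)
    }
  }
  mix_children(grn$layer2_ids)
  mix_children(grn$layer3_ids)

  values <- noiseless[, rep(seq_len(n_tp), each = n_rep), drop = FALSE]
  if (config$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(length(values),
                                           sd = config$noise_sd),
                              nrow = nrow(values))
  }
  expression_matrix(values,
                    time_point = rep(tp, each = n_rep),
                    replicate = rep(seq_len(n_rep), times = n_tp))
}

#' Score recovery of a planted hierarchy by an inferred network
#'
#' Compares the directed edge sets of an inferred [hierarchical_grn()]
#' against the planted truth, separately for layer1->layer2 and
#' layer2->layer3, ignoring weights and signs.
#'
#' @param planted A [planted_grn()].
#' @param inferred A [hierarchical_grn()].
#' @return Data frame with one row per layer pair and columns
#'   `layer_pair`, `n_planted`, `n_inferred`, `n_correct`, `precision`,
#'   `recall`, `f1`.  An empty inferred edge set yields `NaN` precision and
#'   zero recall rather than an error.
#' @export
score_recovery <- function(planted, inferred) {
  stopifnot(inherits(planted, "PlantedGRN"),
            inherits(inferred, "HierarchicalGRN"))
  out <- lapply(c("1->2", "2->3"), function(lp) {
    p <- planted$edges[planted$edges$layer_pair == lp, ]
    i <- inferred$edges[inferred$edges$layer_pair == lp, ]
    p_keys <- paste(p$regulator, p$target)
    i_keys <- paste(i$source, i$target)
    n_correct <- length(intersect(p_keys, i_keys))
    precision <- if (length(i_keys) == 0) NaN else n_correct / length(i_keys)
    recall <- if (length(p_keys) == 0) NaN else n_correct / length(p_keys)
    f1 <- if (is.nan(precision) || precision + recall == 0) NaN else
      2 * precision * recall / (precision + recall)
    data.frame(layer_pair = lp, n_planted = length(p_keys),
               n_inferred = length(i_keys), n_correct = n_correct,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a planted hierarchy as an edge-list TSV
#'
#' Columns: `regulator`, `target`, `weight`, `layer_pair`.
#' @param grn A [planted_grn()].
#' @param path Output file path.
#' @export
write_planted_grn <- function(grn, path) {
  stopifnot(inherits(grn, "PlantedGRN"))
  utils::write.table(grn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
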