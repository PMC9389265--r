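#' Specify a registration benchmark experiment
#'
#' Describes one repeated-registration experiment: a reference image (a
#' phantom spec or a file path), a ground-truth construction transform for
#' the floating image, the set of optimizers to compare, and the repetition
#' protocol. Repetition `r` runs with seed `base_seed + r - 1`, so any
#' individual run can be reproduced in isolation and the whole benchmark is
#' a pure function of the spec.
#'
#' By default the objective-evaluation budgets of all optimizers are matched
#' to the membrane optimizer's budget (`9 * particles * (steps + 1)`
#' evaluations), so comparisons are budget-fair: swarm iteration counts and
#' GA generation counts are derived from that budget, and the Powell stage
#' has a reserved share.
#'
#' @param reference a [phantom_spec], an [image2d], or a file path readable
#'   by [read_image()].
#' @param true_params construction transform for the floating image
#'   ([transform_params]).
#' @param algorithms subset of `c("tpsysir", "ga", "pso", "pso_powell")`.
#' @param repetitions number of seeded repetitions per algorithm
#'   (default 8).
#' @param modality `"single"` (float is the transformed reference) or
#'   `"multi"` (reference is the T2-like contrast, float the transformed
#'   T1-like contrast of the same anatomy).
#' @param bounds 4x2 search bounds matrix (default [default_bounds()]).
#' @param bins histogram bins for the MI objective.
#' @param base_seed integer; repetition `r` uses `base_seed + r - 1`.
#' @param tps_config an [evolution_config] for the membrane optimizer (its
#'   `bounds`/`bins`/`seed` fields are overridden per run by this spec).
#' @param configs optional named list of per-algorithm config overrides
#'   (`pso`, `ga`, `pso_powell`).
#' @param match_budget match every optimizer's evaluation budget to the
#'   membrane optimizer's (default `TRUE`).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(reference = phantom_spec(),
                            true_params = transform_params(8, 6, 5, 1),
                            algorithms = c("tpsysir", "ga", "pso", "pso_powell"),
                            repetitions = 8L,
                            modality = c("single", "multi"),
                            bounds = default_bounds(),
                            bins = 64L,
                            base_seed = 1L,
                            tps_config = NULL,
                            configs = list(),
                            match_budget = TRUE) {
  modality <- match.arg(modality)
  known <- c("tpsysir", "ga", "pso", "pso_powell")
  if (length(algorithms) < 1L) stop("at least one algorithm is required")
  bad <- setdiff(algorithms, known)
  if (length(bad) > 0)
    stop("unknown algorithm name(s): ", paste(bad, collapse = ", "))
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("`repetitions` must be >= 1")
  if (is.null(tps_config)) tps_config <- evolution_config(bounds = bounds, bins = bins)
  structure(list(reference = reference,
                 true_params = as_transform_params(true_params),
                 algorithms = algorithms, repetitions = repetitions,
                 modality = modality, bounds = validate_bounds(bounds),
                 bins = as.integer(bins), base_seed = as.integer(base_seed),
                 tps_config = tps_config, configs = configs,
                 match_budget = match_budget),
            class = "experiment_spec")
}

build_experiment_images <- function(spec) {
  ref_input <- spec$reference
  if (inherits(ref_input, "phantom_spec")) {
    ph <- make_phantom(ref_input)
    if (spec$modality == "multi") {
      pair <- make_modality_pair(ph$image, ph$labels, ref_input)
      ref <- pair$t2
      flt <- make_float(pair$t1, spec$true_params)
    } else {
      ref <- ph$image
      flt <- make_float(ph$image, spec$true_params)
    }
  } else {
    ref <- if (inherits(ref_input, "image2d")) ref_input else read_image(ref_input)
    if (spec$modality == "multi")
      stop("multimodal experiments require a phantom_spec reference")
    flt <- make_float(ref, spec$true_params)
  }
  list(ref = ref, flt = flt)
}

# total objective evaluations the membrane optimizer spends
tps_budget <- function(cfg) 9L * cfg$particles_per_membrane * (cfg$steps + 1L)

# evaluation share reserved for the Powell refinement stage when budgets
# are matched (each bracketed line search costs ~30-40 evaluations)
POWELL_RESERVE <- 500L

resolve_algorithm_configs <- function(spec) {
  budget <- tps_budget(spec$tps_config)
  pso <- modifyList(pso_config(), spec$configs[["pso"]] %||% list())
  ga <- modifyList(ga_config(), spec$configs[["ga"]] %||% list())
  psp <- modifyList(pso_powell_config(), spec$configs[["pso_powell"]] %||% list())
  if (isTRUE(spec$match_budget)) {
    pso$iters <- max(1L, as.integer(round(budget / pso$swarm)) - 1L)
    ga$gens <- max(1L, as.integer(round((budget - ga$pop) / (ga$pop - 1L))))
    psp$iters <- max(1L, as.integer(round(max(budget - POWELL_RESERVE, psp$swarm) /
                                            psp$swarm)) - 1L)
  }
  list(pso = pso, ga = ga, pso_powell = psp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one <- function(algorithm, objective, spec, cfgs, seed) {
  switch(algorithm,
         tpsysir = {
           cfg <- spec$tps_config
           cfg$bounds <- spec$bounds
           cfg$bins <- spec$bins
           run_tps_objective(objective, spec$bounds, cfg, seed)
         },
         pso = run_pso(objective, spec$bounds, cfgs$pso, seed),
         ga = run_ga(objective, spec$bounds, cfgs$ga, seed),
         pso_powell = run_pso_powell(objective, spec$bounds, cfgs$pso_powell, seed),
         stop("unknown algorithm name: ", algorithm))
}

# absolute angular difference folded into [0, 180]
angle_abs_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Run a repeated registration benchmark
#'
#' Builds the reference and floating images, then runs every requested
#' optimizer for `repetitions` seeded registrations. Each run records the
#' absolute deviation of every recovered parameter from the ground-truth
#' inverse transform (`dx`, `dy` in pixels, `dtheta` in degrees folded
#' modulo 360, `dZ` unitless) and the final MI score; deviations are
#' aggregated per algorithm into Max / Min / Mean and the half-range
#' `Delta = (Max - Min) / 2`.
#'
#' @param spec an [experiment_spec].
#' @return An object of class `experiment_result`: list with `summary` (one
#'   data.frame row per algorithm x statistic, one column per quantity),
#'   `runs` (per-run data.frame), `results` (list of
#'   `registration_result`s) and `spec`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  imgs <- build_experiment_images(spec)
  objective <- make_objective(imgs$ref, imgs$flt, spec$bins)
  truth <- as.numeric(attr(imgs$flt, "true_inverse"))
  cfgs <- resolve_algorithm_configs(spec)
  rows <- list()
  results <- list()
  for (alg in spec$algorithms) {
    for (r in seq_len(spec$repetitions)) {
      seed <- spec$base_seed + r - 1L
      res <- run_one(alg, objective, spec, cfgs, seed)
      p <- as.numeric(res$best_params)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, repetition = r, seed = seed,
        x = p[1], y = p[2], theta = p[3], Z = p[4],
        dx = abs(p[1] - truth[1]), dy = abs(p[2] - truth[2]),
        dtheta = angle_abs_diff(p[3], truth[3]), dZ = abs(p[4] - truth[4]),
        mi = res$best_score, evals = res$evals,
        stringsAsFactors = FALSE)
      results[[paste(alg, r, sep = "_")]] <- res
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(summary = summarize_runs(runs), runs = runs,
                 results = results, spec = spec,
                 truth_inverse = truth),
            class = "experiment_result")
}

#' Aggregate per-run records into a Max/Min/Mean/Delta table
#'
#' For each algorithm and each quantity (`dx`, `dy`, `dtheta`, `dZ`, `mi`)
#' computes the maximum, minimum and mean over repetitions and the
#' half-range `Delta = (Max - Min) / 2`. By construction
#' `Min <= Mean <= Max` and `Delta >= 0`; with a single repetition
#' `Max = Min = Mean` and `Delta = 0`.
#'
#' @param runs data.frame with columns `algorithm`, `dx`, `dy`, `dtheta`,
#'   `dZ`, `mi` (one row per run).
#' @return A data.frame with columns `algorithm`, `statistic` and the five
#'   quantities.
#' @export
summarize_runs <- function(runs) {
  quantities <- c("dx", "dy", "dtheta", "dZ", "mi")
  stopifnot(all(c("algorithm", quantities) %in% names(runs)))
  out <- list()
  for (alg in unique(runs$algorithm)) {
    sub <- runs[runs$algorithm == alg, , drop = FALSE]
    stats <- list(Max = function(v) max(v),
                  Min = function(v) min(v),
                  Mean = function(v) mean(v),
                  Delta = function(v) (max(v) - min(v)) / 2)
    for (s in names(stats)) {
      row <- data.frame(algorithm = alg, statistic = s,
                        stringsAsFactors = FALSE)
      for (q in quantities) row[[q]] <- stats[[s]](sub[[q]])
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %d algorithm(s) x %d repetition(s)>\n",
              length(unique(x$runs$algorithm)), x$spec$repetitions))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write benchmark outputs to disk
#'
#' Serializes a completed experiment: per-run records as JSON (parameters,
#' deviations, score, seed, trace), the Max/Min/Mean/Delta summary as CSV
#' (one row per algorithm x statistic, one column per quantity), and a
#' boxplot-ready long-format CSV of MI values (one row per algorithm x
#' repetition).
#'
#' @param result an `experiment_result` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(runs = file.path(dir, "runs.json"),
             summary = file.path(dir, "summary.csv"),
             mi_long = file.path(dir, "mi_long.csv"))
  records <- lapply(seq_len(nrow(result$runs)), function(i) {
    row <- result$runs[i, ]
    res <- result$results[[paste(row$algorithm, row$repetition, sep = "_")]]
    list(algorithm = row$algorithm, repetition = row$repetition,
         seed = row$seed,
         params = list(x = row$x, y = row$y, theta = row$theta, Z = row$Z),
         deviation = list(dx = row$dx, dy = row$dy, dtheta = row$dtheta,
                          dZ = row$dZ),
         mi = row$mi, evals = row$evals,
         trace = res$trace$score)
  })
  jsonlite::write_json(records, paths[["runs"]], auto_unbox = TRUE, digits = NA)
  write.csv(result$summary, paths[["summary"]], row.names = FALSE)
  write.csv(result$runs[, c("algorithm", "repetition", "seed", "mi")],
            paths[["mi_long"]], row.names = FALSE)
  invisible(paths)
}
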