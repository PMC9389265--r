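#' Configuration for the tissue-P-system optimizer
#'
#' Bundles every tunable of the membrane optimizer. Velocity updates follow a
#' three-attractor swarm rule: each particle is pulled toward its membrane's
#' local best, a randomly chosen neighbor-membrane best, and the parent
#' membrane's best, with an inertia weight that decays linearly across steps.
#'
#' @param omega_start,omega_end inertia schedule endpoints
#'   (`omega_start >= omega_end >= 0`); default 0.9 down to 0.4.
#' @param l0,l1,l2 non-negative learning factors weighting the pull toward
#'   the local, neighbor and parent best respectively; default 1.0 each,
#'   which keeps the total attraction weight at 3 — inside the convergent
#'   regime of swarm dynamics and matching the flat baseline swarm's
#'   `c1 + c2` (larger values make particles orbit the optimum without
#'   settling).
#' @param bounds 4x2 numeric matrix of closed search intervals, rows
#'   `(x, y, theta, Z)`; the `Z` lower bound must be positive. A zero-width
#'   row pins that parameter.
#' @param velocity_clamp per-dimension positive clamp on velocity magnitude,
#'   or `NULL` for the default of half the bound width per dimension.
#' @param particles_per_membrane particles in each of the 9 level-3
#'   membranes (default 10, i.e. a 90-particle system).
#' @param steps number of full system steps before halting (default 40).
#' @param bins histogram bins for the MI objective (default 64).
#' @param seed integer seed; the whole run is a pure function of
#'   (images, config, seed).
#' @return An object of class `evolution_config` (a list).
#' @export
evolution_config <- function(omega_start = 0.9, omega_end = 0.4,
                             l0 = 1.0, l1 = 1.0, l2 = 1.0,
                             bounds = default_bounds(),
                             velocity_clamp = NULL,
                             particles_per_membrane = 10L,
                             steps = 40L, bins = 64L, seed = 1L) {
  bounds <- validate_bounds(bounds)
  if (!(omega_start >= omega_end && omega_end >= 0))
    stop("inertia schedule requires omega_start >= omega_end >= 0")
  if (any(c(l0, l1, l2) < 0)) stop("learning factors must be non-negative")
  particles_per_membrane <- as.integer(particles_per_membrane)
  steps <- as.integer(steps)
  if (particles_per_membrane < 1L) stop("need at least one particle per membrane")
  if (steps < 1L) stop("`steps` must be a positive integer")
  widths <- bounds[, 2] - bounds[, 1]
  if (is.null(velocity_clamp)) velocity_clamp <- 0.5 * widths
  if (length(velocity_clamp) == 1L) velocity_clamp <- rep(velocity_clamp, 4)
  if (any(velocity_clamp < 0)) stop("velocity clamp must be non-negative")
  structure(list(omega_start = omega_start, omega_end = omega_end,
                 l0 = l0, l1 = l1, l2 = l2,
                 bounds = bounds, velocity_clamp = as.numeric(velocity_clamp),
                 particles_per_membrane = particles_per_membrane,
                 steps = steps, bins = as.integer(bins),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

#' Default search bounds for registration
#'
#' Translations within +/- 15 pixels, rotation within +/- 15 degrees, scale
#' in `[0.5, 1.5]`.
#'
#' @return A 4x2 matrix with rownames `x`, `y`, `theta`, `Z`.
#' @export
default_bounds <- function() {
  b <- rbind(x = c(-15, 15), y = c(-15, 15), theta = c(-15, 15), Z = c(0.5, 1.5))
  colnames(b) <- c("lower", "upper")
  b
}

validate_bounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (!identical(dim(bounds), c(4L, 2L)) || anyNA(bounds) || any(!is.finite(bounds)))
    stop("`bounds` must be a finite 4x2 matrix of (lower, upper) rows")
  if (any(bounds[, 2] < bounds[, 1])) stop("bounds must satisfy lower <= upper")
  if (bounds[4, 1] <= 0) stop("the Z lower bound must be positive")
  rownames(bounds) <- c("x", "y", "theta", "Z")
  colnames(bounds) <- c("lower", "upper")
  bounds
}

#' Inertia weight at a given step
#'
#' Linear interpolation from `omega_start` (step 0) to `omega_end`
#' (step `T - 1`); constant `omega_start` when `T = 1`. Non-increasing in `t`.
#'
#' @param t 0-based step index.
#' @param config an [evolution_config].
#' @return The inertia weight.
#' @export
inertia_weight <- function(t, config) {
  T <- config$steps
  if (T <= 1L) return(config$omega_start)
  config$omega_start + (config$omega_end - config$omega_start) * t / (T - 1)
}

# A membrane's evolving state. Level-3 membranes hold a positions/velocities
# matrix (m x 4); level-1/2 membranes aggregate only. `local_best` is a
# length-4 numeric with cached score; `neighbor_bests` / `pool` are lists of
# list(params, score) value-copies received over channels.
new_membrane_state <- function(id, positions = NULL, velocities = NULL) {
  list(id = id,
       positions = positions, velocities = velocities,
       local_best = NULL, local_best_score = -Inf,
       neighbor_bests = list(), parent_best = NULL,
       parent_best_score = -Inf,
       pool = list())
}

#' Pick the neighbor-best attractor for a membrane
#'
#' A uniformly random choice from the local optima most recently received
#' from sibling membranes. Before any communication has happened (the first
#' step) the membrane's own local best is used, which makes step 1
#' well-defined.
#'
#' @param mem a membrane state (see [run_tps()] internals).
#' @return A list with `params` (length-4 numeric) and `score`.
#' @keywords internal
#' @export
select_neighbor_best <- function(mem) {
  n <- length(mem$neighbor_bests)
  if (n == 0L)
    return(list(params = mem$local_best, score = mem$local_best_score))
  if (n == 1L) return(mem$neighbor_bests[[1L]])
  mem$neighbor_bests[[sample.int(n, 1L)]]
}

#' One evolution pass over a level-3 membrane
#'
#' For each particle, per dimension: draw `z0, z1, z2 ~ U(0,1)` and update
#' `v <- w_t v + l0 z0 (local - pos) + l1 z1 (neighbor - pos) +
#' l2 z2 (parent - pos)`, clamp the velocity per dimension, advance
#' `pos <- pos + v`, and clip into bounds. The membrane's local best is then
#' the objective argmax over all new positions and the incumbent best, ties
#' keeping the incumbent, so the local best score never decreases.
#'
#' @param mem a level-3 membrane state with at least one particle.
#' @param objective function mapping a length-4 numeric to a score.
#' @param t 0-based step index (sets the inertia weight).
#' @param config an [evolution_config].
#' @return The updated membrane state.
#' @keywords internal
#' @export
evolve_membrane <- function(mem, objective, t, config) {
  pos <- mem$positions
  vel <- mem$velocities
  if (is.null(pos) || nrow(pos) < 1L)
    stop("evolve_membrane requires a level-3 membrane with particles")
  w <- inertia_weight(t, config)
  nb <- select_neighbor_best(mem)$params
  pb <- if (is.null(mem$parent_best)) mem$local_best else mem$parent_best
  lb <- mem$local_best
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  clamp <- config$velocity_clamp
  m <- nrow(pos)
  for (k in seq_len(m)) {
    z0 <- runif(4); z1 <- runif(4); z2 <- runif(4)
    v <- w * vel[k, ] +
      config$l0 * z0 * (lb - pos[k, ]) +
      config$l1 * z1 * (nb - pos[k, ]) +
      config$l2 * z2 * (pb - pos[k, ])
    v <- pmin(pmax(v, -clamp), clamp)
    p <- pmin(pmax(pos[k, ] + v, lo), hi)
    if (any(!is.finite(v)) || any(!is.finite(p)))
      stop("non-finite particle update; check bounds and velocity clamp")
    vel[k, ] <- v
    pos[k, ] <- p
  }
  scores <- apply(pos, 1L, objective)
  best_k <- which.max(scores)
  mem$positions <- pos
  mem$velocities <- vel
  if (scores[best_k] > mem$local_best_score) {   # ties keep the incumbent
    mem$local_best <- pos[best_k, ]
    mem$local_best_score <- scores[best_k]
  }
  mem
}

#' Exchange local bests among sibling membranes
#'
#' Replicative intra-level communication: each membrane's `neighbor_bests`
#' is replaced by value-copies of every other sibling's current local best.
#' Sources are never mutated, and calling the exchange twice without
#' intervening evolution is idempotent.
#'
#' @param siblings list of membrane states sharing one parent.
#' @return The updated list of membrane states.
#' @keywords internal
#' @export
intra_communicate <- function(siblings) {
  bests <- lapply(siblings, function(s)
    list(params = s$local_best, score = s$local_best_score))
  for (i in seq_along(siblings)) {
    siblings[[i]]$neighbor_bests <- bests[-i]
  }
  siblings
}

#' Exchange local bests between a parent and its children
#'
#' Replicative inter-level communication: the parent accumulates value-copies
#' of all children's local bests into its candidate pool, and every child
#' receives a value-copy of the parent's (pre-call) local best. Children's
#' own local bests are unchanged.
#'
#' @param parent a level-2 membrane state.
#' @param children list of its level-3 children's states.
#' @return `list(parent, children)` with updated states.
#' @keywords internal
#' @export
inter_communicate <- function(parent, children) {
  up <- lapply(children, function(ch)
    list(params = ch$local_best, score = ch$local_best_score))
  parent$pool <- c(parent$pool, up)
  down <- list(params = parent$local_best, score = parent$local_best_score)
  for (i in seq_along(children)) {
    children[[i]]$parent_best <- down$params
    children[[i]]$parent_best_score <- down$score
  }
  list(parent = parent, children = children)
}

#' Select-and-substitute at an aggregating membrane
#'
#' Replaces the membrane's local best with the argmax of the objective over
#' its candidate pool and the incumbent, ties keeping the incumbent; the
#' pool is then cleared. Candidates communicated with cached scores are not
#' re-evaluated.
#'
#' @param parent a level-2 membrane state holding a candidate pool.
#' @param objective the similarity closure (used only for candidates that
#'   arrive without a cached score).
#' @return The updated membrane state.
#' @keywords internal
#' @export
select_substitute <- function(parent, objective) {
  for (cand in parent$pool) {
    if (is.null(cand$params)) next
    sc <- if (is.null(cand$score) || is.na(cand$score)) objective(cand$params) else cand$score
    if (sc > parent$local_best_score) {
      parent$local_best <- cand$params
      parent$local_best_score <- sc
    }
  }
  parent$pool <- list()
  parent
}

#' Promote level-2 bests to the output membrane
#'
#' The output membrane's best becomes the maximum-score object among the
#' level-2 local bests and its own incumbent; it never decreases.
#'
#' @param output_mem the level-1 output membrane state.
#' @param level2 list of the three level-2 membrane states.
#' @return The updated output membrane state.
#' @keywords internal
#' @export
promote_global <- function(output_mem, level2) {
  for (u in level2) {
    if (!is.null(u$local_best) && u$local_best_score > output_mem$local_best_score) {
      output_mem$local_best <- u$local_best
      output_mem$local_best_score <- u$local_best_score
    }
  }
  output_mem
}

#' One full system step
#'
#' In order: evolve all nine level-3 membranes; exchange local bests within
#' each sibling triple; exchange between each level-2 parent and its
#' children; select-and-substitute at each level-2 membrane; promote to the
#' output membrane. The global best score is non-decreasing across steps.
#'
#' @param sys system state as built by [run_tps()]: list with `topology`
#'   and `membranes` (named list of membrane states).
#' @param objective the similarity closure.
#' @param t 0-based step index.
#' @param config an [evolution_config].
#' @return The updated system state.
#' @keywords internal
#' @export
tps_step <- function(sys, objective, t, config) {
  topo <- sys$topology
  mem <- sys$membranes
  level2 <- topo$children[["m0"]]
  # rule 1 + 2: local evolution in every level-3 membrane
  for (u in level2) {
    for (ab in topo$children[[u]]) {
      mem[[ab]] <- evolve_membrane(mem[[ab]], objective, t, config)
    }
  }
  # rule 3: sibling exchange within each triple
  for (u in level2) {
    kids <- topo$children[[u]]
    mem[kids] <- intra_communicate(mem[kids])
  }
  # rule 4: parent <-> child exchange; rule 6: selection at level 2
  for (u in level2) {
    kids <- topo$children[[u]]
    ic <- inter_communicate(mem[[u]], mem[kids])
    mem[[u]] <- select_substitute(ic$parent, objective)
    mem[kids] <- ic$children
  }
  # rule 5: promotion to the output membrane
  mem[["m0"]] <- promote_global(mem[["m0"]], mem[level2])
  sys$membranes <- mem
  sys
}

#' Register two images with the tissue-P-system optimizer
#'
#' Builds the 13-membrane topology, initializes the nine level-3 membranes
#' with `particles_per_membrane` particles drawn uniformly within bounds
#' (velocities zero), evaluates the initial positions, and runs exactly
#' `steps` full system steps. The object held by the output membrane at
#' halting is returned as the solution.
#'
#' @param ref the fixed reference [image2d].
#' @param flt the floating [image2d].
#' @param config an [evolution_config]; `config$seed` makes the whole run
#'   deterministic.
#' @return A `registration_result`: list with `best_params`
#'   ([transform_params]), `best_score` (bits), `trace` (data.frame of step
#'   and global best score, non-decreasing), `steps_run`, `seed` and `evals`
#'   (objective evaluations spent).
#' @examples
#' \donttest{
#' ph <- make_phantom(phantom_spec(size = 64, seed = 1))
#' flt <- make_float(ph$image, transform_params(4, 3, 5, 1))
#' cfg <- evolution_config(particles_per_membrane = 5, steps = 10, seed = 7)
#' res <- run_tps(ph$image, flt, cfg)
#' res$best_params
#' }
#' @export
run_tps <- function(ref, flt, config = evolution_config()) {
  objective <- make_objective(ref, flt, config$bins)
  run_tps_objective(objective, config$bounds, config, config$seed)
}

# Objective-level entry point shared with the benchmark harness: identical
# contract (objective, bounds, config, seed) as the baseline optimizers.
run_tps_objective <- function(objective, bounds, config, seed) {
  config$bounds <- validate_bounds(bounds)
  set.seed(as.integer(seed))
  nevals <- 0L
  counted <- function(p) { nevals <<- nevals + 1L; objective(p) }

  topo <- build_topology()
  membranes <- setNames(lapply(topo$membrane_ids, new_membrane_state),
                        topo$membrane_ids)
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  m <- config$particles_per_membrane
  for (ab in topo$membrane_ids[topo$level == 3L]) {
    pos <- matrix(0, m, 4)
    for (d in 1:4) pos[, d] <- runif(m, lo[d], hi[d])
    st <- membranes[[ab]]
    st$positions <- pos
    st$velocities <- matrix(0, m, 4)
    scores <- apply(pos, 1L, counted)
    k <- which.max(scores)
    st$local_best <- pos[k, ]
    st$local_best_score <- scores[k]
    membranes[[ab]] <- st
  }
  sys <- list(topology = topo, membranes = membranes)

  trace_score <- numeric(config$steps)
  for (t in seq_len(config$steps) - 1L) {
    sys <- tps_step(sys, counted, t, config)
    trace_score[t + 1L] <- sys$membranes[["m0"]]$local_best_score
  }
  out <- sys$membranes[["m0"]]
  registration_result(best_params = out$local_best,
                      best_score = out$local_best_score,
                      trace = data.frame(step = seq_len(config$steps),
                                         score = trace_score),
                      steps_run = config$steps,
                      seed = as.integer(seed),
                      evals = nevals,
                      algorithm = "tpsysir")
}

registration_result <- function(best_params, best_score, trace, steps_run,
                                seed, evals, algorithm) {
  structure(list(best_params = as_transform_params(best_params),
                 best_score = best_score, trace = trace,
                 steps_run = steps_run, seed = seed, evals = evals,
                 algorithm = algorithm),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result [%s]: MI = %.4f bits after %d steps (%d evals, seed %d)>\n",
              x$algorithm, x$best_score, x$steps_run, x$evals, x$seed))
  print(x$best_params)
  invisible(x)
}
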