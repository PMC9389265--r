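#' Configuration for the baseline optimizers
#'
#' `pso_config()`: a single flat global-best swarm with linearly decaying
#' inertia, cognitive and social pulls, per-dimension velocity clamping and
#' position clipping — the same motion contracts as the membrane optimizer.
#'
#' `ga_config()`: a real-coded genetic algorithm with tournament selection,
#' blend (BLX-alpha) crossover, Gaussian mutation clipped to bounds and
#' elitism of one.
#'
#' `pso_powell_config()`: the swarm settings plus a derivative-free
#' coordinate-descent refinement stage (successive bracketed line
#' minimizations of the negated objective along each parameter direction,
#' repeated until the per-sweep improvement drops below `powell_tol` or
#' `powell_max_sweeps` is reached).
#'
#' @param swarm particles in the swarm (default 30).
#' @param iters swarm iterations (default 60).
#' @param omega_start,omega_end inertia schedule endpoints.
#' @param c1,c2 cognitive and social learning factors (default 1.49445,
#'   the constriction-factor value that keeps the swarm convergent).
#' @param pop GA population size (default 40).
#' @param gens GA generations (default 80).
#' @param pcross crossover probability per offspring pair (default 0.9).
#' @param pmut per-gene mutation probability (default 0.1).
#' @param mut_sd mutation standard deviation as a fraction of the bound
#'   width (default 0.1).
#' @param tournament tournament size (default 3).
#' @param blx_alpha blend-crossover expansion factor (default 0.5).
#' @param powell_tol minimum per-sweep score improvement to continue
#'   refinement (default 1e-4); `Inf` disables refinement entirely.
#' @param powell_max_sweeps maximum refinement sweeps (default 20).
#' @return A named list of settings.
#' @export
pso_config <- function(swarm = 30L, iters = 60L,
                       omega_start = 0.9, omega_end = 0.4,
                       c1 = 1.49445, c2 = 1.49445) {
  list(swarm = as.integer(swarm), iters = as.integer(iters),
       omega_start = omega_start, omega_end = omega_end, c1 = c1, c2 = c2)
}

#' @rdname pso_config
#' @export
ga_config <- function(pop = 40L, gens = 80L, pcross = 0.9, pmut = 0.1,
                      mut_sd = 0.1, tournament = 3L, blx_alpha = 0.5) {
  list(pop = as.integer(pop), gens = as.integer(gens), pcross = pcross,
       pmut = pmut, mut_sd = mut_sd, tournament = as.integer(tournament),
       blx_alpha = blx_alpha)
}

#' @rdname pso_config
#' @export
pso_powell_config <- function(swarm = 30L, iters = 60L,
                              omega_start = 0.9, omega_end = 0.4,
                              c1 = 1.49445, c2 = 1.49445,
                              powell_tol = 1e-4, powell_max_sweeps = 20L) {
  c(pso_config(swarm, iters, omega_start, omega_end, c1, c2),
    list(powell_tol = powell_tol, powell_max_sweeps = as.integer(powell_max_sweeps)))
}

#' Global-best particle swarm optimization
#'
#' Maximizes `objective` over the box `bounds` with one flat swarm. The
#' velocity update combines inertia (linearly decaying), a cognitive pull
#' toward each particle's personal best and a social pull toward the global
#' best; velocities are clamped per dimension to half the bound width and
#' positions clipped into bounds. The global-best trace is non-decreasing
#' and the run is a pure function of `(objective, bounds, config, seed)`.
#'
#' @param objective function from a length-4 numeric vector to a score
#'   (maximized).
#' @param bounds 4x2 matrix of closed intervals, rows `(x, y, theta, Z)`.
#' @param config see [pso_config()].
#' @param seed integer seed.
#' @return A `registration_result`.
#' @export
run_pso <- function(objective, bounds, config = pso_config(), seed = 1L) {
  bounds <- validate_bounds(bounds)
  set.seed(as.integer(seed))
  nevals <- 0L
  f <- function(p) { nevals <<- nevals + 1L; objective(p) }
  lo <- bounds[, 1]; hi <- bounds[, 2]
  clamp <- 0.5 * (hi - lo)
  S <- config$swarm; I <- config$iters
  pos <- matrix(0, S, 4)
  for (d in 1:4) pos[, d] <- runif(S, lo[d], hi[d])
  vel <- matrix(0, S, 4)
  pscore <- apply(pos, 1L, f)
  pbest <- pos
  g <- which.max(pscore)
  gbest <- pos[g, ]; gscore <- pscore[g]
  trace_score <- numeric(I)
  for (t in seq_len(I) - 1L) {
    w <- if (I <= 1L) config$omega_start else
      config$omega_start + (config$omega_end - config$omega_start) * t / (I - 1)
    for (k in seq_len(S)) {
      z1 <- runif(4); z2 <- runif(4)
      v <- w * vel[k, ] +
        config$c1 * z1 * (pbest[k, ] - pos[k, ]) +
        config$c2 * z2 * (gbest - pos[k, ])
      v <- pmin(pmax(v, -clamp), clamp)
      vel[k, ] <- v
      pos[k, ] <- pmin(pmax(pos[k, ] + v, lo), hi)
    }
    sc <- apply(pos, 1L, f)
    upd <- sc > pscore
    pbest[upd, ] <- pos[upd, , drop = FALSE]
    pscore[upd] <- sc[upd]
    g <- which.max(pscore)
    if (pscore[g] > gscore) { gbest <- pbest[g, ]; gscore <- pscore[g] }
    trace_score[t + 1L] <- gscore
  }
  registration_result(gbest, gscore,
                      data.frame(step = seq_len(I), score = trace_score),
                      I, as.integer(seed), nevals, "pso")
}

#' Real-coded genetic algorithm
#'
#' Tournament selection, blend (BLX-alpha) crossover, Gaussian mutation
#' clipped to bounds, and elitism of one, maximizing `objective`. The
#' best-so-far trace is non-decreasing (the elite is carried unchanged).
#'
#' @inheritParams run_pso
#' @param config see [ga_config()].
#' @return A `registration_result`.
#' @export
run_ga <- function(objective, bounds, config = ga_config(), seed = 1L) {
  bounds <- validate_bounds(bounds)
  set.seed(as.integer(seed))
  nevals <- 0L
  f <- function(p) { nevals <<- nevals + 1L; objective(p) }
  lo <- bounds[, 1]; hi <- bounds[, 2]
  width <- hi - lo
  P <- config$pop; G <- config$gens
  pop <- matrix(0, P, 4)
  for (d in 1:4) pop[, d] <- runif(P, lo[d], hi[d])
  fit <- apply(pop, 1L, f)
  trace_score <- numeric(G)
  pick <- function() {
    cand <- sample.int(P, config$tournament, replace = TRUE)
    cand[which.max(fit[cand])]
  }
  for (g in seq_len(G)) {
    elite_i <- which.max(fit)
    elite <- pop[elite_i, ]; elite_fit <- fit[elite_i]
    newpop <- matrix(0, P, 4)
    n_done <- 0L
    while (n_done < P) {
      a <- pop[pick(), ]; b <- pop[pick(), ]
      if (runif(1) < config$pcross) {
        # BLX-alpha: children uniform in the parent interval expanded by alpha
        cmin <- pmin(a, b); cmax <- pmax(a, b)
        span <- cmax - cmin
        l <- cmin - config$blx_alpha * span
        u <- cmax + config$blx_alpha * span
        c1 <- runif(4, l, u); c2 <- runif(4, l, u)
      } else {
        c1 <- a; c2 <- b
      }
      for (ch in list(c1, c2)) {
        if (n_done >= P) break
        mut <- runif(4) < config$pmut
        if (any(mut))
          ch[mut] <- ch[mut] + rnorm(sum(mut), 0, config$mut_sd * width[mut])
        n_done <- n_done + 1L
        newpop[n_done, ] <- pmin(pmax(ch, lo), hi)
      }
    }
    # elitism: the incumbent best occupies the first slot, carried unchanged
    newpop[1L, ] <- elite
    pop <- newpop
    fit <- c(elite_fit, apply(pop[-1L, , drop = FALSE], 1L, f))
    trace_score[g] <- max(fit)
  }
  besti <- which.max(fit)
  registration_result(pop[besti, ], fit[besti],
                      data.frame(step = seq_len(G), score = trace_score),
                      G, as.integer(seed), nevals, "ga")
}

#' Particle swarm with Powell-style local refinement
#'
#' Runs [run_pso()] and then refines its best point by derivative-free
#' coordinate-direction descent: bracketed line minimization of the negated
#' objective along each of the four parameter directions in turn, repeating
#' sweeps until the improvement in a full sweep falls below `powell_tol` or
#' `powell_max_sweeps` is reached. Refinement accepts only improvements, so
#' the final score is always >= the swarm's final score. With
#' `powell_tol = Inf` the refinement stage is disabled and the result is
#' identical to [run_pso()].
#'
#' @inheritParams run_pso
#' @param config see [pso_powell_config()].
#' @return A `registration_result`.
#' @export
run_pso_powell <- function(objective, bounds, config = pso_powell_config(),
                           seed = 1L) {
  bounds <- validate_bounds(bounds)
  base <- run_pso(objective, bounds, config, seed)
  if (is.infinite(config$powell_tol)) {
    base$algorithm <- "pso_powell"
    return(base)
  }
  nevals <- base$evals
  f <- function(p) { nevals <<- nevals + 1L; objective(p) }
  lo <- bounds[, 1]; hi <- bounds[, 2]
  p <- as.numeric(base$best_params)
  score <- base$best_score
  for (sweep in seq_len(config$powell_max_sweeps)) {
    sweep_start <- score
    for (d in 1:4) {
      if (hi[d] <= lo[d]) next   # pinned dimension
      line <- function(v) { q <- p; q[d] <- v; -f(q) }
      opt <- optimize(line, lower = lo[d], upper = hi[d], tol = 1e-6)
      if (-opt$objective > score) {
        p[d] <- opt$minimum
        score <- -opt$objective
      }
    }
    if (score - sweep_start < config$powell_tol) break
  }
  trace <- base$trace
  trace <- rbind(trace, data.frame(step = nrow(trace) + 1L, score = score))
  registration_result(p, score, trace, base$steps_run, as.integer(seed),
                      nevals, "pso_powell")
}
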