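test_that("the membrane topology is the fixed 13-node three-level tree", {
  topo <- build_topology()
  expect_equal(length(topo$membrane_ids), 13)
  expect_equal(sum(topo$level == 1L), 1)
  expect_equal(sum(topo$level == 2L), 3)
  expect_equal(sum(topo$level == 3L), 9)
  for (u in topo$children[["m0"]])
    expect_length(topo$children[[u]], 3)
  # channels are symmetric: (a,b) present iff (b,a) present
  key <- paste(topo$channels[, 1], topo$channels[, 2])
  rev <- paste(topo$channels[, 2], topo$channels[, 1])
  expect_setequal(key, rev)
  # parent-child and sibling arcs all present
  expect_true("m0 m01" %in% key)
  expect_true("m011 m012" %in% key)
  expect_false("m011 m021" %in% key)   # no cross-parent sibling channels
})

test_that("inertia weight interpolates linearly between its endpoints", {
  cfg <- evolution_config(omega_start = 0.9, omega_end = 0.4, steps = 21)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(20, cfg), 0.4)
  expect_equal(inertia_weight(10, cfg), (0.9 + 0.4) / 2)
  w <- sapply(0:20, inertia_weight, config = cfg)
  expect_true(all(diff(w) <= 0))
  cfg1 <- evolution_config(steps = 1)
  expect_equal(inertia_weight(0, cfg1), 0.9)
})

test_that("neighbor-best selection is uniform with a local fallback", {
  mem <- make_test_membrane(matrix(0, 1, 4), lbest = c(1, 2, 3, 1), lscore = 5)
  # empty neighbor list: the membrane's own best
  expect_equal(select_neighbor_best(mem)$params, c(1, 2, 3, 1))
  # singleton: always that object
  mem$neighbor_bests <- list(list(params = c(9, 9, 9, 1), score = 1))
  for (i in 1:5) expect_equal(select_neighbor_best(mem)$params, c(9, 9, 9, 1))
  # three neighbors: uniform to ~3 sigma over 3000 seeded draws
  mem$neighbor_bests <- lapply(1:3, function(i) list(params = rep(i, 4), score = i))
  set.seed(2024)
  picks <- replicate(3000, select_neighbor_best(mem)$params[1])
  freq <- tabulate(picks, 3) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("one evolution step matches the scalar velocity-position oracle", {
  cfg <- evolution_config(bounds = test_bounds(), steps = 10,
                          particles_per_membrane = 1)
  obj <- quad_objective(c(1, 2, 3, 1))
  pos <- matrix(c(2, -3, 4, 0.8), 1, 4)
  vel <- matrix(c(0.5, -0.2, 1, 0.05), 1, 4)
  mem <- make_test_membrane(pos, vel, lbest = c(1, 1, 1, 1), lscore = obj(c(1, 1, 1, 1)))
  mem$parent_best <- c(0, 0, 0, 1.2)
  t <- 3
  set.seed(555)
  out <- evolve_membrane(mem, obj, t, cfg)
  # replay the same seeded draws through the independent scalar oracle
  set.seed(555)
  z0 <- runif(4); z1 <- runif(4); z2 <- runif(4)
  w <- inertia_weight(t, cfg)
  oracle <- pso_update_oracle(pos[1, ], vel[1, ],
                              lbest = c(1, 1, 1, 1), nbest = c(1, 1, 1, 1),
                              pbest = c(0, 0, 0, 1.2),
                              w = w, l0 = cfg$l0, l1 = cfg$l1, l2 = cfg$l2,
                              z0 = z0, z1 = z1, z2 = z2,
                              clamp = cfg$velocity_clamp,
                              lo = cfg$bounds[, 1], hi = cfg$bounds[, 2])
  expect_equal(out$velocities[1, ], oracle$vel, tolerance = 1e-12)
  expect_equal(out$positions[1, ], oracle$pos, tolerance = 1e-12)
  # local best replaced only on strict improvement
  if (obj(oracle$pos) > obj(c(1, 1, 1, 1))) {
    expect_equal(out$local_best, oracle$pos)
  } else {
    expect_equal(out$local_best, c(1, 1, 1, 1))
  }
})

test_that("pure inertia advances positions by exactly the old velocity", {
  cfg <- evolution_config(bounds = test_bounds(100), l0 = 0, l1 = 0, l2 = 0,
                          omega_start = 1, omega_end = 1, steps = 5,
                          velocity_clamp = rep(1e6, 4),
                          particles_per_membrane = 3)
  pos <- matrix(runif(12, -5, 5), 3, 4)
  pos[, 4] <- runif(3, 0.7, 1.3)          # scale must stay inside its bounds
  vel <- matrix(runif(12, -1, 1), 3, 4)
  vel[, 4] <- runif(3, -0.1, 0.1)
  mem <- make_test_membrane(pos, vel, lbest = pos[1, ], lscore = 0)
  out <- evolve_membrane(mem, function(p) 0, 0, cfg)
  expect_equal(out$positions, pos + vel, tolerance = 1e-12)
  expect_equal(out$velocities, vel, tolerance = 1e-12)
})

test_that("a converged particle is a fixed point of the update", {
  cfg <- evolution_config(bounds = test_bounds(), steps = 5,
                          particles_per_membrane = 1)
  p <- c(1, 2, 3, 1)
  mem <- make_test_membrane(matrix(p, 1, 4), matrix(0, 1, 4),
                            lbest = p, lscore = 0)
  mem$parent_best <- p
  mem$neighbor_bests <- list(list(params = p, score = 0))
  out <- evolve_membrane(mem, function(q) 0, 0, cfg)
  expect_equal(out$positions[1, ], p)
  expect_equal(out$velocities[1, ], rep(0, 4))
  expect_equal(out$local_best, p)
})

test_that("sibling communication copies bests without mutating sources", {
  sib <- lapply(1:3, function(i) {
    m <- make_test_membrane(matrix(i, 1, 4), lbest = rep(i, 4), lscore = i)
    m$id <- paste0("m01", i)
    m
  })
  out <- intra_communicate(sib)
  # membrane 1 holds exactly the bests of membranes 2 and 3
  got <- sapply(out[[1]]$neighbor_bests, function(b) b$params[1])
  expect_setequal(got, c(2, 3))
  # sources unchanged, copies value-equal
  for (i in 1:3) expect_equal(out[[i]]$local_best, rep(i, 4))
  expect_equal(out[[2]]$neighbor_bests[[1]]$params, rep(1, 4))
  # idempotent without intervening evolution
  expect_identical(intra_communicate(out), out)
})

test_that("parent-child communication copies in both directions", {
  parent <- tpsreg:::new_membrane_state("m01")
  parent$local_best <- c(7, 7, 7, 1); parent$local_best_score <- 0.7
  children <- lapply(1:3, function(i)
    make_test_membrane(matrix(i, 1, 4), lbest = rep(i, 4), lscore = i / 10))
  ic <- inter_communicate(parent, children)
  expect_length(ic$parent$pool, 3)
  for (i in 1:3) {
    expect_equal(ic$children[[i]]$parent_best, c(7, 7, 7, 1))
    expect_equal(ic$children[[i]]$local_best, rep(i, 4))  # unchanged
  }
  pooled <- sapply(ic$parent$pool, function(b) b$params[1])
  expect_setequal(pooled, 1:3)
})

test_that("select-substitute is a max with incumbent-keeping ties", {
  obj <- function(p) p[1]
  parent <- tpsreg:::new_membrane_state("m01")
  parent$local_best <- c(5, 0, 0, 1); parent$local_best_score <- 5

  parent$pool <- list(list(params = c(9, 0, 0, 1), score = 9))
  out <- select_substitute(parent, obj)
  expect_equal(out$local_best_score, 9)
  expect_length(out$pool, 0)

  parent$pool <- list(list(params = c(1, 0, 0, 1), score = 1),
                      list(params = c(2, 0, 0, 1), score = 2))
  out <- select_substitute(parent, obj)
  expect_equal(out$local_best, c(5, 0, 0, 1))     # all candidates worse

  parent$pool <- list(list(params = c(99, 0, 0, 1), score = 5))  # exact tie
  out <- select_substitute(parent, obj)
  expect_equal(out$local_best, c(5, 0, 0, 1))     # incumbent retained
})

test_that("promotion takes the max over level-2 bests and never decreases", {
  outm <- tpsreg:::new_membrane_state("m0")
  l2 <- lapply(c(0.3, 0.9, 0.6), function(s) {
    m <- tpsreg:::new_membrane_state("u")
    m$local_best <- c(s, 0, 0, 1); m$local_best_score <- s
    m
  })
  outm <- promote_global(outm, l2)
  expect_equal(outm$local_best_score, 0.9)        # first step: best of level 2
  worse <- lapply(l2, function(m) { m$local_best_score <- 0.1; m })
  expect_equal(promote_global(outm, worse)$local_best_score, 0.9)
})

test_that("a full step conserves particles and the global best tracks the tree max", {
  obj <- quad_objective(c(1, -2, 3, 1))
  cfg <- evolution_config(bounds = test_bounds(), steps = 20,
                          particles_per_membrane = 3, seed = 5)
  set.seed(5)
  topo <- build_topology()
  membranes <- setNames(lapply(topo$membrane_ids, tpsreg:::new_membrane_state),
                        topo$membrane_ids)
  for (ab in topo$membrane_ids[topo$level == 3L]) {
    pos <- matrix(runif(12, -5, 5), 3, 4)
    pos[, 4] <- runif(3, 0.5, 1.5)
    membranes[[ab]]$positions <- pos
    membranes[[ab]]$velocities <- matrix(0, 3, 4)
    sc <- apply(pos, 1, obj)
    membranes[[ab]]$local_best <- pos[which.max(sc), ]
    membranes[[ab]]$local_best_score <- max(sc)
  }
  state <- list(topology = topo, membranes = membranes)
  prev_global <- -Inf
  for (t in 0:4) {
    state <- tps_step(state, obj, t, cfg)
    mems <- state$membranes
    for (ab in topo$membrane_ids[topo$level == 3L])
      expect_equal(nrow(mems[[ab]]$positions), 3)
    scores <- sapply(mems, function(m) m$local_best_score)
    expect_equal(mems[["m0"]]$local_best_score, max(scores))
    expect_gte(mems[["m0"]]$local_best_score, prev_global)
    prev_global <- mems[["m0"]]$local_best_score
  }
})

test_that("a zeroed system with no attraction is a step fixed point", {
  cfg <- evolution_config(bounds = test_bounds(), l0 = 0, l1 = 0, l2 = 0,
                          omega_start = 1, omega_end = 1,
                          particles_per_membrane = 2, steps = 5)
  topo <- build_topology()
  membranes <- setNames(lapply(topo$membrane_ids, tpsreg:::new_membrane_state),
                        topo$membrane_ids)
  for (ab in topo$membrane_ids[topo$level == 3L]) {
    pos <- matrix(rep(c(1, 1, 1, 1), each = 2), 2, 4)
    membranes[[ab]]$positions <- pos
    membranes[[ab]]$velocities <- matrix(0, 2, 4)
    membranes[[ab]]$local_best <- pos[1, ]
    membranes[[ab]]$local_best_score <- 0
  }
  state <- list(topology = topo, membranes = membranes)
  out <- tps_step(state, function(p) 0, 0, cfg)
  for (ab in topo$membrane_ids[topo$level == 3L])
    expect_equal(out$membranes[[ab]]$positions,
                 state$membranes[[ab]]$positions)
})

test_that("runs are seeded-deterministic with a well-formed trace", {
  ph <- make_phantom(phantom_spec(size = 48, seed = 2))
  flt <- make_float(ph$image, transform_params(3, 2, 4, 1))
  cfg <- evolution_config(bounds = test_bounds(8), particles_per_membrane = 3,
                          steps = 6, bins = 32, seed = 77)
  r1 <- run_tps(ph$image, flt, cfg)
  r2 <- run_tps(ph$image, flt, cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$trace), 6)
  expect_equal(r1$trace$score[6], r1$best_score)
  expect_true(all(diff(r1$trace$score) >= 0))
  expect_equal(r1$evals, 9 * 3 * 7)
})

test_that("a constant reference yields a zero-MI run without error", {
  ref <- image2d(matrix(0.5, 32, 32))
  flt <- image2d(matrix(runif(32 * 32), 32, 32))
  cfg <- evolution_config(bounds = test_bounds(5), particles_per_membrane = 2,
                          steps = 3, bins = 16, seed = 1)
  res <- run_tps(ref, flt, cfg)
  expect_equal(res$best_score, 0)
  expect_equal(res$steps_run, 3)
})

test_that("invalid configurations are rejected", {
  expect_error(evolution_config(steps = 0), "steps")
  expect_error(evolution_config(particles_per_membrane = 0), "particle")
  expect_error(evolution_config(omega_start = 0.2, omega_end = 0.5), "inertia")
  bad_z <- rbind(c(-1, 1), c(-1, 1), c(-1, 1), c(-1, 1))
  expect_error(evolution_config(bounds = bad_z), "Z lower bound")
  expect_error(evolution_config(bounds = matrix(1, 2, 2)), "4x2")
})
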