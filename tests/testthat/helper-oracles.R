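# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit loops, index permutations, closed forms) kept
# separate from the package's own code paths.

# direct-summation mutual information of a joint probability/count matrix,
# cell by cell (base 2)
mi_oracle <- function(joint) {
  p <- joint / sum(joint)
  pa <- rowSums(p)
  pb <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pa[i] * pb[j]))
    }
  }
  mi
}

# Shannon entropy (bits) of an image's B-bin marginal intensity histogram
entropy_oracle <- function(img, bins) {
  v <- img$pixels[img$mask]
  q <- pmin(floor(v * bins), bins - 1)
  p <- tabulate(q + 1, nbins = bins)
  p <- p / sum(p)
  -sum(p[p > 0] * log2(p[p > 0]))
}

# exact CCW quarter-turn as an index permutation (k quarter turns)
rot90_oracle <- function(m, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# integer translation (x pixels up, y pixels left) with NA-filled borders
shift_oracle <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rs <- r + x; cs <- c + y
      if (rs >= 1 && rs <= H && cs >= 1 && cs <= W) out[r, c] <- m[rs, cs]
    }
  }
  out
}

# scalar, dimension-by-dimension velocity/position update with clamping and
# clipping, given explicit random draws
pso_update_oracle <- function(pos, vel, lbest, nbest, pbest, w, l0, l1, l2,
                              z0, z1, z2, clamp, lo, hi) {
  v <- numeric(4); p <- numeric(4)
  for (d in 1:4) {
    vd <- w * vel[d] +
      l0 * z0[d] * (lbest[d] - pos[d]) +
      l1 * z1[d] * (nbest[d] - pos[d]) +
      l2 * z2[d] * (pbest[d] - pos[d])
    if (vd > clamp[d]) vd <- clamp[d]
    if (vd < -clamp[d]) vd <- -clamp[d]
    pd <- pos[d] + vd
    if (pd < lo[d]) pd <- lo[d]
    if (pd > hi[d]) pd <- hi[d]
    v[d] <- vd
    p[d] <- pd
  }
  list(vel = v, pos = p)
}

# smooth test image (low-frequency sinusoid product), interpolates cleanly
smooth_image <- function(n) {
  r <- seq(0, 2 * pi, length.out = n)
  px <- outer(sin(r), cos(1.5 * r))
  image2d((px - min(px)) / (max(px) - min(px)))
}

# separable quadratic surrogate objective with known argmax
quad_objective <- function(center) {
  force(center)
  function(p) -sum((p - center)^2)
}

# a tiny level-3 membrane state for rule-level tests
make_test_membrane <- function(pos, vel = NULL, lbest = NULL, lscore = -Inf) {
  st <- tpsreg:::new_membrane_state("m011")
  st$positions <- pos
  st$velocities <- if (is.null(vel)) matrix(0, nrow(pos), 4) else vel
  st$local_best <- if (is.null(lbest)) pos[1, ] else lbest
  st$local_best_score <- lscore
  st
}

test_bounds <- function(w = 10) {
  rbind(x = c(-w, w), y = c(-w, w), theta = c(-w, w), Z = c(0.5, 1.5))
}
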