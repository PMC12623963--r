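# Independent oracles, implemented in plain R against the score definitions:
# an exhaustive contiguous-seed Kabsch search plus a dense rotation grid with
# centroid-matched translation. They share no code with the package's
# compiled search path.

r_kabsch_oracle <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  H <- t(sweep(mov, 2, cm)) %*% sweep(ref, 2, cr)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cr - as.vector(R %*% cm))
}

dist_under_rt <- function(ref, mov, R, t) {
  moved <- mov %*% t(R) + matrix(t, nrow(mov), 3, byrow = TRUE)
  sqrt(rowSums((ref - moved)^2))
}

euler_grid <- function(step_deg = 12) {
  a <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  b <- seq(0, pi, by = step_deg * pi / 180)
  g <- expand.grid(a = a, b = b, c = a)
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  lapply(seq_len(nrow(g)), function(i) rz(g$a[i]) %*% ry(g$b[i]) %*% rz(g$c[i]))
}

# Squared distances (n x K) of centred mov vs centred ref under K rotations,
# computed via the bilinear expansion d^2 = |p|^2 + |q|^2 - 2 <R, p q^T>.
grid_dist2 <- function(ref, mov, rotations) {
  p <- sweep(ref, 2, colMeans(ref))
  q <- sweep(mov, 2, colMeans(mov))
  W <- t(sapply(seq_len(nrow(p)), function(i) as.vector(p[i, ] %o% q[i, ])))
  R9 <- sapply(rotations, as.vector)
  cross <- W %*% R9
  outer(rowSums(p^2) + rowSums(q^2), rep(1, length(rotations))) - 2 * cross
}

# Best TM and per-threshold GDT fractions over the literal brute-force
# search: every contiguous seed window (all lengths, all starts) superposed
# once by Kabsch, plus a dense one-shot rotation grid with centroid-matched
# translation. Because the scores are maxima over superpositions, every
# value here is an achievable lower bound of the true optimum: a correct
# implementation must reach at least this level (it may legitimately exceed
# it, since its refinement iterations tighten the bound further).
oracle_scores <- function(ref, mov, d0, lnorm, thresholds = c(1, 2, 4, 8),
                          rotations = NULL) {
  n <- nrow(ref)
  best_tm <- 0
  best_frac <- rep(0, length(thresholds))
  score_d <- function(d) {
    best_tm <<- max(best_tm, sum(1 / (1 + (d / d0)^2)) / lnorm)
    best_frac <<- pmax(best_frac,
                       vapply(thresholds, function(t) sum(d <= t) / lnorm,
                              numeric(1)))
  }
  for (l in 3:n) {
    for (s in 1:(n - l + 1)) {
      idx <- s:(s + l - 1)
      k <- r_kabsch_oracle(ref[idx, , drop = FALSE], mov[idx, , drop = FALSE])
      score_d(dist_under_rt(ref, mov, k$R, k$t))
    }
  }
  if (is.null(rotations)) rotations <- euler_grid()
  d2 <- grid_dist2(ref, mov, rotations)
  best_tm <- max(best_tm, colSums(1 / (1 + d2 / d0^2)) / lnorm)
  for (k in seq_along(thresholds)) {
    best_frac[k] <- max(best_frac[k],
                        max(colSums(d2 <= thresholds[k]^2)) / lnorm)
  }
  list(tm = best_tm, gdt = mean(best_frac))
}

# Minimum RMSD over rotations: dense grid + Nelder-Mead polish on Euler
# angles, translation fixed at centroid matching (optimal for RMSD).
oracle_min_rmsd <- function(ref, mov) {
  rots <- euler_grid(10)
  d2 <- grid_dist2(ref, mov, rots)
  rmsds <- sqrt(colMeans(d2))
  p <- sweep(ref, 2, colMeans(ref))
  q <- sweep(mov, 2, colMeans(mov))
  obj <- function(ang) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    R <- rz(ang[1]) %*% ry(ang[2]) %*% rz(ang[3])
    sqrt(mean(rowSums((p - q %*% t(R))^2)))
  }
  best <- which.min(rmsds)
  g <- expand.grid(a = seq(0, 2 * pi - 1e-9, by = 10 * pi / 180),
                   b = seq(0, pi, by = 10 * pi / 180),
                   c = seq(0, 2 * pi - 1e-9, by = 10 * pi / 180))
  start <- as.numeric(g[best, ])
  optim(start, obj, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 2000))$value
}

# Random compact toy chain for oracle comparisons.
toy_chain_coords <- function(n, spread = 3) {
  matrix(rnorm(3 * n, sd = spread), n, 3)
}
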