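# Independent numerical oracles used across the test suite.

# Brute-force writhe: discretized double Gauss integral over the closed
# polygon (midpoint rule with K sub-segments per cylinder).  Independent of
# the segment-pair closed form used by the package.
writhe_brute <- function(V, K = 16) {
  n <- nrow(V)
  Vn <- V[c(2:n, 1), ]
  D <- Vn - V
  idx <- rep(seq_len(n), each = K)
  frac <- rep((seq_len(K) - 0.5) / K, times = n)
  P <- V[idx, ] + D[idx, ] * frac
  Tg <- D[idx, ] / K                     # tangent * ds
  seg <- idx
  m <- nrow(P)
  acc <- 0
  for (a in seq_len(m - 1)) {
    b <- (a + 1):m
    sb <- seg[b]
    keep <- sb != seg[a] & abs(sb - seg[a]) != 1 & abs(sb - seg[a]) != n - 1
    if (!any(keep)) next
    b <- b[keep]
    r1 <- P[a, 1] - P[b, 1]; r2 <- P[a, 2] - P[b, 2]; r3 <- P[a, 3] - P[b, 3]
    d3 <- (r1^2 + r2^2 + r3^2)^1.5
    cr1 <- Tg[a, 2] * Tg[b, 3] - Tg[a, 3] * Tg[b, 2]
    cr2 <- Tg[a, 3] * Tg[b, 1] - Tg[a, 1] * Tg[b, 3]
    cr3 <- Tg[a, 1] * Tg[b, 2] - Tg[a, 2] * Tg[b, 1]
    acc <- acc + sum((cr1 * r1 + cr2 * r2 + cr3 * r3) / d3)
  }
  2 * acc / (4 * pi)
}

# Random self-avoiding closed chains obtained by scrambling a circle with
# energy-free crankshaft moves (inputs for oracle comparisons).
random_closed_chain <- function(n_cyl, seed, n_sweeps = 150) {
  set.seed(seed)
  ch <- build_initial_circle(30 * n_cyl, 0)
  em0 <- energy_model()
  em0$kappa <- 0
  mp <- move_params(M = max(2, n_cyl %/% 3), max_angle = pi / 2)
  tr <- run_sweeps(ch, em0, mp, n_sweeps, torsion = FALSE,
                   self_avoid = TRUE, wr_jump_max = Inf)
  tr$chain
}

# joint bending angles of a conformation
joint_angles <- function(V, closed = TRUE) {
  n <- nrow(V)
  d <- V[c(2:n, 1), ] - V
  u <- d / sqrt(rowSums(d^2))
  cs <- rowSums(u * u[c(2:n, 1), ])
  th <- acos(pmin(1, pmax(-1, cs)))
  if (closed) th else th[seq_len(n - 2)]
}
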