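# Distance distributions, local writhe, minima detection, threshold
# selection and branch counting.

test_that("distance samples reproduce circle chords exactly", {
  # one-frame "ensemble": the rigid planar circle; r(s) = 2 R sin(pi k/N)
  ch <- build_initial_circle(3000, 0)
  ens <- manual_ensemble(list(list(list(ch$vertices))), sigma = 0,
                         n_bp = 3000, Lk0 = ch$Lk0)
  R <- 10.2 / (2 * sin(pi / 100))
  s <- c(0, 300, 600, 1500)
  ds <- distance_samples(ens, level = 1, s_grid_bp = s)
  for (j in seq_along(s)) {
    k <- s[j] / 30
    expect_equal(unique(round(ds$samples[[j]], 9)),
                 round(2 * R * sin(pi * k / 100), 9))
  }
  # s = 0 gives r = 0 for every frame and reference vertex
  expect_true(all(ds$samples[[1]] == 0))
  # offsets beyond L/2 fold back with a warning
  expect_warning(ds2 <- distance_samples(ens, 1, s_grid_bp = 2400),
                 "folded")
  expect_equal(mean(ds2$samples[[1]]),
               mean(distance_samples(ens, 1, s_grid_bp = 600)$samples[[1]]))
})

test_that("P_s(r) histograms are normalized densities", {
  sp <- standin_spec()
  ds <- generate_standin_samples(sp, c(300, 3000), 2000, seed = 8)
  Ps <- estimate_Ps(ds)
  dr <- diff(Ps$r_breaks)
  for (j in 1:2)
    expect_equal(sum(Ps$P[, j] * dr), 1, tolerance = 1e-12)
})

test_that("local writhe is consistent with the global writhe", {
  ch <- random_closed_chain(30, seed = 17)
  # planar circle: wr(i) ~ 0 everywhere
  circ <- build_initial_circle(1800, 0)
  expect_lt(max(abs(local_writhe(circ, 10))), 1e-10)
  # invariance under global rotation + translation
  wr1 <- local_writhe(ch, 10)
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ch2 <- ch
  ch2$vertices <- sweep(ch$vertices %*% Rz, 2, c(5, -3, 11), "+")
  expect_equal(local_writhe(ch2, 10), wr1, tolerance = 1e-10)
  # full window recovers twice the global writhe (each pair counted twice)
  expect_equal(sum(local_writhe(ch, m = 30)), 2 * writhe(ch),
               tolerance = 1e-9)
})

test_that("periodic local minima handle plateaus and degenerate profiles", {
  x <- c(0, -1, 0, 0.5, 0.2, 0.7)
  m <- find_local_minima(x)
  expect_equal(m$index, c(2, 5))
  expect_equal(m$value, c(-1, 0.2))
  # constant profile: none
  expect_length(find_local_minima(rep(1, 10))$index, 0)
  # pure cosine over the ring: exactly one minimum
  i <- 0:99
  m2 <- find_local_minima(cos(2 * pi * i / 100))
  expect_equal(m2$index, 51)
  # plateau collapsed to a single central call
  x3 <- c(5, 1, 1, 1, 5, 5)
  m3 <- find_local_minima(x3)
  expect_equal(m3$index, 3)
  # plateau wrapping across the seam is still one call
  x4 <- c(1, 5, 5, 5, 1, 1)
  expect_length(find_local_minima(x4)$index, 1)
})

test_that("threshold selection separates a bimodal minima mixture", {
  set.seed(21)
  pooled <- c(rnorm(2000, -0.05, 0.03), rnorm(600, -0.6, 0.08))
  thr <- select_writhe_threshold(pooled)
  expect_gt(thr, -0.6)
  expect_lt(thr, -0.15)
  # unimodal: undefined, and counts fall back to zero
  uni <- rnorm(2000, -0.04, 0.03)
  expect_true(is.na(select_writhe_threshold(uni)))
  expect_equal(count_branches(c(0, -1, 0, -0.5, 0.2), NA_real_), 0L)
  # too few minima: NA with a warning
  expect_warning(t2 <- select_writhe_threshold(rnorm(50)), "few")
  expect_true(is.na(t2))
})

test_that("branch counting recovers planted deep minima", {
  set.seed(33)
  n <- 200                      # profile length (sites)
  n_prof <- 150
  planted <- integer(n_prof)
  profiles <- vector("list", n_prof)
  for (p in seq_len(n_prof)) {
    k <- sample(0:5, 1)
    x <- rnorm(n, 0, 0.02)      # thermal ripple
    if (k > 0) {
      centers <- sample(seq(5, n - 5, by = 12), k)
      for (c0 in centers) {
        depth <- runif(1, 0.45, 0.75)
        x[(c0 - 2):(c0 + 2)] <- x[(c0 - 2):(c0 + 2)] -
          depth * c(0.3, 0.75, 1, 0.75, 0.3)
      }
    }
    planted[p] <- k
    profiles[[p]] <- x
  }
  pooled <- unlist(lapply(profiles, function(x) find_local_minima(x)$value))
  thr <- select_writhe_threshold(pooled)
  expect_false(is.na(thr))
  counts <- vapply(profiles, count_branches, integer(1), wr_star = thr)
  expect_gte(mean(counts == planted), 0.95)
})

test_that("summary curves aggregate with across-run standard errors", {
  # two-level, three-run toy ensemble built from rigid circles of two sizes
  c1 <- build_initial_circle(1800, 0)$vertices
  c2 <- build_initial_circle(1800, 0)$vertices * 0.5
  frames <- list(
    list(list(c1, c1), list(c1, c1), list(c1, c1)),
    list(list(c2, c2), list(c2, c2), list(c2, c2)))
  ens <- manual_ensemble(frames, sigma = c(0, -0.05), n_bp = 1800,
                         Lk0 = 171)
  gc <- gyration_curve(ens)
  expect_equal(gc$Rg[1], radius_of_gyration(c1), tolerance = 1e-12)
  expect_equal(gc$Rg[2], gc$Rg[1] / 2, tolerance = 1e-12)
  # identical runs: zero spread, sem = sqrt(var/(n_runs - 1)) = 0
  expect_equal(gc$sem, c(0, 0))
  bc <- branch_count_curve(ens, min_count = 5)
  expect_equal(bc$branches, c(0, 0))   # circles have no plectonemes
})
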