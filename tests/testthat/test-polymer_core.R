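# Geometry, topology and energetics of the rod-like chain.

test_that("initial circle has the documented geometry and linking state", {
  ch <- build_initial_circle(30000, sigma = 0)
  expect_equal(ch$n_cylinders, 1000L)
  expect_equal(ch$Lk0, 2850)
  expect_equal(ch$Lk, 2850)
  expect_equal(writhe(ch), 0, tolerance = 1e-8)
  # all segment lengths exactly 10.2 nm (relative 1e-9)
  V <- ch$vertices
  len <- sqrt(rowSums((V[c(2:1000, 1), ] - V)^2))
  expect_true(all(abs(len - 10.2) < 1e-9 * 10.2))

  ch2 <- build_initial_circle(3000, 0)
  expect_equal(ch2$n_cylinders, 100L)
  # chord-exact circumscribed radius; ~ circumference / (2*pi) = 162.3 nm
  R <- 10.2 / (2 * sin(pi / 100))
  expect_equal(sqrt(sum(ch2$vertices[1, ]^2)), R, tolerance = 1e-12)
  expect_equal(R, 100 * 10.2 / (2 * pi), tolerance = 1e-3)
  expect_equal(radius_of_gyration(ch2), R, tolerance = 1e-12)

  expect_error(build_initial_circle(30010, 0), "divisible")
  expect_warning(build_initial_circle(3000, -0.1), "regime")
  expect_warning(build_initial_circle(3000, 0.01), "regime")
})

test_that("sigma is set from the linking-number state", {
  ch <- build_initial_circle(30000, sigma = -0.05)
  expect_equal(chain_sigma(ch), -0.05)
  expect_equal(ch$Lk, 2850 * 0.95)
})

test_that("bending energy matches the per-joint closed form", {
  em <- energy_model(kappa_method = "ratio")  # kappa = 50/10.2 = 4.902
  expect_equal(em$kappa, 50 / 10.2)
  # single 90-degree joint on an open 3-vertex chain
  V <- rbind(c(0, 0, 0), c(10.2, 0, 0), c(10.2, 10.2, 0))
  ch <- rlc_chain(V, Lk = 0, Lk0 = 1, closed = FALSE)
  expect_equal(bending_energy(ch, em), em$kappa * (1 - cos(pi / 2)),
               tolerance = 1e-12)
  # straight run has zero bending
  V2 <- cbind(seq(0, 40.8, by = 10.2), 0, 0)
  ch2 <- rlc_chain(V2, Lk = 0, Lk0 = 1, closed = FALSE)
  expect_equal(bending_energy(ch2, em), 0, tolerance = 1e-12)
  # planar regular N-gon: kappa * N * (1 - cos(2 pi / N))
  ch3 <- build_initial_circle(3000, 0)
  expect_equal(bending_energy(ch3, em),
               em$kappa * 100 * (1 - cos(2 * pi / 100)), tolerance = 1e-12)
})

test_that("langevin kappa calibration reproduces the persistence length", {
  em <- energy_model()  # default langevin mapping
  k <- em$kappa
  # the mapping identity itself
  expect_equal(1 / tanh(k) - 1 / k, exp(-10.2 / 50), tolerance = 1e-10)
  # exact equilibrium draws recover l_p = 50 nm within 5%
  set.seed(5)
  th <- sample_bending_angles(2e5, em)
  lp_hat <- -em$l / log(mean(cos(th)))
  expect_lt(abs(lp_hat - 50) / 50, 0.05)
})

test_that("torsional energy follows the uniform-twist form", {
  em <- energy_model()
  ch <- build_initial_circle(30000, 0)
  # relaxed: sigma = 0 and Wr = 0
  expect_equal(torsional_energy(ch, em), 0, tolerance = 1e-10)
  # all supercoiling in writhe: dTw = 0
  ch$Lk <- ch$Lk0 - 20
  expect_equal(torsional_energy(ch, em, Wr = -20), 0, tolerance = 1e-12)
  # plug-in value: N = 1000, C = 86, dTw = 10 -> 2 pi^2 86 * 100 / 10200
  ch$Lk <- ch$Lk0 + 10
  expect_equal(torsional_energy(ch, em, Wr = 0),
               2 * pi^2 * 86 * 100 / 10200, tolerance = 1e-12)
})

test_that("topology bookkeeping identity holds by construction", {
  ch <- random_closed_chain(20, seed = 2)
  ch$Lk <- ch$Lk0 - 3
  ts <- topology_state(ch)
  expect_equal(ts$dTw + ts$Wr, ch$Lk - ch$Lk0, tolerance = 1e-12)
  expect_equal(ts$sigma, -3 / ch$Lk0)
})

test_that("writhe closed form agrees with the brute-force Gauss integral", {
  for (s in 1:10) {
    n <- sample(c(12, 16, 24, 32, 40), 1)
    ch <- random_closed_chain(n, seed = 100 + s)
    expect_lt(abs(writhe(ch) - writhe_brute(ch$vertices, K = 16)), 1e-3)
  }
})

test_that("writhe is near +-1 for a lifted figure-eight and antisymmetric", {
  t <- seq(0, 2 * pi, length.out = 201)[-201]
  V8 <- cbind(cos(t), sin(t) * cos(t), 0.02 * sin(t))
  w <- writhe(V8)
  expect_lt(abs(abs(w) - 1), 0.05)
  expect_equal(w, writhe_brute(V8, K = 8), tolerance = 1e-3)
  # mirror antisymmetry on several stored conformations
  for (s in 1:3) {
    ch <- random_closed_chain(16, seed = 200 + s)
    expect_equal(writhe(mirror_chain(ch)), -writhe(ch), tolerance = 1e-12)
  }
  # coincident vertices rejected
  Vbad <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(writhe(Vbad), "coincident")
})

test_that("self-avoidance uses the 4 nm center-line hard core", {
  em <- energy_model()
  expect_true(check_self_avoidance(build_initial_circle(3000, 0), em))
  # open 3-segment hairpin: only the first and last segments are
  # non-adjacent, parallel at a center-line distance equal to the gap
  Vg <- function(gap) rbind(c(0, 0, 0), c(10.2, 0, 0),
                            c(10.2, 0, gap), c(0, 0, gap))
  ch39 <- rlc_chain(Vg(3.9), 0, 1, closed = FALSE, validate = FALSE)
  ch41 <- rlc_chain(Vg(4.1), 0, 1, closed = FALSE, validate = FALSE)
  expect_false(check_self_avoidance(ch39, em))
  expect_true(check_self_avoidance(ch41, em))
  expect_equal(min_nonadjacent_distance(ch41), 4.1, tolerance = 1e-9)
})

test_that("radius of gyration matches simple geometries", {
  # all vertices on a circle of radius R
  ch <- build_initial_circle(3000, 0)
  R <- 10.2 / (2 * sin(pi / 100))
  expect_equal(radius_of_gyration(ch), R, tolerance = 1e-12)
  # two antipodal equal-weight clusters at +-d
  V <- rbind(matrix(rep(c(5, 0, 0), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(-5, 0, 0), 4), ncol = 3, byrow = TRUE))
  expect_equal(radius_of_gyration(V), 5, tolerance = 1e-12)
})

test_that("helix removal updates sigma without touching geometry", {
  ch <- build_initial_circle(30000, 0)
  V0 <- ch$vertices
  ch1 <- remove_helices(ch, 14)
  expect_equal(chain_sigma(ch1), -14 / 2850, tolerance = 1e-12)
  expect_identical(ch1$vertices, V0)
  expect_equal(chain_sigma(remove_helices(ch, 0)), 0)
  # 16 removals of 14 helices: sigma = -224/2850
  ch16 <- ch
  for (i in 1:16) ch16 <- remove_helices(ch16, 14)
  expect_equal(chain_sigma(ch16), -224 / 2850, tolerance = 1e-12)
  expect_equal(round(chain_sigma(ch16), 4), -0.0786)
  # dropping below the floor warns
  expect_warning(remove_helices(ch, 240), "floor")
})
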