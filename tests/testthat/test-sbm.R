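# Cluster concentration profiles, the center-offset kernel, the binding
# profile estimator, the protein-count formula and the screening length.

kinds <- c("quenched", "leaky", "gaussian", "exponential")

test_that("every cluster kind is saturated at the center with FWHM omega", {
  for (k in kinds) {
    cm <- cluster_model(k, omega = 44)
    expect_equal(c0_profile(cm, 0), 1, info = k)
    expect_equal(c0_profile(cm, 22), 0.5, tolerance = 1e-12, info = k)
    # monotone non-increasing
    r <- seq(0, 200, by = 0.5)
    expect_true(all(diff(c0_profile(cm, r)) <= 1e-12), info = k)
  }
  expect_error(c0_profile(cluster_model("leaky", 40), -1), "non-negative")
})

test_that("leaky profile has the documented 1/r halo values", {
  cm <- cluster_model("leaky", omega = 40)
  expect_equal(c0_profile(cm, 20), 0.5)    # r = omega/2
  expect_equal(c0_profile(cm, 40), 0.25)   # r = omega
  expect_equal(c0_profile(cm, 80), 1 / 8)  # r = 2 omega
  expect_equal(c0_profile(cm, 10), 1)      # saturated core r <= omega/4
})

test_that("tails order as leaky >= exponential >= gaussian >= quenched", {
  r <- seq(45, 300, by = 5)  # r > omega
  p <- lapply(kinds, function(k) c0_profile(cluster_model(k, 44), r))
  names(p) <- kinds
  expect_true(all(p$leaky >= p$exponential - 1e-12))
  expect_true(all(p$exponential >= p$gaussian - 1e-12))
  expect_true(all(p$gaussian >= p$quenched))
})

test_that("center-offset kernel integrates to one and matches sampling", {
  # r = 0 regime: Pi = 3 x^2 / rho^3 on [0, rho]
  rho <- 10
  x <- seq(0, rho, length.out = 101)
  expect_equal(center_offset_kernel(0, x, rho), 3 * x^2 / rho^3)
  expect_equal(center_offset_kernel(0, c(10.5, 20), rho), c(0, 0))
  # normalization over a grid spanning r < rho, r = rho, r > rho
  for (rho in c(5, 11, 20)) {
    for (r in c(0, 0.3 * rho, rho, 2.5 * rho)) {
      v <- integrate(function(x) center_offset_kernel(r, x, rho),
                     max(0, r - rho), r + rho,
                     abs.tol = 1e-12, rel.tol = 1e-12)$value
      expect_equal(v, 1, tolerance = 1e-8,
                   info = sprintf("r=%g rho=%g", r, rho))
    }
  }
  # Monte-Carlo oracle: uniform cluster centers in the ball around parS,
  # probe at distance r; the sampled |center - probe| matches the kernel's
  # first moment
  set.seed(71)
  rho <- 12; r <- 8
  n <- 2e5
  u <- matrix(rnorm(3 * n), ncol = 3)
  pts <- u / sqrt(rowSums(u^2)) * rho * runif(n)^(1 / 3)
  xs <- sqrt((pts[, 1] - r)^2 + pts[, 2]^2 + pts[, 3]^2)
  m1 <- integrate(function(x) x * center_offset_kernel(r, x, rho),
                  0, r + rho, rel.tol = 1e-10)$value
  expect_lt(abs(mean(xs) - m1), 3 * sd(xs) / sqrt(n))
})

test_that("effective concentration reduces to C0 in the right limits", {
  # convolution off returns C0 exactly
  cm <- cluster_model("gaussian", omega = 44)
  r <- seq(0, 150, by = 1.7)
  expect_identical(effective_concentration(cm, r), c0_profile(cm, r))
  # quenched with rho = omega/2: the center is always within omega/2 of
  # parS, so C(0) = 1
  cmq <- cluster_model("quenched", omega = 60)
  expect_equal(effective_concentration(cmq, 0), 1, tolerance = 1e-9)
  # delta-kernel limit rho -> 0 recovers C0
  cml <- cluster_model("leaky", omega = 44, rho = 1e-3)
  r <- c(15, 30, 60, 120)
  expect_equal(effective_concentration(cml, r), c0_profile(cml, r),
               tolerance = 1e-5)
  # bounded in [0, 1] for all kinds with convolution on
  for (k in kinds) {
    cmk <- cluster_model(k, omega = 44, convolve_center = TRUE)
    v <- effective_concentration(cmk, seq(0, 200, by = 2))
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-9), info = k)
  }
})

test_that("binding profile is the sample-mean estimator of the integral", {
  sp <- standin_spec(nu = 0.5, b = 2)
  ds <- generate_standin_samples(sp, s_grid_bp = c(0, 600, 3000, 9000),
                                 n_samples = 4000, seed = 31)
  cm <- cluster_model("leaky", omega = 44)
  bp <- binding_profile(ds, cm)
  expect_equal(bp$B[1], 1)                    # s = 0: r = 0 always
  expect_true(all(bp$B >= 0 & bp$B <= 1))
  # C == 1 everywhere gives B == 1
  cm1 <- cluster_model("quenched", omega = 1e9, convolve_center = FALSE)
  expect_true(all(binding_profile(ds, cm1)$B == 1))
  # binned-integral cross-check: sum P_s(r) C(r) dr within 1%
  Ps <- estimate_Ps(ds, r_breaks = seq(0, max(unlist(ds$samples)) * 1.001,
                                       length.out = 201))
  for (j in 2:4) {
    rmid <- Ps$r_mid
    dr <- diff(Ps$r_breaks)
    binned <- sum(Ps$P[, j] * effective_concentration(cm, rmid) * dr)
    expect_equal(binned, bp$B[j], tolerance = 0.01)
  }
})

test_that("protein count matches its quadrature oracle and scaling", {
  cm <- cluster_model("leaky", omega = 36)
  # independent quadrature of the defining integral, split at the core
  quad <- function(omega, a, R) {
    cmw <- cluster_model("leaky", omega = omega)
    v <- 4 * pi * a^3 / 3
    (integrate(function(r) c0_profile(cmw, r) * 4 * pi * r^2, 0, omega / 4,
               rel.tol = 1e-12)$value +
     integrate(function(r) c0_profile(cmw, r) * 4 * pi * r^2, omega / 4, R,
               rel.tol = 1e-12)$value) / v
  }
  for (a in c(5, 10, 15, 20))
    expect_equal(protein_count(cm, a = a), quad(36, a, 400),
                 tolerance = 1e-10)
  # doubling a divides the count by 8 exactly
  expect_equal(protein_count(cm, a = 10), protein_count(cm, a = 20) * 8,
               tolerance = 1e-12)
  expect_error(protein_count(cluster_model("quenched", 36), a = 5),
               "leaky")
})

test_that("screening length follows sqrt(D/Gamma) and solves the
           stationary diffusion-dilution equation", {
  expect_equal(screening_length(D = 1, Gamma = 1), 1000)
  expect_equal(screening_length(D = 1, Gamma = 4),
               screening_length(D = 1, Gamma = 1) / 2)
  # Yukawa residual: D r^-2 d/dr(r^2 dC/dr) = Gamma C for r > rho,
  # via symbolic differentiation of the solution
  D <- 1e6       # nm^2/s
  Gamma <- 1     # 1/s
  xi <- sqrt(D / Gamma)
  rho <- 10
  dC <- deriv(~ rho * exp(-r / xi) / r, "r", hessian = TRUE,
              function.arg = c("r", "rho", "xi"))
  for (r in c(25, 100, 400, 900)) {
    v <- dC(r, rho, xi)
    C1 <- attr(v, "gradient")[1, "r"]
    C2 <- attr(v, "hessian")[1, "r", "r"]
    lhs <- D * (2 / r * C1 + C2)   # D r^-2 (r^2 C')'
    expect_equal(unname(lhs), Gamma * as.numeric(v), tolerance = 1e-10)
  }
})
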