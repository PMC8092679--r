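# Synthetic inputs with known ground truth: an analytic stand-in for the
# distance statistics P_s(r) (to test the SBM and fitting layers without
# running the polymer simulation) and noisy ChIP-seq-like coverage
# profiles generated from a chosen cluster model.

#' Analytic stand-in for the distance statistics
#'
#' A Gaussian-chain surrogate for `P_s(r)`: at genomic offset `s` the
#' locus-parS vector is isotropic Gaussian, so the radial density is
#' Maxwell with root-mean-square distance `b * s^nu` (nm, `s` in bp).
#' This is a cheap testing surrogate for the SBM/fit layers only; it does
#' not model supercoiling and is never a substitute for the simulated
#' ensembles in scientific use.
#'
#' @param nu scaling exponent (0.5 = ideal chain).
#' @param b prefactor (nm per bp^nu).
#' @return Object of class `standin_spec`.
#' @export
standin_spec <- function(nu = 0.5, b = 2) {
  stopifnot(nu > 0, b > 0)
  structure(list(nu = nu, b = b), class = "standin_spec")
}

# rms distance of the stand-in at offset s (bp)
standin_rms <- function(spec, s_bp) spec$b * s_bp^spec$nu

#' Draw stand-in distance samples
#'
#' Reproducible radial draws from the stand-in Maxwell density at each
#' genomic offset; `E[r^2]` equals `(b s^nu)^2` exactly.
#'
#' @param spec a [standin_spec()].
#' @param s_grid_bp genomic offsets (bp).
#' @param n_samples draws per offset.
#' @param seed integer seed.
#' @return A `distance_samples` object compatible with
#'   [binding_profile()].
#' @export
generate_standin_samples <- function(spec, s_grid_bp, n_samples, seed = 1) {
  set.seed(seed)
  samples <- lapply(s_grid_bp, function(s) {
    if (n_samples == 0) return(numeric(0))
    if (s == 0) return(numeric(n_samples))
    standin_rms(spec, s) * sqrt(rchisq(n_samples, df = 3) / 3)
  })
  structure(list(s_bp = as.numeric(s_grid_bp), samples = samples,
                 sigma = NA_real_, n_frames = n_samples,
                 standin = spec),
            class = "distance_samples")
}

# Maxwell radial density with rms sigma_r
maxwell_density <- function(r, sigma_r) {
  a <- sigma_r / sqrt(3)
  sqrt(2 / pi) * r^2 / a^3 * exp(-r^2 / (2 * a^2))
}

#' Noise-free binding profile of the stand-in
#'
#' `B(s) = integral of P_s(r) C(r) dr` with the stand-in Maxwell density,
#' by adaptive quadrature (an estimator independent of the sample-mean
#' route used in fitting).
#'
#' @param spec a [standin_spec()].
#' @param cm a [cluster_model()].
#' @param s_grid_bp genomic offsets (bp).
#' @return Numeric vector `B(s)`.
#' @export
standin_binding_profile <- function(spec, cm, s_grid_bp) {
  rmax <- standin_rms(spec, max(s_grid_bp)) * 8
  conc <- concentration_interpolator(cm, max(rmax, 1))
  # composite Simpson on a fine fixed grid: robust to the kink the cluster
  # core edge leaves in C(r)
  simpson <- function(f, a, b, n = 2000) {
    x <- seq(a, b, length.out = n + 1)
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f(x)) * (b - a) / (3 * n)
  }
  vapply(s_grid_bp, function(s) {
    if (s == 0) return(effective_concentration(cm, 0))
    sr <- standin_rms(spec, s)
    simpson(function(r) maxwell_density(r, sr) * conc(r), 0, sr * 8)
  }, numeric(1))
}

#' Specification of a synthetic ChIP-seq-like profile
#'
#' Ground truth for the generator: a cluster model, a distance model (the
#' analytic stand-in), sequencing depth, fragment-center smoothing, Poisson
#' read noise, and optional localized multiplicative dips mimicking
#' promoter/roadblock distortions.
#'
#' @param kind,omega ground-truth cluster kind and FWHM (nm).
#' @param depth expected read count at the profile maximum (> 0).  The
#'   default, 10000, corresponds to a well-covered library; the
#'   max-normalization step divides by a noisy maximum, so very shallow
#'   depths bias the normalized profile downward.
#' @param fragment_size mean fragment size in bp (0 disables smoothing).
#' @param parS_plateau width (bp) of the saturated specific-binding
#'   region upstream of the `s = 0` origin (the origin sits at the edge
#'   of the parS array, whose ~0.7 kb of strong sites bind at the
#'   saturation level).  The plateau anchors the profile maximum, as in
#'   real data, so that fragment smoothing does not depress it; set 0 to
#'   omit.
#' @param distortions list of `list(center, width, dip)` entries; expected
#'   coverage is multiplied by
#'   `1 - (1 - dip) * exp(-(s - center)^2 / (2 width^2))`, so the factor
#'   equals `dip` at the center (`dip` in (0, 1]).
#' @param s_max,resolution extent (bp) and spacing (bp) of the profile.
#' @param standin a [standin_spec()] distance model.
#' @param noise apply Poisson noise (disable for exact-recovery checks).
#' @return Object of class `synthetic_profile_spec`.
#' @export
synthetic_profile_spec <- function(kind = "leaky", omega = 44,
                                   depth = 10000, fragment_size = 200,
                                   parS_plateau = 720,
                                   distortions = list(),
                                   s_max = 12000, resolution = 30,
                                   standin = standin_spec(),
                                   noise = TRUE) {
  stopifnot(depth > 0, fragment_size >= 0, parS_plateau >= 0)
  for (d in distortions)
    stopifnot(d$dip > 0, d$dip <= 1, d$width > 0)
  structure(list(kind = kind, omega = omega, depth = depth,
                 fragment_size = fragment_size,
                 parS_plateau = parS_plateau,
                 distortions = distortions,
                 s_max = s_max, resolution = resolution,
                 standin = standin, noise = noise),
            class = "synthetic_profile_spec")
}

distortion_factor <- function(spec, s) {
  f <- rep(1, length(s))
  for (d in spec$distortions)
    f <- f * (1 - (1 - d$dip) * exp(-(s - d$center)^2 / (2 * d$width^2)))
  f
}

#' Generate a synthetic coverage profile with ground truth
#'
#' Expected coverage is `depth * B_true(s)` times the distortion factor,
#' box-smoothed over the fragment size (fragment-center smoothing acts on
#' the expected coverage), and observed counts are Poisson draws.
#'
#' @param spec a [synthetic_profile_spec()].
#' @param seed integer seed.
#' @return List with `profile` (a raw-count `coverage_profile`), and
#'   `truth` (spec, `s_bp`, noise-free `B_true` and expected `lambda`).
#' @export
generate_profile <- function(spec, seed = 1) {
  set.seed(seed)
  s <- seq(-spec$parS_plateau, spec$s_max, by = spec$resolution)
  cm <- cluster_model(spec$kind, omega = spec$omega)
  B_true <- numeric(length(s))
  B_true[s <= 0] <- 1   # saturated parS array
  B_true[s > 0] <- standin_binding_profile(spec$standin, cm, s[s > 0])
  lambda <- spec$depth * B_true * distortion_factor(spec, s)
  if (spec$fragment_size > 0) {
    w <- max(1L, round(spec$fragment_size / spec$resolution))
    if (w > 1) {
      kern <- rep(1 / w, w)
      ext <- c(rep(lambda[1], w), lambda, rep(lambda[length(lambda)], w))
      sm <- stats::filter(ext, kern, sides = 2)
      lambda <- as.numeric(sm[(w + 1):(w + length(lambda))])
    }
  }
  counts <- if (spec$noise) rpois(length(lambda), lambda) else lambda
  list(profile = new_coverage_profile(s, counts, spec$fragment_size),
       truth = list(spec = spec, s_bp = s, B_true = B_true,
                    lambda = lambda))
}

#' Parameter-recovery experiment for the grid fit
#'
#' Generates replicate synthetic profiles from a known (kind, omega)
#' truth, fits each with [grid_fit()] over an omega grid (model profiles
#' are computed once from the noise-free stand-in quadrature and reused),
#' and summarizes how often the truth is recovered.  Optionally also fits
#' a second cluster family to quantify kind discrimination via the RMSD
#' gap.
#'
#' @param kind,omega ground truth.
#' @param omega_grid omega grid for the fit (nm); should contain the
#'   truth.
#' @param n_replicates number of synthetic replicates.
#' @param seed master seed.
#' @param depth,fragment_size,distortions passed to
#'   [synthetic_profile_spec()].
#' @param window fit window (bp).
#' @param alt_kind optional second cluster family to fit (e.g.
#'   `"quenched"` against a leaky truth); `NULL` to skip.
#' @param standin the stand-in distance model.
#' @return Object of class `recovery_summary`: per-replicate data frame
#'   (`omega_hat`, `rmsd`, plus `omega_hat_alt`/`rmsd_alt`), the truth,
#'   and the grid.
#' @export
recovery_experiment <- function(kind = "leaky", omega = 44,
                                omega_grid = seq(28, 60, by = 4),
                                n_replicates = 20, seed = 1,
                                depth = 10000, fragment_size = 200,
                                distortions = list(),
                                window = c(1500, 9000),
                                alt_kind = NULL,
                                standin = standin_spec()) {
  s <- seq(0, 12000, by = 30)
  models <- lapply(omega_grid, function(w)
    data.frame(s_bp = s,
               B = standin_binding_profile(standin,
                                           cluster_model(kind, omega = w),
                                           s)))
  models <- list(models)
  attr(models, "sigma_labels") <- "standin"
  attr(models, "omega_grid") <- omega_grid
  alt_models <- NULL
  if (!is.null(alt_kind)) {
    alt_models <- list(lapply(omega_grid, function(w)
      data.frame(s_bp = s,
                 B = standin_binding_profile(standin,
                                             cluster_model(alt_kind,
                                                           omega = w),
                                             s))))
    attr(alt_models, "sigma_labels") <- "standin"
    attr(alt_models, "omega_grid") <- omega_grid
  }
  spec <- synthetic_profile_spec(kind = kind, omega = omega, depth = depth,
                                 fragment_size = fragment_size,
                                 distortions = distortions,
                                 standin = standin)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  res <- lapply(seq_len(n_replicates), function(i) {
    g <- generate_profile(spec, seed = rep_seeds[i])
    dat <- normalize_profile(g$profile)
    fit <- grid_fit(data = dat, window = window, model_profiles = models)
    row <- data.frame(replicate = i, omega_hat = fit$best$omega,
                      rmsd = fit$best$rmsd)
    if (!is.null(alt_models)) {
      fa <- grid_fit(data = dat, window = window,
                     model_profiles = alt_models)
      row$omega_hat_alt <- fa$best$omega
      row$rmsd_alt <- fa$best$rmsd
    }
    row
  })
  res <- do.call(rbind, res)
  step <- if (length(omega_grid) > 1) min(diff(sort(omega_grid))) else NA
  structure(list(results = res,
                 truth = list(kind = kind, omega = omega),
                 omega_grid = omega_grid, grid_step = step,
                 recovered_within_step =
                   mean(abs(res$omega_hat - omega) <= step),
                 alt_kind = alt_kind),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("omega recovery: truth %s omega = %g nm, %d replicates\n",
              x$truth$kind, x$truth$omega, nrow(x$results)))
  cat(sprintf("  recovered within one grid step (%g nm): %.0f%%\n",
              x$grid_step, 100 * x$recovered_within_step))
  if (!is.null(x$alt_kind))
    cat(sprintf("  median RMSD: %s %.4g vs %s %.4g\n",
                x$truth$kind, stats::median(x$results$rmsd),
                x$alt_kind, stats::median(x$results$rmsd_alt)))
  invisible(x)
}
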