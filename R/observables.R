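# Ensemble observables: parS-distance distributions P_s(r), local-writhe
# profiles, plectoneme branch counting, and per-sigma summary curves with
# across-run standard errors.

#' Extract parS-distance samples from an ensemble
#'
#' For each stored conformation and each genomic offset `s`, records the
#' 3-D distance `r` between the locus at `s` and the parS locus.  Because
#' the simulated chain is sequence-homogeneous, statistics are by default
#' averaged over all reference vertices (every vertex serves once as parS)
#' and over both genomic directions, which reduces variance without
#' changing the expectation.  Offsets beyond half the chain length are
#' folded back (with a warning), since genomic separation on a circle is
#' at most L/2.
#'
#' @param ensemble a `conformation_ensemble` from
#'   [run_annealing_protocol()].
#' @param level sigma-level index (row of `ensemble$levels`).
#' @param s_grid_bp genomic offsets in bp (multiples of the 30 bp cylinder
#'   resolution; others are rounded).
#' @param parS_vertex 1-based index of the parS vertex when
#'   `average_reference = FALSE`.
#' @param average_reference average over all reference loci (default).
#' @return Object of class `distance_samples`: list with `s_bp` and
#'   `samples` (one numeric vector of distances in nm per offset), plus
#'   provenance metadata.
#' @export
distance_samples <- function(ensemble, level, s_grid_bp,
                             parS_vertex = 1, average_reference = TRUE) {
  fr <- unlist(ensemble$frames[[level]], recursive = FALSE)
  if (length(fr) == 0) stop("ensemble has no frames at this level")
  N <- ensemble$n_cylinders
  L_bp <- ensemble$n_bp
  folded <- s_grid_bp > L_bp / 2
  if (any(folded)) {
    warning("offsets beyond half the chain length folded back")
    s_grid_bp[folded] <- L_bp - s_grid_bp[folded]
  }
  k_grid <- as.integer(round(s_grid_bp / 30)) %% N
  samples <- lapply(k_grid, function(k) {
    unlist(lapply(fr, function(V) {
      if (average_reference) {
        idx <- ((seq_len(N) - 1L + k) %% N) + 1L
        sqrt(rowSums((V[idx, , drop = FALSE] - V)^2))
      } else {
        i <- parS_vertex
        j <- ((i - 1L + k) %% N) + 1L
        sqrt(sum((V[j, ] - V[i, ])^2))
      }
    }), use.names = FALSE)
  })
  structure(list(s_bp = as.numeric(s_grid_bp), samples = samples,
                 sigma = ensemble$levels$sigma[level],
                 n_frames = length(fr), n_cylinders = N),
            class = "distance_samples")
}

#' Estimate the radial distribution P_s(r)
#'
#' Histograms the distance samples at each genomic offset, normalized so
#' that `sum(P * dr) = 1` per offset.
#'
#' @param ds a [distance_samples()] object.
#' @param r_breaks bin edges in nm; defaults to 60 equal bins covering the
#'   sampled range.
#' @return List of class `Ps_estimate` with `s_bp`, `r_mid`, and a matrix
#'   `P` (rows = r bins, columns = offsets).
#' @export
estimate_Ps <- function(ds, r_breaks = NULL) {
  stopifnot(inherits(ds, "distance_samples"))
  if (is.null(r_breaks)) {
    rmax <- max(unlist(lapply(ds$samples, max)), 1e-6)
    r_breaks <- seq(0, rmax * (1 + 1e-9), length.out = 61)
  }
  dr <- diff(r_breaks)
  P <- vapply(ds$samples, function(r) {
    h <- tabulate(findInterval(r, r_breaks, rightmost.closed = TRUE),
                  nbins = length(r_breaks) - 1)
    dens <- h / sum(h) / dr
    dens
  }, numeric(length(r_breaks) - 1))
  structure(list(s_bp = ds$s_bp, r_breaks = r_breaks,
                 r_mid = (head(r_breaks, -1) + tail(r_breaks, -1)) / 2,
                 P = P, sigma = ds$sigma),
            class = "Ps_estimate")
}

#' Local writhe profile
#'
#' \eqn{wr(i) = (2\pi)^{-1} \sum_{j=i-m/2}^{i+m/2} \Omega_{ij}} with the
#' same segment-pair Gauss-integral closed form as the global writhe and
#' periodic indexing.  The default window `m = 10` spans two bending
#' persistence lengths, making the profile sensitive to the tightest
#' plectonemic curls; deep negative minima flag plectoneme branch ends.
#'
#' @param chain an `rlc_chain` or vertex matrix (closed).
#' @param m window size in cylinders (even; `m < N`).  Passing `m >= N - 1`
#'   sums over all non-adjacent pairs, so that the profile sums to twice
#'   the global writhe.
#' @return Numeric vector `wr(i)`, one value per cylinder.
#' @export
local_writhe <- function(chain, m = 10) {
  stopifnot(m %% 2 == 0 || m >= nrow(chain_vertices(chain)) - 1)
  cpp_local_writhe(chain_vertices(chain), as.integer(m), closed = TRUE)
}

#' Periodic strict local minima of a profile
#'
#' Finds indices i with `x[i] < x[i-1]` and `x[i] < x[i+1]` under periodic
#' boundary conditions.  Flat plateaus that are lower than both flanking
#' values are collapsed to a single call at the plateau center, so a flat
#' apex is never double-counted.  A constant profile has no minima.
#'
#' @param x numeric profile (e.g. from [local_writhe()]).
#' @return List with `index` and `value` of the minima.
#' @export
find_local_minima <- function(x) {
  n <- length(x)
  if (n < 3 || diff(range(x)) == 0)
    return(list(index = integer(0), value = numeric(0)))
  # run-length encode the periodic profile to handle plateaus
  r <- rle(x)
  k <- length(r$values)
  if (k == 1) return(list(index = integer(0), value = numeric(0)))
  # rotate so the sequence does not start mid-plateau across the seam
  offset <- 0L
  if (r$values[1] == r$values[k]) {
    offset <- r$lengths[k]
    x2 <- c(x[(n - offset + 1):n], x[1:(n - offset)])
    r <- rle(x2)
    k <- length(r$values)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- integer(0)
  for (t in seq_len(k)) {
    prev <- r$values[if (t == 1) k else t - 1]
    nxt  <- r$values[if (t == k) 1 else t + 1]
    if (r$values[t] < prev && r$values[t] < nxt) {
      center <- floor((starts[t] + ends[t]) / 2)
      idx <- c(idx, center)
    }
  }
  idx <- ((idx - 1L - offset) %% n) + 1L
  list(index = idx, value = x[idx])
}

#' Select the plectoneme writhe threshold wr*
#'
#' Pools local-writhe minima over a per-sigma ensemble and, when their
#' distribution is multimodal, places the threshold at the antimode (the
#' deepest density valley) between the non-plectonemic mode near zero and
#' the plectonemic mode at more negative values, on a kernel density
#' estimate with Silverman's bandwidth.  When the distribution is
#' unimodal the threshold is undefined (`NA`) and branch counts are
#' reported as zero; multimodality only appears once supercoiling is
#' strong enough for plectonemes to form.
#'
#' @param minima pooled minima values (turns).
#' @param min_count minimum number of pooled minima required (default
#'   100); fewer returns `NA` with a warning.
#' @param bw kernel bandwidth; default Silverman's rule (`"nrd0"`).
#' @param depth_floor candidate plectonemic modes are searched at or
#'   below this value (turns).  The default -0.1 sits well past the
#'   thermal-ripple scale of the m = 10 window (local minima of
#'   non-plectonemic DNA stay within about +-0.05 turns) while branch
#'   apexes lie below about -0.2.
#' @param valley_ratio the distribution counts as multimodal only if the
#'   candidate mode's density exceeds the density at the intervening
#'   valley by this factor; smaller bumps are kernel wiggles on the
#'   shoulder of the main mode.
#' @return Threshold wr* in turns, or `NA` if undefined.
#' @export
select_writhe_threshold <- function(minima, min_count = 100, bw = "nrd0",
                                    depth_floor = -0.1,
                                    valley_ratio = 1.2) {
  minima <- minima[is.finite(minima)]
  if (length(minima) < min_count) {
    warning("too few pooled minima to locate a threshold")
    return(NA_real_)
  }
  if (diff(range(minima)) == 0) return(NA_real_)
  d <- density(minima, bw = bw, n = 512)
  y <- d$y
  k <- length(y)
  loc_max <- which(c(FALSE,
                     y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
                     FALSE))
  if (length(loc_max) < 2) return(NA_real_)
  m0 <- loc_max[which.max(y[loc_max])]  # non-plectonemic mode, near zero
  cand <- loc_max[loc_max < m0 & d$x[loc_max] <= depth_floor]
  if (!length(cand)) return(NA_real_)
  # density at the deepest valley separating each candidate from the main
  # mode; a genuine plectonemic mode rises clearly above its valley
  val <- vapply(cand, function(m) min(y[m:m0]), numeric(1))
  ok <- y[cand] >= valley_ratio * pmax(val, 1e-300)
  if (!any(ok)) return(NA_real_)  # unimodal
  m1 <- cand[ok][which.max((y[cand] - val)[ok])]
  valley <- m1 + which.min(y[m1:m0]) - 1
  d$x[valley]
}

#' Count plectonemic branches of one conformation
#'
#' The branch count is the number of local-writhe minima at or below the
#' threshold wr*.  An undefined threshold (`NA`) yields zero.
#'
#' @param wr_profile local-writhe profile (from [local_writhe()]).
#' @param wr_star threshold in turns (from [select_writhe_threshold()]).
#' @return Integer branch count.
#' @export
count_branches <- function(wr_profile, wr_star) {
  if (is.na(wr_star)) return(0L)
  mins <- find_local_minima(wr_profile)
  sum(mins$value <= wr_star)
}

# run-resolved means of an observable computed per frame:
# f(V, wr) -> scalar; returns matrix [level, run]
per_run_means <- function(ensemble, f) {
  n_lev <- nrow(ensemble$levels)
  out <- matrix(NA_real_, n_lev, ensemble$n_runs)
  for (t in seq_len(n_lev))
    for (r in seq_len(ensemble$n_runs)) {
      fr <- ensemble$frames[[t]][[r]]
      if (length(fr))
        out[t, r] <- mean(vapply(fr, f, numeric(1)))
    }
  out
}

# standard error across runs: sqrt(var(run means) / (n_runs - 1)),
# the convention used for 20-run ensembles (var/19)
sem_across_runs <- function(run_means) {
  n <- sum(is.finite(run_means))
  if (n < 2) return(NA_real_)
  sqrt(var(run_means, na.rm = TRUE) / (n - 1))
}

#' Radius-of-gyration curve over sigma
#'
#' Mean radius of gyration per sigma level, with the standard error of the
#' mean computed from the across-run variance of the per-run means
#' (`sqrt(var / (n_runs - 1))`).
#'
#' @param ensemble a `conformation_ensemble`.
#' @return Data frame with `sigma`, `Rg`, `sem`, and per-run means as an
#'   attribute `run_means`.
#' @export
gyration_curve <- function(ensemble) {
  rm_ <- per_run_means(ensemble, function(V) radius_of_gyration(V))
  out <- data.frame(sigma = ensemble$levels$sigma,
                    Rg = rowMeans(rm_, na.rm = TRUE),
                    sem = apply(rm_, 1, sem_across_runs))
  attr(out, "run_means") <- rm_
  out
}

#' Plectoneme branch-count curve over sigma
#'
#' For each sigma level: local-writhe profiles are computed for all stored
#' conformations, their local minima pooled, the threshold wr* selected
#' (unless overridden), and branches counted per conformation.  Reported
#' are the per-level mean branch count and the across-run standard error.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param m local-writhe window (cylinders).
#' @param wr_star optional numeric vector of manual thresholds, one per
#'   level (NA entries fall back to automatic selection).
#' @param min_count passed to [select_writhe_threshold()].
#' @return Data frame with `sigma`, `branches`, `sem`, `wr_star`;
#'   attribute `run_means` carries the per-run matrix.
#' @export
branch_count_curve <- function(ensemble, m = 10, wr_star = NULL,
                               min_count = 100) {
  n_lev <- nrow(ensemble$levels)
  n_runs <- ensemble$n_runs
  thresholds <- numeric(n_lev)
  counts <- matrix(NA_real_, n_lev, n_runs)
  for (t in seq_len(n_lev)) {
    profs <- lapply(seq_len(n_runs), function(r)
      lapply(ensemble$frames[[t]][[r]], local_writhe, m = m))
    pooled <- unlist(lapply(profs, function(pr)
      unlist(lapply(pr, function(p) find_local_minima(p)$value))),
      use.names = FALSE)
    thr <- if (!is.null(wr_star) && is.finite(wr_star[t])) wr_star[t]
           else suppressWarnings(
             select_writhe_threshold(pooled, min_count = min_count))
    thresholds[t] <- thr
    for (r in seq_len(n_runs)) {
      if (length(profs[[r]]))
        counts[t, r] <- mean(vapply(profs[[r]], count_branches,
                                    numeric(1), wr_star = thr))
    }
  }
  out <- data.frame(sigma = ensemble$levels$sigma,
                    branches = rowMeans(counts, na.rm = TRUE),
                    sem = apply(counts, 1, sem_across_runs),
                    wr_star = thresholds)
  attr(out, "run_means") <- counts
  out
}
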