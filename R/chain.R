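# Geometry, topology and energetics of the discrete self-avoiding
# rod-like chain (sRLC): a closed polygon of rigid 10.2 nm cylinders with
# hard-core radius 2 nm, bending stiffness calibrated to a 50 nm persistence
# length and torsional stiffness 86 nm.

#' Elastic and geometric parameters of the rod-like chain
#'
#' Bundles the microscopic parameters of the sRLC model: persistence length,
#' torsional stiffness, cylinder length and hard-core radius, together with
#' the per-joint bending constant `kappa` derived from the persistence
#' length.
#'
#' With a per-joint bending energy \eqn{E = \kappa (1 - \cos\theta)}, the
#' equilibrium tangent correlation of an unconstrained chain is
#' \eqn{\langle\cos\theta\rangle = \coth\kappa - 1/\kappa} (the Langevin
#' function).  The default calibration (`kappa_method = "langevin"`) solves
#' \eqn{\coth\kappa - 1/\kappa = \exp(-l/l_p)} so that the discrete chain
#' reproduces the target persistence length exactly at the 10.2 nm
#' discretization.  The cruder continuum mapping \eqn{\kappa = l_p / l} is
#' available as `kappa_method = "ratio"`.
#'
#' @param l_p bending persistence length (nm); 50 nm for B-DNA in vivo-like
#'   salt conditions.
#' @param C torsional stiffness (nm); 86 nm for B-DNA.
#' @param l cylinder length (nm); 10.2 nm corresponds to 30 bp of B-DNA.
#' @param r_e hard-core cylinder radius (nm); the effective electrostatic
#'   radius, 2 nm.  Non-adjacent cylinder axes may not approach closer than
#'   `2 * r_e`.
#' @param kappa_method calibration of the per-joint bending constant, see
#'   Details.
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' em <- energy_model()
#' em$kappa
energy_model <- function(l_p = 50, C = 86, l = 10.2, r_e = 2,
                         kappa_method = c("langevin", "ratio")) {
  kappa_method <- match.arg(kappa_method)
  stopifnot(l_p > 0, C > 0, l > 0, r_e > 0)
  kappa <- switch(kappa_method,
    langevin = kappa_from_persistence(l, l_p),
    ratio    = l_p / l)
  structure(list(l_p = l_p, C = C, l = l, r_e = r_e,
                 kappa = kappa, kappa_method = kappa_method),
            class = "energy_model")
}

# solve coth(kappa) - 1/kappa = exp(-l / l_p) for kappa
kappa_from_persistence <- function(l, l_p) {
  target <- exp(-l / l_p)
  langevin <- function(k) 1 / tanh(k) - 1 / k
  uniroot(function(k) langevin(k) - target,
          lower = 1e-8, upper = 1e6, tol = 1e-12)$root
}

#' @export
print.energy_model <- function(x, ...) {
  cat("sRLC energy model:\n")
  cat(sprintf("  persistence length l_p = %g nm, torsional stiffness C = %g nm\n",
              x$l_p, x$C))
  cat(sprintf("  cylinder length l = %g nm, hard-core radius r_e = %g nm\n",
              x$l, x$r_e))
  cat(sprintf("  bending constant kappa = %.4f (%s mapping)\n",
              x$kappa, x$kappa_method))
  invisible(x)
}

#' Construct a chain conformation
#'
#' Low-level constructor: wraps an N x 3 vertex matrix (nm) together with
#' its linking-number state.  `build_initial_circle()` is the standard way
#' to obtain a starting conformation.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates in nm.
#' @param Lk linking number (turns).
#' @param Lk0 relaxed linking number (turns).
#' @param closed logical; `TRUE` for a circular chain (segment N joins
#'   vertex N to vertex 1).
#' @param validate check that all segment lengths are equal (relative
#'   tolerance 1e-9).
#' @return An object of class `rlc_chain` with elements `vertices`, `Lk`,
#'   `Lk0`, `closed`, `n_cylinders`, `l` (cylinder length, nm).
#' @export
rlc_chain <- function(vertices, Lk, Lk0, closed = TRUE, validate = TRUE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 3)
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  d <- vertices[c(2:n, 1), ] - vertices
  if (!closed) d <- d[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("chain has coincident consecutive vertices")
  l <- mean(len)
  if (validate && any(abs(len - l) > 1e-9 * l))
    stop("segment lengths are not uniform (relative tolerance 1e-9)")
  structure(list(vertices = vertices, Lk = Lk, Lk0 = Lk0, closed = closed,
                 n_cylinders = if (closed) n else n - 1L, l = l),
            class = "rlc_chain")
}

#' @export
print.rlc_chain <- function(x, ...) {
  cat(sprintf("sRLC conformation: %d cylinders (%s), l = %.3f nm\n",
              x$n_cylinders, if (x$closed) "closed" else "open", x$l))
  cat(sprintf("  Lk = %g, Lk0 = %g, sigma = %.5f\n",
              x$Lk, x$Lk0, chain_sigma(x)))
  invisible(x)
}

#' Supercoiling density of a conformation
#'
#' @param chain an `rlc_chain`.
#' @return sigma = (Lk - Lk0) / Lk0.
#' @export
chain_sigma <- function(chain) (chain$Lk - chain$Lk0) / chain$Lk0

#' Build the initial planar circular conformation
#'
#' Places `n_bp / 30` vertices on a planar circle whose radius
#' `l / (2 sin(pi/N))` makes every chord exactly one cylinder length
#' (circumference `N * l` up to the N^-2 polygon correction), and sets
#' the linking-number state: `Lk0` is the number of
#' double-helical turns of the relaxed molecule (`round(n_bp /
#' helical_repeat)`), and `Lk = Lk0 * (1 + sigma)`.
#'
#' @param n_bp chain length in base pairs; must be divisible by 30 (one
#'   cylinder per 30 bp).
#' @param sigma supercoiling density; the model is calibrated for
#'   `sigma` in `[-0.08, 0]` (values outside trigger a warning: below
#'   -0.08 supercoiled DNA enters a hyperbranched regime not covered here).
#' @param em an [energy_model()] providing the cylinder length.
#' @param helical_repeat helical repeat in bp/turn used to set `Lk0`.  The
#'   default, 30000/2850, makes a 30 kb chain relax at exactly 2850 turns.
#' @return An [rlc_chain()] on a planar circle (writhe 0).
#' @export
#' @examples
#' ch <- build_initial_circle(30000, sigma = 0)
#' ch$n_cylinders  # 1000
#' ch$Lk0          # 2850
build_initial_circle <- function(n_bp, sigma = 0, em = energy_model(),
                                 helical_repeat = 30000 / 2850) {
  if (n_bp %% 30 != 0)
    stop("n_bp must be divisible by 30 (one cylinder per 30 bp)")
  if (sigma < -0.08 || sigma > 0)
    warning("sigma outside [-0.08, 0]: untested supercoiling regime")
  N <- as.integer(n_bp / 30)
  R <- em$l / (2 * sin(pi / N))
  phi <- 2 * pi * (seq_len(N) - 1) / N
  V <- cbind(R * cos(phi), R * sin(phi), 0)
  Lk0 <- round(n_bp / helical_repeat)
  rlc_chain(V, Lk = Lk0 * (1 + sigma), Lk0 = Lk0)
}

chain_vertices <- function(x) {
  if (inherits(x, "rlc_chain")) x$vertices else as.matrix(x)
}

#' Bending energy of a conformation
#'
#' \eqn{E_{bend} = \kappa \sum_i (1 - \cos\theta_i)} in units of kT, where
#' `theta_i` is the angle between consecutive cylinder axes and `kappa` is
#' the per-joint stiffness of the energy model.
#'
#' @param chain an `rlc_chain` (or bare vertex matrix, treated as closed).
#' @param em an [energy_model()].
#' @return Energy in kT.
#' @export
bending_energy <- function(chain, em = energy_model()) {
  closed <- !inherits(chain, "rlc_chain") || chain$closed
  cpp_bending_energy(chain_vertices(chain), em$kappa, closed)
}

#' Writhe of a closed chain
#'
#' Computes \eqn{Wr = (4\pi)^{-1} \sum_{i \ne j} \Omega_{ij}} using the
#' closed-form Gauss-integral contribution of straight segment pairs.
#' Contributions of identical and adjacent segment pairs vanish and are
#' skipped.
#'
#' @param chain an `rlc_chain` or an N x 3 vertex matrix of a closed
#'   polygon.
#' @return Writhe in turns.  Zero (to numerical tolerance) for planar
#'   curves; changes sign under mirror reflection.
#' @export
writhe <- function(chain) {
  V <- chain_vertices(chain)
  n <- nrow(V)
  d <- V[c(2:n, 1), ] - V
  if (any(rowSums(d^2) == 0)) stop("chain has coincident consecutive vertices")
  closed <- !inherits(chain, "rlc_chain") || chain$closed
  if (!closed) stop("writhe is defined for closed chains")
  cpp_writhe(V, closed = TRUE)
}

#' Topology bookkeeping of a conformation
#'
#' Decomposes the linking-number deficit as `Lk - Lk0 = dTw + Wr`
#' (the twist deficit `dTw` is defined by this identity, which therefore
#' holds exactly).
#'
#' @param chain an `rlc_chain`.
#' @param Wr optional precomputed writhe (turns).
#' @return List with `Wr`, `dTw`, `sigma`.
#' @export
topology_state <- function(chain, Wr = NULL) {
  if (is.null(Wr)) Wr <- writhe(chain)
  list(Wr = Wr, dTw = (chain$Lk - chain$Lk0) - Wr, sigma = chain_sigma(chain))
}

#' Torsional energy of a conformation
#'
#' Uniform-twist torsional energy
#' \eqn{E_{tw} = (2 \pi^2 C / L)\, \Delta Tw^2} in kT, with `L = N l` the
#' contour length and \eqn{\Delta Tw = (Lk - Lk_0) - Wr} the twist deficit.
#' Because the chain has no intrinsic curvature and the torsional energy is
#' homogeneous-quadratic, uniform twist is the energy minimum at fixed
#' writhe, so this form yields the same equilibrium ensemble as per-joint
#' twist bookkeeping.
#'
#' @inheritParams bending_energy
#' @param Wr optional precomputed writhe (turns); computed if `NULL`.
#' @return Energy in kT.
#' @export
torsional_energy <- function(chain, em = energy_model(), Wr = NULL) {
  if (is.null(Wr)) Wr <- writhe(chain)
  L <- chain$n_cylinders * em$l
  dTw <- (chain$Lk - chain$Lk0) - Wr
  2 * pi^2 * em$C / L * dTw^2
}

#' Hard-core self-avoidance check
#'
#' Tests whether every (moved) cylinder keeps a center-line distance of at
#' least `2 * r_e` from every non-adjacent cylinder, using exact
#' segment-segment minimum distances.  Cylinders sharing a vertex are
#' exempt.
#'
#' @inheritParams bending_energy
#' @param moved_range optional integer vector `c(first, last)` of 1-based
#'   cylinder indices (wrapping allowed, `first > last`) restricting the
#'   check to pairs involving at least one moved cylinder; `NULL` checks
#'   all pairs.
#' @return `TRUE` if no violation.
#' @export
check_self_avoidance <- function(chain, em = energy_model(),
                                 moved_range = NULL) {
  closed <- !inherits(chain, "rlc_chain") || chain$closed
  if (is.null(moved_range)) {
    cpp_check_self_avoidance(chain_vertices(chain), 2 * em$r_e, closed)
  } else {
    cpp_check_self_avoidance(chain_vertices(chain), 2 * em$r_e, closed,
                             moved_range[1] - 1L, moved_range[2] - 1L)
  }
}

#' Minimum center-line distance between non-adjacent cylinders
#'
#' @inheritParams bending_energy
#' @return Distance in nm; ensembles generated with self-avoidance on keep
#'   this at or above 4 nm.
#' @export
min_nonadjacent_distance <- function(chain) {
  closed <- !inherits(chain, "rlc_chain") || chain$closed
  cpp_min_nonadjacent_dist(chain_vertices(chain), closed)
}

#' Radius of gyration
#'
#' Root-mean-square vertex distance from the centroid.
#'
#' @inheritParams bending_energy
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(chain) {
  V <- chain_vertices(chain)
  ctr <- colMeans(V)
  sqrt(mean(rowSums(sweep(V, 2, ctr)^2)))
}

#' Remove helical turns from a closed chain
#'
#' Decrements the linking number by `k` turns without touching the
#' geometry; the writhe is unchanged and the twist deficit absorbs the
#' change.  The induced supercoiling step is `delta sigma = -k / Lk0`.
#'
#' @param chain an `rlc_chain`.
#' @param k number of helices (turns) to remove; `k >= 0`.
#' @param sigma_floor warn if the resulting sigma drops below this value
#'   (default -0.08, the lower edge of the regime the model is built for).
#' @return The chain with updated `Lk`.
#' @export
remove_helices <- function(chain, k, sigma_floor = -0.08) {
  stopifnot(k >= 0)
  chain$Lk <- chain$Lk - k
  if (chain_sigma(chain) < sigma_floor)
    warning(sprintf("sigma = %.4f below configured floor %.3f",
                    chain_sigma(chain), sigma_floor))
  chain
}

#' Mirror image of a conformation
#'
#' Reflects the vertices through the xy-plane.  Writhe is antisymmetric
#' under this operation.
#'
#' @param chain an `rlc_chain`.
#' @return The mirrored chain.
#' @export
mirror_chain <- function(chain) {
  chain$vertices[, 3] <- -chain$vertices[, 3]
  chain
}
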