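# Metropolis Monte-Carlo sampling of the sRLC with crankshaft moves.
# sigma (i.e. Lk) is strictly conserved within a run; strand passages are
# excluded by the hard core plus a writhe-jump guard, so that the linking
# number is a true invariant of the sampled dynamics.

#' Crankshaft move parameters
#'
#' @param M maximum number of cylinders rotated in one crankshaft move
#'   (reference default 100 for a 1000-cylinder chain; scale with N).
#' @param max_angle maximum rotation angle (radians); the move rotates the
#'   block by an angle uniform in `[-max_angle, max_angle]`.  The proposal
#'   is symmetric, so no Hastings correction is needed.
#' @return Object of class `move_params`.
#' @export
move_params <- function(M = 100, max_angle = pi / 4) {
  stopifnot(M >= 1, max_angle > 0, max_angle <= pi)
  structure(list(M = as.integer(M), max_angle = max_angle),
            class = "move_params")
}

#' Propose a crankshaft rotation
#'
#' Chooses two articulating sites i and j with `1 <= (j - i) mod N <= M`
#' uniformly, and rigidly rotates the vertices strictly between them about
#' the i--j axis by an angle uniform in `[-max_angle, max_angle]`.
#' Cylinder lengths are preserved exactly.  Uses R's RNG stream.
#'
#' @param chain an `rlc_chain`.
#' @param mp a [move_params()].
#' @return List with elements `chain` (the proposed conformation), `i`,
#'   `span`, `angle`, and `moved_range` (1-based inclusive cylinder index
#'   range affected by the rotation).
#' @export
propose_crankshaft <- function(chain, mp = move_params()) {
  if (!chain$closed)
    stop("crankshaft proposals are defined for closed chains")
  N <- chain$n_cylinders
  stopifnot(mp$M <= N - 2)
  i <- sample.int(N, 1)                 # 1-based vertex index
  span <- sample.int(mp$M, 1)
  angle <- runif(1, -mp$max_angle, mp$max_angle)
  V <- if (span >= 2)
    cpp_rotate_block(chain$vertices, i - 1L, span, angle, chain$closed)
  else chain$vertices
  out <- chain
  out$vertices <- V
  list(chain = out, i = i, span = span, angle = angle,
       moved_range = c(i, ((i - 1L + span - 1L) %% N) + 1L))
}

#' Metropolis acceptance rule
#'
#' Rejects any move that creates a hard-core overlap; otherwise accepts
#' with probability `min(1, exp(-dE))` (energies in kT).
#'
#' @param dE energy change in kT.
#' @param overlap logical; `TRUE` if the proposal violates self-avoidance.
#' @return `TRUE` to accept.
#' @export
metropolis_accept <- function(dE, overlap = FALSE) {
  if (overlap) return(FALSE)
  if (!is.finite(dE)) stop("non-finite energy change")
  dE <= 0 || runif(1) < exp(-dE)
}

#' Run Monte-Carlo sweeps at constant supercoiling
#'
#' Executes `n_sweeps` sweeps of `N / M` crankshaft attempts each (the
#' reference convention: 10 attempts per sweep for N = 1000, M = 100).
#' The linking number is untouched, so sigma is strictly constant; the
#' writhe is tracked incrementally from moved-vs-unmoved segment-pair
#' contributions and periodically recomputed in full.
#'
#' @param chain an `rlc_chain`.
#' @param em an [energy_model()].
#' @param mp a [move_params()].
#' @param n_sweeps number of sweeps.
#' @param record_at integer vector of sweep indices at which to store a
#'   conformation snapshot (empty for none).
#' @param self_avoid enforce the hard core (disable only for calibration
#'   checks on phantom chains).
#' @param torsion include the torsional energy (disable for torsion-free
#'   calibration runs).
#' @param wr_jump_max reject moves whose writhe change exceeds this many
#'   turns; a jump near +-1 is the signature of a strand passage, which
#'   must be excluded for Lk to be conserved.
#' @param full_writhe_every recompute the writhe from scratch after this
#'   many accepted moves (guards against incremental drift).
#' @param diagnostics record per-sweep writhe, bending energy and
#'   acceptance rate.
#' @return List of class `rlc_trajectory`: `chain` (final state), `Wr`,
#'   `acceptance_rate`, rejection counters, `frames` (list of vertex
#'   matrices), `frame_wr`, `frame_sweep`, and (if requested) a
#'   `diagnostics` data frame.
#' @export
run_sweeps <- function(chain, em = energy_model(), mp = move_params(),
                       n_sweeps, record_at = integer(0),
                       self_avoid = TRUE, torsion = TRUE,
                       wr_jump_max = 1, full_writhe_every = 1000,
                       diagnostics = FALSE) {
  N <- chain$n_cylinders
  stopifnot(mp$M <= N - 2)
  moves_per_sweep <- max(1L, as.integer(round(N / mp$M)))
  L <- N * em$l
  c_tw <- 2 * pi^2 * em$C / L
  record_at <- as.integer(sort(unique(record_at)))
  res <- cpp_run_sweeps(chain$vertices, chain$Lk, chain$Lk0,
                        em$kappa, c_tw, 2 * em$r_e,
                        mp$M, mp$max_angle,
                        as.integer(n_sweeps), moves_per_sweep,
                        self_avoid, chain$closed, torsion,
                        wr_jump_max, as.integer(full_writhe_every),
                        record_at, diagnostics)
  chain$vertices <- res$vertices
  out <- list(chain = chain, Wr = res$Wr,
              acceptance_rate = res$accepted / res$attempted,
              attempted = res$attempted, accepted = res$accepted,
              rejections = c(overlap = res$rej_overlap,
                             wr_jump = res$rej_wrjump,
                             metropolis = res$rej_metropolis),
              frames = res$frames, frame_wr = res$frame_wr,
              frame_sweep = res$frame_sweep,
              moves_per_sweep = moves_per_sweep)
  if (diagnostics)
    out$diagnostics <- data.frame(sweep = seq_len(n_sweeps),
                                  Wr = res$sweep_wr,
                                  E_bend = res$sweep_ebend,
                                  acceptance = res$sweep_acc)
  class(out) <- "rlc_trajectory"
  out
}

#' @export
print.rlc_trajectory <- function(x, ...) {
  cat(sprintf("sRLC trajectory: %d attempts, acceptance %.3f, %d frames\n",
              x$attempted, x$acceptance_rate, length(x$frames)))
  invisible(x)
}

#' Sample bending angles from the per-joint equilibrium distribution
#'
#' Draws i.i.d. joint angles from the equilibrium density
#' \eqn{p(\theta) \propto \sin\theta \exp(-\kappa(1-\cos\theta))} by exact
#' inverse-CDF sampling in \eqn{u = \cos\theta}.  This is the equilibrium
#' ensemble of an open, torsion-free, phantom chain, whose joints are
#' independent; it is used to calibrate and verify the persistence length
#' mapping.
#'
#' @param n number of draws.
#' @param em an [energy_model()] (uses `kappa`).
#' @return Numeric vector of angles in radians.
#' @export
sample_bending_angles <- function(n, em = energy_model()) {
  k <- em$kappa
  u <- runif(n)
  # CDF in cos(theta): F(c) = (exp(k*c) - exp(-k)) / (exp(k) - exp(-k))
  cth <- 1 + log1p(u * expm1(-2 * k)) / k  # numerically stable for large k
  acos(pmin(1, pmax(-1, cth)))
}
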