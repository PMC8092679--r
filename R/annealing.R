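# Simulated-annealing supercoiling protocol: equilibrate/sample at each
# sigma level, then remove helices to step sigma down, repeating from
# sigma = 0 to the configured floor.

#' Annealing schedule over supercoiling densities
#'
#' Defines the ladder of sigma levels (default 17 levels from 0 down to
#' -0.08 in steps of 0.005), the number of sweeps spent at each level, and
#' how the linking number is decremented between levels.  The normalized
#' supercoiling rate `v = 1` corresponds to 5e5 sweeps per level
#' (the quickest reference protocol); slower protocols have `v < 1`.
#'
#' @param sweeps_per_level number of Monte-Carlo sweeps at each sigma
#'   level.
#' @param sigma_min most negative sigma (default -0.08).
#' @param sigma_step magnitude of the sigma decrement between levels
#'   (default 0.005).
#' @param helices_per_step helices removed at each step; `NULL` (default)
#'   derives the per-step removal from the cumulative sigma targets
#'   (`Lk` at level t is `round(Lk0 * (1 + sigma_t))`), which removes
#'   typically 14 helices per step for a 30 kb chain.
#' @return Object of class `annealing_schedule` with the `sigma_values`
#'   ladder and the normalized rate `v`.
#' @export
annealing_schedule <- function(sweeps_per_level, sigma_min = -0.08,
                               sigma_step = 0.005, helices_per_step = NULL) {
  stopifnot(sweeps_per_level >= 1, sigma_min < 0, sigma_step > 0)
  sigma_values <- seq(0, sigma_min, by = -sigma_step)
  structure(list(sigma_values = sigma_values,
                 sweeps_per_level = as.integer(sweeps_per_level),
                 helices_per_step = helices_per_step,
                 v = (sigma_step / sweeps_per_level) / (0.005 / 5e5)),
            class = "annealing_schedule")
}

#' Sampling plan for an annealing study
#'
#' Frames are drawn only from the second half of each level's sweeps
#' (the first half serves as implicit equilibration), at evenly spaced
#' sweep indices.
#'
#' @param n_runs number of independent simulation runs (reference protocol: 20).
#' @param frames_per_run conformations stored per run and sigma level
#'   (reference protocol: 2500).
#' @return Object of class `sampling_plan`.
#' @export
sampling_plan <- function(n_runs = 20, frames_per_run = 2500) {
  stopifnot(n_runs >= 1, frames_per_run >= 0)
  structure(list(n_runs = as.integer(n_runs),
                 frames_per_run = as.integer(frames_per_run)),
            class = "sampling_plan")
}

# sweep indices at which frames are recorded: evenly spaced in
# (n_sweeps/2, n_sweeps]
record_sweeps <- function(n_sweeps, frames_per_run) {
  if (frames_per_run < 1) return(integer(0))
  lo <- floor(n_sweeps / 2)
  unique(as.integer(round(lo + (n_sweeps - lo) *
                            seq_len(frames_per_run) / frames_per_run)))
}

#' Total Monte-Carlo step count of an annealing protocol
#'
#' Number of elementary crankshaft attempts the scheduler will execute for
#' one run: `n_levels * sweeps_per_level * (N / M)`.
#'
#' @param schedule an [annealing_schedule()].
#' @param n_bp chain length in bp.
#' @param mp a [move_params()].
#' @return Step count (double, to hold production-scale magnitudes).
#' @export
#' @examples
#' sch <- annealing_schedule(sweeps_per_level = 1.6e7)
#' annealing_step_count(sch, 30000, move_params(M = 100))  # 2.72e9
annealing_step_count <- function(schedule, n_bp, mp = move_params()) {
  N <- n_bp / 30
  length(schedule$sigma_values) * as.numeric(schedule$sweeps_per_level) *
    round(N / mp$M)
}

#' Run the simulated-annealing supercoiling protocol
#'
#' For each independent run: start from a planar circle at sigma = 0, then
#' at each sigma level sample `sweeps_per_level` sweeps (recording frames
#' per the sampling plan from the second half) and remove helices to reach
#' the next level.  Per-run RNG streams are derived reproducibly from the
#' master seed, so identical seeds give identical trajectories.
#'
#' @param n_bp chain length in bp (divisible by 30).
#' @param schedule an [annealing_schedule()].
#' @param plan a [sampling_plan()].
#' @param em an [energy_model()].
#' @param mp a [move_params()]; `M` must be at most `n_bp/30 - 2`.
#' @param seed master integer seed.
#' @param helical_repeat passed to [build_initial_circle()].
#' @param progress print a line per completed (run, level).
#' @return Object of class `conformation_ensemble`: `levels` data frame
#'   (nominal and realized sigma, Lk per level), `frames[[level]][[run]]`
#'   lists of vertex matrices, `wr[[level]][[run]]` writhe per frame,
#'   diagnostics (acceptance per level/run), plus chain metadata.
#' @export
run_annealing_protocol <- function(n_bp, schedule, plan,
                                   em = energy_model(), mp = move_params(),
                                   seed = 1, helical_repeat = 30000 / 2850,
                                   progress = FALSE) {
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, plan$n_runs)
  sig <- schedule$sigma_values
  n_lev <- length(sig)
  template <- build_initial_circle(n_bp, 0, em, helical_repeat)
  Lk0 <- template$Lk0
  lk_targets <- if (is.null(schedule$helices_per_step))
    round(Lk0 * (1 + sig))
  else
    Lk0 - schedule$helices_per_step * (seq_len(n_lev) - 1)

  frames <- rep(list(vector("list", plan$n_runs)), n_lev)
  wrs    <- rep(list(vector("list", plan$n_runs)), n_lev)
  acc <- matrix(NA_real_, n_lev, plan$n_runs)
  sigma_act <- (lk_targets - Lk0) / Lk0
  rec <- record_sweeps(schedule$sweeps_per_level, plan$frames_per_run)

  for (r in seq_len(plan$n_runs)) {
    set.seed(run_seeds[r])
    chain <- template
    for (t in seq_len(n_lev)) {
      chain$Lk <- lk_targets[t]
      tr <- run_sweeps(chain, em, mp, schedule$sweeps_per_level,
                       record_at = rec)
      chain <- tr$chain
      frames[[t]][[r]] <- tr$frames
      wrs[[t]][[r]] <- tr$frame_wr
      acc[t, r] <- tr$acceptance_rate
      if (progress)
        message(sprintf("run %d level %d (sigma %.4f) acc %.3f Wr %.2f",
                        r, t, sigma_act[t], tr$acceptance_rate, tr$Wr))
    }
  }
  structure(list(levels = data.frame(level = seq_len(n_lev),
                                     sigma_nominal = sig,
                                     sigma = sigma_act,
                                     Lk = lk_targets),
                 frames = frames, wr = wrs, acceptance = acc,
                 n_bp = n_bp, n_cylinders = template$n_cylinders,
                 Lk0 = Lk0, l = em$l, n_runs = plan$n_runs,
                 schedule = schedule, plan = plan, seed = seed),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf(paste0("sRLC conformational ensemble: %d bp (%d cylinders), ",
                     "%d sigma levels x %d runs\n"),
              x$n_bp, x$n_cylinders, nrow(x$levels), x$n_runs))
  cat(sprintf("  sigma from %.3f to %.3f, %d frames per (level, run)\n",
              max(x$levels$sigma), min(x$levels$sigma),
              length(x$frames[[1]][[1]])))
  invisible(x)
}
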