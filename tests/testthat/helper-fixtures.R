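# Shared simulation fixtures, computed once per test session.
#
# The scaled-down annealing study used by the observables and physics
# tests: a 6 kb circular chain (200 cylinders, Lk0 = 570), 5 independent
# runs through the 17-level sigma ladder (0 to -0.08 in 0.005 steps), with
# frames sampled from the second half of each level.  The sweep count per
# level sits in the rate-insensitive regime established for this chain
# size (see the rate-insensitivity test on a 3 kb chain).

.fixtures <- new.env(parent = emptyenv())

annealing_fixture <- function() {
  if (is.null(.fixtures$ens)) {
    em <- energy_model()
    mp <- move_params(M = 20)
    sch <- annealing_schedule(sweeps_per_level = 2000)
    plan <- sampling_plan(n_runs = 5, frames_per_run = 30)
    .fixtures$ens <- run_annealing_protocol(6000, sch, plan, em, mp,
                                            seed = 912650)
  }
  .fixtures$ens
}

# tiny ensemble wrapper around explicit frames, for observable unit tests
manual_ensemble <- function(frames_by_level_run, sigma, n_bp, Lk0) {
  n_lev <- length(frames_by_level_run)
  structure(list(levels = data.frame(level = seq_len(n_lev),
                                     sigma_nominal = sigma, sigma = sigma,
                                     Lk = Lk0 * (1 + sigma)),
                 frames = frames_by_level_run,
                 wr = NULL, acceptance = NULL,
                 n_bp = n_bp, n_cylinders = n_bp / 30, Lk0 = Lk0,
                 l = 10.2, n_runs = length(frames_by_level_run[[1]]),
                 schedule = NULL, plan = NULL, seed = NA),
            class = "conformation_ensemble")
}
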