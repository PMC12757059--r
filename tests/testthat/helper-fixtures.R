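# Shared fixtures, built once per test run and cached. The "desk" model
# (scale 0.1, ~2.5k recurrent neurons) backs the simulation-based tests;
# the "tiny" model (scale 0.01, ~250 neurons) backs cheap unit tests.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) assign(name, build(), .fx_cache)
  get(name, envir = .fx_cache)
}

fx_tiny <- function() fx("tiny", function() make_fixtures(seed = 2))

fx_model <- function() fx("model", function() build_model(scale = 0.1, seed = 7))

fx_matched <- function() fx("matched", function()
  build_model(scale = 0.1, seed = 7, variant = "matched"))

# three-condition normalization experiment on the desk model, with spike
# rasters and current traces for 60 units kept for correlation/covariance
# analyses (2 x 8 s per condition)
fx_norm <- function() fx("norm", function() {
  cnet <- fx_model()
  run_normalization_experiment(cnet, T = 8000, n_sims = 2, seed = 5,
                               keep_spikes = TRUE,
                               trace_units = seq_len(60))
})

fx_norm_matched <- function() fx("norm_matched", function()
  run_normalization_experiment(fx_matched(), T = 8000, n_sims = 2,
                               seed = 5))

# orientation tuning curves of the desk model (18 orientations x 2.5 s)
fx_tuning <- function() fx("tuning", function()
  tuning_curves(fx_model(), T = 2500, seed = 13))

# direct single-neuron harness around the integrator core
sim_one <- function(T, I_ext, DT = 2, V0 = -60, dt = 0.05, taum = 15,
                    tref = 1.5, seed = 1) {
  epar <- c(taum, -60, -50, -10, DT, -65, tref)
  normnet:::sim_eif_network(
    1L, 0L, epar, epar,
    c(0L, 0L), integer(0), numeric(0),
    0L, integer(0), numeric(0),
    0L, integer(0), numeric(0),
    c(1, 5, 1, 8, 2, 100, 0.2, 0.8),
    matrix(0, 0, 0), matrix(0, 0, 0),
    matrix(0, 0, 1), matrix(0, 0, 1),
    matrix(c(1L, 0L, 1L, 0L), 1, 4), T, 0, 0,
    1, 1, 40, 3.5,
    T, dt, 1, 10, 0,
    integer(0), FALSE, I_ext, 0, V0, seed)
}
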