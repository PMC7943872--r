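# Fixtures are built in code: no binary data.

# A beat of zeros with an optional spike so splice/onset logic has a
# dominant deflection to lock onto.
zero_beat <- function(T = 300, fs = 1000) {
  ecg_beat(matrix(0, 12, T), fs)
}

spike_beat <- function(T = 300, fs = 1000, at = 150, lead = 1, amp = 1) {
  v <- matrix(0, 12, T)
  v[lead, at] <- amp
  ecg_beat(v, fs)
}

# Random beat with a guaranteed dominant central spike (stable alignment).
random_beat <- function(T = 300, fs = 1000, sd = 0.1, spike = 5) {
  v <- matrix(rnorm(12 * T, sd = sd), 12, T)
  v[, T %/% 2] <- v[, T %/% 2] + spike
  ecg_beat(v, fs)
}

# Noiseless affine-mode config/dataset shared by localizer oracles.
affine_config <- function(seed = 42, n_sites = 25) {
  synthetic_config(n_sites = n_sites, mode = "affine", beats_per_site = 1,
                   beat_noise_sd = 0, seed = seed)
}

affine_site_at <- function(position, cfg, id = "X") {
  v <- pacemapr:::affine_waveform(position, cfg)
  pacing_site(id, position, list(ecg_beat(v, cfg$sampling_rate)))
}

# Minimal site stub for geometry-only code paths (protocol site selection,
# translation tests with injected splices).
stub_site <- function(id, position, splice = NULL) {
  structure(list(site_id = id, position = as.numeric(position),
                 beats = list(), representative = NULL, splice = splice),
            class = "pacing_site")
}

random_splice <- function(W = 20) {
  splice_vector(rnorm(12 * W), W, 1L)
}

stub_dataset <- function(positions, ids = sprintf("P%02d", seq_len(nrow(positions)))) {
  sites <- lapply(seq_len(nrow(positions)), function(i) {
    stub_site(ids[i], positions[i, ])
  })
  patient_dataset("stub", sites)
}

# Stub localizer returning a fixed (or target-dependent) position.
stub_model <- function(fun, n_init = 3L) {
  f <- function(modeling, target_site) {
    pvc_prediction(fun(modeling, target_site), "stub")
  }
  attr(f, "n_init") <- n_init
  f
}

# Hand-built protocol trace for metric bookkeeping tests.
mk_trace <- function(errors, min_d = rep(30, length(errors)),
                     termination = "exhausted", model = "STUB",
                     target = "T1", n0 = 3, radius = 30) {
  structure(
    list(target_id = target, model_name = model, variant = "adaptive",
         scheme = "range", initial_radius = radius,
         termination = termination,
         rounds = data.frame(
           round = seq_along(errors),
           n_sites = n0 + seq_along(errors) - 1L,
           added_ids = "", modeling_ids = "",
           pred_x = 0, pred_y = 0, pred_z = 0,
           estimated_error = errors,
           min_modeling_distance = min_d,
           stringsAsFactors = FALSE)),
    class = "protocol_trace")
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))
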