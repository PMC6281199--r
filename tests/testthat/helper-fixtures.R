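# shared fixture builders (everything generated in code; no stored data)

# minimal al_epochs around an array [trials, channels, time]
make_epochs <- function(data, fs, time0 = -5, condition = "closed") {
  nt <- dim(data)[3]
  structure(list(
    data = data,
    time = time0 + (seq_len(nt) - 1L) / fs,
    fs = fs,
    condition = rep(condition, dim(data)[1]),
    trial_id = seq_len(dim(data)[1]),
    channels = tibble::tibble(channel = seq_len(dim(data)[2]), array = 1L),
    align = "onset",
    provenance = c("onset-aligned", "rejection only")
  ), class = "al_epochs")
}

# minimal raw al_tfr wrapping power [trials, channels, freqs, time]
make_tfr <- function(power, freqs, time, fs = 1) {
  structure(list(power = power, freqs = freqs, time = time, fs = fs,
                 condition = rep("closed", dim(power)[1]),
                 trial_id = seq_len(dim(power)[1]),
                 channels = tibble::tibble(channel = seq_len(dim(power)[2]),
                                           array = 1L),
                 align = "onset", stream = "total", normalization = "raw"),
            class = "al_tfr")
}

# compact single-condition synthetic session for pipeline tests
small_session <- function(seed = 1, n_blocks = 2, fs = 250,
                          effects = list(), n_arrays = 2,
                          conditions = rep("closed", n_blocks)) {
  sch <- trial_schedule(trials_per_block = 10, rest_duration = 11.5,
                        inter_block_rest = 2, block_conditions = conditions)
  m <- channel_map(n_arrays, layout = c(2, 4), controller = c(1, 1))
  generate_session(effects, sch, m, seed = seed, fs = fs)
}

# alpha-band analysis config sized for tests
alpha_cfg <- function(..., seed = 1, n_draws = 200) {
  analysis_config(
    tfr = tfr_config(freqs = 8:15, n_cycles = 8:15, hf_freqs = NULL),
    bands = bands_default()["alpha"],
    stats = stats_config(n_boot = n_draws, n_perm = n_draws, seed = seed),
    baseline_stride = 4L, ...)
}
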