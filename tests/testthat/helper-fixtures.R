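# Shared fixtures, memoised across test files (test_dir runs in one
# process). Closed-loop runs are the expensive part; build each once.

fs_cache <- new.env(parent = emptyenv())

fs_memo <- function(key, expr) {
  if (is.null(fs_cache[[key]])) fs_cache[[key]] <- force(expr)
  fs_cache[[key]]
}

fx_params7 <- function() gelma_preset("gelma_7pct")
fx_params55 <- function() gelma_preset("gelma_5p5pct")

fx_model7 <- function() fs_memo("model7", to_state_space(fx_params7()))

fx_design7 <- function() fs_memo("design7", controller_design(fx_model7()))

# reference noisy tracking runs (the headline scenario)
fx_trace7 <- function() fs_memo("trace7", run_closed_loop(
  fx_params7(), fx_design7(), loading_command(n_cycles = 3),
  noise_spec(), seed = 1))

fx_trace55 <- function() fs_memo("trace55", run_closed_loop(
  fx_params55(), fx_design7(), loading_command(n_cycles = 3),
  noise_spec(), seed = 1))

# closed-loop runs over a command-amplitude sweep at 0.01 Hz
fx_amp_sweep <- function() fs_memo("amp_sweep", lapply(
  c(3, 4, 5, 6), function(a) run_closed_loop(
    fx_params7(), fx_design7(),
    loading_command(offset_uN = a, amplitude_uN = a, n_cycles = 3),
    noise_spec(), seed = 10 + a)))

# closed-loop runs over a frequency sweep at fixed 5 uN amplitude
fx_freq_sweep <- function() fs_memo("freq_sweep", lapply(
  c(0.005, 0.01, 0.02), function(f) run_closed_loop(
    fx_params7(), fx_design7(),
    loading_command(frequency_Hz = f, n_cycles = 3),
    noise_spec(), seed = round(1e3 * f))))

fx_fiber <- function() fiber_spec(diameter_um = 150, L0_um = 1000)
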