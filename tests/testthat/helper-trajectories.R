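# Shared trajectory cache: several tests interrogate the same reference
# integrations, so each is computed once per test run.
.traj_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .traj_cache)) assign(key, fn(), envir = .traj_cache)
  get(key, envir = .traj_cache)
}

traj_K <- function(K, t_end = 1000) {
  cached(sprintf("K%g_%g", K, t_end), function()
    integrate_model(update_params(dormprey_params(), K = K),
                    t_span = c(0, t_end)))
}

traj_preset <- function(name) {
  cached(paste0("preset_", name), function() {
    pr <- scenario_preset(name)
    integrate_model(pr$params, pr$initial, pr$t_span)
  })
}

# Independent brute-force peak oracle: scan every interior sample.
brute_peaks <- function(t, v) {
  idx <- 1L + which(vapply(2:(length(v) - 1L), function(i)
    v[i] > v[i - 1L] && v[i] > v[i + 1L], logical(1)))
  data.frame(time = t[idx], value = v[idx])
}
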