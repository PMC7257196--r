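# shared fixtures, all built in code

# uniform points over a rectangle, deterministic under seed
make_points <- function(n, extent = c(0, 6000, 0, 6000), seed = 1) {
  withr::with_seed(seed, data.frame(
    id = sprintf("p%05d", seq_len(n)),
    x = stats::runif(n, extent[1], extent[2]),
    y = stats::runif(n, extent[3], extent[4])))
}

# full synthetic audit dataset: GRF latent field + logistic responses
make_sim_dataset <- function(n = 1500, extent = c(0, 7500, 0, 7500), seed = 1,
                             spec = simulation_spec(seed = seed)) {
  pts <- make_points(n, extent, seed)
  f <- simulate_latent_field(pts, spec$latent_model,
                             seed = derive_seed(seed, "field"))
  simulate_responses(pts, f, spec)
}

# empirical variogram object from known bins (noise-free oracle input)
make_emp <- function(model, max_lag = 4, n_lags = 40, np = 100) {
  lag <- seq(max_lag / n_lags / 2, max_lag - max_lag / n_lags / 2,
             length.out = n_lags)
  out <- data.frame(lag = lag, gamma = model_semivariance(model, lag),
                    np = rep(np, n_lags))
  class(out) <- c("empirical_variogram", "data.frame")
  attr(out, "max_lag") <- max_lag
  out
}
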