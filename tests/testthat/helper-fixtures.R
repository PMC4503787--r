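## Shared fixtures built in code.

## Small reference specs (kept tiny so unit tests stay fast).
small_spec <- function(kind = "unclustered", N = 200, c = 4, ...) {
  network_spec(kind, N = N, c = c, ...)
}

## Deterministic raster: each neuron fires periodically at `rate_hz` from
## t = offset; duration in seconds.
periodic_raster <- function(rates_hz, duration_s = 2, N = length(rates_hz),
                            offset_ms = 1) {
  ev <- do.call(rbind, lapply(seq_along(rates_hz), function(i) {
    if (rates_hz[i] <= 0) return(NULL)
    t <- seq(offset_ms, duration_s * 1000, by = 1000 / rates_hz[i])
    data.frame(id = i, time_ms = t)
  }))
  if (is.null(ev)) ev <- data.frame(id = integer(), time_ms = numeric())
  ev <- ev[order(ev$time_ms, ev$id), ]
  structure(ev, class = c("spike_raster", "data.frame"),
            duration_ms = duration_s * 1000, N = N,
            types = rep("E", N))
}

## Homogeneous Poisson raster at `rate_hz` for all N neurons.
poisson_raster <- function(N, rate_hz, duration_s, seed) {
  set.seed(seed)
  n_sp <- stats::rpois(N, rate_hz * duration_s)
  ev <- data.frame(
    id = rep(seq_len(N), n_sp),
    time_ms = stats::runif(sum(n_sp), 0, duration_s * 1000))
  ev <- ev[order(ev$time_ms), ]
  structure(ev, class = c("spike_raster", "data.frame"),
            duration_ms = duration_s * 1000, N = N,
            types = rep("E", N))
}

simple_partition <- function(group) list(group = group, scope = "E",
                                         levels = NULL)

## Admissible random rate-model parameters.
random_rate_params <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(s = stats::runif(n, 0.3, 1.2),
             eps = stats::runif(n, 0.01, 0.29),
             k = stats::runif(n, 1, 3))
}
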