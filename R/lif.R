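#' Leaky integrate-and-fire simulation parameters
#'
#' Defaults follow the reference balanced-network setup: dimensionless
#' membrane potential with threshold 1 and reset 0; membrane time constants
#' 15 ms (excitatory) and 10 ms (inhibitory); refractory period 5 ms;
#' constant suprathreshold drive \eqn{\mu} drawn once per neuron, uniformly
#' in \[1.1, 1.2\] for excitatory and \[1, 1.05\] for inhibitory neurons;
#' exponential synaptic kinetics with \eqn{\tau_E = 3} ms and
#' \eqn{\tau_I = 2} ms; integration step 0.1 ms.
#'
#' @param duration Simulated time in seconds.
#' @param dt Integration step in ms (must be below both synaptic time
#'   constants).
#' @param tau_m_E,tau_m_I Membrane time constants in ms.
#' @param tau_E,tau_I Synaptic decay time constants in ms.
#' @param refractory Refractory period in ms.
#' @param mu_E,mu_I Ranges (length-2) of the constant drive per neuron type.
#' @param threshold,reset Firing threshold and reset potential.
#' @param seed Seed for the per-neuron drives and initial potentials.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(duration = 20, dt = 0.1,
                       tau_m_E = 15, tau_m_I = 10,
                       tau_E = 3, tau_I = 2,
                       refractory = 5,
                       mu_E = c(1.1, 1.2), mu_I = c(1, 1.05),
                       threshold = 1, reset = 0, seed = 1L) {
  stopifnot(duration > 0, dt > 0, dt < min(tau_E, tau_I), refractory >= 0,
            length(mu_E) == 2, length(mu_I) == 2)
  structure(list(duration = duration, dt = dt, tau_m_E = tau_m_E,
                 tau_m_I = tau_m_I, tau_E = tau_E, tau_I = tau_I,
                 refractory = refractory, mu_E = mu_E, mu_I = mu_I,
                 threshold = threshold, reset = reset,
                 seed = as.integer(seed)),
            class = "lif_params")
}

#' Simulate a leaky integrate-and-fire network
#'
#' Integrates \eqn{dV_i/dt = (\mu_i - V_i)/\tau_m + \sum_j W_{ij} g_j(t)}
#' with exponential synaptic traces \eqn{g_j} that jump by 1 one step after
#' each presynaptic spike and decay with \eqn{\tau_E} or \eqn{\tau_I}
#' according to the presynaptic type. Threshold crossings are detected at
#' step boundaries; a spiking neuron is reset and clamped for the refractory
#' period. Initial potentials are uniform in \[0, 1).
#'
#' @param net An `ssa_network` (or a list with a square matrix `W` and a
#'   `types` vector of `"E"`/`"I"` labels).
#' @param params A [lif_params()].
#' @return A `spike_raster`: data frame with columns `id` (1-based neuron
#'   index) and `time_ms`, time-sorted, with attributes `duration_ms`, `N`
#'   and `types`.
#' @examples
#' net <- generate_network(network_spec("unclustered", N = 100, c = 4))
#' r <- simulate_lif(net, lif_params(duration = 0.5, seed = 2))
#' head(r)
#' @export
simulate_lif <- function(net, params = lif_params()) {
  W <- net$W
  N <- nrow(W)
  types <- if (!is.null(net$types)) net$types else rep("E", N)
  stopifnot(ncol(W) == N, length(types) == N)
  inhib <- types == "I"
  set.seed(params$seed)
  mu <- numeric(N)
  mu[!inhib] <- stats::runif(sum(!inhib), params$mu_E[1], params$mu_E[2])
  mu[inhib] <- stats::runif(sum(inhib), params$mu_I[1], params$mu_I[2])
  v0 <- stats::runif(N, 0, 1)
  tau_m <- ifelse(inhib, params$tau_m_I, params$tau_m_E)
  n_steps <- round(params$duration * 1000 / params$dt)
  res <- lif_core(W, inhib, mu, v0, tau_m, params$dt, n_steps,
                  params$tau_E, params$tau_I,
                  as.integer(round(params$refractory / params$dt)),
                  params$threshold, params$reset)
  raster <- data.frame(id = res$id, time_ms = res$time_ms)
  raster <- raster[order(raster$time_ms, raster$id), , drop = FALSE]
  rownames(raster) <- NULL
  structure(raster, class = c("spike_raster", "data.frame"),
            duration_ms = params$duration * 1000, N = N, types = types)
}

#' @export
print.spike_raster <- function(x, ...) {
  N <- attr(x, "N"); dur <- attr(x, "duration_ms")
  cat(sprintf("<spike_raster> %d spikes, %d neurons, %.1f s (%.2f Hz mean)\n",
              nrow(x), N, dur / 1000, nrow(x) / N / (dur / 1000)))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, cex = 0.2, ...) {
  graphics::plot(x$time_ms / 1000, x$id, pch = ".", cex = cex,
                 xlab = "time (s)", ylab = "neuron", ...)
  invisible(x)
}

#' Mean firing rates from a raster
#'
#' @param raster A `spike_raster`.
#' @param by Either `"neuron"` or `"type"`.
#' @return Rates in Hz.
#' @export
firing_rates <- function(raster, by = c("neuron", "type")) {
  by <- match.arg(by)
  N <- attr(raster, "N")
  dur_s <- attr(raster, "duration_ms") / 1000
  counts <- tabulate(raster$id, nbins = N)
  if (by == "neuron") return(counts / dur_s)
  tapply(counts / dur_s, attr(raster, "types"), mean)
}

#' Report the expected excitatory/inhibitory input balance
#'
#' Computes, per neuron type, the expected summed synaptic input implied by
#' the realized weight matrix (mean row sum split into excitatory and
#' inhibitory contributions) and flags networks whose excitatory input
#' exceeds inhibition in magnitude, i.e. which are not balanced.
#'
#' @param net An `ssa_network`.
#' @return A data frame with one row per postsynaptic type, plus attributes
#'   `balanced` and `recurrent`.
#' @export
validate_balance <- function(net) {
  ty <- net$types
  rows <- lapply(c("E", "I"), function(post) {
    B <- net$W[ty == post, , drop = FALSE]
    exc <- sum(B[, ty == "E"]) / nrow(B)
    inh <- sum(B[, ty == "I"]) / nrow(B)
    data.frame(post_type = post, excitatory_in = exc, inhibitory_in = inh,
               net_in = exc + inh)
  })
  out <- do.call(rbind, rows)
  attr(out, "recurrent") <- any(net$W != 0)
  ## realized sums fluctuate around the expected balance; allow a small
  ## sampling margin relative to the inhibitory input before flagging
  attr(out, "balanced") <- all(out$net_in <= 0.02 * abs(out$inhibitory_in))
  if (!attr(out, "recurrent"))
    message("no recurrence: weight matrix is all zero")
  else if (!attr(out, "balanced"))
    warning("expected excitatory input exceeds inhibition; ",
            "network is not balanced")
  out
}

#' Raster CSV I/O
#'
#' Rasters are written as two-column CSV `neuron_id,time_ms` with 0-based
#' neuron indices.
#'
#' @param raster A `spike_raster`.
#' @param path Output path.
#' @param N,duration_ms Metadata needed to reconstruct the raster on read;
#'   `read_raster` infers them from the data when not given.
#' @return `read_raster` returns a `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  utils::write.csv(data.frame(neuron_id = raster$id - 1L,
                              time_ms = raster$time_ms),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, N = NULL, duration_ms = NULL) {
  df <- utils::read.csv(path)
  out <- data.frame(id = df$neuron_id + 1L, time_ms = df$time_ms)
  structure(out, class = c("spike_raster", "data.frame"),
            duration_ms = if (is.null(duration_ms)) max(df$time_ms)
                          else duration_ms,
            N = if (is.null(N)) max(out$id) else N,
            types = NULL)
}
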