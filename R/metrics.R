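## Spike-train metrics of slow-switching assembly dynamics.

## Population standard deviation (divide by n, not n-1); held fixed across
## all variability scores.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

## Per-neuron spike counts in non-overlapping windows: n x T matrix for the
## given neuron indices.
neuron_window_counts <- function(raster, neurons, window_ms, duration_ms) {
  T_n <- floor(duration_ms / window_ms)
  keep <- raster$id %in% neurons & raster$time_ms <= T_n * window_ms
  id_f <- factor(raster$id[keep], levels = neurons)
  win <- pmin(floor(raster$time_ms[keep] / window_ms) + 1L, T_n)
  counts <- table(id_f, factor(win, levels = seq_len(T_n)))
  matrix(as.integer(counts), nrow = length(neurons),
         dimnames = list(NULL, NULL))
}

#' Group firing-rate matrix
#'
#' Average spiking frequency of each partition group over non-overlapping
#' windows: entry `(i, t)` is the spike count of group `i` in window `t`
#' divided by group size and window length, in Hz. The 100 ms window is the
#' convention for the variability scores; 250 ms is used for PCA patterns.
#'
#' @param raster A `spike_raster` (or data frame with `id`, `time_ms` plus
#'   a `duration_ms` attribute).
#' @param partition Partition list with `$group`.
#' @param window_ms Window length in ms.
#' @return A `c x T` matrix of rates in Hz, with attribute `window_ms`.
#' @export
group_rate_matrix <- function(raster, partition, window_ms = 100) {
  grp <- partition$group
  duration_ms <- attr(raster, "duration_ms")
  if (window_ms > duration_ms) stop("window exceeds raster duration")
  neurons <- which(!is.na(grp))
  stopifnot(length(neurons) > 0)
  counts <- neuron_window_counts(raster, neurons, window_ms, duration_ms)
  g <- grp[neurons]
  gids <- sort(unique(g))
  rates <- do.call(rbind, lapply(gids, function(gg) {
    colSums(counts[g == gg, , drop = FALSE]) /
      (sum(g == gg) * window_ms / 1000)
  }))
  rownames(rates) <- gids
  structure(rates, window_ms = window_ms)
}

## Shared engine for the two variability scores. Shuffles permute the
## group assignment uniformly among exactly the partitioned neurons,
## preserving group sizes; the shuffle RNG is seeded independently of the
## simulation.
variability_engine <- function(raster, partition, window_ms, n_shuffles,
                               seed, statistic) {
  grp <- partition$group
  neurons <- which(!is.na(grp))
  g <- grp[neurons]
  gids <- sort(unique(g))
  if (length(gids) < 2) stop("need at least 2 groups")
  duration_ms <- attr(raster, "duration_ms")
  counts <- neuron_window_counts(raster, neurons, window_ms, duration_ms)
  win_s <- window_ms / 1000
  score_for <- function(assign) {
    rates <- do.call(rbind, lapply(gids, function(gg) {
      colSums(counts[assign == gg, , drop = FALSE]) /
        (sum(assign == gg) * win_s)
    }))
    statistic(rates)
  }
  S <- score_for(g)
  set.seed(seed)
  S_shuff <- vapply(seq_len(n_shuffles),
                    function(i) score_for(sample(g)), numeric(1))
  list(S = S, S_shuff_mean = mean(S_shuff), S_hat = S - mean(S_shuff),
       S_shuff = S_shuff, n_shuffles = n_shuffles)
}

#' Spike-rate variability across assemblies (S, S-hat)
#'
#' For each 100 ms window the standard deviation of the `c` group firing
#' rates is computed; `S` is its time average and `S_hat = S - <S_shuff>`
#' subtracts the mean over random reshufflings of neurons into groups of
#' the same sizes. `S_hat` is near zero for asynchronous firing and grows
#' with slow-switching assembly activity.
#'
#' @param raster A `spike_raster`.
#' @param partition Partition list with `$group`.
#' @param window_ms Rate window (ms).
#' @param n_shuffles Number of random reshufflings for the baseline.
#' @param seed Shuffle seed (independent of the simulation seed).
#' @return List of class `variability_scores` with `S`, `S_shuff_mean`,
#'   `S_hat` (all Hz) and the individual shuffle values.
#' @export
spike_rate_variability <- function(raster, partition, window_ms = 100,
                                   n_shuffles = 10, seed = 1L) {
  out <- variability_engine(raster, partition, window_ms, n_shuffles, seed,
                            statistic = function(rates)
                              mean(apply(rates, 2, pop_sd)))
  structure(c(out, list(type = "across_groups")),
            class = "variability_scores")
}

#' Spike-rate variability across time (S_T, S-hat_T)
#'
#' For each group the standard deviation of its rate trace over time is
#' computed; `S_T` is the group average and `S_hat_T` subtracts the
#' shuffled baseline. This score distinguishes switching dynamics from a
#' single persistently dominant assembly: it rises with slow-switching
#' activity but collapses when one assembly dominates throughout.
#'
#' @inheritParams spike_rate_variability
#' @return List of class `variability_scores` with `S`, `S_shuff_mean` and
#'   `S_hat` (here the temporal variants, in Hz).
#' @export
temporal_rate_variability <- function(raster, partition, window_ms = 100,
                                      n_shuffles = 10, seed = 1L) {
  out <- variability_engine(raster, partition, window_ms, n_shuffles, seed,
                            statistic = function(rates)
                              mean(apply(rates, 1, pop_sd)))
  structure(c(out, list(type = "across_time")),
            class = "variability_scores")
}

#' @export
print.variability_scores <- function(x, ...) {
  lab <- if (x$type == "across_groups") c("S", "S_hat")
         else c("S_T", "S_hat_T")
  cat(sprintf("<variability_scores> %s = %.4f Hz, shuffled = %.4f, %s = %.4f\n",
              lab[1], x$S, x$S_shuff_mean, lab[2], x$S_hat))
  invisible(x)
}

#' Dominant firing patterns by PCA
#'
#' Bins every neuron's firing rate (250 ms default) into an `N x T` matrix,
#' row-centers it, and returns the leading left singular vectors: the
#' `c - 1` dominant population activity patterns. If the matrix has lower
#' rank only the available components are returned, with a warning.
#'
#' @param raster A `spike_raster`.
#' @param bin_ms Bin width in ms.
#' @param n_components Number of patterns to keep (conventionally `c - 1`).
#' @return `N x n_components` matrix of patterns; attribute `var_explained`
#'   holds the fraction of variance each component captures.
#' @export
pca_firing_patterns <- function(raster, bin_ms = 250, n_components) {
  N <- attr(raster, "N")
  duration_ms <- attr(raster, "duration_ms")
  T_n <- floor(duration_ms / bin_ms)
  if (T_n < n_components)
    stop("fewer time bins than requested components")
  counts <- neuron_window_counts(raster, seq_len(N), bin_ms, duration_ms)
  rates <- counts / (bin_ms / 1000)
  centered <- rates - rowMeans(rates)
  sv <- svd(centered)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (pos < n_components) {
    warning("rate matrix rank ", pos, " below requested ", n_components,
            " components; returning the available ones")
    n_components <- pos
  }
  P <- sv$u[, seq_len(n_components), drop = FALSE]
  structure(P, var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}

#' First principal angle between pattern and Schur subspaces
#'
#' Orthonormalizes both bases and computes
#' \eqn{\cos\theta = \max_{u \in U, p \in P} u^T p / (\|u\|\|p\|)}, the
#' largest singular value of the cross-Gram matrix. \eqn{\theta \approx 0}
#' means the observed firing patterns are aligned with the dominant Schur
#' subspace of the weight matrix.
#'
#' @param P Pattern basis (columns span the observed subspace).
#' @param U Dominant Schur basis.
#' @return List of class `alignment_result` with `theta_deg` and
#'   `cos_theta`.
#' @export
principal_angle <- function(P, U) {
  stopifnot(nrow(P) == nrow(U), ncol(P) >= 1, ncol(U) >= 1)
  Qp <- qr.Q(qr(P))[, seq_len(qr(P)$rank), drop = FALSE]
  Qu <- qr.Q(qr(U))[, seq_len(qr(U)$rank), drop = FALSE]
  sv <- svd(crossprod(Qu, Qp))
  cos_theta <- min(max(sv$d[1], 0), 1)
  if (cos_theta > 0.99) {
    ## acos loses precision near 1; recover the small angle through its
    ## sine: project the best-aligned pattern vector out of span(U)
    p1 <- Qp %*% sv$v[, 1]
    s <- sqrt(sum((p1 - Qu %*% crossprod(Qu, p1))^2))
    theta <- asin(min(1, s))
  } else {
    theta <- acos(cos_theta)
  }
  structure(list(theta_deg = theta * 180 / pi, cos_theta = cos_theta),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> theta = %.2f deg (cos = %.4f)\n",
              x$theta_deg, x$cos_theta))
  invisible(x)
}
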