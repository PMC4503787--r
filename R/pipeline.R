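## Orchestration: generate -> simulate -> spectral-analyze -> score,
## for single configurations and parameter sweeps.

#' Derive independent per-stage seeds from a master seed
#'
#' Counter-based scheme so that the topology draw, the simulation and the
#' metric shuffles can be re-run in isolation; all derived seeds stay below
#' 2^31.
#'
#' @param master Master seed (integer).
#' @param stage One of `"topology"`, `"lif"`, `"shuffle"`.
#' @param index Extra counter (e.g. sweep-point index).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage = c("topology", "lif", "shuffle"),
                        index = 0L) {
  stage <- match.arg(stage)
  code <- match(stage, c("topology", "lif", "shuffle"))
  as.integer((as.numeric(master) * 48271 + code * 1000003 +
                as.numeric(index) * 7919) %% 2147483629) + 1L
}

#' Evaluate one network configuration end to end
#'
#' Generates the network, simulates the LIF dynamics, computes the spectral
#' diagnostics (eigengap at `m = c - 1`, \eqn{\lambda_{max}}, dominant
#' Schur basis and its block-localization) and the assembly metrics
#' (`S_hat`, `S_hat_T`, principal angle between the `c - 1` leading PCA
#' patterns and the dominant Schur subspace). Unstructured topologies
#' without an embedded partition are scored against a putative contiguous
#' partition so the metrics remain defined.
#'
#' @param spec A [network_spec()] (its own `seed` field is ignored here).
#' @param seed Master seed; expanded into stage seeds via [derive_seed()].
#' @param duration Simulation length in seconds.
#' @param window_ms Variability-score window.
#' @param pca_bin_ms PCA bin width.
#' @param n_shuffles Shuffles for the variability baselines.
#' @param m Leading-eigenvalue count; default `spec$c - 1`.
#' @return One-row data frame: swept metadata plus `gap`, `lambda_max`,
#'   `S_hat`, `S_hat_T`, `theta_deg`, `localization`, `rate_hz`,
#'   `runtime_s`.
#' @export
run_point <- function(spec, seed = 1L, duration = 10, window_ms = 100,
                      pca_bin_ms = 250, n_shuffles = 10, m = NULL) {
  t0 <- proc.time()[["elapsed"]]
  spec$seed <- derive_seed(seed, "topology")
  net <- generate_network(spec)
  partition <- net$partition
  if (is.null(partition$group) || !any(!is.na(partition$group)))
    partition <- contiguous_partition(spec)
  if (is.null(m)) m <- spec$c - 1
  eig <- eigen(net$W)
  gap <- detect_gap(eig$values, m = m)
  basis <- dominant_schur_basis(net$W, m, eig = eig)
  loc <- block_localization_score(basis, partition)
  raster <- simulate_lif(net, lif_params(duration = duration,
                                         seed = derive_seed(seed, "lif")))
  sh_seed <- derive_seed(seed, "shuffle")
  sv <- spike_rate_variability(raster, partition, window_ms,
                               n_shuffles, seed = sh_seed)
  tv <- temporal_rate_variability(raster, partition, window_ms,
                                  n_shuffles, seed = sh_seed)
  patterns <- pca_firing_patterns(raster, bin_ms = pca_bin_ms,
                                  n_components = m)
  ang <- principal_angle(patterns, basis)
  data.frame(kind = spec$kind, N = spec$N, c = spec$c, seed = seed,
             m = attr(basis, "m"), gap = gap$gap,
             lambda_max = max(Re(eig$values)),
             S_hat = sv$S_hat, S_hat_T = tv$S_hat,
             theta_deg = ang$theta_deg, localization = loc,
             rate_hz = nrow(raster) / spec$N / duration,
             runtime_s = proc.time()[["elapsed"]] - t0)
}

#' Run a parameter sweep
#'
#' Evaluates [run_point()] on a grid of values of one `network_spec` field
#' crossed with a set of master seeds, collecting a long-format table plus
#' per-value mean/sd summaries. Failures at single points are recorded
#' (`status` column) and the sweep continues.
#'
#' @param template A [network_spec()] serving as the template.
#' @param field Name of the swept field (e.g. `"R_EE"`, `"W_EE"`).
#' @param values Numeric sweep values (at least one).
#' @param seeds Master seeds per point (at least one).
#' @param ... Passed to [run_point()].
#' @param out_dir Optional directory; when given, `results.csv` and
#'   `summary.csv` are written there.
#' @return List of class `sweep_result` with `results` (long table) and
#'   `summary`.
#' @export
run_sweep <- function(template, field, values, seeds = 1:3, ...,
                      out_dir = NULL) {
  stopifnot(inherits(template, "network_spec"),
            field %in% names(template),
            length(values) >= 1, length(seeds) >= 1)
  rows <- list()
  for (v in values) {
    for (sd_ in seeds) {
      spec <- template
      spec[[field]] <- v
      ## revalidate the modified spec
      spec <- do.call(network_spec,
                      spec[setdiff(names(spec), c("N_E", "N_I"))])
      row <- tryCatch({
        cbind(value = v, run_point(spec, seed = sd_, ...), status = "ok")
      }, error = function(e) {
        data.frame(value = v, kind = template$kind, N = template$N,
                   c = template$c, seed = sd_, m = NA, gap = NA,
                   lambda_max = NA, S_hat = NA, S_hat_T = NA,
                   theta_deg = NA, localization = NA, rate_hz = NA,
                   runtime_s = NA, status = conditionMessage(e))
      })
      rows <- c(rows, list(row))
    }
  }
  results <- do.call(rbind, rows)
  names(results)[1] <- field
  num <- c("gap", "lambda_max", "S_hat", "S_hat_T", "theta_deg",
           "localization", "rate_hz")
  agg <- stats::aggregate(results[num], by = results[field], FUN = mean,
                          na.rm = TRUE)
  sdv <- stats::aggregate(results[num], by = results[field],
                          FUN = stats::sd, na.rm = TRUE)
  names(sdv)[-1] <- paste0(num, "_sd")
  summary <- merge(agg, sdv, by = field)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, summary = summary, field = field),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over {%s}, %d rows\n", x$field,
              paste(unique(x$results[[x$field]]), collapse = ", "),
              nrow(x$results)))
  print(x$summary[, c(x$field, "gap", "lambda_max", "S_hat", "S_hat_T",
                      "theta_deg")], digits = 3)
  invisible(x)
}
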