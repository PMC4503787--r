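#' Specify a structured balanced network
#'
#' Builds the configuration object from which all synaptic weight matrices are
#' generated. The defaults reproduce the reference balanced network of
#' \eqn{N = 2000} neurons (1600 excitatory, 400 inhibitory, ratio fixed 4:1)
#' with connection probabilities \eqn{p^{EE} = 0.2},
#' \eqn{p^{EI} = p^{IE} = p^{II} = 0.5} and synaptic weights
#' \eqn{w^{EE} = 0.0156}, \eqn{w^{IE} = 0.0074},
#' \eqn{w^{EI} = w^{II} = -0.0297}. In the probability superscripts the first
#' letter is the destination type and the second the origin, so \eqn{p^{EI}}
#' is the probability that an excitatory neuron receives a connection from an
#' inhibitory one. For network sizes other than 2000 all weights are scaled by
#' \eqn{2000/N} so that the balanced operating point is preserved.
#'
#' @param kind Topology family. One of `"unclustered"`, `"clustered_prob"`,
#'   `"clustered_weight"`, `"ei_coclustered"`, `"small_world"`,
#'   `"scale_free"`, `"hierarchical"`.
#' @param N Total number of neurons (excitatory + inhibitory).
#' @param c Number of assemblies (groups of excitatory neurons, or
#'   excitatory-inhibitory pairs for `"ei_coclustered"`). For
#'   `"hierarchical"` this is the number of subgroups and must be twice
#'   `c_top`.
#' @param R_EE In/out ratio of excitatory-excitatory connection
#'   *probabilities* (topological clustering strength); 1 is unclustered.
#' @param W_EE In/out ratio of excitatory-excitatory synaptic *weights*
#'   (weight clustering strength at uniform connectivity).
#' @param R_EI,W_EI Clustering ratios of the inhibitory-to-excitatory
#'   feedback. These are *inverse* in/out ratios: values above 1 mean an
#'   inhibitory group inhibits its partner excitatory group more weakly
#'   than the rest of the network.
#' @param R_IE,W_IE Clustering ratios of the excitatory-to-inhibitory
#'   projection (ordinary in/out ratios).
#' @param R_sw Ring-neighborhood in/out probability ratio of the small-world
#'   construction.
#' @param R_top,R_sub Top-level and sub-level probability ratios of the
#'   hierarchical construction (`p_group = R_top * p_out`,
#'   `p_sub = R_sub * p_group`).
#' @param d Attachment parameter (edges per new node) of the scale-free
#'   preferential-attachment construction.
#' @param c_top Number of top-level groups in the hierarchical construction.
#' @param w_sub Within-subgroup excitatory weight of the hierarchical
#'   construction, at the `N = 2000` reference scale.
#' @param base_probs Named vector of baseline connection probabilities
#'   (`EE`, `EI`, `IE`, `II`).
#' @param base_weights Named vector of baseline synaptic weights at the
#'   `N = 2000` reference scale (`EE`, `EI`, `IE`, `II`).
#' @param ratio_EI Excitatory:inhibitory count ratio (fixed at 4 in all the
#'   standard constructions).
#' @param seed Integer seed; the same spec and seed yield a bit-identical
#'   matrix.
#'
#' @return An object of class `network_spec`.
#' @seealso [generate_network()]
#' @export
network_spec <- function(kind = c("unclustered", "clustered_prob",
                                  "clustered_weight", "ei_coclustered",
                                  "small_world", "scale_free", "hierarchical"),
                         N = 2000, c = 20,
                         R_EE = 1, W_EE = 1,
                         R_EI = 1, R_IE = 1, W_EI = 1, W_IE = 1,
                         R_sw = 1, R_top = 1, R_sub = 1,
                         d = 64, c_top = 16, w_sub = 0.0163,
                         base_probs = c(EE = 0.2, EI = 0.5, IE = 0.5, II = 0.5),
                         base_weights = c(EE = 0.0156, EI = -0.0297,
                                          IE = 0.0074, II = -0.0297),
                         ratio_EI = 4, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(N > 0, N %% (ratio_EI + 1) == 0)
  N_E <- N * ratio_EI / (ratio_EI + 1)
  N_I <- N - N_E
  if (any(base_probs < 0 | base_probs > 1))
    stop("base connection probabilities must lie in [0, 1]")
  if (base_weights[["EE"]] <= 0 || base_weights[["IE"]] <= 0)
    stop("excitatory base weights must be positive")
  if (base_weights[["EI"]] >= 0 || base_weights[["II"]] >= 0)
    stop("inhibitory base weights must be negative")
  ratios <- c(R_EE = R_EE, W_EE = W_EE, R_EI = R_EI, R_IE = R_IE,
              W_EI = W_EI, W_IE = W_IE, R_sw = R_sw,
              R_top = R_top, R_sub = R_sub)
  if (any(ratios < 0)) stop("clustering ratios must be >= 0")
  if (kind %in% c("clustered_prob", "clustered_weight", "ei_coclustered",
                  "small_world", "hierarchical")) {
    if (kind == "hierarchical") {
      if (c != 2L * c_top)
        stop("hierarchical networks need c = 2 * c_top subgroups")
      if (N_E %% c != 0)
        stop("excitatory neurons must divide evenly into subgroups")
    } else if (N_E %% c != 0) {
      stop("excitatory neurons must divide evenly into ", c, " groups")
    }
    if (kind == "ei_coclustered" && N_I %% c != 0)
      stop("inhibitory neurons must divide evenly into ", c, " pairs")
  }
  if (kind == "scale_free" && (d < 1 || N_E <= d))
    stop("scale-free attachment needs 1 <= d < N_E")
  structure(list(kind = kind, N = N, N_E = N_E, N_I = N_I, c = c,
                 R_EE = R_EE, W_EE = W_EE, R_EI = R_EI, R_IE = R_IE,
                 W_EI = W_EI, W_IE = W_IE, R_sw = R_sw,
                 R_top = R_top, R_sub = R_sub, d = d, c_top = c_top,
                 w_sub = w_sub, base_probs = base_probs,
                 base_weights = base_weights, ratio_EI = ratio_EI,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Scale synaptic weights with network size
#'
#' Balanced-network weights scale as \eqn{1/N}: relative to the
#' \eqn{N = 2000} reference, all weights are multiplied by \eqn{2000/N}
#' (e.g. doubled for \eqn{N = 1000}).
#'
#' @param weights Numeric vector of weights at the `N = 2000` reference.
#' @param N Target network size.
#' @return Scaled weights.
#' @export
scale_weights_for_size <- function(weights, N) {
  stopifnot(N > 0)
  weights * (2000 / N)
}

#' Solve in/out values conserving a fixed average
#'
#' Given a target average `avg`, an in/out ratio and the fraction `f_in` of
#' potential partners that are in-group, returns the pair
#' `(in_value, out_value)` with `in_value = ratio * out_value` and
#' `f_in * in_value + (1 - f_in) * out_value = avg`. This is the primitive
#' through which every clustered construction conserves the unclustered
#' average connectivity or weight exactly while the clustering ratio varies.
#'
#' @param avg Target average (negative for inhibitory weights).
#' @param ratio In/out ratio (> 0). Use the reciprocal for quantities
#'   defined by an inverse ratio.
#' @param f_in Fraction of potential partners that are in-group, in (0, 1).
#' @param prob If `TRUE` the values are probabilities and solutions outside
#'   \[0, 1\] are rejected.
#' @return Named numeric vector `c(in = ..., out = ...)`.
#' @export
solve_in_out <- function(avg, ratio, f_in, prob = FALSE) {
  stopifnot(ratio > 0, f_in > 0, f_in < 1)
  out <- avg / (1 + f_in * (ratio - 1))
  inn <- ratio * out
  if (prob && (inn > 1 || out > 1))
    stop(sprintf(paste0("in-group probability %.4f exceeds 1; the ratio ",
                        "%.3g is too large for this partition"),
                 max(inn, out), ratio))
  c("in" = inn, "out" = out)
}

## ---- internal helpers -----------------------------------------------------

## Neuron indexing convention: 1..N_E excitatory, (N_E+1)..N inhibitory.
neuron_types <- function(spec) {
  rep(c("E", "I"), times = c(spec$N_E, spec$N_I))
}

## Contiguous equal partition of the excitatory neurons. Used both for
## embedded groups and as the putative partition of unstructured networks
## (the variability scores need a partition even when none is built in).
contiguous_partition <- function(spec, scope = "E") {
  n_g <- spec$N_E / spec$c
  grp <- rep(NA_integer_, spec$N)
  grp[seq_len(spec$N_E)] <- rep(seq_len(spec$c), each = n_g)
  if (scope == "E+I") {
    n_gi <- spec$N_I / spec$c
    grp[spec$N_E + seq_len(spec$N_I)] <- rep(seq_len(spec$c), each = n_gi)
  }
  list(group = grp, scope = scope, levels = NULL)
}

## Baseline probability/weight matrices for all four type blocks, with the
## 2000/N weight scaling applied. Entry [i, j] refers to connection j -> i.
base_pm <- function(spec) {
  ty <- neuron_types(spec)
  bw <- scale_weights_for_size(spec$base_weights, spec$N)
  key <- outer(ty, ty, function(post, pre) paste0(post, pre))
  P <- matrix(spec$base_probs[key], spec$N, spec$N)
  M <- matrix(bw[key], spec$N, spec$N)
  list(P = P, M = M)
}

## Bernoulli realization of (P, M); no self-connections.
draw_W <- function(P, M) {
  N <- nrow(P)
  W <- M * (matrix(stats::runif(N * N), N, N) < P)
  diag(W) <- 0
  W
}

ssa_network <- function(W, spec, partition, extra = NULL) {
  structure(c(list(W = W, types = neuron_types(spec), spec = spec,
                   partition = partition), extra),
            class = "ssa_network")
}

## ---- generators -----------------------------------------------------------

make_unclustered <- function(spec) {
  pm <- base_pm(spec)
  ssa_network(draw_W(pm$P, pm$M), spec, contiguous_partition(spec))
}

make_clustered <- function(spec, mode = c("prob", "weight")) {
  mode <- match.arg(mode)
  pm <- base_pm(spec)
  part <- contiguous_partition(spec)
  eidx <- seq_len(spec$N_E)
  same <- outer(part$group[eidx], part$group[eidx], "==")
  n_g <- spec$N_E / spec$c
  f_in <- (n_g - 1) / (spec$N_E - 1)  # self excluded
  if (mode == "prob") {
    io <- solve_in_out(spec$base_probs[["EE"]], spec$R_EE, f_in, prob = TRUE)
    pm$P[eidx, eidx] <- ifelse(same, io[["in"]], io[["out"]])
  } else {
    w_ee <- scale_weights_for_size(spec$base_weights[["EE"]], spec$N)
    io <- solve_in_out(w_ee, spec$W_EE, f_in)
    pm$M[eidx, eidx] <- ifelse(same, io[["in"]], io[["out"]])
  }
  ssa_network(draw_W(pm$P, pm$M), spec, part)
}

make_ei_coclustered <- function(spec) {
  pm <- base_pm(spec)
  part <- contiguous_partition(spec, scope = "E+I")
  eidx <- seq_len(spec$N_E)
  iidx <- spec$N_E + seq_len(spec$N_I)
  pair_E <- part$group[eidx]
  pair_I <- part$group[iidx]
  bw <- scale_weights_for_size(spec$base_weights, spec$N)
  ## E -> I block (rows I, cols E): ordinary in/out ratios R_IE, W_IE.
  same_ie <- outer(pair_I, pair_E, "==")
  f_ie <- (spec$N_E / spec$c) / spec$N_E
  p_ie <- solve_in_out(spec$base_probs[["IE"]], spec$R_IE, f_ie, prob = TRUE)
  w_ie <- solve_in_out(bw[["IE"]], spec$W_IE, f_ie)
  pm$P[iidx, eidx] <- ifelse(same_ie, p_ie[["in"]], p_ie[["out"]])
  pm$M[iidx, eidx] <- ifelse(same_ie, w_ie[["in"]], w_ie[["out"]])
  ## I -> E block (rows E, cols I): R_EI, W_EI are inverse in/out ratios,
  ## so the in-pair inhibition is *weaker* when the ratio exceeds 1.
  same_ei <- outer(pair_E, pair_I, "==")
  f_ei <- (spec$N_I / spec$c) / spec$N_I
  p_ei <- solve_in_out(spec$base_probs[["EI"]], 1 / spec$R_EI, f_ei,
                       prob = TRUE)
  w_ei <- solve_in_out(bw[["EI"]], 1 / spec$W_EI, f_ei)
  pm$P[eidx, iidx] <- ifelse(same_ei, p_ei[["in"]], p_ei[["out"]])
  pm$M[eidx, iidx] <- ifelse(same_ei, w_ei[["in"]], w_ei[["out"]])
  ssa_network(draw_W(pm$P, pm$M), spec, part)
}

make_small_world <- function(spec) {
  pm <- base_pm(spec)
  part <- contiguous_partition(spec)
  eidx <- seq_len(spec$N_E)
  half_width <- 40L
  ring <- abs(outer(eidx, eidx, "-"))
  ring <- pmin(ring, spec$N_E - ring) <= half_width
  diag(ring) <- FALSE
  f_in <- (2 * half_width) / (spec$N_E - 1)
  io <- solve_in_out(spec$base_probs[["EE"]], spec$R_sw, f_in, prob = TRUE)
  pm$P[eidx, eidx] <- ifelse(ring, io[["in"]], io[["out"]])
  ssa_network(draw_W(pm$P, pm$M), spec, part)
}

make_scale_free <- function(spec) {
  pm <- base_pm(spec)
  eidx <- seq_len(spec$N_E)
  ## Undirected preferential attachment (no multi-edges), seeded with a
  ## d-clique nucleus; both directions of each edge carry w^EE.
  g <- igraph::sample_pa(spec$N_E, m = spec$d, directed = FALSE,
                         algorithm = "psumtree",
                         start.graph = igraph::make_full_graph(spec$d))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  w_ee <- scale_weights_for_size(spec$base_weights[["EE"]], spec$N)
  EE <- w_ee * as.matrix(A != 0)
  diag(EE) <- 0
  ## keep the baseline draws for the other three blocks
  pm$P[eidx, eidx] <- 0
  W <- draw_W(pm$P, pm$M)
  W[eidx, eidx] <- EE
  part <- list(group = rep(NA_integer_, spec$N), scope = "none",
               levels = NULL)
  deg <- igraph::degree(g)
  ssa_network(W, spec, part, extra = list(hub_order = order(deg,
                                                            decreasing = TRUE)))
}

make_hierarchical <- function(spec) {
  pm <- base_pm(spec)
  eidx <- seq_len(spec$N_E)
  n_sub <- spec$N_E / spec$c
  sub_of <- rep(seq_len(spec$c), each = n_sub)
  top_of <- as.integer(ceiling(sub_of / 2))  # subgroups 2g-1, 2g share top g
  grp <- rep(NA_integer_, spec$N); grp[eidx] <- sub_of
  top <- rep(NA_integer_, spec$N); top[eidx] <- top_of
  part <- list(group = grp, scope = "E",
               levels = list(top = top, sub = grp))
  ## Three probability tiers conserving the average p^EE:
  ##   p_sub = R_sub * p_group, p_group = R_top * p_out,
  ##   f_sub p_sub + f_grp p_group + f_out p_out = p^EE.
  f_sub <- (n_sub - 1) / (spec$N_E - 1)
  f_grp <- n_sub / (spec$N_E - 1)
  f_out <- (spec$N_E - 2 * n_sub) / (spec$N_E - 1)
  p_out <- spec$base_probs[["EE"]] /
    (f_sub * spec$R_sub * spec$R_top + f_grp * spec$R_top + f_out)
  p_grp <- spec$R_top * p_out
  p_sub <- spec$R_sub * p_grp
  if (p_sub > 1)
    stop("within-subgroup probability exceeds 1; reduce R_top or R_sub")
  same_sub <- outer(sub_of, sub_of, "==")
  same_top <- outer(top_of, top_of, "==")
  pm$P[eidx, eidx] <- ifelse(same_sub, p_sub,
                             ifelse(same_top, p_grp, p_out))
  w_sub <- scale_weights_for_size(spec$w_sub, spec$N)
  w_ee <- scale_weights_for_size(spec$base_weights[["EE"]], spec$N)
  pm$M[eidx, eidx] <- ifelse(same_sub, w_sub, w_ee)
  ssa_network(draw_W(pm$P, pm$M), spec, part)
}

#' Generate a structured balanced network
#'
#' Realizes the synaptic weight matrix described by a [network_spec()]:
#' independent Bernoulli draws per ordered neuron pair (directed graph, no
#' self-connections), with connection probabilities and weights set so that
#' the average connectivity and average weight of every type block equal the
#' unclustered baseline for any clustering ratio. The entry `W[i, j]` is the
#' weight of the connection from neuron `j` to neuron `i`; columns therefore
#' have a uniform sign given by the presynaptic neuron's type.
#'
#' @param spec A [network_spec()].
#' @return An object of class `ssa_network`: a list with the `N x N` weight
#'   matrix `W`, the neuron `types` (`"E"`/`"I"`), the generating `spec`, and
#'   a `partition` (`$group` is an integer group id per neuron, `NA` when
#'   unassigned; hierarchical networks additionally carry nested
#'   `$levels$top` and `$levels$sub` labels; scale-free networks carry a
#'   `hub_order` instead of a partition).
#' @examples
#' net <- generate_network(network_spec("clustered_prob", N = 200, c = 4,
#'                                      R_EE = 3, seed = 7))
#' net
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  switch(spec$kind,
         unclustered      = make_unclustered(spec),
         clustered_prob   = make_clustered(spec, "prob"),
         clustered_weight = make_clustered(spec, "weight"),
         ei_coclustered   = make_ei_coclustered(spec),
         small_world      = make_small_world(spec),
         scale_free       = make_scale_free(spec),
         hierarchical     = make_hierarchical(spec))
}

#' @export
print.ssa_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ssa_network> %s, N = %d (%d E / %d I), seed = %d\n",
              s$kind, s$N, s$N_E, s$N_I, s$seed))
  ng <- sum(!is.na(x$partition$group))
  if (ng > 0)
    cat(sprintf("  partition: %d neurons in %d groups (scope %s)\n",
                ng, length(unique(stats::na.omit(x$partition$group))),
                x$partition$scope))
  dens <- mean(x$W[x$types == "E", x$types == "E"] != 0)
  cat(sprintf("  realized E-E density: %.4f\n", dens))
  invisible(x)
}

#' @export
summary.ssa_network <- function(object, ...) {
  ty <- object$types
  blocks <- expand.grid(post = c("E", "I"), pre = c("E", "I"))
  out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    B <- object$W[ty == blocks$post[b], ty == blocks$pre[b]]
    data.frame(block = paste0(blocks$post[b], "<-", blocks$pre[b]),
               density = mean(B != 0),
               mean_weight = mean(B[B != 0]))
  }))
  out
}

#' @export
plot.ssa_network <- function(x, max_show = 400, ...) {
  idx <- seq_len(min(nrow(x$W), max_show))
  graphics::image(t(x$W[rev(idx), idx] != 0), col = c("white", "black"),
                  axes = FALSE, main = sprintf("connectivity (%s)",
                                               x$spec$kind), ...)
  invisible(x)
}

## ---- Matrix Market + JSON sidecar I/O -------------------------------------

#' Write or read a network as Matrix Market plus JSON sidecar
#'
#' The weight matrix is stored as a real general sparse Matrix Market file;
#' neuron types and the partition go to a JSON sidecar
#' (`{"types": [...], "groups": [...], "levels": {...}}`, 0 encoding
#' "unassigned").
#'
#' @param net An `ssa_network` (or any list with `W`, `types`, `partition`).
#' @param mtx_path Path of the `.mtx` file.
#' @param json_path Path of the sidecar; defaults to `mtx_path` with a
#'   `.json` extension.
#' @return `write_network` returns the paths invisibly; `read_network`
#'   returns an `ssa_network`-like list.
#' @export
write_network <- function(net, mtx_path,
                          json_path = sub("\\.mtx$", ".json", mtx_path)) {
  Matrix::writeMM(methods::as(Matrix::Matrix(net$W, sparse = TRUE),
                              "generalMatrix"), mtx_path)
  grp <- net$partition$group
  grp[is.na(grp)] <- 0L
  lv <- net$partition$levels
  if (!is.null(lv))
    lv <- lapply(lv, function(v) { v[is.na(v)] <- 0L; v })
  jsonlite::write_json(list(types = net$types, groups = grp,
                            scope = net$partition$scope, levels = lv),
                       json_path, auto_unbox = TRUE)
  invisible(c(mtx = mtx_path, json = json_path))
}

#' @rdname write_network
#' @export
read_network <- function(mtx_path,
                         json_path = sub("\\.mtx$", ".json", mtx_path)) {
  W <- as.matrix(Matrix::readMM(mtx_path))
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  grp <- as.integer(side$groups)
  grp[grp == 0L] <- NA_integer_
  lv <- side$levels
  if (!is.null(lv) && length(lv))
    lv <- lapply(lv, function(v) { v <- as.integer(v); v[v == 0L] <- NA; v })
  else lv <- NULL
  structure(list(W = W, types = as.character(side$types),
                 spec = NULL,
                 partition = list(group = grp, scope = side$scope,
                                  levels = lv)),
            class = "ssa_network")
}
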