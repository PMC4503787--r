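#' Stylized linear rate models of assembly switching
#'
#' Configuration for the two coarse-grained linear rate models
#' \eqn{\tau\,dr/dt = -(I - W)r + \xi}: a 3-node model (two clustered
#' excitatory groups plus one inhibitory group) and a 4-node model (two
#' excitatory-to-inhibitory feedback pairs). `s` is the self/in-group
#' excitatory coupling, `eps` the cross-group coupling and `k >= 1` the
#' inhibition-dominance factor; the derived scale is `w = s + eps` for the
#' 3-node model and `w = (s + eps)/2` for the 4-node model. The admissible
#' region is `s > eps > 0`, which makes the clustering strength `s - eps`
#' positive.
#'
#' @param s Self/in-group excitatory coupling.
#' @param eps Cross-group excitatory coupling.
#' @param k Inhibition dominance factor, `>= 1`.
#' @param model `"3node"` or `"4node"`.
#' @param tau Membrane time constant (arbitrary units; time in the traces is
#'   measured in units of `tau`).
#' @param noise_sd Standard deviation of the white-noise drive per unit
#'   time.
#' @return An object of class `rate_model`.
#' @export
rate_model_spec <- function(s, eps, k = 1, model = c("3node", "4node"),
                            tau = 1, noise_sd = 0.1) {
  model <- match.arg(model)
  if (!(s > eps && eps > 0)) stop("admissible parameters require s > eps > 0")
  if (k < 1) stop("k must be >= 1")
  w <- if (model == "3node") s + eps else (s + eps) / 2
  structure(list(s = s, eps = eps, k = k, w = w, model = model,
                 tau = tau, noise_sd = noise_sd),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s: s = %g, eps = %g, k = %g (w = %g)\n",
              x$model, x$s, x$eps, x$k, x$w))
  st <- stability_margin(x)
  cat(sprintf("  clustering strength s - eps = %g; eta_max = %g (%s)\n",
              x$s - x$eps, st$eta_max,
              if (st$stable) "stable" else "unstable"))
  invisible(x)
}

#' Connectivity matrices of the stylized rate models
#'
#' `build_w3` returns the 3-node matrix
#' \deqn{W = \begin{pmatrix} s & \epsilon & -kw \\ \epsilon & s & -kw \\
#'   w/2 & w/2 & -kw \end{pmatrix}, \quad w = s + \epsilon,}
#' with rates ordered \eqn{(r_{e1}, r_{e2}, r_i)}. Every row sums to
#' \eqn{(1-k)w \le 0}, the balance condition. `build_w4` returns the 4-node
#' feedback matrix with rates ordered \eqn{(r_{e1}, r_{e2}, r_{i1},
#' r_{i2})} and \eqn{w = (s+\epsilon)/2}; each excitatory group drives its
#' partner inhibitory group with strength \eqn{s} and the other with
#' \eqn{\epsilon}, while inhibition returns more weakly to the partner
#' (\eqn{-k\epsilon}) than to the opposite pair (\eqn{-ks}).
#'
#' @param spec A [rate_model_spec()] of the matching model.
#' @return A 3x3 or 4x4 numeric matrix.
#' @export
build_w3 <- function(spec) {
  stopifnot(inherits(spec, "rate_model"), spec$model == "3node")
  s <- spec$s; e <- spec$eps; k <- spec$k; w <- spec$w
  matrix(c(s,     e,     -k * w,
           e,     s,     -k * w,
           w / 2, w / 2, -k * w), 3, 3, byrow = TRUE)
}

#' @rdname build_w3
#' @export
build_w4 <- function(spec) {
  stopifnot(inherits(spec, "rate_model"), spec$model == "4node")
  s <- spec$s; e <- spec$eps; k <- spec$k; w <- spec$w
  matrix(c(w, w, -k * e, -k * s,
           w, w, -k * s, -k * e,
           s, e, -k * w, -k * w,
           e, s, -k * w, -k * w), 4, 4, byrow = TRUE)
}

#' @rdname build_w3
#' @export
rate_matrix <- function(spec) {
  if (spec$model == "3node") build_w3(spec) else build_w4(spec)
}

#' Closed-form eigenvalues of the stylized models
#'
#' For the 3-node model the eigenvalues of `W` are
#' \eqn{\lambda_1 = -w^+ = -w(k-1) \le \lambda_2 = 0 < \lambda_3 = s -
#' \epsilon}; the eigengap \eqn{\lambda_3 - \lambda_2 = s - \epsilon} is the
#' clustering strength. For the 4-node model they are
#' \eqn{-w^+ = -(k-1)(s+\epsilon)}, 0, and \eqn{\pm\sqrt{k}(s-\epsilon)}
#' for the two localized modes.
#'
#' @param spec A [rate_model_spec()].
#' @return Numeric vector of eigenvalues, in mode order (global, difference,
#'   localized slow, \[localized fast\]).
#' @export
rate_eigenvalues <- function(spec) {
  s <- spec$s; e <- spec$eps; k <- spec$k
  if (spec$model == "3node") {
    c(-spec$w * (k - 1), 0, s - e)
  } else {
    c(-(k - 1) * (s + e), 0, sqrt(k) * (s - e), -sqrt(k) * (s - e))
  }
}

#' Analytic Schur decomposition of the stylized models
#'
#' Returns the orthonormal Schur basis `U` and upper-triangular `Q` with
#' `W = U Q U'` exactly. For the 3-node model the modes are the global mean
#' \eqn{u_1 = (1,1,1)/\sqrt3}, the excitatory-inhibitory difference
#' \eqn{u_2 = \sqrt{2/3}\,(1/2, 1/2, -1)} and the localized switching mode
#' \eqn{u_3 = (1,-1,0)/\sqrt2} (zero weight on the inhibitory node); the only
#' feedforward term couples modes 1-2 with weight
#' \eqn{w_{ff} = \sqrt2\,(k + 1/2)\,w}. For the 4-node model the modes are
#' the global sum and difference vectors \eqn{(1,1,1,1)/2, (1,1,-1,-1)/2}
#' coupled by \eqn{w_{ff} = (k+1)(s+\epsilon)}, plus two localized modes
#' \eqn{u_3 = (\sqrt k, -\sqrt k, 1, -1)/\sqrt{2k+2}} (correlated within
#' each excitatory-inhibitory pair, anti-correlated across pairs) and
#' \eqn{u_4 = (1, -1, -\sqrt k, \sqrt k)/\sqrt{2k+2}}, coupled by
#' \eqn{w_{ff,2} = -(k-1)(s-\epsilon)}. Schur vectors are sign-normalized so
#' that the first nonzero component is positive.
#'
#' @param spec A [rate_model_spec()].
#' @return An object of class `schur_form`: list with `U`, `Q`,
#'   `eigenvalues` (diagonal of `Q`), `drift_eigenvalues`
#'   (\eqn{\eta_i = -1 + \lambda_i}) and the feedforward weights.
#' @export
analytic_schur <- function(spec) {
  s <- spec$s; e <- spec$eps; k <- spec$k; w <- spec$w
  if (spec$model == "3node") {
    U <- cbind(c(1, 1, 1) / sqrt(3),
               sqrt(2 / 3) * c(0.5, 0.5, -1),
               c(1, -1, 0) / sqrt(2))
    w_plus <- w * (k - 1)
    w_ff <- sqrt(2) * (k + 0.5) * w
    Q <- diag(c(-w_plus, 0, s - e))
    Q[1, 2] <- w_ff
    ff <- c(w_plus = w_plus, w_ff = w_ff)
  } else {
    nrm <- sqrt(2 * k + 2)
    U <- cbind(c(1, 1, 1, 1) / 2,
               c(1, 1, -1, -1) / 2,
               c(sqrt(k), -sqrt(k), 1, -1) / nrm,
               c(1, -1, -sqrt(k), sqrt(k)) / nrm)
    w_plus <- (k - 1) * (s + e)
    w_ff <- (k + 1) * (s + e)
    w_ff2 <- -(k - 1) * (s - e)
    Q <- diag(c(-w_plus, 0, sqrt(k) * (s - e), -sqrt(k) * (s - e)))
    Q[1, 2] <- w_ff
    Q[3, 4] <- w_ff2
    ff <- c(w_plus = w_plus, w_ff = w_ff, w_ff2 = w_ff2)
  }
  W <- rate_matrix(spec)
  res <- max(abs(W - U %*% Q %*% t(U)))
  if (res > 1e-10)
    stop("analytic Schur reconstruction residual ", res, " above tolerance")
  structure(list(U = U, Q = Q, eigenvalues = diag(Q),
                 drift_eigenvalues = -1 + diag(Q), feedforward = ff,
                 spec = spec, residual = res),
            class = "schur_form")
}

#' @export
print.schur_form <- function(x, ...) {
  cat(sprintf("<schur_form> %s model; eigenvalues: %s\n", x$spec$model,
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  cat("  feedforward:",
      paste(names(x$feedforward), signif(x$feedforward, 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Linear stability of the rate models
#'
#' The drift matrix is \eqn{-(I - W)} so stability requires every
#' \eqn{\eta_i = -1 + \lambda_i < 0}. The binding mode is the slow localized
#' one: \eqn{\eta_{max} = -1 + (s - \epsilon)} for the 3-node model and
#' \eqn{\eta_{max} = -1 + \sqrt{k}(s - \epsilon)} for the 4-node model, so
#' the stable regions are \eqn{0 < s - \epsilon < 1} and
#' \eqn{0 < \sqrt{k}(s - \epsilon) < 1}.
#'
#' @param spec A [rate_model_spec()].
#' @return List with `eta_max`, `stable`, and the stability `product`
#'   (\eqn{s-\epsilon} or \eqn{\sqrt k (s-\epsilon)}) whose critical value
#'   is 1.
#' @export
stability_margin <- function(spec) {
  prod <- if (spec$model == "3node") spec$s - spec$eps
          else sqrt(spec$k) * (spec$s - spec$eps)
  list(eta_max = -1 + prod, stable = prod < 1, product = prod)
}

#' Locate the stability threshold by bisection
#'
#' Parameterizes \eqn{(s, \epsilon)} at fixed \eqn{s + \epsilon} and
#' bisects the clustering strength \eqn{s - \epsilon} for the point where
#' the largest real part of the numerically computed eigenvalues of
#' \eqn{-(I - W)} crosses zero.
#'
#' @param model `"3node"` or `"4node"`.
#' @param k Inhibition dominance factor.
#' @param s_plus_eps Fixed value of `s + eps`.
#' @param tol Bisection tolerance on `s - eps`.
#' @return List with the critical `delta` (`s - eps`), the stability
#'   `product` at the threshold (\eqn{s-\epsilon}, resp.
#'   \eqn{\sqrt k(s-\epsilon)}), and `k_times_delta`.
#' @export
find_stability_threshold <- function(model = c("3node", "4node"), k = 1,
                                     s_plus_eps = 1.8, tol = 1e-6) {
  model <- match.arg(model)
  eta_max_at <- function(delta) {
    s <- (s_plus_eps + delta) / 2
    e <- (s_plus_eps - delta) / 2
    W <- rate_matrix(rate_model_spec(s, e, k, model))
    max(Re(eigen(-(diag(nrow(W)) - W), only.values = TRUE)$values))
  }
  lo <- tol; hi <- s_plus_eps - tol
  if (eta_max_at(lo) > 0 || eta_max_at(hi) < 0)
    stop("no sign change of eta_max inside the admissible range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eta_max_at(mid) < 0) lo <- mid else hi <- mid
  }
  delta <- (lo + hi) / 2
  list(delta = delta,
       product = if (model == "3node") delta else sqrt(k) * delta,
       k_times_delta = k * delta)
}

#' Integrate a linear rate model driven by white noise
#'
#' Euler-Maruyama integration of \eqn{\tau\,dr/dt = -(I - W) r + \xi} with
#' independent Gaussian increments of standard deviation
#' `noise_sd * sqrt(dt)` per component. Unstable systems are integrated as
#' requested; divergence is flagged via the `diverged` attribute.
#'
#' @param W Square drift-defining connectivity matrix.
#' @param tau Time constant.
#' @param noise_sd Noise standard deviation per unit time (0 gives the
#'   deterministic flow).
#' @param duration,dt Total time and step, in units of `tau`'s time base.
#' @param seed RNG seed.
#' @param r0 Initial rate vector (defaults to 0).
#' @return Matrix with `duration/dt + 1` rows (time in attribute `time`),
#'   one column per node.
#' @export
integrate_rate_model <- function(W, tau = 1, noise_sd = 0.1,
                                 duration = 100, dt = 0.01, seed = 1L,
                                 r0 = NULL) {
  n <- nrow(W)
  A <- -(diag(n) - W)
  n_steps <- round(duration / dt)
  r <- if (is.null(r0)) numeric(n) else as.numeric(r0)
  out <- matrix(NA_real_, n_steps + 1, n)
  out[1, ] <- r
  set.seed(seed)
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(n_steps * n, sd = noise_sd * sqrt(dt)), n_steps, n)
  for (i in seq_len(n_steps)) {
    r <- r + (dt / tau) * as.numeric(A %*% r)
    if (!is.null(noise)) r <- r + noise[i, ] / tau
    out[i + 1, ] <- r
  }
  diverged <- !all(is.finite(out))
  if (diverged) warning("rate trajectory diverged (unstable model)")
  structure(out, time = seq(0, by = dt, length.out = n_steps + 1),
            diverged = diverged)
}
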