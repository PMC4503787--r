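#' Eigenvalue spectrum of a weight matrix
#'
#' @param W Square real matrix, or an `ssa_network`.
#' @return Complex vector of all eigenvalues.
#' @export
eig_spectrum <- function(W) {
  if (inherits(W, "ssa_network")) W <- W$W
  eigen(W, only.values = TRUE)$values
}

## Sort eigenvalues by descending real part, ties by descending |Im|.
sort_by_re <- function(values) {
  values[order(-Re(values), -abs(Im(values)))]
}

#' Detect the spectral gap
#'
#' Sorts the eigenvalues by descending real part and measures the gap
#' \eqn{\Delta\lambda = Re\,\lambda_{(m)} - Re\,\lambda_{(m+1)}}. When `m`
#' is not supplied it is chosen as the largest consecutive real-part gap
#' among the top `K` eigenvalues (`K` caps the search so that spurious gaps
#' deep in the bulk are ignored); when the embedded group count `c` is known
#' the conventional choice is `m = c - 1`.
#'
#' @param values Complex eigenvalue vector (or a matrix/`ssa_network`, whose
#'   spectrum is computed first).
#' @param m Optional leading-eigenvalue count.
#' @param K Search cap for automatic detection; default
#'   `min(N - 1, 50, max(N/10, 10))`.
#' @return List with `m`, `gap`, and the sorted real parts `re`.
#' @export
detect_gap <- function(values, m = NULL, K = NULL) {
  if (is.matrix(values) || inherits(values, "ssa_network"))
    values <- eig_spectrum(values)
  n <- length(values)
  stopifnot(n >= 2)
  re <- Re(sort_by_re(values))
  if (is.null(m)) {
    if (is.null(K)) K <- min(n - 1, 50, max(ceiling(n / 10), 10))
    gaps <- re[seq_len(K)] - re[seq_len(K) + 1]
    m <- which.max(gaps)
  }
  list(m = m, gap = re[m] - re[m + 1], re = re)
}

#' Dominant Schur basis (leading invariant subspace)
#'
#' Returns an orthonormal basis of the invariant subspace spanned by the
#' `m` eigenvalues of largest real part. The basis is assembled from the
#' real and imaginary parts of the leading eigenvectors and orthonormalized
#' by QR, which spans the same subspace as the leading block of an ordered
#' real Schur decomposition. If a complex-conjugate pair straddles the cut,
#' `m` is extended by one to keep the subspace real and invariant. Columns
#' are sign-normalized (first non-negligible component positive).
#'
#' @param W Square matrix or `ssa_network`.
#' @param m Requested leading count.
#' @param eig Optional precomputed `eigen(W)` result.
#' @return An `N x m'` orthonormal matrix with attributes `m` (possibly
#'   `m + 1`) and `values` (the leading eigenvalues).
#' @export
dominant_schur_basis <- function(W, m, eig = NULL) {
  if (inherits(W, "ssa_network")) W <- W$W
  n <- nrow(W)
  stopifnot(m >= 1, m < n)
  if (is.null(eig)) eig <- eigen(W)
  ord <- order(-Re(eig$values), -abs(Im(eig$values)))
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  tol <- 1e-9 * max(1, abs(values[1]))
  if (abs(Im(values[m])) > tol && m < n &&
      abs(values[m + 1] - Conj(values[m])) < 1e-6 * max(1, abs(values[m])))
    m <- m + 1
  cols <- list()
  i <- 1
  while (i <= m) {
    v <- vectors[, i]
    if (abs(Im(values[i])) > tol) {
      cols <- c(cols, list(Re(v), Im(v)))
      i <- i + 2
    } else {
      cols <- c(cols, list(Re(v)))
      i <- i + 1
    }
  }
  B <- qr.Q(qr(do.call(cbind, cols)))[, seq_len(m), drop = FALSE]
  for (j in seq_len(ncol(B))) {
    lead <- which(abs(B[, j]) > 1e-8)[1]
    if (!is.na(lead) && B[lead, j] < 0) B[, j] <- -B[, j]
  }
  structure(B, m = m, values = values[seq_len(m)])
}

#' Invariant-subspace residual
#'
#' Relative Frobenius residual \eqn{\|WB - B(B'WB)\|_F / \|W\|_F}; near
#' zero when the columns of `B` span an invariant subspace of `W`.
#'
#' @param W Square matrix.
#' @param B Orthonormal basis matrix.
#' @return Scalar residual.
#' @export
subspace_residual <- function(W, B) {
  if (inherits(W, "ssa_network")) W <- W$W
  WB <- W %*% B
  norm(WB - B %*% (crossprod(B, WB)), "F") / norm(W, "F")
}

#' Block-localization score of a basis on a partition
#'
#' For each basis column `u` the score is \eqn{\|\Pi u\|^2 / \|u\|^2},
#' where \eqn{\Pi} projects onto vectors constant within each group of the
#' partition and zero on unassigned neurons; the result is averaged over
#' columns. Exact group indicators score 1; an isotropically random vector
#' scores about `c/N` in expectation.
#'
#' @param basis Numeric matrix (columns are patterns over neurons).
#' @param partition Partition list with a `group` element (integer per
#'   neuron, `NA` for unassigned), as produced by [generate_network()].
#' @return Mean score in \[0, 1\].
#' @export
block_localization_score <- function(basis, partition) {
  grp <- partition$group
  stopifnot(nrow(basis) == length(grp), any(!is.na(grp)))
  gids <- sort(unique(grp[!is.na(grp)]))
  scores <- apply(basis, 2, function(u) {
    num <- sum(vapply(gids, function(g) {
      idx <- which(grp == g)
      length(idx) * mean(u[idx])^2
    }, numeric(1)))
    num / sum(u^2)
  })
  mean(scores)
}

#' Winner-takes-all indicator
#'
#' Flags \eqn{\lambda_{max} \ge 1}, the linear condition under which one
#' assembly's self-excitation sustains its own activity, suppressing
#' switching.
#'
#' @param W Matrix, `ssa_network`, or precomputed eigenvalue vector.
#' @return List with `lambda_max` and logical `flag`.
#' @export
winner_takes_all_flag <- function(W) {
  values <- if (is.complex(W) || (is.numeric(W) && is.null(dim(W)))) W
            else eig_spectrum(W)
  lambda_max <- max(Re(values))
  list(lambda_max = lambda_max, flag = lambda_max >= 1)
}

## Isolated complex pair with most-negative real part, > 3 bulk radii from
## the spectral centroid (the damped global activation mode of a balanced
## network). Informational.
find_balance_pair <- function(values) {
  centroid <- mean(values)
  r_bulk <- stats::median(Mod(values - centroid))
  cand <- values[abs(Im(values)) > 1e-9]
  if (!length(cand)) return(NULL)
  cand <- cand[Re(cand) == min(Re(cand))]
  if (Mod(cand[1] - centroid) > 3 * r_bulk)
    c(cand[1], Conj(cand[1]))
  else NULL
}

#' Spectral summary of a weight matrix
#'
#' One-shot diagnosis: full spectrum, eigengap (automatic or at a supplied
#' leading count), dominant Schur basis, block-localization score against
#' the partition, \eqn{\lambda_{max}} with the winner-takes-all flag, and
#' the balance pair if detectable.
#'
#' @param net An `ssa_network`, or a square matrix (then supply `partition`
#'   if a localization score is wanted).
#' @param m Leading count; default automatic gap detection.
#' @param partition Optional partition overriding `net$partition`.
#' @return An object of class `spectral_summary`.
#' @export
spectral_summary <- function(net, m = NULL, partition = NULL) {
  W <- if (inherits(net, "ssa_network")) net$W else net
  if (is.null(partition) && inherits(net, "ssa_network"))
    partition <- net$partition
  eig <- eigen(W)
  gap <- detect_gap(eig$values, m = m)
  basis <- dominant_schur_basis(W, gap$m, eig = eig)
  loc <- if (!is.null(partition) && any(!is.na(partition$group)))
    block_localization_score(basis, partition) else NA_real_
  wta <- winner_takes_all_flag(eig$values)
  structure(list(eigenvalues = eig$values, m = attr(basis, "m"),
                 gap = gap$gap, lambda_max = wta$lambda_max,
                 winner_takes_all = wta$flag,
                 balance_pair = find_balance_pair(eig$values),
                 dominant_basis = basis, localization = loc,
                 residual = subspace_residual(W, basis)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> N = %d\n", length(x$eigenvalues)))
  cat(sprintf("  gap: m = %d, delta_lambda = %.4f; lambda_max = %.4f%s\n",
              x$m, x$gap, x$lambda_max,
              if (x$winner_takes_all) " (winner-takes-all regime)" else ""))
  if (!is.na(x$localization))
    cat(sprintf("  block-localization of leading basis: %.3f\n",
                x$localization))
  if (!is.null(x$balance_pair))
    cat(sprintf("  balance pair: %.4f +/- %.4fi\n",
                Re(x$balance_pair[1]), abs(Im(x$balance_pair[1]))))
  invisible(x)
}

#' @export
plot.spectral_summary <- function(x, ...) {
  graphics::plot(Re(x$eigenvalues), Im(x$eigenvalues), pch = 20, cex = 0.4,
                 xlab = "Re", ylab = "Im", ...)
  re <- Re(sort_by_re(x$eigenvalues))
  graphics::abline(v = mean(re[x$m + 0:1]), lty = 2, col = "red")
  invisible(x)
}
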