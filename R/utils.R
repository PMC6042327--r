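# Shared numerical helpers.

#' Cardinal sine
#'
#' `sinc(x) = sin(x)/x` with `sinc(0) = 1`, applied elementwise.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Derive a per-item RNG seed from a base seed
#'
#' Stream-splitting rule used for all per-conformer / per-replicate randomness:
#' item `i` under base seed `s` uses `(s * 48271 + i) mod (2^31 - 1)`, kept in
#' the positive 32-bit integer range so the same streams are reproduced on any
#' platform.
#'
#' @param seed base integer seed.
#' @param i item index (1-based).
#' @return an integer seed.
#' @export
seed_stream <- function(seed, i) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + i) %% m)
}

#' @keywords internal
random_unit_vector <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' @keywords internal
random_rotation <- function() {
  # uniform rotation from a normalized random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @keywords internal
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Locate the corner of an L-curve
#'
#' Given per-alpha residual norms and solution seminorms, returns the index of
#' maximum curvature of the log-log L-curve (discrete Menger curvature over
#' point triples). Degenerate curves (no interior curvature maximum towards the
#' convex side) are flagged.
#'
#' @param residual_norm,seminorm numeric vectors, one entry per candidate
#'   regularization weight (ordered by increasing alpha).
#' @return list with `index` and logical `degenerate`.
#' @export
lcurve_corner <- function(residual_norm, seminorm) {
  stopifnot(length(residual_norm) == length(seminorm))
  n <- length(residual_norm)
  if (n < 3) return(list(index = ceiling(n / 2), degenerate = TRUE))
  lx <- log10(pmax(residual_norm, .Machine$double.xmin))
  ly <- log10(pmax(seminorm, .Machine$double.xmin))
  # triangle method on axis-normalized coordinates: the corner is the interior
  # point farthest (on the convex side) from the chord joining the endpoints
  rx <- diff(range(lx)); ry <- diff(range(ly))
  if (rx == 0 || ry == 0) return(list(index = ceiling(n / 2),
                                      degenerate = TRUE))
  x <- (lx - min(lx)) / rx
  y <- (ly - min(ly)) / ry
  a <- c(x[1], y[1]); b <- c(x[n], y[n])
  ab <- b - a
  nab <- sqrt(sum(ab^2))
  # signed distance: positive towards the origin-facing (convex) side
  d <- ((x - a[1]) * ab[2] - (y - a[2]) * ab[1]) / nab
  d[c(1, n)] <- 0
  if (max(d) <= 0) return(list(index = ceiling(n / 2), degenerate = TRUE))
  list(index = which.max(d), degenerate = FALSE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fast non-negative least squares (FNNLS)
#'
#' Solves `min ||C x - d||` subject to `x >= 0` by the active-set algorithm of
#' Bro & De Jong operating on the normal equations, returning the exact
#' Karush-Kuhn-Tucker point at convergence. Used by the regularized indirect
#' transform and the Tikhonov distance inversion.
#'
#' @param C design matrix (m x n).
#' @param d response (length m).
#' @param tol dual-feasibility tolerance; defaults to a scaled machine epsilon.
#' @return list with `x` (length n) and `iterations`.
#' @export
fnnls <- function(C, d, tol = NULL) {
  AtA <- crossprod(C)
  Atb <- crossprod(C, d)[, 1]
  n <- ncol(C)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(AtA)) * n
  x <- numeric(n)
  P <- logical(n)
  w <- Atb - AtA %*% x
  iter <- 0L
  max_iter <- 50L * n
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      iter <- iter + 1L
      sP <- numeric(n)
      idx <- which(P)
      if (length(idx) == 0) { x <- numeric(n); break }
      sol <- tryCatch(
        solve(AtA[idx, idx, drop = FALSE], Atb[idx]),
        error = function(e)
          as.numeric(MASS::ginv(AtA[idx, idx, drop = FALSE]) %*% Atb[idx]))
      sP[idx] <- sol
      if (all(sP[idx] > tol)) { x <- sP; break }
      neg <- idx[sP[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - sP[neg]))
      x <- x + alpha * (sP - x)
      P[x <= tol] <- FALSE
      x[!P] <- 0
      if (iter >= max_iter) break
    }
    w <- Atb - AtA %*% x
    if (iter >= max_iter) break
  }
  list(x = pmax(x, 0), iterations = iter)
}
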