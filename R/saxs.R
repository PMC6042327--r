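# Small-angle scattering: forward Debye model for bead models, Guinier
# analysis, regularized indirect transform to P(r), Dmax estimation, Porod
# invariant/volume, Kratky transform and forward-scattering molecular weight.
# Momentum transfer s = 4*pi*sin(theta)/lambda in 1/nm throughout; distances nm.

#' Construct a scattering curve
#'
#' @param s momentum transfer grid (1/nm), strictly increasing, non-negative.
#' @param I intensities (arbitrary units).
#' @param sigma optional per-point uncertainties (> 0).
#' @param metadata optional list (sample name, concentration mg/ml, ...).
#' @return object of class `scattering_curve`.
#' @export
scattering_curve <- function(s, I, sigma = NULL, metadata = list()) {
  stopifnot(length(s) == length(I), all(s >= 0), !is.unsorted(s, strictly = TRUE))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(I), all(sigma > 0))
  }
  structure(list(s = as.numeric(s), I = as.numeric(I),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
                 metadata = metadata),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat("Scattering curve:", length(x$s), "points, s in [",
      signif(min(x$s), 3), ",", signif(max(x$s), 3), "] 1/nm",
      if (is.null(x$sigma)) "(no uncertainties)" else "", "\n")
  invisible(x)
}

#' Read a 3-column ASCII scattering file
#'
#' The de facto SAXS exchange format: whitespace-separated columns s, I and
#' (optionally) sigma; `#` comments and non-numeric header/footer lines are
#' skipped; a 4th column is ignored. Units of s are 1/nm by default; pass
#' `angstrom = TRUE` for 1/A data (converted on read).
#'
#' @param path file path.
#' @param angstrom logical; input s grid is 1/A.
#' @return a [scattering_curve()].
#' @export
read_saxs_dat <- function(path, angstrom = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\\s+")
  keep <- vapply(fields, function(f) {
    length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2])))
  }, logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) stop("no numeric data rows in ", path)
  s <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  I <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  sigma <- vapply(fields, function(f) {
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_
  }, numeric(1))
  ok <- is.finite(s) & is.finite(I) & s >= 0
  s <- s[ok]; I <- I[ok]; sigma <- sigma[ok]
  o <- order(s)
  s <- s[o]; I <- I[o]; sigma <- sigma[o]
  dup <- duplicated(s)
  s <- s[!dup]; I <- I[!dup]; sigma <- sigma[!dup]
  if (angstrom) s <- s * 10
  if (anyNA(sigma) || any(sigma <= 0, na.rm = TRUE)) sigma <- NULL
  scattering_curve(s, I, sigma, metadata = list(file = path))
}

#' Write a scattering curve as 3-column ASCII
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @export
write_saxs_dat <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# s(1/nm)  I  sigma", con)
  sig <- curve$sigma %||% rep(NA_real_, length(curve$s))
  writeLines(sprintf("%.8g %.10g %.10g", curve$s, curve$I, sig), con)
  invisible(path)
}

#' Fetch deposited SASBDB scattering curves
#'
#' Maps accession identifiers to local `.dat` files, downloading from SASBDB
#' into `cache_dir` when not already present. Requires network access for the
#' first call per accession.
#'
#' @param accessions character vector of SASBDB codes (e.g. `"SASDDB6"`).
#' @param cache_dir directory for downloaded files.
#' @return named character vector of file paths.
#' @export
fetch_sasbdb <- function(accessions, cache_dir = tools::R_user_dir("sgtadimer",
                                                                   "cache")) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(accessions))
  names(paths) <- accessions
  for (i in seq_along(accessions)) {
    acc <- accessions[i]
    dest <- file.path(cache_dir, paste0(acc, ".dat"))
    if (!file.exists(dest)) {
      url <- sprintf("https://www.sasbdb.org/media/intensities_files/%s.dat", acc)
      status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                              mode = "wb"),
                         error = function(e) -1L, warning = function(w) -1L)
      if (!identical(status, 0L) || !file.exists(dest) ||
          file.size(dest) == 0) {
        if (file.exists(dest)) unlink(dest)
        stop("could not obtain ", acc, " from SASBDB (no network?); ",
             "place the file at ", dest, " manually to proceed")
      }
    }
    paths[i] <- dest
  }
  paths
}

# ---- forward model --------------------------------------------------------

#' Debye scattering intensity of a bead model
#'
#' `I(s) = sum_ij w_i w_j sinc(s r_ij)`, so `I(0) = (sum w)^2`. The exact
#' pairwise sum is used by default; `method = "histogram"` bins the pair
#' distances (bin width `bin_nm`) before the transform, which is
#' indistinguishable at SAXS resolution and much faster for conformer pools.
#'
#' @param model a [bead_model()].
#' @param s_grid momentum transfer grid (1/nm).
#' @param method `"exact"` or `"histogram"`.
#' @param bin_nm histogram bin width.
#' @return a noiseless [scattering_curve()].
#' @export
debye_intensity <- function(model, s_grid, method = c("exact", "histogram"),
                            bin_nm = 0.01) {
  method <- match.arg(method)
  stopifnot(all(s_grid >= 0))
  xyz <- bm_coords(model)
  w <- model$beads$weight
  if (nrow(xyz) == 1) {
    return(scattering_curve(s_grid, rep(w^2, length(s_grid))))
  }
  d <- as.numeric(stats::dist(xyz))
  # pair weights in dist() order (columns of the lower triangle)
  wp <- outer(w, w)[lower.tri(outer(w, w))]
  self_term <- sum(w^2)
  if (method == "histogram") {
    idx <- pmax(1L, ceiling(d / bin_nm))
    h <- rowsum(wp, idx)
    centers <- (as.numeric(rownames(h)) - 0.5) * bin_nm
    I <- self_term + 2 * vapply(s_grid, function(ss)
      sum(h[, 1] * sinc(ss * centers)), numeric(1))
  } else {
    I <- self_term + 2 * vapply(s_grid, function(ss)
      sum(wp * sinc(ss * d)), numeric(1))
  }
  scattering_curve(s_grid, I, metadata = list(forward_model = "debye"))
}

# ---- Guinier --------------------------------------------------------------

#' Guinier fit of the low-angle region
#'
#' Weighted linear fit of `ln I` against `s^2`; `Rg = sqrt(-3 slope)`,
#' `I0 = exp(intercept)`. The fit range is found self-consistently: starting
#' from the full low-angle window the upper limit is shrunk until
#' `s_max * Rg <= sRg_limit`.
#'
#' @param curve a [scattering_curve()].
#' @param sRg_limit upper `s Rg` limit (conventional 1.3 for globular
#'   particles).
#' @param min_points minimum usable points.
#' @return object of class `guinier_fit` with `rg`, `I0`, `s_range`,
#'   `n_points`, `residual_sd`.
#' @export
guinier_fit <- function(curve, sRg_limit = 1.3, min_points = 5) {
  s <- curve$s; I <- curve$I
  pos <- I > 0 & s > 0
  s <- s[pos]; I <- I[pos]
  sig <- if (!is.null(curve$sigma)) curve$sigma[pos] else NULL
  n <- length(s)
  if (n < min_points) stop("insufficient low-angle range for Guinier fit")
  m <- n
  rg <- NA_real_
  for (iter in 1:50) {
    x <- s[1:m]^2; y <- log(I[1:m])
    wts <- if (!is.null(sig)) (I[1:m] / sig[1:m])^2 else rep(1, m)
    fit <- stats::lm.wfit(cbind(1, x), y, wts)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) {
      stop("non-Guinier behaviour: non-negative low-angle slope")
    }
    rg <- sqrt(-3 * slope)
    m_new <- max(min_points, sum(s * rg <= sRg_limit))
    m_new <- min(m_new, n)
    if (m_new == m) break
    m <- m_new
  }
  if (m < min_points) stop("insufficient points inside the s*Rg limit")
  x <- s[1:m]^2; y <- log(I[1:m])
  wts <- if (!is.null(sig)) (I[1:m] / sig[1:m])^2 else rep(1, m)
  fit <- stats::lm.wfit(cbind(1, x), y, wts)
  rg <- unname(sqrt(-3 * fit$coefficients[2]))
  structure(list(
    rg = rg,
    I0 = unname(exp(fit$coefficients[1])),
    s_range = c(s[1], s[m]), n_points = m,
    residual_sd = stats::sd(fit$residuals),
    sRg_max = s[m] * rg
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.3f nm, I0 = %.4g (%d pts, sRg <= %.2f)\n",
              x$rg, x$I0, x$n_points, x$sRg_max))
  invisible(x)
}

# ---- indirect transform ---------------------------------------------------

#' @keywords internal
ift_design <- function(s, r) {
  # I(s) = 4*pi * integral p(r) sinc(s r) dr, trapezoid on the r grid
  wr <- trapz_weights(r)
  A <- 4 * pi * outer(s, r, function(ss, rr) sinc(ss * rr))
  sweep(A, 2, wr, "*")
}

#' Regularized indirect transform to the pair-distance distribution
#'
#' Solves `min || (A p - I)/sigma ||^2 + alpha ||L p||^2` for `p >= 0` on a
#' fixed r grid in `[0, dmax]` with `p(0) = p(dmax) = 0` (L = second
#' difference), via non-negative least squares on the stacked system. When
#' `alpha` is `NULL` it is chosen at the corner of the L-curve.
#'
#' @param curve a [scattering_curve()]; if uncertainties are absent, 1% of I is
#'   used and flagged in the result.
#' @param dmax assumed maximum particle dimension (nm).
#' @param alpha regularization weight (> 0) or `NULL` for L-curve choice.
#' @param n_r number of r grid points.
#' @return object of class `pofr`: `r`, `p`, `dmax`, `alpha`, `chi2`,
#'   `rg`, `I0`, `fit` (back-transformed curve), `sigma_assumed` flag.
#' @export
ift_pofr <- function(curve, dmax, alpha = NULL, n_r = 101) {
  stopifnot(dmax > 0)
  if (!is.null(alpha) && alpha <= 0) stop("invalid regularization: alpha must be > 0")
  s <- curve$s; I <- curve$I
  sigma_assumed <- is.null(curve$sigma)
  sig <- curve$sigma %||% (0.01 * (abs(I) + 0.01 * max(abs(I))))
  r <- seq(0, dmax, length.out = n_r)
  A <- ift_design(s, r)
  # endpoint zeros: solve for interior points only
  Ai <- A[, 2:(n_r - 1), drop = FALSE]
  Aw <- Ai / sig
  yw <- I / sig
  nI <- n_r - 2
  L <- matrix(0, nI, nI)
  for (j in seq_len(nI)) {
    L[j, j] <- -2
    if (j > 1) L[j, j - 1] <- 1
    if (j < nI) L[j, j + 1] <- 1
  }
  solve_one <- function(a) {
    C <- rbind(Aw, sqrt(a) * L)
    dvec <- c(yw, rep(0, nI))
    fnnls(C, dvec)$x
  }
  if (is.null(alpha)) {
    agrid <- 10^seq(-6, 4, length.out = 18)
    resn <- semn <- numeric(length(agrid))
    sols <- vector("list", length(agrid))
    for (k in seq_along(agrid)) {
      pk <- solve_one(agrid[k])
      sols[[k]] <- pk
      resn[k] <- sqrt(sum((Aw %*% pk - yw)^2))
      semn[k] <- sqrt(sum((L %*% pk)^2))
    }
    corner <- lcurve_corner(resn, semn)
    alpha <- agrid[corner$index]
    p_in <- sols[[corner$index]]
  } else {
    p_in <- solve_one(alpha)
  }
  p <- c(0, p_in, 0)
  Ifit <- as.numeric(A %*% p)
  chi2 <- sum(((Ifit - I) / sig)^2) / max(1, length(I) - nI)
  wr <- trapz_weights(r)
  m0 <- sum(wr * p)
  I0 <- 4 * pi * m0
  rg <- if (m0 > 0) sqrt(sum(wr * p * r^2) / (2 * m0)) else NA_real_
  structure(list(r = r, p = p, dmax = dmax, alpha = alpha, chi2 = chi2,
                 rg = rg, I0 = I0,
                 fit = scattering_curve(s, Ifit),
                 sigma_assumed = sigma_assumed),
            class = "pofr")
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf("P(r): dmax = %.2f nm, alpha = %.3g, chi2 = %.3g, Rg = %.3f nm\n",
              x$dmax, x$alpha, x$chi2, x$rg))
  invisible(x)
}

#' Estimate the maximum particle dimension
#'
#' Scans candidate `dmax` values, solves the regularized indirect transform at
#' each, and returns the smallest candidate beyond which the back-transform
#' fit quality plateaus (score within `rel_tol` of the scan minimum).
#'
#' @param curve a [scattering_curve()].
#' @param dmax_grid candidate dmax values; default `seq(2, 5, 0.25) * Rg` from
#'   a Guinier fit.
#' @param alpha regularization weight passed to [ift_pofr()] (default 1, a
#'   mild smoothing for scoring purposes).
#' @param rel_tol plateau tolerance on the chi2 score.
#' @return list with `dmax`, `grid`, `score`, `plateau_found`.
#' @export
estimate_dmax <- function(curve, dmax_grid = NULL, alpha = 1, rel_tol = 0.10) {
  if (is.null(dmax_grid)) {
    rg <- guinier_fit(curve)$rg
    dmax_grid <- seq(2, 5, by = 0.15) * rg
  }
  score <- vapply(dmax_grid, function(dm) ift_pofr(curve, dm, alpha)$chi2,
                  numeric(1))
  best <- min(score)
  # absolute slack keeps the plateau detectable on noiseless data (chi2 ~ 0)
  ok <- score <= max(best * (1 + rel_tol), best + 0.05)
  # plateau: from the first qualifying dmax onwards, scores stay qualifying
  idx <- which(ok)
  plateau <- NA_integer_
  for (i in idx) {
    if (all(ok[i:length(ok)])) { plateau <- i; break }
  }
  if (is.na(plateau)) {
    return(list(dmax = dmax_grid[which.min(score)], grid = dmax_grid,
                score = score, plateau_found = FALSE))
  }
  list(dmax = dmax_grid[plateau], grid = dmax_grid, score = score,
       plateau_found = TRUE)
}

# ---- Porod / Kratky / MW --------------------------------------------------

#' Porod invariant and Porod volume
#'
#' `Q = integral s^2 I(s) ds` computed by the trapezoid rule over the data with
#' a Porod-law tail: `I ~ A/s^4 + B` is fitted over the last decade of s, the
#' constant background B subtracted, and the tail integral `A/s_max` added.
#' `Vp = 2 pi^2 I0 / Q`.
#'
#' @param curve a [scattering_curve()].
#' @param I0 forward scattering (from Guinier or the indirect transform).
#' @param tail_frac_warn flag the result when the extrapolated tail carries
#'   more than this fraction of Q.
#' @return object of class `porod_result`: `Q`, `vp`, `tail_fraction`,
#'   `converged`.
#' @export
porod_volume <- function(curve, I0, tail_frac_warn = 0.2) {
  s <- curve$s; I <- curve$I
  stopifnot(I0 > 0)
  smax <- max(s)
  tail <- s >= smax / 10^0.5 & s > 0   # last half-decade for the Porod fit
  if (sum(tail) < 5) tail <- s >= stats::quantile(s, 0.7)
  X <- cbind(1, 1 / s[tail]^4)
  cf <- stats::lm.fit(X, I[tail])$coefficients
  B <- max(0, cf[1]); A <- max(0, cf[2])
  Isub <- pmax(I - B, 0)
  wq <- trapz_weights(s)
  Q_data <- sum(wq * s^2 * Isub)
  Q_tail <- A / smax
  Q <- Q_data + Q_tail
  if (Q <= 0) stop("non-positive Porod invariant")
  tail_fraction <- Q_tail / Q
  structure(list(Q = Q, vp = 2 * pi^2 * I0 / Q,
                 tail_fraction = tail_fraction,
                 converged = tail_fraction <= tail_frac_warn),
            class = "porod_result")
}

#' Kratky transform
#'
#' Pointwise `(s, s^2 I(s))`; no smoothing.
#'
#' @param curve a [scattering_curve()].
#' @return data frame with columns `s`, `s2I`.
#' @export
kratky <- function(curve) {
  data.frame(s = curve$s, s2I = curve$s^2 * curve$I)
}

#' Molecular weight from forward scattering against a standard
#'
#' `MW = MW_ref * (I0/c) / (I0_ref/c_ref)`, the bovine-serum-albumin-style
#' concentration-normalized comparison.
#'
#' @param I0_sample,c_sample forward scattering and concentration (mg/ml) of
#'   the sample.
#' @param I0_ref,c_ref,mw_ref same for the reference protein (MW in kDa).
#' @return object of class `mw_estimate` with `mw` (kDa) and the reference.
#' @export
mw_from_forward_scattering <- function(I0_sample, c_sample, I0_ref, c_ref,
                                       mw_ref) {
  if (any(c(I0_sample, c_sample, I0_ref, c_ref, mw_ref) <= 0)) {
    stop("all forward-scattering inputs must be positive")
  }
  structure(list(mw = mw_ref * (I0_sample / c_sample) / (I0_ref / c_ref),
                 reference = list(mw = mw_ref, I0 = I0_ref, conc = c_ref)),
            class = "mw_estimate")
}

#' Add Gaussian noise to a scattering curve
#'
#' Measurement model for synthetic data: `sigma_i = noise_frac * (I_i +
#' floor_frac * max I)`, `I_obs = I + N(0, sigma)`. The additive floor mimics
#' the detector/background noise that keeps real uncertainties finite at
#' form-factor minima.
#'
#' @param curve noiseless [scattering_curve()].
#' @param noise_frac relative noise level (e.g. 0.02).
#' @param rng_seed integer seed.
#' @param floor_frac noise floor as a fraction of the peak intensity.
#' @return a [scattering_curve()] with uncertainties.
#' @export
perturb_curve <- function(curve, noise_frac = 0.02, rng_seed = NULL,
                          floor_frac = 0.01) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sigma <- noise_frac * (abs(curve$I) + floor_frac * max(abs(curve$I)))
  I <- curve$I + stats::rnorm(length(curve$I), 0, sigma)
  scattering_curve(curve$s, I, sigma = sigma, metadata = curve$metadata)
}
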