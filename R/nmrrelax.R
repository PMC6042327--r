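# NMR relaxation and chemical-shift analyses: per-residue exponential decay
# fits (T1 inversion recovery, T2 CPMG), per-domain summaries and rotational
# correlation times from the T1/T2 ratio under isotropic tumbling,
# heteronuclear NOE ratios, chemical shift perturbation, and chemical shift
# index secondary-structure calls.

#' Default relaxation delay schedules (ms)
#'
#' The 11 inversion-recovery delays and 10 CPMG echo delays used for the SGTA
#' constructs.
#'
#' @name relaxation_delays
#' @export
t1_delays_ms <- c(30.8, 61.6, 123.2, 246.4, 369.6, 554.4, 739.2, 985.5,
                  1232, 1386, 1540)

#' @rdname relaxation_delays
#' @export
t2_delays_ms <- c(16.96, 33.92, 50.88, 67.84, 84.8, 118.72, 152.64, 186.56,
                  220.48, 254.4)

#' Per-residue relaxation series
#'
#' @param residue_id residue index.
#' @param experiment_type `"T1"` or `"T2"`.
#' @param delays_ms strictly increasing delays (>= 2 points).
#' @param intensities peak intensities.
#' @param sigma optional intensity uncertainties.
#' @return object of class `relaxation_series`.
#' @export
relaxation_series <- function(residue_id, experiment_type, delays_ms,
                              intensities, sigma = NULL) {
  stopifnot(experiment_type %in% c("T1", "T2"),
            length(delays_ms) >= 2,
            !is.unsorted(delays_ms, strictly = TRUE),
            length(delays_ms) == length(intensities))
  structure(list(residue_id = residue_id, experiment_type = experiment_type,
                 delays_ms = as.numeric(delays_ms),
                 intensities = as.numeric(intensities),
                 sigma = sigma),
            class = "relaxation_series")
}

#' Single-exponential decay fit of a relaxation series
#'
#' Nonlinear least squares of `I(t) = I0 exp(-t / T)`; the time constant is
#' reported in seconds with its covariance-based uncertainty. Non-decaying
#' series return `converged = FALSE` rather than an exception.
#'
#' @param series a [relaxation_series()].
#' @return object of class `rate_fit`: `residue_id`, `T_s`, `se_s`,
#'   `residual`, `converged`, `flagged` (TRUE for 2-point fits).
#' @export
fit_exponential <- function(series) {
  t_s <- series$delays_ms / 1000
  I <- series$intensities
  flagged <- length(t_s) < 3
  fail <- function() structure(
    list(residue_id = series$residue_id, T_s = NA_real_, se_s = NA_real_,
         residual = NA_real_, converged = FALSE, flagged = flagged),
    class = "rate_fit")
  if (all(I <= 0)) return(fail())
  # log-linear start values
  pos <- I > 0
  cf <- stats::lm.fit(cbind(1, t_s[pos]), log(I[pos]))$coefficients
  if (!is.finite(cf[2]) || cf[2] >= 0) return(fail())
  st <- list(I0 = unname(exp(cf[1])), T = unname(-1 / cf[2]))
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch(
    if (is.null(series$sigma)) {
      minpack.lm::nlsLM(I ~ I0 * exp(-t_s / T), start = st, control = ctl)
    } else {
      minpack.lm::nlsLM(I ~ I0 * exp(-t_s / T), start = st,
                        weights = 1 / series$sigma^2, control = ctl)
    },
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  est <- stats::coef(fit)
  if (!is.finite(est["T"]) || est["T"] <= 0) return(fail())
  se <- tryCatch(summary(fit)$coefficients["T", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(residue_id = series$residue_id, T_s = unname(est["T"]),
                 se_s = unname(se),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 converged = TRUE, flagged = flagged),
            class = "rate_fit")
}

#' Rotational correlation time from averaged T1/T2
#'
#' Isotropic-tumbling estimate: `tau_c = 1/(4 pi nu_N) * sqrt(6 T1/T2 - 7)`,
#' returned in ns. `nu_N` is the 15N resonance frequency in Hz and must be
#' supplied explicitly.
#'
#' @param mean_T1_s,mean_T2_s averaged relaxation times (s).
#' @param nu_N_hz 15N frequency (Hz), e.g. 60.8e6 on a 600 MHz spectrometer.
#' @return tau_c in ns.
#' @export
domain_tc <- function(mean_T1_s, mean_T2_s, nu_N_hz) {
  stopifnot(nu_N_hz > 0, mean_T1_s > 0, mean_T2_s > 0)
  ratio <- mean_T1_s / mean_T2_s
  if (6 * ratio < 7) {
    stop("tau_c undefined: 6 T1/T2 = ", signif(6 * ratio, 4),
         " < 7 (T1/T2 = ", signif(ratio, 4), ")")
  }
  1e9 / (4 * pi * nu_N_hz) * sqrt(6 * ratio - 7)
}

#' Invert the correlation-time relation for T2
#'
#' Given a target tau_c and a T1 scale, returns the T2 for which [domain_tc()]
#' reproduces tau_c exactly; used by the synthetic relaxation generator.
#'
#' @param tau_c_ns target correlation time (ns).
#' @param T1_s chosen T1 (s).
#' @param nu_N_hz 15N frequency (Hz).
#' @return T2 in seconds.
#' @export
t2_for_tc <- function(tau_c_ns, T1_s, nu_N_hz) {
  x <- (tau_c_ns * 1e-9 * 4 * pi * nu_N_hz)^2   # = 6 T1/T2 - 7
  6 * T1_s / (x + 7)
}

#' Per-domain relaxation summary
#'
#' Averages converged T1 and T2 fits over residues inside an inclusive range,
#' reports the residue count actually used, and the correlation time with a
#' first-order propagated uncertainty.
#'
#' @param fits_t1,fits_t2 lists of `rate_fit` objects (or data frames with
#'   columns `residue_id`, `T_s`, `converged`).
#' @param range inclusive residue range `c(lo, hi)`.
#' @param nu_N_hz 15N frequency (Hz).
#' @param name domain label.
#' @return object of class `domain_summary`: `domain`, `range`, `n`,
#'   `mean_T1_s`, `sd_T1_s`, `mean_T2_s`, `sd_T2_s`, `tc_ns`, `tc_se_ns`.
#' @export
summarize_domain <- function(fits_t1, fits_t2, range, nu_N_hz,
                             name = "domain") {
  as_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(f)
      data.frame(residue_id = f$residue_id, T_s = f$T_s,
                 converged = f$converged)))
  }
  d1 <- as_df(fits_t1); d2 <- as_df(fits_t2)
  d1 <- d1[d1$converged & d1$residue_id >= range[1] & d1$residue_id <= range[2], ]
  d2 <- d2[d2$converged & d2$residue_id >= range[1] & d2$residue_id <= range[2], ]
  common <- intersect(d1$residue_id, d2$residue_id)
  if (length(common) == 0) stop("empty domain: no converged residues in range")
  T1 <- d1$T_s[match(common, d1$residue_id)]
  T2 <- d2$T_s[match(common, d2$residue_id)]
  m1 <- mean(T1); m2 <- mean(T2)
  tc <- domain_tc(m1, m2, nu_N_hz)
  # delta-method propagation through tau_c(T1, T2)
  n <- length(common)
  se1 <- stats::sd(T1) / sqrt(n); se2 <- stats::sd(T2) / sqrt(n)
  if (!is.finite(se1)) se1 <- 0
  if (!is.finite(se2)) se2 <- 0
  x <- 6 * m1 / m2 - 7
  pref <- 1e9 / (4 * pi * nu_N_hz)
  dtc_dT1 <- pref * 3 / (m2 * sqrt(x))
  dtc_dT2 <- -pref * 3 * m1 / (m2^2 * sqrt(x))
  tc_se <- sqrt((dtc_dT1 * se1)^2 + (dtc_dT2 * se2)^2)
  structure(list(domain = name, range = range, n = n,
                 mean_T1_s = m1, sd_T1_s = stats::sd(T1),
                 mean_T2_s = m2, sd_T2_s = stats::sd(T2),
                 tc_ns = tc, tc_se_ns = tc_se, nu_N_hz = nu_N_hz),
            class = "domain_summary")
}

#' @export
print.domain_summary <- function(x, ...) {
  cat(sprintf("%s (%d-%d): n = %d, T1 = %.3f s, T2 = %.3f s, tau_c = %.2f ns\n",
              x$domain, x$range[1], x$range[2], x$n, x$mean_T1_s,
              x$mean_T2_s, x$tc_ns))
  invisible(x)
}

#' Heteronuclear NOE table
#'
#' Ratio of saturated to equilibrium crosspeak intensities per residue.
#' Residues missing from either table, or with non-positive equilibrium
#' intensity, are excluded and listed.
#'
#' @param equilibrium,saturated data frames with columns `residue_id`,
#'   `intensity`.
#' @return list with `table` (residue_id, ratio) and `excluded` (residue ids).
#' @export
het_noe <- function(equilibrium, saturated) {
  common <- intersect(equilibrium$residue_id, saturated$residue_id)
  all_ids <- union(equilibrium$residue_id, saturated$residue_id)
  ieq <- equilibrium$intensity[match(common, equilibrium$residue_id)]
  isat <- saturated$intensity[match(common, saturated$residue_id)]
  ok <- is.finite(ieq) & is.finite(isat) & ieq > 0
  excluded <- sort(c(setdiff(all_ids, common), common[!ok]))
  list(table = data.frame(residue_id = common[ok],
                          ratio = isat[ok] / ieq[ok]),
       excluded = excluded)
}

#' Combined amide chemical shift perturbation
#'
#' `delta = sqrt(dH^2 + (w_N dN)^2)` between two shift tables, computed for
#' residues present (with both 1H and 15N shifts) in both tables.
#'
#' @param table_a,table_b shift tables: data frames with columns `residue_id`,
#'   `h_ppm`, `n_ppm`.
#' @param weight_N 15N scaling weight (conventional 0.14).
#' @return data frame with `residue_id`, `csp_ppm`.
#' @export
csp <- function(table_a, table_b, weight_N = 0.14) {
  ok_a <- table_a[is.finite(table_a$h_ppm) & is.finite(table_a$n_ppm), ]
  ok_b <- table_b[is.finite(table_b$h_ppm) & is.finite(table_b$n_ppm), ]
  common <- intersect(ok_a$residue_id, ok_b$residue_id)
  if (length(common) == 0) stop("no common residues with complete amide shifts")
  ia <- match(common, ok_a$residue_id); ib <- match(common, ok_b$residue_id)
  dH <- ok_a$h_ppm[ia] - ok_b$h_ppm[ib]
  dN <- ok_a$n_ppm[ia] - ok_b$n_ppm[ib]
  data.frame(residue_id = common,
             csp_ppm = sqrt(dH^2 + (weight_N * dN)^2))
}

#' Load the random-coil 13C shift reference table
#'
#' Standard random-coil Calpha and CO chemical shifts for the 20 amino acids
#' (one-letter codes), shipped with the package.
#'
#' @return data frame with `residue_type`, `ca_ppm`, `co_ppm`.
#' @export
random_coil_shifts <- function() {
  utils::read.delim(system.file("extdata", "random_coil_shifts.tsv",
                                package = "sgtadimer"))
}

#' Chemical shift index profile
#'
#' Per-residue deviation of Calpha and CO shifts from random-coil reference
#' values, with a windowed secondary-structure call: helix where a window of
#' `window` consecutive assigned residues has mean dCa > `ca_thresh` and mean
#' dCO > `co_thresh`; strand for the mirrored negative thresholds; coil
#' otherwise; undetermined where shifts are missing (gaps are preserved, never
#' interpolated).
#'
#' @param table data frame with columns `residue_id`, `residue_type`
#'   (one-letter), `ca_ppm`, `co_ppm` (NA allowed).
#' @param reference random-coil table, default [random_coil_shifts()].
#' @param ca_thresh,co_thresh,window call thresholds (ppm) and window length.
#' @return data frame with `residue_id`, `d_ca`, `d_co`, `call`; unknown
#'   residue types are flagged in the `call` column as `"undetermined"`.
#' @export
csi <- function(table, reference = random_coil_shifts(), ca_thresh = 0.7,
                co_thresh = 0.5, window = 4) {
  m <- match(table$residue_type, reference$residue_type)
  d_ca <- table$ca_ppm - reference$ca_ppm[m]
  d_co <- table$co_ppm - reference$co_ppm[m]
  n <- nrow(table)
  call <- rep("coil", n)
  known <- is.finite(d_ca) & is.finite(d_co)
  call[!known] <- "undetermined"
  helix_hit <- strand_hit <- rep(FALSE, n)
  for (i in seq_len(max(0, n - window + 1))) {
    idx <- i:(i + window - 1)
    # windows must be consecutive residues, all assigned
    if (any(!known[idx])) next
    if (any(diff(table$residue_id[idx]) != 1)) next
    if (mean(d_ca[idx]) > ca_thresh && mean(d_co[idx]) > co_thresh) {
      helix_hit[idx] <- TRUE
    }
    if (mean(d_ca[idx]) < -ca_thresh && mean(d_co[idx]) < -co_thresh) {
      strand_hit[idx] <- TRUE
    }
  }
  call[helix_hit & known] <- "helix"
  call[strand_hit & !helix_hit & known] <- "strand"
  data.frame(residue_id = table$residue_id, d_ca = d_ca, d_co = d_co,
             call = call)
}

#' Simulate a per-residue relaxation dataset from domain correlation times
#'
#' For each domain a T1 scale is chosen and T2 set so the isotropic
#' T1/T2-to-tau_c relation returns the target tau_c exactly; noiseless decays
#' at the given schedules are then perturbed with Gaussian noise. Inverse
#' construction: with `noise_sd = 0` the fit-summarize-tau_c pipeline is the
#' identity.
#'
#' @param domains list of `list(name=, range=c(lo, hi), tc_ns=)` entries.
#' @param nu_N_hz 15N frequency (Hz).
#' @param noise_sd relative intensity noise (fraction of I0).
#' @param rng_seed integer seed.
#' @param T1_scale_s T1 value assigned to every residue (s).
#' @param delays list with `t1` and `t2` delay vectors (ms).
#' @param I0 intensity scale.
#' @return list with `t1` and `t2`: lists of [relaxation_series()], plus the
#'   `truth` per-domain table.
#' @export
simulate_relaxation_dataset <- function(domains, nu_N_hz, noise_sd = 0,
                                        rng_seed = NULL, T1_scale_s = 1.1,
                                        delays = list(t1 = t1_delays_ms,
                                                      t2 = t2_delays_ms),
                                        I0 = 100) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  t1 <- list(); t2 <- list()
  truth <- data.frame()
  for (dm in domains) {
    stopifnot(dm$tc_ns >= 0)
    T1 <- T1_scale_s
    T2 <- t2_for_tc(dm$tc_ns, T1, nu_N_hz)
    truth <- rbind(truth, data.frame(name = dm$name, tc_ns = dm$tc_ns,
                                     T1_s = T1, T2_s = T2))
    for (res in seq.int(dm$range[1], dm$range[2])) {
      I1 <- I0 * exp(-delays$t1 / 1000 / T1)
      I2 <- I0 * exp(-delays$t2 / 1000 / T2)
      if (noise_sd > 0) {
        I1 <- I1 + stats::rnorm(length(I1), 0, noise_sd * I0)
        I2 <- I2 + stats::rnorm(length(I2), 0, noise_sd * I0)
      }
      t1[[length(t1) + 1]] <- relaxation_series(res, "T1", delays$t1, I1)
      t2[[length(t2) + 1]] <- relaxation_series(res, "T2", delays$t2, I2)
    }
  }
  list(t1 = t1, t2 = t2, truth = truth)
}

#' Fit every series in a simulated or imported relaxation dataset
#'
#' @param series_list list of [relaxation_series()].
#' @return data frame with one `rate_fit` row per series.
#' @export
fit_relaxation_set <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    f <- fit_exponential(s)
    data.frame(residue_id = f$residue_id, T_s = f$T_s, se_s = f$se_s,
               converged = f$converged, flagged = f$flagged)
  }))
}
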