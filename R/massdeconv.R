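# Native mass spectrometry: charge-state series assignment in positive-ion
# mode, neutral-mass deconvolution, oligomeric-state assignment, and detection
# of repeated-adduct mass ladders (the dimer + n x ~360 Da pattern).

PROTON_DA <- 1.00728

#' Construct a centroided peak list
#'
#' @param mz m/z values (Th), > 0.
#' @param intensity peak intensities.
#' @param metadata optional list (instrument, solution, ...).
#' @return object of class `mz_peaklist`, sorted by m/z.
#' @export
mz_peaklist <- function(mz, intensity, metadata = list()) {
  stopifnot(length(mz) == length(intensity), all(mz > 0))
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 metadata = metadata),
            class = "mz_peaklist")
}

#' Read/write peak lists as TSV (mz, intensity)
#'
#' @param path file path.
#' @return an [mz_peaklist()].
#' @export
read_peaklist <- function(path) {
  d <- utils::read.delim(path)
  mz_peaklist(d[[1]], d[[2]], metadata = list(file = path))
}

#' @rdname read_peaklist
#' @param peaks an [mz_peaklist()].
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(data.frame(mz = peaks$mz, intensity = peaks$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign charge-state series in a peak list
#'
#' Positive-ion mode: a peak at m/z `m` with charge `z` implies the neutral
#' mass `M = z (m - m_p)`. Candidate series are seeded from every (peak, z)
#' pair, extended across adjacent charges by looking up the predicted m/z
#' within `tol_ppm`, deduplicated, and reported as disjoint series in order of
#' decreasing total intensity. Peaks that join no series of at least
#' `min_peaks` members are left unassigned; with no consistent series the
#' result is an empty list, not an error.
#'
#' @param peaks an [mz_peaklist()].
#' @param z_range integer charge range searched.
#' @param tol_ppm m/z agreement tolerance (native-MS appropriate default 50).
#' @param min_peaks minimum series length (default 2).
#' @return list of charge series; each has `peak_index`, `z`, `mass_da`
#'   (per-peak derived masses), `intensity`.
#' @export
assign_charge_series <- function(peaks, z_range = c(4, 30), tol_ppm = 50,
                                 min_peaks = 2) {
  mz <- peaks$mz
  n <- length(mz)
  if (n < min_peaks) return(list())
  zs <- seq.int(z_range[1], z_range[2])
  cand <- list()
  for (i in seq_len(n)) {
    for (z in zs) {
      M <- z * (mz[i] - PROTON_DA)
      # extend to neighbouring charges while predicted peaks exist
      members <- i; charges <- z
      for (dzdir in c(1L, -1L)) {
        zz <- z
        repeat {
          zz <- zz + dzdir
          if (zz < z_range[1] || zz > z_range[2]) break
          pred <- (M + zz * PROTON_DA) / zz
          j <- which.min(abs(mz - pred))
          if (abs(mz[j] - pred) / pred * 1e6 > tol_ppm) break
          members <- c(members, j); charges <- c(charges, zz)
        }
      }
      if (length(unique(members)) >= min_peaks) {
        o <- order(charges)
        cand[[length(cand) + 1]] <- list(peak_index = members[o],
                                         z = charges[o])
      }
    }
  }
  if (length(cand) == 0) return(list())
  # deduplicate identical member sets, keep the longest first
  key <- vapply(cand, function(s) paste(sort(s$peak_index), collapse = ","),
                character(1))
  cand <- cand[!duplicated(key)]
  tot_int <- vapply(cand, function(s) sum(peaks$intensity[s$peak_index]),
                    numeric(1))
  len <- vapply(cand, function(s) length(s$peak_index), numeric(1))
  cand <- cand[order(-len, -tot_int)]
  used <- logical(n)
  out <- list()
  for (s in cand) {
    avail <- !used[s$peak_index]
    if (sum(avail) < min_peaks) next
    pi <- s$peak_index[avail]; zz <- s$z[avail]
    used[pi] <- TRUE
    masses <- zz * (mz[pi] - PROTON_DA)
    out[[length(out) + 1]] <- structure(
      list(peak_index = pi, z = zz, mass_da = masses,
           mz = mz[pi], intensity = peaks$intensity[pi]),
      class = "charge_series")
  }
  tot <- vapply(out, function(s) sum(s$intensity), numeric(1))
  out[order(-tot)]
}

#' Neutral mass from a charge series
#'
#' Intensity-weighted mean of the per-peak derived masses, with the standard
#' deviation over members.
#'
#' @param series a `charge_series` from [assign_charge_series()].
#' @return object of class `species_mass`: `mass_da`, `sd_da`, `n_peaks`,
#'   `intensity`.
#' @export
deconvolve_mass <- function(series) {
  stopifnot(length(series$mass_da) >= 2)
  m <- sum(series$mass_da * series$intensity) / sum(series$intensity)
  structure(list(mass_da = m, sd_da = stats::sd(series$mass_da),
                 n_peaks = length(series$mass_da),
                 intensity = sum(series$intensity)),
            class = "species_mass")
}

#' @export
print.species_mass <- function(x, ...) {
  cat(sprintf("Species: %.1f +/- %.1f Da (%d peaks)\n", x$mass_da, x$sd_da,
              x$n_peaks))
  invisible(x)
}

#' Assign an oligomeric state to a deconvolved mass
#'
#' `n = round(M / monomer)`; assigned when `|M - n monomer| <= tol` (default
#' 1% of M, absorbing adducts and solvent retention typical of native MS).
#'
#' @param species a `species_mass` (or a bare mass in Da).
#' @param monomer_mass_da monomer mass (Da).
#' @param tol_da assignment tolerance; default `0.01 * M`.
#' @return object of class `oligomer_assignment`: `mass_da`,
#'   `monomer_mass_da`, `n_mer` (NA when unassigned), `error_da`,
#'   `error_ppm`, `assigned`.
#' @export
assign_oligomer <- function(species, monomer_mass_da, tol_da = NULL) {
  stopifnot(monomer_mass_da > 0)
  M <- if (inherits(species, "species_mass")) species$mass_da else
    as.numeric(species)
  if (is.null(tol_da)) tol_da <- 0.01 * M
  n <- max(1L, as.integer(round(M / monomer_mass_da)))
  err <- M - n * monomer_mass_da
  assigned <- abs(err) <= tol_da
  structure(list(mass_da = M, monomer_mass_da = monomer_mass_da,
                 n_mer = if (assigned) n else NA_integer_,
                 error_da = err, error_ppm = err / M * 1e6,
                 assigned = assigned),
            class = "oligomer_assignment")
}

#' Detect a repeated-adduct mass ladder
#'
#' Fits `M_i ~ M0 + k_i a` over integer stoichiometries `k_i` by grid search
#' on the increment `a`, minimizing the residual standard deviation. A ladder
#' is reported only when at least `min_rungs` distinct stoichiometries occur,
#' the ladder is gap-free from its lowest rung, and the residual SD is below
#' `resid_sd_max`.
#'
#' @param masses numeric masses (Da) or list of `species_mass` objects
#'   (>= 3 values).
#' @param max_stoich maximum stoichiometry considered.
#' @param a_grid candidate increments (Da); default 100-1000 Da in 1 Da steps.
#' @param resid_sd_max acceptance threshold on the residual SD (Da).
#' @return object of class `adduct_ladder` (`base_mass_da`, `increment_da`,
#'   `increment_sd_da`, `stoichiometries`, `residual_sd_da`) or `NULL` when no
#'   ladder qualifies.
#' @export
detect_adduct_ladder <- function(masses, max_stoich = 6,
                                 a_grid = seq(100, 1000, by = 1),
                                 resid_sd_max = 12) {
  if (is.list(masses)) {
    masses <- vapply(masses, function(m) m$mass_da, numeric(1))
  }
  if (length(masses) < 3) return(NULL)
  M <- sort(masses)
  Mref <- M[1]
  best <- NULL
  for (a in a_grid) {
    k <- round((M - Mref) / a)
    if (any(k > max_stoich) || any(k < 0)) next
    if (length(unique(k)) < 3) next
    # gap-free from the lowest rung
    ks <- sort(unique(k))
    if (any(diff(ks) != 1)) next
    M0 <- mean(M - k * a)
    resid <- M - M0 - k * a
    rsd <- sqrt(mean(resid^2))
    if (rsd > resid_sd_max) next
    if (is.null(best) || rsd < best$rsd) {
      best <- list(a = a, k = k, M0 = M0, rsd = rsd)
    }
  }
  if (is.null(best)) return(NULL)
  # per-step increment spread for the +/- uncertainty
  o <- order(best$k)
  ks <- best$k[o]; Ms <- M[o]
  steps <- diff(Ms) / diff(ks)
  steps <- steps[is.finite(steps)]
  structure(list(base_mass_da = best$M0, increment_da = best$a,
                 increment_sd_da = if (length(steps) > 1) stats::sd(steps)
                 else 0,
                 stoichiometries = sort(unique(best$k)),
                 residual_sd_da = best$rsd),
            class = "adduct_ladder")
}

#' @export
print.adduct_ladder <- function(x, ...) {
  cat(sprintf("Adduct ladder: base %.0f Da + k x (%.0f +/- %.0f) Da, k in {%s}\n",
              x$base_mass_da, x$increment_da, x$increment_sd_da,
              paste(x$stoichiometries, collapse = ", ")))
  invisible(x)
}

#' Simulate a native-MS peak list
#'
#' Emits peaks at `(M + z m_p)/z` for charges in a Gaussian-weighted envelope
#' around `z0 ~ envelope_scale * sqrt(M)` (electrospray charging of folded
#' proteins), with intensities proportional to abundance x envelope weight and
#' ppm-scale m/z jitter.
#'
#' @param species data frame with columns `mass_da`, `abundance`.
#' @param mz_noise_ppm m/z jitter (ppm).
#' @param rng_seed integer seed.
#' @param envelope_width charge-envelope standard deviation (charges).
#' @param envelope_halfspan charges emitted each side of the envelope centre.
#' @param envelope_scale charge-to-sqrt-mass factor.
#' @return an [mz_peaklist()].
#' @export
simulate_spectrum <- function(species, mz_noise_ppm = 0, rng_seed = NULL,
                              envelope_width = 1.5, envelope_halfspan = 3L,
                              envelope_scale = 0.0778) {
  stopifnot(all(species$mass_da > 0))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mz <- numeric(0); inten <- numeric(0)
  for (i in seq_len(nrow(species))) {
    M <- species$mass_da[i]
    z0 <- max(2L, round(envelope_scale * sqrt(M)))
    zvec <- seq.int(max(1L, z0 - envelope_halfspan), z0 + envelope_halfspan)
    w <- exp(-(zvec - z0)^2 / (2 * envelope_width^2))
    m <- (M + zvec * PROTON_DA) / zvec
    if (mz_noise_ppm > 0) {
      m <- m * (1 + stats::rnorm(length(m), 0, mz_noise_ppm * 1e-6))
    }
    mz <- c(mz, m)
    inten <- c(inten, species$abundance[i] * w)
  }
  mz_peaklist(mz, inten)
}

#' Full native-MS analysis of a peak list
#'
#' Charge-series assignment, per-series deconvolution, oligomer assignment
#' against a monomer mass, and adduct-ladder detection over the deconvolved
#' masses; the structured report mirrors the JSON output of the workbench.
#'
#' @param peaks an [mz_peaklist()].
#' @param monomer_mass_da monomer mass (Da).
#' @param z_range,tol_ppm passed to [assign_charge_series()].
#' @param ladder_args list of extra arguments for [detect_adduct_ladder()].
#' @return list with `species` (data frame), `oligomers` (data frame) and
#'   `ladder` (or NULL).
#' @export
ms_analyze <- function(peaks, monomer_mass_da, z_range = c(4, 30),
                       tol_ppm = 50, ladder_args = list()) {
  series <- assign_charge_series(peaks, z_range, tol_ppm)
  if (length(series) == 0) {
    return(list(species = data.frame(), oligomers = data.frame(),
                ladder = NULL))
  }
  sp <- lapply(series, deconvolve_mass)
  species <- do.call(rbind, lapply(sp, function(x)
    data.frame(mass_da = x$mass_da, sd_da = x$sd_da, n_peaks = x$n_peaks,
               intensity = x$intensity)))
  olig <- do.call(rbind, lapply(sp, function(x) {
    oa <- assign_oligomer(x, monomer_mass_da)
    data.frame(mass_da = oa$mass_da, n_mer = oa$n_mer,
               error_da = oa$error_da, assigned = oa$assigned)
  }))
  ladder <- if (nrow(species) >= 3) {
    do.call(detect_adduct_ladder, c(list(masses = species$mass_da),
                                    ladder_args))
  }
  list(species = species, oligomers = olig, ladder = ladder)
}
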