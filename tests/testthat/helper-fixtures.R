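# Shared fixtures, cached per session: dimer ensembles are expensive, so
# tests that only need "some open/closed conformers" reuse these pools.

.fixtures <- new.env(parent = emptyenv())

shared_arch <- function() {
  if (is.null(.fixtures$arch)) .fixtures$arch <- sgta_architecture()
  .fixtures$arch
}

shared_pool <- function(kind = c("open", "closed", "mixed"), n = 40) {
  kind <- match.arg(kind)
  key <- paste0(kind, "_", n)
  if (is.null(.fixtures[[key]])) {
    frac <- switch(kind, open = 0, closed = 1, mixed = 0.5)
    seed <- switch(kind, open = 4001, closed = 4002, mixed = 4003)
    .fixtures[[key]] <- generate_pool(shared_arch(), n, frac, seed)
  }
  .fixtures[[key]]
}

# ---- analytic oracles -----------------------------------------------------

# homogeneous sphere form factor, I(0) = I0
sphere_curve <- function(R, s, I0 = 100, sigma_frac = NULL) {
  x <- s * R
  I <- I0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
  sig <- if (!is.null(sigma_frac)) sigma_frac * (I + 0.01 * max(I))
  scattering_curve(s, I, sigma = sig)
}

# analytic sphere pair-distance distribution (unnormalized)
sphere_pofr <- function(r, R) {
  u <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * u + 0.5 * u^3)
  p[u > 1] <- 0
  p
}

# Debye chain (Gaussian coil) scattering
debye_chain_curve <- function(rg, s, I0 = 1) {
  x <- (s * rg)^2
  scattering_curve(s, I0 * 2 * (exp(-x) + x - 1) / x^2)
}

# random bead cloud as a bead_model
random_cloud <- function(n, sd = 1, seed = 1, weight = 1) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = sd), ncol = 3)
  bead_model(data.frame(protomer = "A", resno = seq_len(n),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        domain = "cloud", weight = weight))
}
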