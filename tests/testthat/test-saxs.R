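# Scattering analysis: Debye forward model, Guinier, indirect transform,
# Dmax scan, Porod volume, Kratky, forward-scattering MW.

test_that("Debye intensity matches closed forms and conserves I(0)", {
  s <- seq(0, 3, by = 0.1)
  one <- bead_model(data.frame(protomer = "A", resno = 1, x = 0, y = 0, z = 0,
                               domain = "d", weight = 1))
  expect_equal(debye_intensity(one, s)$I, rep(1, length(s)))

  two <- bead_model(data.frame(protomer = "A", resno = 1:2,
                               x = c(0, 0.38), y = 0, z = 0,
                               domain = "d", weight = 1))
  expect_equal(debye_intensity(two, s)$I, 2 * (1 + sinc(s * 0.38)),
               tolerance = 1e-12)

  wcloud <- random_cloud(20, seed = 5)
  wcloud$beads$weight <- seq(0.5, 2.4, 0.1)
  cv <- debye_intensity(wcloud, c(0, 0.5))
  expect_equal(cv$I[1], sum(wcloud$beads$weight)^2, tolerance = 1e-12)

  # histogram evaluation is indistinguishable at SAXS resolution
  cl <- random_cloud(60, seed = 6)
  sg <- seq(0, 4.8, length.out = 60)
  ce <- debye_intensity(cl, sg)$I
  ch <- debye_intensity(cl, sg, method = "histogram")$I
  expect_lt(max(abs(ce - ch)) / max(ce), 1e-3)
})

test_that("Guinier analysis recovers Rg from exact and model curves", {
  # exact Gaussian curve
  s <- seq(0.01, 0.6, length.out = 60)
  g <- scattering_curve(s, 100 * exp(-s^2 * 9 / 3))
  fit <- guinier_fit(g)
  expect_equal(fit$rg, 3.0, tolerance = 1e-9)
  expect_equal(fit$I0, 100, tolerance = 1e-9)

  # homogeneous sphere: Rg = sqrt(3/5) R within 1%
  R <- 3.873
  sph <- sphere_curve(R, seq(0.02, 3, length.out = 250))
  expect_equal(guinier_fit(sph, sRg_limit = 0.8)$rg, sqrt(3 / 5) * R,
               tolerance = 0.01)

  # noiseless bead model: curve Rg matches coordinate Rg; the low-s expansion
  # window (s Rg <= 0.25) agrees to 0.1%
  cl <- random_cloud(50, sd = 1.2, seed = 2)
  cv <- debye_intensity(cl, seq(0.005, 1.2, length.out = 150))
  expect_equal(guinier_fit(cv, sRg_limit = 0.8)$rg, radius_of_gyration(cl),
               tolerance = 0.01)
  expect_equal(guinier_fit(cv, sRg_limit = 0.25)$rg, radius_of_gyration(cl),
               tolerance = 0.001)
})

test_that("Guinier Rg stays accurate under 2% noise across seeds", {
  # a low-angle-dense acquisition, as Guinier analysis presumes
  R <- 3.873
  s <- seq(0.02, 1.5, length.out = 300)
  errs <- vapply(seq_len(100), function(seed) {
    noisy <- perturb_curve(sphere_curve(R, s), 0.02, rng_seed = seed)
    abs(guinier_fit(noisy, sRg_limit = 0.8)$rg - sqrt(3 / 5) * R) /
      (sqrt(3 / 5) * R)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("Guinier fit fails informatively on bad inputs", {
  s <- seq(0.01, 0.3, length.out = 4)
  expect_error(guinier_fit(scattering_curve(s, exp(-s^2))), "insufficient")
  s2 <- seq(0.01, 0.5, length.out = 30)
  expect_error(guinier_fit(scattering_curve(s2, exp(+s2^2 * 3))),
               "non-Guinier")
})

test_that("indirect transform recovers the sphere distance distribution", {
  R <- 3.873
  sph <- sphere_curve(R, seq(0.02, 3, length.out = 200), sigma_frac = 0.01)
  pr <- ift_pofr(sph, dmax = 2 * R)
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[length(pr$p)], 0)
  expect_true(all(pr$p >= -1e-8 * max(pr$p)))
  expect_true(is.finite(pr$chi2))
  pan <- sphere_pofr(pr$r, R)
  pan <- pan / sum(pan); pn <- pr$p / sum(pr$p)
  expect_lt(sqrt(mean((pn - pan)^2)) / max(pan), 0.02)
  # moments agree with the Guinier route on noiseless data
  expect_equal(pr$rg, sqrt(3 / 5) * R, tolerance = 0.01)
  expect_equal(pr$I0, 100, tolerance = 0.02)
  expect_error(ift_pofr(sph, dmax = 2 * R, alpha = -1), "regularization")
})

test_that("indirect transform resolves a dumbbell into two distance modes", {
  set.seed(11)
  c1 <- matrix(rnorm(90, sd = 0.5), ncol = 3)
  c2 <- sweep(matrix(rnorm(90, sd = 0.5), ncol = 3), 2, c(6, 0, 0), "+")
  xyz <- rbind(c1, c2)
  md <- bead_model(data.frame(protomer = "A", resno = 1:60, x = xyz[, 1],
                              y = xyz[, 2], z = xyz[, 3], domain = "d",
                              weight = 1))
  dmax <- max(dist(xyz)) * 1.05
  cv <- perturb_curve(debye_intensity(md, seq(0.02, 4, length.out = 150)),
                      0.01, rng_seed = 4)
  pr <- ift_pofr(cv, dmax = dmax)
  # oracle: direct pair-distance histogram binned on the same r grid
  h <- hist(dist(xyz), breaks = c(pr$r, max(pr$r) + diff(pr$r)[1]) -
              diff(pr$r)[1] / 2, plot = FALSE)
  dens <- h$density
  step <- diff(pr$r)[1]
  # two dominant well-separated maxima of p(r) vs of the histogram (the
  # dumbbell's intra-cluster and inter-cluster distance scales)
  top2 <- function(y, r, min_sep = 2) {
    i1 <- which.max(y)
    far <- abs(r - r[i1]) > min_sep
    i2 <- which(far)[which.max(y[far])]
    sort(c(r[i1], r[i2]))
  }
  expect_lt(max(abs(top2(pr$p, pr$r) - top2(dens, pr$r))), step * 1.01)
})

test_that("dmax estimation brackets the true particle size", {
  R <- 3.873
  sph <- sphere_curve(R, seq(0.02, 3, length.out = 200), sigma_frac = 0.01)
  ed <- estimate_dmax(sph)
  expect_true(ed$plateau_found)
  expect_lt(abs(ed$dmax - 2 * R) / (2 * R), 0.10)
  # score plateau: no strong improvement beyond the chosen dmax
  beyond <- ed$score[ed$grid >= ed$dmax]
  expect_true(all(beyond <= min(ed$score) + max(0.05, 0.15 * min(ed$score))))

  # elongated two-cluster fixture: dmax at least the largest distance - step
  set.seed(3)
  c1 <- matrix(rnorm(60, sd = 0.4), ncol = 3)
  c2 <- sweep(matrix(rnorm(60, sd = 0.4), ncol = 3), 2, c(7, 0, 0), "+")
  xyz <- rbind(c1, c2)
  md <- bead_model(data.frame(protomer = "A", resno = 1:40, x = xyz[, 1],
                              y = xyz[, 2], z = xyz[, 3], domain = "d",
                              weight = 1))
  cv <- perturb_curve(debye_intensity(md, seq(0.02, 4, length.out = 150)),
                      0.01, rng_seed = 9)
  grid <- seq(4, 12, by = 0.5)
  ed2 <- estimate_dmax(cv, dmax_grid = grid)
  expect_gte(ed2$dmax, max(dist(xyz)) - 0.5)
})

test_that("Porod volume approximates the particle volume and is scale-free", {
  R <- 3.0
  s <- seq(0.02, 8, length.out = 500)
  sph <- sphere_curve(R, s)
  pv <- porod_volume(sph, I0 = 100)
  expect_lt(abs(pv$vp - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3), 0.10)
  sph2 <- scattering_curve(sph$s, 7.3 * sph$I)
  pv2 <- porod_volume(sph2, I0 = 730)
  expect_equal(pv2$vp, pv$vp, tolerance = 1e-9)
})

test_that("Kratky transform distinguishes flexible from globular scatterers", {
  s <- seq(0.05, 2, length.out = 50)
  flat <- kratky(scattering_curve(s, 1 / s^2))
  expect_equal(flat$s2I, rep(1, 50), tolerance = 1e-12)

  # Gaussian chain: plateau at high s (relative drift < 5% over last decade)
  sd_ <- seq(0.01, 30, length.out = 600)
  kr <- kratky(debye_chain_curve(2, sd_))
  last <- kr$s >= max(kr$s) / 10
  drift <- diff(range(kr$s2I[last])) / mean(kr$s2I[last])
  expect_lt(drift, 0.05)

  # globular sphere: rises then decays towards zero
  ks <- kratky(sphere_curve(3, seq(0.02, 6, length.out = 400)))
  pk <- which.max(ks$s2I)
  expect_gt(pk, 5)
  expect_lt(mean(tail(ks$s2I, 20)), 0.2 * max(ks$s2I))
})

test_that("forward-scattering MW estimates scale as expected", {
  expect_equal(mw_from_forward_scattering(50, 2, 50, 2, 66)$mw, 66)
  expect_equal(mw_from_forward_scattering(100, 2, 50, 2, 66)$mw, 132)
  expect_error(mw_from_forward_scattering(50, 0, 50, 2, 66), "positive")

  # synthetic dimer against a synthetic 66-kDa reference: I0 proportional to
  # c * MW; recover the generator mass within noise-propagated uncertainty
  s <- seq(0.02, 2, length.out = 150)
  k <- 3.7
  mw_true <- 68; mw_ref <- 66
  ref <- perturb_curve(scattering_curve(s, k * 1.0 * mw_ref * exp(-s^2 * 3)),
                       0.02, rng_seed = 21)
  smp <- perturb_curve(scattering_curve(s, k * 2.0 * mw_true * exp(-s^2 * 4)),
                       0.02, rng_seed = 22)
  I0r <- guinier_fit(ref)$I0
  I0s <- guinier_fit(smp)$I0
  est <- mw_from_forward_scattering(I0s, 2.0, I0r, 1.0, mw_ref)
  expect_equal(est$mw, mw_true, tolerance = 0.05)
})

test_that("parameter extraction is deterministic for a fixed curve", {
  R <- 3.0
  sph <- sphere_curve(R, seq(0.02, 3, length.out = 150), sigma_frac = 0.01)
  expect_identical(guinier_fit(sph)$rg, guinier_fit(sph)$rg)
  p1 <- ift_pofr(sph, 6); p2 <- ift_pofr(sph, 6)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$alpha, p2$alpha)
})

test_that("SAXS .dat files round-trip with comments and junk tolerated", {
  s <- seq(0.07, 4.8, length.out = 40)
  cv <- scattering_curve(s, exp(-s), sigma = rep(0.01, 40))
  path <- tempfile(fileext = ".dat")
  write_saxs_dat(cv, path)
  lines <- readLines(path)
  writeLines(c("Sample description header", lines, "# trailing comment"),
             path)
  cv2 <- read_saxs_dat(path)
  expect_equal(cv2$s, cv$s, tolerance = 1e-7)
  expect_equal(cv2$I, cv$I, tolerance = 1e-9)
  expect_equal(cv2$sigma, cv$sigma, tolerance = 1e-9)
})
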