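# DEER: dipolar kernel, trace simulation, background correction, Tikhonov
# inversion, alpha selection, distribution statistics.

test_that("dipolar kernel matches adaptive quadrature and its bounds", {
  t <- seq(0, 4, by = 0.032)
  r <- c(1, 2, 3.2, 5, 8)
  K <- dipolar_kernel(t, r)
  expect_equal(K[1, ], rep(1, length(r)), tolerance = 1e-12)
  expect_true(all(K <= 1 + 1e-12) && all(K >= -0.5))
  # oracle: adaptive quadrature of the powder integral; the 1/r^3 frequencies
  # 52.04 MHz (1 nm) and 6.505 MHz (2 nm) enter through omega
  for (j in c(1, 2, 3)) {
    nu <- 52.04 / r[j]^3
    expect_equal(nu, c(52.04, 6.505, 52.04 / 3.2^3)[j], tolerance = 1e-12)
    w <- 2 * pi * nu
    oracle <- vapply(t, function(tt)
      integrate(function(x) cos((1 - 3 * x^2) * w * tt), 0, 1,
                rel.tol = 1e-10, subdivisions = 50000L)$value, numeric(1))
    expect_lt(max(abs(K[, j] - oracle)), 1e-6)
  }
  # the fixed Gauss-Legendre rule agrees where it has not dephased
  Kq <- dipolar_kernel(t, r[3:5], method = "quadrature")
  expect_lt(max(abs(Kq - K[, 3:5])), 1e-9)
  # even in time
  Kneg <- dipolar_kernel(-t, r)
  expect_equal(Kneg, K, tolerance = 1e-12)
})

test_that("trace simulation obeys its closed forms", {
  acq <- deer_acquisition(tau2_us = 4)
  # lambda = 0: pure homogeneous 3D background
  tr0 <- simulate_trace(gaussian_distribution(5, 0.3),
                        bg = list(k = 0.1, lambda = 0), acquisition = acq)
  expect_equal(tr0$V, exp(-0.1 * tr0$t), tolerance = 1e-12)
  # delta distribution, k = 0: V = 1 - lambda + lambda K(t, r0)
  r0 <- 4.0
  Pd <- distance_distribution(r0 + c(-0.001, 0, 0.001), c(0, 1, 0))
  trd <- simulate_trace(Pd, bg = list(k = 0, lambda = 0.4), acquisition = acq)
  Kcol <- dipolar_kernel(trd$t, r0)[, 1]
  expect_equal(trd$V, 1 - 0.4 + 0.4 * Kcol, tolerance = 1e-3)
})

test_that("background correction recovers rate and modulation depth", {
  # pure background: lambda ~ 0, k recovered, low-modulation warning
  tr <- simulate_trace(gaussian_distribution(5, 0.3),
                       bg = list(k = 0.12, lambda = 0))
  evo <- background_correct(tr)
  expect_lt(evo$lambda, 0.02)
  expect_equal(evo$k, 0.12, tolerance = 1e-6)
  expect_true(any(grepl("shallow", evo$warnings)))

  # known lambda at SNR 50: unbiased within 5% in the median over seeds
  P <- gaussian_distribution(5, 0.3)
  lam <- vapply(1:15, function(s) {
    background_correct(simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                                      noise_sd = 1 / 50, rng_seed = s))$lambda
  }, numeric(1))
  expect_lt(abs(median(lam) - 0.3), 0.015)

  # shallow modulation: warning emitted, result still returned
  trs <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.05),
                        noise_sd = 1 / 50, rng_seed = 2)
  evs <- background_correct(trs)
  expect_true(any(grepl("shallow", evs$warnings)))
  expect_true(is.finite(evs$lambda))
})

test_that("Tikhonov inversion recovers single and bimodal truths", {
  # noiseless single Gaussian: mode within 0.1 nm
  P <- gaussian_distribution(5.0, 0.3)
  tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3))
  an <- deer_analyze(tr, alpha = 1)
  main <- an$stats[which.max(an$stats$mass), ]
  expect_lt(abs(main$mode - 5.0), 0.1)
  # constraints hold for every input
  res <- an$result
  expect_true(all(res$distribution$P >= 0))
  expect_equal(sum(trapz_weights(res$distribution$r) * res$distribution$P), 1,
               tolerance = 1e-6)

  # the broad-5-nm + sharp-7-nm composition at SNR 30: both modes within 0.2
  P2 <- gaussian_distribution(weights = c(0.6, 0.4), means = c(5, 7),
                              sds = c(0.6, 0.15))
  tr2 <- simulate_trace(P2, bg = list(k = 0.08, lambda = 0.3),
                        noise_sd = 1 / 30, rng_seed = 5)
  an2 <- deer_analyze(tr2, alpha = NULL)
  st <- an2$stats[order(-an2$stats$mass), ][1:2, ]
  st <- st[order(st$mode), ]
  expect_lt(abs(st$mode[1] - 5.0), 0.2)
  expect_lt(abs(st$mode[2] - 7.0), 0.2)
})

test_that("inversion is deterministic and rejects bad inputs", {
  P <- gaussian_distribution(4.5, 0.4)
  tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                       noise_sd = 1 / 40, rng_seed = 8)
  evo <- background_correct(tr)
  r1 <- tikhonov_invert(evo, alpha = 1)
  r2 <- tikhonov_invert(evo, alpha = 1)
  expect_identical(r1$distribution$P, r2$distribution$P)
  expect_error(tikhonov_invert(evo, alpha = 0), "alpha")
  expect_error(dipolar_kernel(tr$t, c(-1, 2)), "invalid distance")
})

test_that("L-curve alpha choice is sane, deterministic and near optimal", {
  P <- gaussian_distribution(5.0, 0.4)
  tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                       noise_sd = 1 / 30, rng_seed = 4)
  evo <- background_correct(tr)
  agrid <- 10^seq(-3, 2, length.out = 11)
  ch <- choose_alpha(evo, alpha_grid = agrid)
  ch2 <- choose_alpha(evo, alpha_grid = agrid)
  expect_identical(ch$alpha, ch2$alpha)
  # residual norm non-decreasing in alpha
  expect_true(all(diff(ch$residual_norm) > -1e-8))
  # within 2x of the oracle-optimal alpha in true-distribution error
  r_grid <- seq(1.5, 10, length.out = 201)
  truthP <- gaussian_distribution(5.0, 0.4, r_grid = r_grid)$P
  err <- vapply(agrid, function(a) {
    Pa <- tikhonov_invert(evo, r_grid, a)$distribution$P
    sqrt(mean((Pa - truthP)^2))
  }, numeric(1))
  err_chosen <- err[which(agrid == ch$alpha)]
  expect_lte(err_chosen, 2 * min(err))
  expect_error(choose_alpha(evo, alpha_grid = c(0.5, 1, 2)), "three decades")
})

test_that("full pipeline recovers modes across the addressable range", {
  # seeded simulations with single-Gaussian truths spread over 3-7 nm
  set.seed(1234)
  modes <- runif(50, 3, 7)
  res <- t(vapply(seq_along(modes), function(i) {
    P <- gaussian_distribution(modes[i], 0.4)
    tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                         noise_sd = 1 / 30, rng_seed = 9000 + i)
    an <- deer_analyze(tr, alpha = 1)
    main <- an$stats[which.max(an$stats$mass), ]
    c(mode_err = abs(main$mode - modes[i]),
      width_err = abs(main$width - 0.4) / 0.4)
  }, numeric(2)))
  expect_lt(median(res[, "mode_err"]), 0.1)
  expect_lt(median(res[, "width_err"]), 0.30)
})

test_that("distributions near the long-distance limit broaden, not sharpen", {
  # truth modes near the resolvable limit of the 7 us window (~7.6 nm): the
  # recovered main mode is never sharper than the 0.3 nm truth width
  for (mode_nm in c(7, 7.3, 7.6, 8)) {
    P <- gaussian_distribution(mode_nm, 0.3)
    tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                         noise_sd = 1 / 40, rng_seed = 21,
                         acquisition = deer_acquisition(tau2_us = 7))
    an <- deer_analyze(tr, alpha = NULL)
    expect_gte(an$stats$width[which.max(an$stats$mass)], 0.3)
  }
})

test_that("distribution statistics report modes, shifts and unit mass", {
  P <- gaussian_distribution(5.0, 0.3)
  st <- distribution_stats(P)
  expect_equal(nrow(st), 1)
  expect_lt(abs(st$mode - 5.0), diff(P$r[1:2]) + 1e-12)
  expect_equal(sum(st$mass), 1, tolerance = 1e-9)

  # paired scenarios with truths 7.1 and 7.4 nm: recovered shift ~ 0.3 nm
  step <- diff(seq(1.5, 10, length.out = 201))[1]
  rec <- vapply(c(7.1, 7.4), function(m0) {
    P <- gaussian_distribution(m0, 0.25)
    tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.35),
                         noise_sd = 1 / 50, rng_seed = round(m0 * 100))
    an <- deer_analyze(tr, alpha = 1)
    an$stats$mode[which.max(an$stats$mass)]
  }, numeric(1))
  expect_lt(abs((rec[2] - rec[1]) - 0.3), 2 * step)

  flat <- distance_distribution(seq(2, 8, 0.1), rep(1, 61))
  expect_equal(nrow(distribution_stats(flat)), 0)
})

test_that("trace files round-trip in both time units", {
  P <- gaussian_distribution(4, 0.3)
  tr <- simulate_trace(P, bg = list(k = 0.05, lambda = 0.3),
                       acquisition = deer_acquisition(tau2_us = 2))
  path <- tempfile(fileext = ".dat")
  write_deer_trace(tr, path)
  tr2 <- read_deer_trace(path)
  expect_equal(tr2$t, tr$t, tolerance = 1e-9)
  expect_equal(tr2$V, tr$V, tolerance = 1e-9)
})
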