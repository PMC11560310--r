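test_that("fitMonoexponential recovers exact decays and flags flat data", {
  t <- seq(0.01, 1, length.out = 8)
  fit <- fitMonoexponential(t, 10 * exp(-2 * t))
  expect_equal(fit$rate, 2, tolerance = 1e-8)
  expect_equal(fit$I0, 10, tolerance = 1e-8)
  expect_warning(fitMonoexponential(t, rep(5, 8)), "non-decaying")
  expect_error(fitMonoexponential(c(0.1, 0.2), c(1, 0.5)), "at least 3")
})

test_that("fitMonoexponential covers the truth under repeated 2% noise", {
  t <- seq(0.02, 0.8, length.out = 10)
  I <- 100 * exp(-3 * t)
  set.seed(91)
  hit <- 0
  for (k in 1:200) {
    fit <- fitMonoexponential(t, I + rnorm(10, 0, 2),
                              uncertainties = rep(2, 10))
    if (abs(fit$rate - 3) <= 2 * fit$rateSE) hit <- hit + 1
  }
  expect_gte(hit / 200, 0.90)
})

test_that("r2FromR1rho applies the tilt-angle correction", {
  expect_equal(r2FromR1rho(8, 2, 90)$r2, 8, tolerance = 1e-12)
  expect_equal(r2FromR1rho(5, 5, 37)$r2, 5, tolerance = 1e-10)
  r <- r2FromR1rho(8, 2, 60, r1rhoSE = 0.2, r1SE = 0.1)
  expect_equal(r$r2, 10, tolerance = 1e-10)
  expect_equal(r$r2SE, sqrt(0.2^2 + (0.25 * 0.1)^2) / 0.75,
               tolerance = 1e-12)
  expect_error(r2FromR1rho(8, 2, 0), "tilt")
})

test_that("hetNOE propagates first-order uncertainties", {
  expect_equal(hetNOE(5, 5)$noe, 1)
  expect_equal(hetNOE(0, 5, 0.1, 0.1)$noe, 0)
  h <- hetNOE(3, 5, 0.2, 0.3)
  expect_equal(h$noeSE, sqrt((0.2 / 5)^2 + (3 * 0.3 / 25)^2),
               tolerance = 1e-12)
  expect_error(hetNOE(1, 0), "nonzero")
})

test_that("reduced spectral density mapping round-trips the forward model", {
  cns <- relaxationConstants(B0 = 14.1)
  tau <- 2e-9
  J <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  fw <- forwardRelaxationRates(J, cns)
  expect_lt(fw$noe, 1)  # 15N NOE below 1 for ns tumbling
  mapd <- reducedSpectralDensity(fw$r1, fw$r2, fw$noe, cns)
  expect_lt(abs(mapd$J0 - J(0)) / J(0), 0.05)
  expect_lt(abs(mapd$JwN - J(cns$omegaN)) / J(cns$omegaN), 0.05)
  # documented approximation quality: <= 5% for tau_c in [1, 5] ns; the
  # high-frequency approximation is worst for fast tumbling (~5% at 0.5 ns)
  for (tauc in c(1e-9, 2e-9, 4e-9, 5e-9)) {
    Jt <- function(w) 0.4 * tauc / (1 + (w * tauc)^2)
    f <- forwardRelaxationRates(Jt, cns)
    m <- reducedSpectralDensity(f$r1, f$r2, f$noe, cns)
    expect_lt(abs(m$J0 - Jt(0)) / Jt(0), 0.05)
  }
  Jfast <- function(w) 0.4 * 0.5e-9 / (1 + (w * 0.5e-9)^2)
  ff <- forwardRelaxationRates(Jfast, cns)
  mf <- reducedSpectralDensity(ff$r1, ff$r2, ff$noe, cns)
  expect_lt(abs(mf$J0 - Jfast(0)) / Jfast(0), 0.06)
})

test_that("reduced mapping is linear and zeroes J(0.87wH) at NOE = 1", {
  cns <- relaxationConstants(14.1)
  m0 <- reducedSpectralDensity(2, 5, 1, cns)
  expect_equal(m0$JwH, 0)
  m1 <- reducedSpectralDensity(2, 5, 0.7, cns)
  m2 <- reducedSpectralDensity(4, 10, 0.7, cns)
  expect_equal(m2$J0, 2 * m1$J0, tolerance = 1e-10)
  expect_equal(m2$JwN, 2 * m1$JwN, tolerance = 1e-10)
  expect_equal(m2$JwH, 2 * m1$JwH, tolerance = 1e-10)
  expect_warning(reducedSpectralDensity(2, 5, 1.2, cns), "NOE > 1")
})

test_that("exchangeContribution flags exchange-free residues", {
  ex <- exchangeContribution(5, 5, kappa = 1, r2SE = 0.2, rddSE = 0.2)
  expect_equal(ex$rex, 0)
  expect_true(ex$noExchange)
  expect_equal(exchangeContribution(5, 4)$rex, 1)
  ex2 <- exchangeContribution(8, 4, kappa = 1, r2SE = 0.3, rddSE = 0.4)
  expect_equal(ex2$rexSE, sqrt(0.3^2 + 0.4^2), tolerance = 1e-12)
  expect_false(ex2$noExchange)
  expect_error(exchangeContribution(5, 4, kappa = 0), "kappa")
})

test_that("stejskalTannerFit recovers D exactly and under noise", {
  g <- seq(0.02, 0.55, length.out = 10)
  dt <- dosyDecayTable(2.34e-10, g, delta = 0.004, Delta = 0.2)
  fit <- stejskalTannerFit(dt)
  expect_equal(fit$D, 2.34e-10, tolerance = 1e-7)  # 6 significant figures
  flat <- dosyDecayTable(0, g)
  expect_warning(flatFit <- stejskalTannerFit(flat), "non-decaying")
  expect_equal(flatFit$D, 0, tolerance = 1e-18)
  # invariance under intensity rescaling
  dt2 <- dt; dt2$intensity <- dt$intensity * 42
  attr(dt2, "delta") <- 0.004; attr(dt2, "Delta") <- 0.2
  attr(dt2, "gamma") <- attr(dt, "gamma")
  expect_equal(stejskalTannerFit(dt2)$D, fit$D, tolerance = 1e-12)
  noisy <- dosyDecayTable(2.34e-10, g, noiseSD = 0.01, seed = 92)
  expect_lt(abs(stejskalTannerFit(noisy)$D - 2.34e-10) / 2.34e-10, 0.02)
  expect_error(stejskalTannerFit(dt[1:3, ]), "delta|4 gradient")
})

test_that("welchTOneTailed reproduces textbook statistics", {
  w0 <- welchTOneTailed(3, 1, 5, 3, 1, 5)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)
  wa <- welchTOneTailed(2.52, 0.09, 3, 2.34, 0.05, 3)
  wb <- welchTOneTailed(2.34, 0.05, 3, 2.52, 0.09, 3)
  expect_equal(wb$t, -wa$t, tolerance = 1e-12)
  expect_equal(wa$t, 3.028, tolerance = 1e-3)
  expect_equal(wa$df, 3.127, tolerance = 1e-3)
  expect_true(wa$df >= 2 && wa$df <= 4)  # min(n)-1 <= df <= n1+n2-2
  expect_lt(wa$p, 0.05)
  # cross-check against t.test on raw data with matching summaries
  set.seed(93)
  a <- c(2.4, 2.5, 2.6); b <- c(2.2, 2.3, 2.4)
  ref <- t.test(a, b, alternative = "greater")
  w <- welchTOneTailed(mean(a), sd(a), 3, mean(b), sd(b), 3)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
})

test_that("montecarloErrors matches analytic propagation for linear fits", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 + 3 * x
  fitSlope <- function(yy) c(slope = unname(coef(lm(yy ~ x))[2]))
  expect_equal(unname(montecarloErrors(fitSlope, y, 0, nDraws = 100,
                                       seed = 94)), 0)
  sd0 <- 0.1
  mc <- montecarloErrors(fitSlope, y, sd0, nDraws = 2000, seed = 94)
  analytic <- sd0 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(mc["slope"] - analytic) / analytic, 0.10)
  mc2 <- montecarloErrors(fitSlope, y, sd0, nDraws = 2000, seed = 94)
  expect_identical(mc, mc2)
})
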