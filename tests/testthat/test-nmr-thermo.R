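test_that("cisPopulation computes per-residue fractions and aggregates", {
  tab <- data.frame(residue = rep(c("E55", "Q56", "E59"), each = 2),
                    isomer = rep(c("cis", "trans"), 3),
                    volume = c(50, 50, 5.7, 100, 5.7, 100))
  cp <- cisPopulation(tab)
  expect_equal(unname(cp$perResidue["E55"]), 0.5)
  expect_equal(unname(cp$perResidue["Q56"]), 5.7 / 105.7, tolerance = 1e-12)
  expect_equal(100 * unname(cp$perResidue["Q56"]), 5.39, tolerance = 1e-2)
  tab2 <- data.frame(residue = rep(c("a", "b", "c"), each = 2),
                     isomer = rep(c("cis", "trans"), 3),
                     volume = c(4, 96, 5, 95, 6, 94))
  cp2 <- cisPopulation(tab2)
  expect_equal(cp2$mean, 0.05, tolerance = 1e-12)
  expect_equal(cp2$sd, 0.01, tolerance = 1e-12)
  # scale invariance
  tab2$volume <- tab2$volume * 7.3
  expect_equal(cisPopulation(tab2)$mean, 0.05, tolerance = 1e-12)
  # a residue with only one peak is excluded and reported
  tab3 <- rbind(tab2, data.frame(residue = "d", isomer = "cis", volume = 5))
  expect_message(cp3 <- cisPopulation(tab3), "excluded")
  expect_equal(cp3$excluded, "d")
})

test_that("equilibriumConstant and its inverse round-trip", {
  expect_equal(equilibriumConstant(0.5), 1)
  expect_equal(equilibriumConstant(0.1), 1 / 9, tolerance = 1e-12)
  set.seed(81)
  p <- runif(50, 0.001, 0.999)
  expect_equal(cisFractionFromK(equilibriumConstant(p)), p,
               tolerance = 1e-15)
  expect_error(equilibriumConstant(1), "strictly inside")
})

test_that("vantHoffFit recovers generating thermodynamics exactly", {
  tt <- seq(275.65, 313.15, length.out = 10)
  R <- 8.314
  K <- exp(-(16000 - tt * 34) / (R * tt))
  vf <- vantHoffFit(tt, K)
  expect_equal(vf$dH, 16000, tolerance = 1e-7)
  expect_equal(vf$dS, 34, tolerance = 1e-9)
  expect_equal(vf$nTemperatures, 10)
  # constant K: dH = 0, dS = R ln K
  vf2 <- vantHoffFit(tt, rep(0.2, 10))
  expect_equal(vf2$dH, 0, tolerance = 1e-8)
  expect_equal(vf2$dS, R * log(0.2), tolerance = 1e-10)
  expect_error(vantHoffFit(c(280, 290), c(0.1, 0.2)), "at least 3")
})

test_that("vantHoffFit recovers truth within 2 SE under ln-K noise", {
  tt <- seq(275.65, 313.15, length.out = 10)
  R <- 8.314
  lnK <- -(16000 - tt * 34) / (R * tt)
  set.seed(82)
  hit <- 0
  for (k in 1:50) {
    Kn <- exp(lnK + rnorm(10, 0, 0.05))
    vf <- vantHoffFit(tt, Kn, lnKSigma = rep(0.05, 10))
    if (abs(vf$dH - 16000) <= 2 * vf$dHSE) hit <- hit + 1
  }
  expect_gte(hit, 42)  # ~95% nominal coverage
})

test_that("populationAtTemperature reproduces hand evaluations and round-trips", {
  expect_equal(populationAtTemperature(0, 0, 300), 0.5)
  expect_equal(100 * populationAtTemperature(14000, 25, 310.15), 8.1,
               tolerance = 0.05)
  expect_equal(100 * populationAtTemperature(16000, 34, 310.15), 10.76,
               tolerance = 0.01)
  tt <- seq(275.65, 313.15, length.out = 10)
  K <- exp(-(16000 - tt * 34) / (8.314 * tt))
  vf <- vantHoffFit(tt, K)
  expect_equal(populationAtTemperature(vf$dH, vf$dS, tt),
               cisFractionFromK(K), tolerance = 1e-12)
})

test_that("temperatureCoefficient flags the -4.5 ppb/K hydrogen-bond rule", {
  tt <- seq(278.15, 310.15, length.out = 8)
  tc <- temperatureCoefficient(tt, 8.5 - 6e-3 * (tt - 278.15))
  expect_equal(tc$slope, -6, tolerance = 1e-9)
  expect_equal(tc$flag, "no persistent H-bond")
  tc0 <- temperatureCoefficient(tt, rep(8.2, 8))
  expect_equal(tc0$slope, 0, tolerance = 1e-9)
  expect_equal(tc0$flag, "possible H-bond")
  set.seed(83)
  shifts <- 8.5 - 3e-3 * tt + rnorm(8, 0, 1e-3)
  tcn <- temperatureCoefficient(tt, shifts)
  ref <- lm(shifts ~ tt)
  expect_equal(tcn$slope, unname(coef(ref)[2]) * 1000, tolerance = 1e-9)
})

test_that("the Cb-Cg shift difference diagnoses the proline isomer", {
  expect_equal(prolineIsomerFromShifts(32.5, 23.0), "cis")      # ~9.5 ppm
  expect_equal(prolineIsomerFromShifts(32.1, 27.6), "trans")    # ~4.5 ppm
  expect_equal(prolineIsomerFromShifts(32.0, 25.0), "ambiguous")
})

test_that("sspScore maps coil, helix and mixtures onto [-1, 1]", {
  refs <- shiftReferences()
  residues <- strsplit("SKSLTENKYSQLDEEQAMEID", "")[[1]]  # no proline
  aa3 <- ProlineEnsembles:::.AA3[residues]
  mkShifts <- function(col) {
    do.call(rbind, lapply(seq_along(aa3), function(i) {
      r <- refs[refs$resname == aa3[i], ]
      data.frame(resid = i, resname = aa3[i], nucleus = r$nucleus,
                 observed = r[[col]], row.names = NULL)
    }))
  }
  coilScores <- sspScore(mkShifts("coil"), refs)
  expect_equal(coilScores$ssp, rep(0, length(aa3)), tolerance = 1e-12)
  helixScores <- sspScore(mkShifts("helix"), refs)
  expect_equal(helixScores$ssp, rep(1, length(aa3)), tolerance = 1e-12)
  half <- mkShifts("coil")
  half$observed <- (mkShifts("helix")$observed + half$observed) / 2
  expect_equal(sspScore(half, refs)$ssp, rep(0.5, length(aa3)),
               tolerance = 1e-12)
  strandScores <- sspScore(mkShifts("strand"), refs)
  expect_equal(strandScores$ssp, rep(-1, length(aa3)), tolerance = 1e-12)
})

test_that("sspScore is antisymmetric under swapping reference roles", {
  # synthetic symmetric reference set: strand offsets mirror helix offsets
  refs <- data.frame(resname = "ALA", nucleus = c("HA", "CA", "CB"),
                     coil = c(4.3, 52.5, 19.0),
                     helix = c(4.3, 52.5, 19.0) + c(0.4, 2.6, 0.5),
                     strand = c(4.3, 52.5, 19.0) - c(0.4, 2.6, 0.5))
  swapped <- refs
  swapped$helix <- refs$strand
  swapped$strand <- refs$helix
  set.seed(84)
  obs <- do.call(rbind, lapply(1:7, function(i)
    data.frame(resid = i, resname = "ALA", nucleus = c("HA", "CA", "CB"),
               observed = c(4.3, 52.5, 19.0) + rnorm(3, 0, 0.8))))
  neg <- obs
  neg$observed <- 2 * c(4.3, 52.5, 19.0) - obs$observed  # negated secondary
  s1 <- sspScore(obs, refs)
  s2 <- sspScore(neg, swapped)
  expect_equal(s2$ssp, -s1$ssp, tolerance = 1e-12)
})
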