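.mkEns <- function(coordsList, weights, atoms) {
  arr <- array(NA_real_, c(nrow(atoms), 3, length(coordsList)))
  for (k in seq_along(coordsList)) arr[, , k] <- coordsList[[k]]
  new("ConformerEnsemble", atoms = atoms, coords = arr,
      weights = weights / sum(weights), metadata = list())
}

test_that("splitByIsomer partitions weights exactly", {
  set.seed(71)
  mk <- function(om) buildBackbone("AAPA", phi = runif(4, -160, -40),
                                   psi = runif(4, 100, 170),
                                   omega = c(180, 180, om, 180))
  confs <- list(mk(0), mk(180), mk(175))
  ens <- .mkEns(lapply(confs, atomCoords), c(0.25, 0.25, 0.5),
                atomTable(confs[[1]]))
  sp <- splitByIsomer(ens, 3)
  expect_equal(unname(sp$populations), c(0.25, 0.75))
  expect_equal(sum(sp$populations), 1)
  expect_equal(sum(priorWeights(sp$trans)), 1, tolerance = 1e-12)
  expect_equal(nFrames(sp$cis), 1)
  # all-trans ensemble: empty cis subensemble, population 0
  ensT <- .mkEns(lapply(confs[2:3], atomCoords), c(0.5, 0.5),
                 atomTable(confs[[1]]))
  spT <- splitByIsomer(ensT, 3)
  expect_equal(unname(spT$populations["cis"]), 0)
  expect_null(spT$cis)
  expect_error(splitByIsomer(ens, 2), "not a proline")
})

test_that("splitByIsomer recovers the generator cis fraction", {
  n <- 600
  cfg <- generatorConfig(nConformers = n, seed = 103, cisFraction = 0.10)
  ens <- cachedEnsemble("binom600", cfg)
  sp <- splitByIsomer(ens, 17)
  expect_lt(abs(sp$populations["cis"] - 0.10), 3 * sqrt(0.09 / n))
})

test_that("weightedKDE is an exact kernel sum that integrates to 1", {
  kde1 <- weightedKDE(5, bandwidth = 0.3)
  expect_equal(kde1$density, dnorm(kde1$grid, 5, 0.3), tolerance = 1e-12)
  set.seed(72)
  v <- rnorm(40, 2, 0.5)
  w <- runif(40); w <- w / sum(w)
  kde <- weightedKDE(v, w)
  integral <- sum(kde$density) * diff(kde$grid[1:2])
  expect_lt(abs(integral - 1), 1e-3)
  # brute-force kernel sum at a few points
  for (x in c(1.5, 2, 2.5)) {
    hand <- sum(w * dnorm(x, v, kde$bandwidth))
    expect_equal(stats::approx(kde$grid, kde$density, x)$y, hand,
                 tolerance = 1e-4)
  }
  # zero-variance input: near-delta, still normalized
  kdeD <- weightedKDE(rep(1, 5))
  expect_lt(abs(sum(kdeD$density) * diff(kdeD$grid[1:2]) - 1), 1e-3)
})

test_that("full-ensemble KDE is the population mixture of subensemble KDEs", {
  cfg <- generatorConfig(nConformers = 60, seed = 73, cisFraction = 0.4)
  ens <- cachedEnsemble("mix60", cfg)
  sp <- splitByIsomer(ens, 17)
  rg <- cvSeries(ens, "rg")$values
  grid <- seq(0.6, 2.2, length.out = 200)
  h <- 0.05
  full <- weightedKDE(rg, priorWeights(ens), bandwidth = h, grid = grid)
  kc <- weightedKDE(rg[sp$labels == "cis"], priorWeights(sp$cis),
                    bandwidth = h, grid = grid)
  kt <- weightedKDE(rg[sp$labels == "trans"], priorWeights(sp$trans),
                    bandwidth = h, grid = grid)
  mix <- sp$populations["cis"] * kc$density +
    sp$populations["trans"] * kt$density
  expect_lt(max(abs(full$density - mix)), 1e-10)
})

test_that("halfSplitUncertainty is the two-point standard deviation", {
  cfg <- generatorConfig(nConformers = 10, seed = 74)
  ens <- sampleEnsemble(cfg)
  # identical halves: duplicate the first half
  dup <- new("ConformerEnsemble", atoms = atomTable(ens),
             coords = atomCoords(ens)[, , c(1:5, 1:5)],
             weights = rep(0.1, 10), metadata = list())
  rgMean <- function(e) sum(priorWeights(e) * cvSeries(e, "rg")$values)
  expect_equal(halfSplitUncertainty(rgMean, dup)$sd, 0, tolerance = 1e-12)
  # forced arithmetic: halves giving 1.0 and 1.2 differ by 0.1414
  fake <- local({
    i <- 0
    function(e) { i <<- i + 1; if (i == 1) 1.0 else 1.2 }
  })
  expect_equal(halfSplitUncertainty(fake, ens)$sd, 0.2 / sqrt(2),
               tolerance = 1e-12)
  hs <- halfSplitUncertainty(rgMean, ens)
  expect_equal(hs$sd, abs(diff(hs$halves)) / sqrt(2), tolerance = 1e-12)
})

test_that("ssClassify assigns canonical basin angles", {
  expect_equal(ssClassify(-60, -45), "helix")
  expect_equal(ssClassify(-120, 130), "strand")
  expect_equal(ssClassify(-75, 150), "coil")   # PPII counts as coil
  expect_equal(ssClassify(60, 45), "coil")
})

test_that("ssPopulations match hand counting on a 3-frame toy", {
  mk <- function(phi, psi) buildBackbone("AAAA", phi = rep(phi, 4),
                                         psi = rep(psi, 4),
                                         omega = rep(180, 4))
  helixF <- mk(-60, -45); strandF <- mk(-120, 130); coilF <- mk(-75, 150)
  ens <- .mkEns(list(atomCoords(helixF), atomCoords(strandF),
                     atomCoords(coilF)),
                c(0.5, 0.25, 0.25), atomTable(helixF))
  sspop <- ssPopulations(ens)
  # residues 2..3 have both angles; termini are excluded
  expect_equal(attr(sspop, "excluded"), c(1L, 4L))
  expect_equal(sspop$helix, rep(0.5, 2), tolerance = 1e-12)
  expect_equal(sspop$strand, rep(0.25, 2), tolerance = 1e-12)
  expect_equal(sspop$coil, rep(0.25, 2), tolerance = 1e-12)
  expect_equal(sspop$coil + sspop$helix + sspop$strand, rep(1, 2),
               tolerance = 1e-12)
})

test_that("cis-only compaction yields a more compact, faster-diffusing cis state", {
  cfg <- generatorConfig(nConformers = 250, seed = 75, cisFraction = 0.5,
                         compaction = 3, compactIsomer = "cis")
  ens <- cachedEnsemble("cisCompact250", cfg)
  sp <- splitByIsomer(ens, 17)
  rgC <- sum(priorWeights(sp$cis) * cvSeries(sp$cis, "rg")$values)
  rgT <- sum(priorWeights(sp$trans) * cvSeries(sp$trans, "rg")$values)
  expect_lt(rgC, rgT)
  dC <- stokesEinsteinD(kirkwoodRh(sp$cis))
  dT <- stokesEinsteinD(kirkwoodRh(sp$trans))
  expect_gt(dC, dT)
})

test_that("subensembleSummary assembles consistent per-isomer summaries", {
  cfg <- generatorConfig(nConformers = 60, seed = 73, cisFraction = 0.4)
  ens <- cachedEnsemble("mix60", cfg)
  ss <- subensembleSummary(ens, 17)
  expect_equal(sum(ss$populations), 1)
  expect_equal(ss$cis$population + ss$trans$population, 1)
  expect_true(is.matrix(ss$trans$contactMap))
  dx <- diff(ss$cis$kde$grid[1:2])
  expect_lt(abs(sum(ss$cis$kde$density) * dx - 1), 1e-3)
})
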