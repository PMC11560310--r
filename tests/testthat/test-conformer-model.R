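test_that("dihedralAngle reproduces coplanar geometry and the vector-formula oracle", {
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  set.seed(11)
  for (k in 1:100) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracleDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-12)
  }
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedralAngle is invariant under rigid-body transforms", {
  set.seed(12)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    a0 <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    q <- randomRigidTransform(p)
    a1 <- dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_lt(abs(a1 - a0), 1e-9)
  }
})

test_that("buildBackbone echoes requested geometry and dihedrals", {
  set.seed(13)
  n <- 6
  phi <- runif(n, -180, 180); psi <- runif(n, -180, 180)
  conf <- buildBackbone(paste(rep("A", n), collapse = ""), phi, psi,
                        omega = rep(180, n))
  at <- atomTable(conf); xyz <- atomCoords(conf)
  # every N-CA bond reproduces the default length
  for (r in 1:n) {
    iN <- which(at$resid == r & at$name == "N")
    iCA <- which(at$resid == r & at$name == "CA")
    expect_equal(sqrt(sum((xyz[iN, ] - xyz[iCA, ])^2)), 0.1458,
                 tolerance = 1e-9)
  }
  bd <- backboneDihedrals(conf)
  expect_equal(abs(bd$omega[-1]), rep(180, n - 1), tolerance = 1e-4)
  expect_equal(bd$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(bd$psi[-n], psi[-n], tolerance = 1e-6)
})

test_that("buildBackbone matches an independent internal-coordinate oracle", {
  set.seed(14)
  for (k in 1:5) {
    phi <- runif(3, -180, 180); psi <- runif(3, -180, 180)
    om <- runif(3, -180, 180)
    conf <- buildBackbone("AAA", phi, psi, om)
    ca <- atomCoords(conf)[atomTable(conf)$name == "CA", ]
    caO <- oracleChainCA(phi, psi, om)
    expect_equal(sqrt(sum((ca[1, ] - ca[3, ])^2)),
                 sqrt(sum((caO[1, ] - caO[3, ])^2)), tolerance = 1e-6)
  }
  expect_error(buildBackbone("AXA", rep(0, 3), rep(0, 3), rep(180, 3)),
               "unknown residue")
  expect_error(buildBackbone("AAA", c(0, 0), rep(0, 3), rep(180, 3)),
               "residue")
})

test_that("classifyIsomer uses the 90-degree boundary with trans at the edge", {
  expect_equal(classifyIsomer(0), "cis")
  expect_equal(classifyIsomer(180), "trans")
  expect_equal(classifyIsomer(-91), "trans")
  expect_equal(classifyIsomer(90), "trans")
  expect_equal(classifyIsomer(-89.9), "cis")
})

test_that("classifyIsomer recovers construction labels on built chains", {
  set.seed(15)
  for (k in 1:20) {
    target <- sample(c(0, 180), 1)
    conf <- buildBackbone("AAPA", phi = runif(4, -160, -40),
                          psi = runif(4, 100, 170),
                          omega = c(180, 180, target, 180))
    expect_equal(classifyIsomer(backboneDihedrals(conf)$omega[3]),
                 if (target == 0) "cis" else "trans")
  }
})

test_that("radiusOfGyration matches hand cases, brute force, and scaling", {
  at <- data.frame(name = c("N", "CA", "C", "O"), resid = 1,
                   resname = "ALA", element = c("N", "C", "C", "O"),
                   mass = c(1, 1, 1, 1))
  two <- new("Conformer", atoms = at[1:4, ],
             coords = rbind(c(0, 0, 0), c(0, 0, 0.2),
                            c(0, 0, 0), c(0, 0, 0.2)))
  # two distinct positions with equal mass, 0.2 nm apart -> Rg 0.1
  expect_equal(radiusOfGyration(two), 0.1, tolerance = 1e-12)
  same <- new("Conformer", atoms = at,
              coords = matrix(0.3, 4, 3))
  expect_equal(radiusOfGyration(same), 0, tolerance = 1e-12)
  set.seed(16)
  conf <- buildBackbone("AA", runif(2, -180, 180), runif(2, -180, 180),
                        rep(180, 2))
  expect_equal(radiusOfGyration(conf),
               oracleRg(atomCoords(conf), atomTable(conf)$mass),
               tolerance = 1e-12)
  scaled <- new("Conformer", atoms = atomTable(conf),
                coords = atomCoords(conf) * 3)
  expect_equal(radiusOfGyration(scaled), 3 * radiusOfGyration(conf),
               tolerance = 1e-12)
})

test_that("endToEnd is the CA1-CAn distance and rigid-transform invariant", {
  set.seed(17)
  conf <- buildBackbone("AAAA", runif(4, -180, 180), runif(4, -180, 180),
                        rep(180, 4))
  ca <- atomCoords(conf)[atomTable(conf)$name == "CA", ]
  expect_equal(endToEnd(conf), sqrt(sum((ca[1, ] - ca[4, ])^2)),
               tolerance = 1e-12)
  moved <- new("Conformer", atoms = atomTable(conf),
               coords = randomRigidTransform(atomCoords(conf)))
  expect_equal(endToEnd(moved), endToEnd(conf), tolerance = 1e-9)
})

test_that("dihedralCorrelation matches limits and term-by-term summation", {
  n <- 6
  conf <- buildBackbone(paste(rep("A", n), collapse = ""),
                        phi = rep(-70, n), psi = rep(140, n),
                        omega = rep(180, n))
  # all psi equal -> n_pairs (n - 2 measurable pairs)
  expect_equal(dihedralCorrelation(conf), n - 2, tolerance = 1e-9)
  alt <- buildBackbone(paste(rep("A", n), collapse = ""),
                       phi = rep(-70, n),
                       psi = rep(c(150, -30), length.out = n),
                       omega = rep(180, n))
  expect_equal(dihedralCorrelation(alt), 0, tolerance = 1e-9)
  set.seed(18)
  psi <- runif(n, -180, 180)
  conf2 <- buildBackbone(paste(rep("A", n), collapse = ""),
                         phi = rep(-70, n), psi = psi, omega = rep(180, n))
  hand <- sum((1 + cos(diff(psi[-n]) * pi / 180)) / 2)
  expect_equal(dihedralCorrelation(conf2), hand, tolerance = 1e-9)
})

test_that("caContactMap is symmetric, brute-force correct, and monotone in cutoff", {
  cfg <- generatorConfig(nConformers = 5, seed = 21, cisFraction = 0.5)
  ens <- cachedEnsemble("tiny5", cfg)
  cm <- caContactMap(ens, cutoff = 0.8)
  expect_identical(cm, t(cm))
  expect_equal(diag(cm), rep(1, nrow(cm)))
  # brute-force per-frame counting
  cai <- which(atomTable(ens)$name == "CA")
  nres <- length(cai)
  brute <- matrix(0, nres, nres)
  for (k in 1:5) {
    x <- atomCoords(ens)[cai, , k]
    for (i in 1:nres) for (j in 1:nres)
      if (sqrt(sum((x[i, ] - x[j, ])^2)) < 0.8)
        brute[i, j] <- brute[i, j] + 0.2
  }
  diag(brute) <- 1
  expect_equal(cm, brute, tolerance = 1e-12)
  # adjacent residues are always in contact at 0.8 nm
  expect_equal(cm[cbind(1:(nres - 1), 2:nres)], rep(1, nres - 1))
  cmBig <- caContactMap(ens, cutoff = 1.2)
  expect_true(all(cmBig - cm >= -1e-15))
  expect_error(caContactMap(ens, cutoff = 0), "cutoff")
})

test_that("cvSeries extracts per-frame values consistent with per-frame calls", {
  cfg <- generatorConfig(nConformers = 5, seed = 21, cisFraction = 0.5)
  ens <- cachedEnsemble("tiny5", cfg)
  rg <- cvSeries(ens, "rg")
  expect_length(rg$values, 5)
  expect_equal(rg$units, "nm")
  expect_equal(rg$values[3], radiusOfGyration(getConformer(ens, 3)),
               tolerance = 1e-12)
  zeta <- cvSeries(ens, "zeta:17")
  for (k in 1:5)
    expect_equal(zeta$values[k], zetaAngle(getConformer(ens, k), 17),
                 tolerance = 1e-12)
  psi <- cvSeries(ens, "psi:10")
  bd <- backboneDihedrals(getConformer(ens, 2))
  expect_equal(psi$values[2], bd$psi[10], tolerance = 1e-12)
  expect_error(cvSeries(ens, "zeta:5"), "not a proline")
  expect_error(cvSeries(ens, "nope"), "unknown CV")
  # identical frames give identical values
  ens3 <- new("ConformerEnsemble", atoms = atomTable(ens),
              coords = atomCoords(ens)[, , c(1, 1, 1)],
              weights = rep(1 / 3, 3), metadata = list())
  expect_equal(diff(range(cvSeries(ens3, "rg")$values)), 0)
})
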