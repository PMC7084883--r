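test_that("default coefficients and their derived base-damage values", {
  co <- damageCoefficients()
  expect_identical(co$kSsb, 5.66e-12)
  expect_identical(co$kDsb, 1.61e-13)
  expect_identical(co$kBd, 5.66e-12 * 1.3)
  expect_identical(co$kCbd, 1.61e-13 * 1.3^2)
  expect_equal(signif(co$kBd, 3), 7.36e-12)
  expect_equal(signif(co$kCbd, 3), 2.72e-13)
  expect_error(damageCoefficients(kSsb = -1), "kSsb")
})

test_that("yields follow k * N / E_dep", {
  # 1000 events depositing 10 keV total -> Y_SSB = 5.66e-10
  es <- make_event_set(matrix(runif(3000, -50, 50), ncol = 3), edep = 10)
  expect_identical(nEvents(es), 1000L)
  expect_equal(eDepKeV(es), 10)
  expect_equal(yieldSSB(es), 5.66e-10)
  expect_equal(yieldBD(es), 5.66e-10 * 1.3)

  # linkage-based yields with a synthetic count: n_link / E_dep scaling
  es2 <- generateTrack(trackParams(nEvents = 400, meanFreePathNm = 2, seed = 3))
  lr <- countLinkages(es2, lcBp = 10)
  expect_equal(yieldDSB(lr, es2), 1.61e-13 * nLink(lr) / eDepKeV(es2))
  expect_equal(as.numeric(yieldCBD(lr, es2)),
               1.61e-13 * 1.3^2 * nLink(lr) / eDepKeV(es2))
  # hand-computed example: 100 links over 10 keV
  expect_equal(1.61e-13 * 100 / 10, 1.61e-12)

  # empty set yields zero; events with zero energy are impossible, but a
  # zero-energy guard protects against corrupted inputs
  expect_identical(yieldSSB(EventSet()), 0)
  broken <- es2
  broken@eDepKeV <- 0
  expect_error(perLink <- yieldDSB(lr, broken), "undefined yield")
})

test_that("base-damage to strand-break yield ratios are coefficient-forced", {
  for (s in 1:10) {
    es <- generateTrack(trackParams(nEvents = sample(10:500, 1), seed = s))
    expect_equal(yieldBD(es) / yieldSSB(es), 1.3, tolerance = 1e-15)
    lr <- countLinkages(es)
    if (nLink(lr) > 0)
      expect_equal(as.numeric(yieldCBD(lr, es)) / yieldDSB(lr, es), 1.3^2,
                   tolerance = 1e-15)
  }
})

test_that("splitByClass conserves the parent yield", {
  # hand-built halves
  blob6 <- generateBlob(6, radiusNm = 1, seed = 1)
  cf6 <- classFractions(countLinkages(blob6), bdScheme())
  sp <- splitByClass(2e-12, cf6, "dsb")
  expect_equal(unname(sp["DSB"]), 2e-12)
  expect_equal(sum(sp), 2e-12)

  for (s in 1:5) {
    es <- generateTrack(trackParams(nEvents = 500, meanFreePathNm = 1.5,
                                    seed = s))
    lr <- countLinkages(es)
    cf <- classFractions(lr, bdScheme())
    y <- yieldDSB(lr, es)
    expect_equal(sum(splitByClass(y, cf, "dsb")), y, tolerance = 1e-12)
    yb <- as.numeric(yieldCBD(lr, es))
    expect_equal(sum(splitByClass(yb, cf, "bd")), yb, tolerance = 1e-12)
  }
  expect_error(splitByClass(1e-12, classFractions(countLinkages(blob6),
                                                  sbScheme()), "bd"),
               "no labels")
})

test_that("detection efficiency thins per-lesion yields by eta^k", {
  rep0 <- runAnalysis(params = trackParams(nEvents = 500,
                                           meanFreePathNm = 1.5, seed = 8),
                      arpLoss = TRUE)
  # eta = 1 is the identity on every corrected field
  rep1 <- applyDetection(rep0, 1)
  corr <- rep1@detection$corrected
  expect_equal(corr$yBD, yields(rep0)$yBD)
  expect_equal(corr$yCBD, yields(rep0)$yCBD)
  expect_equal(corr$perLabel$dsb, yields(rep0)$perLabel$dsb)
  expect_equal(corr$perLabel$bd, yields(rep0)$perLabel$bd)

  # eta = 0.9: Y_BD x 0.9, Y_cBD x 0.81, label with one BD x 0.9
  rep9 <- applyDetection(rep0, 0.9)
  corr <- rep9@detection$corrected
  y0 <- yields(rep0)
  expect_equal(corr$yBD, y0$yBD * 0.9)
  expect_equal(corr$yCBD, y0$yCBD * 0.81)
  expect_equal(corr$yCBDStar, y0$yCBDStar * 0.81)
  expect_equal(unname(corr$perLabel$dsb["DSB"]),
               unname(y0$perLabel$dsb["DSB"]))
  expect_equal(unname(corr$perLabel$dsb["DSB/BD"]),
               unname(y0$perLabel$dsb["DSB/BD"]) * 0.9)
  expect_equal(unname(corr$perLabel$dsb["DSB/BD/BD"]),
               unname(y0$perLabel$dsb["DSB/BD/BD"]) * 0.81)
  expect_equal(unname(corr$perLabel$bd["BD/BD/BD"]),
               unname(y0$perLabel$bd["BD/BD/BD"]) * 0.9^3)

  # strict two-case mode scales only the base-damage stream
  repS <- applyDetection(rep0, 0.9, mode = "strict")
  corrS <- repS@detection$corrected
  expect_equal(corrS$perLabel$dsb, y0$perLabel$dsb)
  expect_equal(corrS$perLabel$bd, y0$perLabel$bd * 0.81)

  expect_error(applyDetection(rep0, 1.2), "eta")
  expect_error(applyDetection(rep0, -0.1), "eta")
})

test_that("per-lesion thinning matches a Monte Carlo labelling simulation", {
  # a site carrying k base damages is seen iff all k probes label, each
  # with probability eta -> expected detected share is eta^k
  eta <- 0.9
  set.seed(123)
  for (k in 1:3) {
    detected <- mean(replicate(20000, all(runif(k) < eta)))
    expect_equal(detected, eta^k, tolerance = 0.02)
  }
})

test_that("probe-size detection loss is the 10 bp / 5 bp yield difference", {
  expect_equal(detectionLoss(4e-12, 1e-12), 3e-12)
  expect_equal(detectionLoss(2e-12, 2e-12), 0)
  expect_error(detectionLoss(1e-12, 2e-12), "same event set")
  expect_error(detectionLoss(structure(1e-12, lcBp = 3), 0), "expected 10 bp")

  # a blob tighter than 5 bp: every linkage also exists at 5 bp -> loss
  # removes the entire clustered yield
  blob <- generateBlob(30, radiusNm = 0.8, seed = 6)
  y10 <- yieldCBD(countLinkages(blob, lcBp = 10), blob)
  y5 <- yieldCBD(countLinkages(blob, lcBp = 5), blob)
  expect_equal(detectionLoss(y10, y5), 0)

  # on generic tracks the loss is within [0, Y_cBD(10 bp)]
  for (s in 1:5) {
    es <- generateTrack(trackParams(nEvents = 300, meanFreePathNm = 2,
                                    seed = s))
    y10 <- yieldCBD(countLinkages(es, lcBp = 10), es)
    y5 <- yieldCBD(countLinkages(es, lcBp = 5), es)
    star <- detectionLoss(y10, y5)
    expect_gte(star, 0)
    expect_lte(star, as.numeric(y10))
  }
})
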