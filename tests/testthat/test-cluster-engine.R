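test_that("pairs at, inside and outside the linkage distance", {
  two <- function(sep) make_event_set(rbind(c(0, 0, 0), c(sep, 0, 0)))
  expect_identical(nLink(countLinkages(two(3.0), lcBp = 10)), 1L)
  expect_identical(nLink(countLinkages(two(3.5), lcBp = 10)), 0L)
  # closed boundary: separation exactly L_c counts
  expect_identical(nLink(countLinkages(two(3.4), lcBp = 10)), 1L)

  # three mutually close events -> all C(3,2) pairs
  tri <- make_event_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0)))
  expect_identical(nLink(countLinkages(tri, lcBp = 10)), 3L)

  expect_identical(nLink(countLinkages(EventSet(), lcBp = 10)), 0L)
})

test_that("n_cl counts the pair plus events within L_c of the midpoint", {
  # isolated pair, nothing else
  pair <- make_event_set(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_identical(sites(countLinkages(pair))$n_cl, 2L)

  # third event exactly at L_c from the centre: closed boundary includes it
  # (pair symmetric about the origin so the midpoint is exact)
  trio <- make_event_set(rbind(c(-1, 0, 0), c(1, 0, 0), c(3.4, 0, 0)))
  lr <- countLinkages(trio, lcBp = 10)
  s <- sites(lr)
  pairSite <- s[s$i == 1 & s$j == 2, ]
  expect_identical(pairSite$n_cl, 3L)

  # blob: every site sees all n events
  blob <- generateBlob(24, radiusNm = 1, seed = 2)
  lr <- countLinkages(blob)
  expect_true(all(sites(lr)$n_cl == 24L))
  expect_identical(computeNcl(sites(lr), blob), sites(lr)$n_cl)
})

test_that("grid search equals the brute-force oracle on random clouds", {
  set.seed(99)
  for (s in 1:25) {
    n <- sample(c(0, 1, 2, 5, 50, 200, 500), 1)
    es <- random_event_set(n, boxNm = sample(c(4, 10, 30), 1), seed = s)
    pts <- as.matrix(events(es)[, c("x_nm", "y_nm", "z_nm")])
    lr <- countLinkages(es, lcBp = 10)
    exp_pairs <- oracle_pairs_within(pts, 3.4)
    expect_identical(nLink(lr), nrow(exp_pairs))
    if (nLink(lr) > 0) {
      got <- as.matrix(sites(lr)[, c("i", "j")])
      expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   exp_pairs, ignore_attr = TRUE)
      # n_cl oracle on a site subsample keeps the O(sites x n) scan cheap
      pick <- sample(nLink(lr), min(nLink(lr), 200))
      ctr <- as.matrix(sites(lr)[pick, c("cx_nm", "cy_nm", "cz_nm")])
      expect_identical(sites(lr)$n_cl[pick], oracle_n_within(pts, ctr, 3.4))
    }
  }
})

test_that("counts are invariant under permutation and rigid motion", {
  es <- random_event_set(150, boxNm = 8, seed = 13)
  lr <- countLinkages(es)

  set.seed(31)
  perm <- sample(nEvents(es))
  lr_p <- countLinkages(EventSet(events(es)[perm, ]))
  expect_identical(nLink(lr_p), nLink(lr))
  expect_identical(sort(sites(lr_p)$n_cl), sort(sites(lr)$n_cl))

  R <- random_rotation(7)
  pts <- as.matrix(events(es)[, c("x_nm", "y_nm", "z_nm")])
  moved <- es
  rot <- pts %*% t(R)
  moved <- EventSet(transform(events(es), x_nm = rot[, 1] + 100,
                              y_nm = rot[, 2] - 50, z_nm = rot[, 3] + 7))
  lr_m <- countLinkages(moved)
  expect_identical(nLink(lr_m), nLink(lr))
  expect_identical(sort(sites(lr_m)$n_cl), sort(sites(lr)$n_cl))
})

test_that("linkage and n_cl counts are monotone in L_c", {
  es <- random_event_set(300, boxNm = 10, seed = 17)
  lcs <- c(3, 5, 10, 15)
  nl <- vapply(lcs, function(lc) nLink(countLinkages(es, lcBp = lc)),
               integer(1))
  expect_true(all(diff(nl) >= 0))

  # for fixed sites, n_cl grows with the counting radius
  lr <- countLinkages(es, lcBp = 5)
  n5 <- computeNcl(sites(lr), es, lcBp = 5)
  n10 <- computeNcl(sites(lr), es, lcBp = 10)
  expect_true(all(n10 >= n5))
})

test_that("greedy pairing uses each event at most once", {
  es <- random_event_set(200, boxNm = 6, seed = 23)
  lr_all <- countLinkages(es, pairing = "all")
  lr_g <- countLinkages(es, pairing = "greedy")
  expect_lte(nLink(lr_g), nLink(lr_all))
  ids <- c(sites(lr_g)$i, sites(lr_g)$j)
  expect_identical(anyDuplicated(ids), 0L)
  # greedy is deterministic
  lr_g2 <- countLinkages(EventSet(events(es)), pairing = "greedy")
  expect_identical(sites(lr_g2), sites(lr_g))
})

test_that("classification bins follow the half-open scheme definitions", {
  bd <- bdScheme()
  expect_identical(bd@lower, c(2L, 11L, 20L))
  expect_identical(bd@upper, c(11L, 20L, 29L))
  sb <- sbScheme()
  expect_identical(sb@lower, c(2L, 14L, 26L))
  expect_identical(sb@upper, c(14L, 26L, 38L))

  expect_identical(as.character(classifySite(c(2, 6, 10, 11, 15, 19, 20, 24, 28), bd)),
                   rep(c("DSB", "DSB/BD", "DSB/BD/BD"), each = 3))
  expect_identical(as.character(classifySite(c(6, 15, 24), bd, stream = "bd")),
                   c("BD/BD", "BD/BD/BD", "BD/BD/BD/BD"))
  expect_identical(as.character(classifySite(c(6, 15, 27, 30), sb)),
                   c("DSB", "DSB+", "DSB++", "DSB++"))

  # overflow clamps to the most complex label and is flagged
  lab <- classifySite(c(10, 29, 100), bd)
  expect_identical(as.character(lab), c("DSB", "DSB/BD/BD", "DSB/BD/BD"))
  expect_identical(attr(lab, "overflow"), c(FALSE, TRUE, TRUE))
  expect_error(classifySite(1, bd), "n_cl < 2")
})

test_that("class fractions sum to one with the overflow bucket", {
  # all sites in one bin
  blob6 <- generateBlob(6, radiusNm = 1, seed = 5)
  cf <- classFractions(countLinkages(blob6), bdScheme())
  expect_equal(fractions(cf)$fraction, c(1, 0, 0))

  # random tracks: normalization and agreement with direct recomputation
  for (s in 1:5) {
    es <- generateTrack(trackParams(nEvents = 500, meanFreePathNm = 2,
                                    seed = s))
    lr <- countLinkages(es)
    cf <- classFractions(lr, bdScheme())
    expect_equal(sum(fractions(cf)$fraction) + overflowFraction(cf), 1,
                 tolerance = 1e-12)
    ncl <- sites(lr)$n_cl
    expect_equal(fractions(cf)$fraction,
                 c(mean(ncl >= 2 & ncl < 11), mean(ncl >= 11 & ncl < 20),
                   mean(ncl >= 20 & ncl < 29)))
    expect_equal(overflowFraction(cf), mean(ncl >= 29))
  }

  # no sites at all -> zero fractions, flagged empty
  lone <- make_event_set(rbind(c(0, 0, 0), c(100, 0, 0)))
  cf0 <- classFractions(countLinkages(lone), bdScheme())
  expect_true(cf0@empty)
  expect_equal(fractions(cf0)$fraction, c(0, 0, 0))
})

test_that("two equally filled bins give fractions of one half", {
  b6 <- events(generateBlob(6, radiusNm = 1, seed = 1))
  b15 <- events(generateBlob(15, radiusNm = 1, seed = 2))
  b15[, c("x_nm")] <- b15$x_nm + 1000  # far apart: clusters independent
  es <- EventSet(rbind(b6, b15))
  lr <- countLinkages(es)
  cf <- classFractions(lr, bdScheme())
  # C(6,2)=15 sites with n_cl=6 and C(15,2)=105 with n_cl=15
  expect_equal(fractions(cf)$nSites, c(15L, 105L, 0L))
  expect_equal(fractions(cf)$fraction, c(15, 105, 0) / 120)
})

test_that("denser tracks shift fraction mass to higher-complexity bins", {
  complexMass <- function(mfp, s) {
    es <- generateTrack(trackParams(nEvents = 400, meanFreePathNm = mfp,
                                    seed = s))
    cf <- classFractions(countLinkages(es), bdScheme())
    sum(fractions(cf)$fraction[-1]) + overflowFraction(cf)
  }
  wins <- vapply(1:20, function(s) complexMass(1, s) >= complexMass(6, s),
                 logical(1))
  expect_gt(mean(wins), 0.5)
})
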