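test_that("circular statistics match the resultant-vector oracle", {
  set.seed(51)
  for (i in 1:50) {
    th <- runif(20, 0, 360)
    expect_equal(circularMean(th), oracleCircMean(th), tolerance = 1e-9)
  }
  ## two angles theta and theta + 20 average to theta + 10
  expect_equal(circularMean(c(350, 10)), 0)
  expect_equal(circularMean(c(170, 190)), 180)
  expect_equal(circularSd(rep(42, 10)), 0)
})

test_that("circular deviation is symmetric, bounded and wrap-aware", {
  expect_equal(circularDiff(10, 350), 20)
  expect_equal(circularDiff(100, 350), 110)
  expect_equal(circularDiff(0, 180), 180)
  set.seed(52)
  a <- runif(100, 0, 360); b <- runif(100, 0, 360)
  expect_equal(circularDiff(a, b), circularDiff(b, a))
  expect_true(all(circularDiff(a, b) >= 0 & circularDiff(a, b) <= 180))
  expect_true(all(circularDiff(a, a + 360) < 1e-9))
})

test_that("circular mean recovers a von Mises location parameter", {
  ## direct parameter-recovery check on the statistic the profile uses
  kappa <- 10; n <- 50; mu <- 200
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    th <- rvonmises(n, mu, kappa)
    est <- circularMean(th)
    tol <- 3 * circularSd(th) / sqrt(n)
    if (circularDiff(est, mu) <= tol) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("reference profile reproduces fixed construction values", {
  prof <- buildReferenceProfile(g4Fixture("left1b"), "left")
  st <- prof@stats
  ## a single idealized core: zero circular spread everywhere
  expect_lt(max(st$sd), 1e-6)
  expect_equal(st$mean[st$angle == "chi"],
               attr(g4Fixture("left1b"), "groundTruth")$spec$chi,
               tolerance = 1e-4)
  expect_equal(st$mean[st$angle == "P"], 162, tolerance = 1e-4)
  expect_equal(prof@majorityPucker, "C2'-endo")
  ## pooling the same structure twice changes nothing
  prof2 <- buildReferenceProfile(list(g4Fixture("left1b"),
                                      g4Fixture("left1b")), "left")
  expect_equal(prof2@stats$mean, st$mean, tolerance = 1e-9)
  expect_equal(prof2@stats$n, 2L * st$n)
})

test_that("bulged or wrong-handed structures cannot enter a profile", {
  expect_error(buildReferenceProfile(g4Fixture("left_bulged"), "left"),
               "bulge")
  expect_error(buildReferenceProfile(g4Fixture("right"), "left"),
               "right-handed")
})

test_that("transition extraction follows the step convention", {
  m <- g4Fixture("left_bulged")
  ann <- g4Annotation("left_bulged")
  rec <- extractTransitions(ann$core, ann$elements, m)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$side, c("previous", "next"))
  b <- ann$elements[ann$elements$kind == "bulge", ]
  expect_equal(rec$core_residue[rec$side == "previous"], b$previous_core)
  expect_equal(rec$core_residue[rec$side == "next"], b$next_core)
  expect_false(anyNA(as.matrix(rec[, c("epsilon", "zeta", "alpha+1",
                                       "beta+1", "gamma+1")])))
  ## skip convention: one record per bulge, measured on the guanines
  rs <- extractTransitions(ann$core, ann$elements, m, "skip")
  expect_equal(nrow(rs), 1)
  expect_equal(rs$side, "skip")
  ## no-bulge core gives an empty collection
  ann0 <- g4Annotation("left1b")
  expect_equal(nrow(extractTransitions(ann0$core, ann0$elements,
                                       g4Fixture("left1b"))), 0)
})

test_that("deviation flags respect wrap-around and the threshold", {
  prof <- buildReferenceProfile(g4Fixture("left1b"), "left")
  rec <- data.frame(bulge_id = "x", side = "previous", core_residue = 1,
                    check.names = FALSE)
  ref <- setNames(prof@stats$mean, prof@stats$angle)
  rec[["epsilon"]] <- (ref[["epsilon"]] + 20) %% 360   # small, wraps fine
  rec[["zeta"]] <- (ref[["zeta"]] + 110) %% 360        # flagged
  rec[["alpha+1"]] <- NA                               # undefined
  rec[["beta+1"]] <- ref[["beta+1"]]
  rec[["gamma+1"]] <- (ref[["gamma+1"]] - 61) %% 360   # just past threshold
  dev <- compareToReference(rec, prof, 60)
  expect_equal(nrow(dev), 5)
  expect_equal(dev$flagged[dev$angle == "epsilon"], FALSE)
  expect_equal(dev$flagged[dev$angle == "zeta"], TRUE)
  expect_equal(dev$flagged[dev$angle == "alpha+1"], FALSE)
  expect_true(is.na(dev$deviation[dev$angle == "alpha+1"]))
  expect_equal(dev$flagged[dev$angle == "gamma+1"], TRUE)
  ## raising the threshold never increases the flagged count
  counts <- vapply(c(0, 30, 60, 90, 120, 180), function(th)
    sum(compareToReference(rec, prof, th)$flagged), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("pucker comparison flags class changes against the majority", {
  m <- g4Fixture("left_bulged")
  ann <- g4Annotation("left_bulged")
  prof <- buildReferenceProfile(g4Fixture("left1b"), "left")
  pk <- comparePucker(ann$core, ann$elements, m, prof)
  expect_equal(nrow(pk), 2)
  expect_true(all(pk$pucker_class == "C2'-endo"))
  expect_false(any(pk$altered))
  expect_true(all(pk$z_c2 > 0))
  ## a C3'-endo core registers as altered against a C2'-endo profile
  m3 <- buildG4(g4BuildSpec(n_tetrads = 2, blocks = 2, twist = 30,
                            sugar_P = 18, bulges = list(c(2, 1))))
  ann3 <- annotateG4(m3)
  pk3 <- comparePucker(ann3$core, ann3$elements, m3, prof)
  expect_true(all(pk3$altered))
  expect_true(all(pk3$pucker_class == "C3'-endo"))
  expect_true(all(pk3$z_c3 > 0))
})

test_that("reports serialize losslessly and count correctly", {
  ann <- g4Annotation("left2b_3bulge")
  m <- g4Fixture("left2b_3bulge")
  prof <- buildReferenceProfile(g4Fixture("left2b"), "left")
  rec <- extractTransitions(ann$core, ann$elements, m)
  expect_equal(nrow(rec), 6)           # 3 bulges x 2 sides
  dev <- compareToReference(rec, prof)
  expect_equal(nrow(dev), 30)          # x 5 angles
  pk <- comparePucker(ann$core, ann$elements, m, prof)
  jp <- withr::local_tempfile(fileext = ".json")
  rep1 <- renderReport(dev, pk, ann$core, profile = prof, jsonPath = jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$summary$n_deviation_rows, nrow(dev))
  expect_equal(back$summary$n_flagged, sum(dev$flagged))
  expect_equal(back$deviations$deviation, dev$deviation,
               tolerance = 1e-12)
  ## empty report stays valid
  dev0 <- compareToReference(rec[0, ], prof)
  rep0 <- renderReport(dev0, pk[0, ], ann$core)
  expect_equal(rep0$summary$n_deviation_rows, 0)
})
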