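test_that("dihedral reproduces planar references and IUPAC range", {
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), 0)
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)), 180)
  expect_equal(dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1),
                        range = "180"), 90)
})

test_that("dihedral agrees with an independent projection oracle", {
  set.seed(11)
  for (i in 1:500) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    ok <- tryCatch({
      d1 <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next  # degenerate draw
    d2 <- oracleDihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_lt(min(abs(d1 - d2), 360 - abs(d1 - d2)), 1e-6)
  }
})

test_that("degenerate torsion geometry raises informative errors", {
  expect_error(dihedral(c(0,0,0), c(0,0,0), c(1,0,0), c(1,1,0)),
               "coincide")
  expect_error(dihedral(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "colinear")
})

test_that("base plane fit matches a brute-force SVD oracle", {
  m <- g4Fixture("left1b")
  res <- getResidue(m, "A", 1)
  pl <- basePlane(res)
  ## flat idealized guanine: all ring atoms essentially in-plane
  ring <- res[res$elety %in% c("N9","C8","N7","C5","C6","N1","C2","N3","C4"),
              c("x", "y", "z")]
  expect_lt(pl$rms, 1e-6)
  ## oracle: SVD plane through the same atoms
  ctr <- colMeans(ring)
  sv <- svd(sweep(as.matrix(ring), 2, ctr))
  n2 <- sv$v[, 3]
  expect_lt(min(vlen(pl$normal - n2), vlen(pl$normal + n2)), 1e-6)
  ## equivariance under a known rotation
  set.seed(3)
  R <- randomRotation()
  res2 <- res
  xyz2 <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
  res2$x <- xyz2[, 1]; res2$y <- xyz2[, 2]; res2$z <- xyz2[, 3]
  pl2 <- basePlane(res2)
  expect_lt(min(vlen(pl2$normal - R %*% pl$normal),
                vlen(pl2$normal + R %*% pl$normal)), 1e-6)
  ## perturbed plane rms bounded and consistent with the SVD oracle
  res3 <- res
  set.seed(4)
  res3$z <- res3$z + rnorm(nrow(res3), sd = 0.05)
  pl3 <- basePlane(res3)
  expect_lt(pl3$rms, 0.05 * 3)
})

test_that("torsions are invariant under global rigid motion", {
  m <- g4Fixture("left1b")
  g1 <- geometryTable(m)
  set.seed(7)
  m2 <- rigidMove(m, randomRotation(), c(12, -8, 5))
  g2 <- geometryTable(m2)
  for (col in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                "chi", "P")) {
    d <- abs(g1[[col]] - g2[[col]])
    d <- pmin(d, 360 - d)
    expect_lt(max(d, na.rm = TRUE), 1e-8)
  }
})

test_that("terminal residues have undefined boundary torsions", {
  m <- g4Fixture("left1b")
  g <- geometryTable(m)
  expect_true(is.na(g$alpha[1]))             # 5' end: no previous O3'
  expect_true(is.na(g$epsilon[nrow(g)]))     # 3' end: no next P
  expect_true(is.na(g$zeta[nrow(g)]))
  expect_false(anyNA(g$chi))
})

test_that("chi and glycosidic class follow the anti window", {
  m <- buildG4(g4BuildSpec(n_tetrads = 2, blocks = 2, twist = 30,
                           chi = 240))
  g <- geometryTable(m)
  core <- g[g$base == "G", ]
  expect_true(all(abs(core$chi - 240) < 1e-3))
  expect_true(all(core$glycosidic == "anti"))
  expect_equal(glycosidicClass(100), "syn")
  expect_equal(glycosidicClass(171), "anti")
  expect_equal(glycosidicClass(311), "syn")
})

test_that("stacking twist recovers construction and identity", {
  ann <- g4Annotation("left1b")
  st <- ann$core@stepTwists
  expect_equal(st$twist, -27, tolerance = 1e-3)
  m <- g4Fixture("left1b")
  r <- getResidue(m, "A", 1)
  expect_equal(stackingTwist(r, r, c(0, 0, 1)), 0)
  expect_error(stackingTwist(r, r, c(0, 0, 0)), "nonzero")
})

test_that("superposition matches the quaternion oracle and is symmetric", {
  set.seed(21)
  for (i in 1:50) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    B <- matrix(rnorm(30, sd = 4), 10, 3)
    r1 <- superposeRmsd(A, B)$rmsd
    expect_lt(abs(r1 - oracleRmsd(A, B)), 1e-8)
    expect_lt(abs(r1 - superposeRmsd(B, A)$rmsd), 1e-8)
    expect_equal(det(superposeRmsd(A, B)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition of rigidly moved copies gives zero rmsd", {
  set.seed(22)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_equal(superposeRmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  B <- A %*% t(randomRotation())
  B <- sweep(B, 2, c(-4, 7, 1))
  fit <- superposeRmsd(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_error(superposeRmsd(A, B[1:5, ]), "correspondence")
})

test_that("superposition cross-checks against bio3d", {
  set.seed(23)
  A <- matrix(rnorm(45, sd = 4), 15, 3)
  B <- matrix(rnorm(45, sd = 4), 15, 3)
  r_pkg <- superposeRmsd(A, B)$rmsd
  r_b3d <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)),
                       fit = TRUE)
  expect_equal(r_pkg, r_b3d, tolerance = 1e-3)
})

test_that("ensemble pairwise rmsd matches enumeration and noise theory", {
  m <- g4Fixture("left1b")
  ident <- ensemblePairwiseRmsd(list(m, m, m))
  expect_equal(ident$mean, 0, tolerance = 1e-12)
  expect_equal(ident$sd, 0, tolerance = 1e-12)
  ## noisy ensemble: per-atom displacement differences are N(0, 2 sigma^2)
  ## in each coordinate, so the mean pairwise rmsd sits near
  ## sigma * sqrt(6) (slightly below: fitting absorbs 6 rigid degrees of
  ## freedom)
  sigma <- 0.3
  set.seed(31)
  ens <- lapply(1:10, function(k) {
    a <- atomTable(m)
    a$x <- a$x + rnorm(nrow(a), sd = sigma)
    a$y <- a$y + rnorm(nrow(a), sd = sigma)
    a$z <- a$z + rnorm(nrow(a), sd = sigma)
    StructureModel(a, k, "noisy")
  })
  r <- ensemblePairwiseRmsd(ens)
  expect_equal(r$n_pairs, choose(10, 2))
  ## direct enumeration oracle
  manual <- mean(apply(utils::combn(10, 2), 2, function(p) {
    A <- cbind(atomTable(ens[[p[1]]])$x, atomTable(ens[[p[1]]])$y,
               atomTable(ens[[p[1]]])$z)
    B <- cbind(atomTable(ens[[p[2]]])$x, atomTable(ens[[p[2]]])$y,
               atomTable(ens[[p[2]]])$z)
    oracleRmsd(A, B)
  }))
  expect_equal(r$mean, manual, tolerance = 1e-8)
  expect_equal(r$mean, sigma * sqrt(6), tolerance = 0.1)
  ## monotonicity under increased noise
  set.seed(32)
  ens2 <- lapply(1:10, function(k) {
    a <- atomTable(m)
    a$x <- a$x + rnorm(nrow(a), sd = 2 * sigma)
    a$y <- a$y + rnorm(nrow(a), sd = 2 * sigma)
    a$z <- a$z + rnorm(nrow(a), sd = 2 * sigma)
    StructureModel(a, k, "noisy2")
  })
  expect_gt(ensemblePairwiseRmsd(ens2)$mean, r$mean)
  expect_error(ensemblePairwiseRmsd(list(m)), ">= 2")
  expect_error(ensemblePairwiseRmsd(list(m, m),
                                    function(a) a$elety == "XX"),
               "fewer than 3")
})
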