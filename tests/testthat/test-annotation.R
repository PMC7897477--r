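test_that("tetrad detection finds the constructed stack and nothing else", {
  ann <- g4Annotation("left2b")
  expect_length(ann$tetrads, 4)
  ## vertex-disjoint members covering 16 distinct guanines
  mem <- do.call(rbind, lapply(ann$tetrads, function(t) t@members))
  expect_equal(nrow(mem), 16)
  expect_false(anyDuplicated(paste(mem$chain, mem$resno)) > 0)
  expect_true(all(vapply(ann$tetrads, function(t) t@planarityRms,
                         numeric(1)) < 1.0))
})

test_that("non-quadruplex guanine arrangements yield zero tetrads", {
  expect_length(detectTetrads(spreadGuanines()), 0)
})

test_that("detection is invariant under rigid motion and stable to noise", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  base <- detectTetrads(m)
  expect_length(base, 1)
  set.seed(41)
  moved <- rigidMove(m, randomRotation(), c(20, -5, 13))
  t2 <- detectTetrads(moved)
  expect_length(t2, 1)
  expect_setequal(t2[[1]]@members$resno, base[[1]]@members$resno)
  ## coordinate noise sigma = 0.1 A: same tetrad recovered every time
  ok <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    a <- atomTable(m)
    a$x <- a$x + rnorm(nrow(a), sd = 0.1)
    a$y <- a$y + rnorm(nrow(a), sd = 0.1)
    a$z <- a$z + rnorm(nrow(a), sd = 0.1)
    tn <- detectTetrads(StructureModel(a))
    if (length(tn) == 1 &&
        setequal(tn[[1]]@members$resno, base[[1]]@members$resno))
      ok <- ok + 1L
  }
  expect_equal(ok, 100L)
})

test_that("hydrogen criteria are honoured when hydrogens exist", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  a <- atomTable(m)
  ## plant an H21 far from every acceptor: detection must now fail
  h <- a[a$elety == "N2", ]
  h$elety <- "H21"; h$elem <- "H"; h$is_h <- TRUE
  h$x <- h$x + 5
  bad <- StructureModel(rbind(a, h))
  expect_length(detectTetrads(bad), 0)
})

test_that("core assembly orders layers, blocks and twists correctly", {
  ann <- g4Annotation("left2b")
  core <- ann$core
  expect_equal(length(core@tetrads), 4)
  expect_equal(vapply(core@tetrads, function(t) t@layer, character(1)),
               c("outer", "inner", "inner", "outer"))
  expect_equal(sort(unique(core@blocks)), c(1L, 2L))
  st <- core@stepTwists
  expect_equal(sum(st$interface), 1)
  expect_equal(st$twist[!st$interface], c(-27, -27), tolerance = 1e-2)
  expect_equal(ann$handedness, "left")
  ## every tetrad guanine belongs to exactly one column entry
  expect_equal(nrow(core@columns), 16)
  expect_false(anyDuplicated(paste(core@columns$chain,
                                   core@columns$resno)) > 0)
})

test_that("well separated tetrads are reported as separate cores", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  a <- atomTable(m)
  b <- a
  b$resno <- b$resno + 10L
  b$z <- b$z + 25
  two <- StructureModel(rbind(a, b))
  tets <- detectTetrads(two)
  expect_length(tets, 2)
  w <- capture_warnings(assembleCore(tets, two))
  expect_true(any(grepl("not stacked", w)))
  cores <- suppressWarnings(assembleCore(tets, two, allCores = TRUE))
  expect_length(cores, 2)
  expect_length(cores[[1]]@tetrads, 1)
})

test_that("handedness calls are mirror-antisymmetric", {
  for (fx in c("left1b", "right")) {
    h1 <- g4Annotation(fx)$handedness
    h2 <- annotateG4(mirrorModel(g4Fixture(fx)))$handedness
    expect_true(all(c(h1, h2) %in% c("left", "right")))
    expect_false(h1 == h2)
  }
})

test_that("element classification recovers bulges, loops and linkers", {
  ann <- g4Annotation("left_bulged")
  el <- ann$elements
  expect_equal(sum(el$kind == "bulge"), 1)
  expect_equal(sum(el$kind == "loop"), 3)
  b <- el[el$kind == "bulge", ]
  gt <- attr(g4Fixture("left_bulged"), "groundTruth")$residues
  expect_equal(b$residues, as.character(gt$resno[gt$role == "bulge"]))
  ## bulge anchors are consecutive members of one column, 5' < bulge < 3'
  expect_equal(b$previous_core + 2L, b$next_core)
  expect_lt(b$previous_core, as.integer(b$residues))
  expect_gt(b$next_core, as.integer(b$residues))
  ## two bulges with correct anchors
  m2 <- g4Fixture("left2b_2bulge")
  ann2 <- g4Annotation("left2b_2bulge")
  el2 <- ann2$elements
  expect_equal(sum(el2$kind == "bulge"), 2)
  gt2 <- attr(m2, "groundTruth")$residues
  expect_setequal(el2$residues[el2$kind == "bulge"],
                  as.character(gt2$resno[gt2$role == "bulge"]))
  ## the two-block fixture has a linker between blocks
  ann3 <- g4Annotation("left2b")
  expect_equal(sum(ann3$elements$kind == "linker"), 1)
  gt3 <- attr(g4Fixture("left2b"), "groundTruth")$residues
  expect_equal(ann3$elements$residues[ann3$elements$kind == "linker"],
               as.character(gt3$resno[gt3$role == "linker"]))
})

test_that("overhangs anchor on one side only", {
  m <- buildG4(g4BuildSpec(n_tetrads = 2, blocks = 2, twist = 30,
                           overhang_len = 2))
  ann <- annotateG4(m)
  ov <- ann$elements[ann$elements$kind == "overhang", ]
  expect_equal(nrow(ov), 1)
  expect_false(is.na(ov$previous_core))
  expect_true(is.na(ov$next_core))
  expect_equal(length(strsplit(ov$residues, ",")[[1]]), 2)
})

test_that("core plus elements plus hetero partitions all residues", {
  for (fx in c("left2b", "left_bulged")) {
    m <- g4Fixture(fx)
    ann <- g4Annotation(fx)
    rt <- residueTable(m, nucOnly = TRUE)
    ck <- unlist(lapply(ann$core@tetrads, function(t)
      paste(t@members$chain, t@members$resno)))
    elres <- unlist(lapply(seq_len(nrow(ann$elements)), function(k)
      paste(ann$elements$chain[k],
            strsplit(ann$elements$residues[k], ",")[[1]])))
    expect_setequal(c(ck, elres), paste(rt$chain, rt$resno))
    expect_length(intersect(ck, elres), 0)
  }
})

test_that("sugar orientation is parallel for core guanines", {
  m <- g4Fixture("left1b")
  ann <- g4Annotation("left1b")
  ck <- ann$core@columns
  for (k in c(1, 5)) {
    r <- getResidue(m, ck$chain[k], ck$resno[k])
    expect_equal(sugarOrientation(r, ann$core, m), "parallel")
  }
  ## missing atoms give undefined
  r <- getResidue(m, "A", 1)
  expect_equal(sugarOrientation(r[r$elety != "C5'", ], ann$core, m),
               "undefined")
})
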