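## Synthetic idealized-G4 coordinate generator. Geometry is assembled in a
## canonical frame: stacking axis = z, tetrads stacked bottom-to-top, all
## columns threaded 5'->3' upwards. Every pipeline stage can be exercised on
## these models without any external coordinates.

## default torsion offsets (degrees, added to the core-step baseline) that
## swing a bulge thymine radially out of the core while keeping the
## flanking guanines stacked and the backbone closed; the alpha/beta
## magnitudes mirror the ~90/~70 degree alterations observed around
## left-handed bulges
DEFAULT_BULGE_OFFSETS <- c(epsilon = 0, zeta = 0, alpha = 90,
                           beta = -70, gamma = 0)

#' Build specification for a synthetic G4 model
#'
#' Defaults describe the study system emulated by the generator: a
#' four-layer left-handed G4 of two stacked two-tetrad blocks (signed twist
#' -27 degrees per intra-block step, rise 3.3 A), anti guanines
#' (chi = 240 degrees), C2'-endo sugars (P = 162, tau_m = 35 degrees),
#' single-thymine propeller loops and a single-thymine block linker.
#'
#' @param n_tetrads Number of stacked tetrads (>= 1).
#' @param blocks Integer partition of the tetrads into stacked blocks
#'   (bottom to top); successive blocks have opposite stacking polarity
#'   (the 5'-5'-type interface).
#' @param twist Signed in-plane rotation per intra-block step, degrees
#'   (negative = left-handed).
#' @param rise Rise per step, Angstrom.
#' @param interface_twist In-plane rotation at a block-block interface.
#' @param chi Glycosidic torsion of the core guanines, degrees. Default
#'   NULL resolves by handedness: 290 (high-anti) for left-handed twists,
#'   240 for right-handed ones — the phosphodiester between stacked
#'   guanines of a left-handed step only closes at high-anti chi, the
#'   geometric counterpart of the twisted left-handed backbone.
#' @param sugar_P,sugar_tau_m Sugar pucker of every residue, degrees.
#' @param loop_len Thymines per propeller loop (between columns).
#' @param linker_len Thymines per block linker.
#' @param overhang_len 3' overhang thymines.
#' @param bulges List of c(column, step) positions: a bulge thymine is
#'   inserted between the guanines of `column` flanking intra-block step
#'   `step` (step s = between tetrads s and s+1).
#' @param bulge_torsions Optional named vector (epsilon, zeta, alpha, beta,
#'   gamma) of absolute step torsions driving the guanine-to-bulge step;
#'   default: core-step baseline plus the builder's fixed outward offsets.
#' @param noise_sd Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Integer seed for the noise realization.
#' @return Object of class "g4BuildSpec" (a validated list).
#' @export
g4BuildSpec <- function(n_tetrads = 4L, blocks = c(2L, 2L), twist = -27,
                        rise = 3.3, interface_twist = 30, chi = NULL,
                        sugar_P = 162, sugar_tau_m = 35, loop_len = 1L,
                        linker_len = 1L, overhang_len = 0L, bulges = list(),
                        bulge_torsions = NULL, noise_sd = 0, seed = 1L) {
  if (is.null(chi)) chi <- if (twist < 0) 290 else 240
  spec <- list(n_tetrads = as.integer(n_tetrads),
               blocks = as.integer(blocks), twist = twist, rise = rise,
               interface_twist = interface_twist, chi = chi,
               sugar_P = sugar_P, sugar_tau_m = sugar_tau_m,
               loop_len = as.integer(loop_len),
               linker_len = as.integer(linker_len),
               overhang_len = as.integer(overhang_len), bulges = bulges,
               bulge_torsions = bulge_torsions, noise_sd = noise_sd,
               seed = as.integer(seed))
  if (spec$n_tetrads < 1L) stop("n_tetrads must be >= 1")
  if (sum(spec$blocks) != spec$n_tetrads)
    stop("blocks must partition the tetrads: sum(blocks) != n_tetrads")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  blockOf <- rep(seq_along(spec$blocks), spec$blocks)
  for (b in spec$bulges) {
    if (length(b) != 2L) stop("each bulge position is c(column, step)")
    if (b[1L] < 1L || b[1L] > 4L) stop("bulge column must be in 1..4")
    s <- b[2L]
    if (s < 1L || s >= spec$n_tetrads)
      stop("bulge step ", s, " out of range")
    if (blockOf[s] != blockOf[s + 1L])
      stop("bulge step ", s, " is a block interface, not a stacking step")
  }
  if (!is.null(spec$bulge_torsions)) {
    need <- c("epsilon", "zeta", "alpha", "beta", "gamma")
    if (!all(need %in% names(spec$bulge_torsions)))
      stop("bulge_torsions needs named entries ",
           paste(need, collapse = ", "))
  }
  structure(spec, class = "g4BuildSpec")
}

#' Build a single idealized G-tetrad
#'
#' Four C4-symmetric guanine nucleotides (base, sugar, C5') in the z = 0
#' plane with exact cyclic Hoogsteen donor-acceptor distances
#' N2->N7 = N1->O6 = 2.9 A.
#'
#' @param spec A [g4BuildSpec()] (chi and sugar pucker are honoured).
#' @return A [StructureModel-class] with four guanine residues.
#' @export
buildTetrad <- function(spec = g4BuildSpec()) {
  nt0 <- attachSugarToBase(tetradGuanine(), "G", spec$chi, spec$sugar_P,
                           spec$sugar_tau_m)
  res <- lapply(0:3, function(k) nt0 %*% t(rotZ(90 * k)))
  modelFromResidues(lapply(seq_along(res), function(i)
    list(base = "G", atoms = res[[i]], role = "coreG")),
    sourceId = "synthetic-tetrad")
}

## assemble a StructureModel from a list of residue descriptors
modelFromResidues <- function(residues, sourceId = "synthetic",
                              groundTruth = NULL) {
  tabs <- lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    xyz <- r$atoms
    makeAtomTable(chain = "A", resno = i,
                  resid = if (r$base == "G") "DG" else "DT",
                  elety = rownames(xyz),
                  elem = substr(gsub("[^A-Z]", "", rownames(xyz)), 1L, 1L),
                  x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1)
  })
  m <- StructureModel(do.call(rbind, tabs), sourceId = sourceId)
  if (!is.null(groundTruth)) attr(m, "groundTruth") <- groundTruth
  m
}

## measure the five transition torsions of a closed linkage res5 -> res3
stepTorsions <- function(a5, a3) {
  c(epsilon = dihedral(a5["C4'", ], a5["C3'", ], a5["O3'", ], a3["P", ]),
    zeta = dihedral(a5["C3'", ], a5["O3'", ], a3["P", ], a3["O5'", ]),
    alpha = dihedral(a5["O3'", ], a3["P", ], a3["O5'", ], a3["C5'", ]),
    beta = dihedral(a3["P", ], a3["O5'", ], a3["C5'", ], a3["C4'", ]),
    gamma = dihedral(a3["O5'", ], a3["C5'", ], a3["C4'", ], a3["C3'", ]))
}

## Close the backbone linkage between sequence neighbours: places O3' of
## res5 and P, O5' of res3 by optimizing the three free spin torsions
## against the O3'-P bond, the ester angles and optional soft step-torsion
## targets. Returns list(o3, p, o5, torsions).
closeLinkage <- function(a5, a3, targets = NULL) {
  g <- NUC_GEOM
  place <- function(th) {
    o3 <- nerfPlace(a5["C5'", ], a5["C4'", ], a5["C3'", ], g$bond_c3_o3,
                    g$ang_c4_c3_o3, th[1L])
    o5 <- nerfPlace(a3["C3'", ], a3["C4'", ], a3["C5'", ], g$bond_c5_o5,
                    g$ang_c4_c5_o5, th[2L])
    p <- nerfPlace(a3["C4'", ], a3["C5'", ], o5, g$bond_p_o5,
                   g$ang_p_o5_c5, th[3L])
    list(o3 = o3, o5 = o5, p = p)
  }
  obj <- function(th) {
    at <- place(th)
    v <- 400 * (vnorm(at$o3 - at$p) - g$bond_p_o3)^2 +
      0.005 * ((vangle(a5["C3'", ] - at$o3, at$p - at$o3) -
                  g$ang_c3_o3_p)^2 +
               (vangle(at$o3 - at$p, at$o5 - at$p) - g$ang_o3_p_o5)^2)
    if (!is.null(targets)) {
      tt <- c(epsilon = dihedral(a5["C4'", ], a5["C3'", ], at$o3, at$p),
              zeta = dihedral(a5["C3'", ], at$o3, at$p, at$o5),
              alpha = dihedral(at$o3, at$p, at$o5, a3["C5'", ]),
              beta = dihedral(at$p, at$o5, a3["C5'", ], a3["C4'", ]),
              gamma = th[2L])
      common <- intersect(names(targets), names(tt))
      v <- v + 0.002 * sum(circularDiff(tt[common], targets[common])^2)
    }
    v
  }
  grid <- seq(-150, 150, by = 60)
  starts <- as.matrix(expand.grid(grid, grid, grid))
  if (!is.null(targets) && all(c("gamma", "beta") %in% names(targets)))
    starts <- rbind(starts,
                    cbind(grid, targets[["gamma"]], targets[["beta"]]))
  vals <- apply(starts, 1L, obj)
  best <- order(vals)[1:3]
  fits <- lapply(best, function(i)
    stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-12)))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  at <- place(fit$par)
  a5x <- rbind(a5, "O3'" = at$o3)
  a3x <- rbind(a3, "P" = at$p, "O5'" = at$o5)
  list(o3 = at$o3, p = at$p, o5 = at$o5,
       torsions = stepTorsions(a5x, a3x),
       bondError = abs(vnorm(at$o3 - at$p) - g$bond_p_o3))
}

## Forward NeRF of the six backbone atoms of the next nucleotide from the
## sugar of residue a5; th = (t0, epsilon, zeta, alpha, beta, gamma) where
## t0 is the O3' placement spin of a5 and the rest are the step torsions
## (realized exactly by construction).
forwardBackbone <- function(a5, th) {
  g <- NUC_GEOM
  o3 <- nerfPlace(a5["C5'", ], a5["C4'", ], a5["C3'", ], g$bond_c3_o3,
                  g$ang_c4_c3_o3, th[1L])
  p <- nerfPlace(a5["C4'", ], a5["C3'", ], o3, g$bond_p_o3,
                 g$ang_c3_o3_p, th[2L])
  o5 <- nerfPlace(a5["C3'", ], o3, p, g$bond_p_o5, g$ang_o3_p_o5,
                  th[3L])
  c5 <- nerfPlace(o3, p, o5, g$bond_c5_o5, g$ang_p_o5_c5, th[4L])
  c4 <- nerfPlace(p, o5, c5, g$bond_c4_c5, g$ang_c4_c5_o5, th[5L])
  c3 <- nerfPlace(o5, c5, c4, SUGAR_BONDS[["c3c4"]], g$ang_c3_c4_c5,
                  th[6L])
  list(o3 = o3, p = p, o5 = o5, c5 = c5, c4 = c4, c3 = c3)
}

## complete a forward-placed backbone into a full nucleotide (sugar ring,
## base via chi)
completeNucleotide <- function(bb, base, chi, P, tau_m) {
  ring <- placeRingOnBond(sugarRingTemplate(P, tau_m), "C4'", "C3'",
                          bb$c4, bb$c3, bb$c5, "O4'",
                          NUC_GEOM$ang_o4_c4_c5, chir = 1)
  baseXYZ <- placeBaseOnSugar(ring, base, chi)
  rbind("P" = bb$p, "O5'" = bb$o5, "C5'" = bb$c5, ring, baseXYZ)
}

## Torsion-driven forward placement of a bulge thymine after core guanine
## a5: realizes the five prev-side step torsions exactly, with the O3' spin
## of a5 chosen to project the base radially out of the core.
placeBulge <- function(a5, torsions, chi, P, tau_m, nextC5) {
  tor5 <- torsions[c("epsilon", "zeta", "alpha", "beta", "gamma")]
  buildAt <- function(t0) {
    bb <- forwardBackbone(a5, c(t0, tor5))
    list(o3 = bb$o3, atoms = completeNucleotide(bb, "T", chi, P, tau_m))
  }
  score <- function(t0) {
    b <- buildAt(t0)
    ctr <- colMeans(b$atoms[rownames(baseTemplate("T")), ])
    radial <- vnorm(ctr[1:2])
    gap <- vnorm(b$atoms["C3'", ] - nextC5)
    4 * max(0, 6.5 - radial)^2 + (gap - 4.5)^2
  }
  tgrid <- seq(-177.5, 180, by = 5)
  sc <- vapply(tgrid, score, numeric(1L))
  t0 <- stats::optimize(score, tgrid[which.min(sc)] + c(-5, 5))$minimum
  buildAt(t0)
}

## Torsion-driven placement of a loop/linker/overhang thymine: all six
## placement torsions are optimized so the nucleotide's 3' end lands a
## closable distance from the next anchor, the backbone stays outside the
## core, and nothing clashes. The 5' linkage is exact by construction.
placeLoopForward <- function(a5, baseline, coreXYZ, nextC5 = NULL,
                             d2target = 4.4, chi, P, tau_m) {
  init <- c(-100, baseline[["epsilon"]], baseline[["zeta"]],
            baseline[["alpha"]], baseline[["beta"]],
            baseline[["gamma"]])
  score <- function(th) {
    bb <- forwardBackbone(a5, th)
    v <- 0
    if (!is.null(nextC5)) v <- v + 3 * (vnorm(bb$c3 - nextC5) - d2target)^2
    v <- v + 1.5 * max(0, 7 - vnorm(bb$c4[1:2]))^2
    pts <- rbind(bb$p, bb$o5, bb$c5, bb$c4, bb$c3)
    dmin <- fieldsMinDist(pts, coreXYZ)
    v + 4 * sum(pmax(0, 3.2 - dmin)^2) +
      5e-5 * sum(circularDiff(th[-1L], init[-1L])^2)
  }
  shifts <- as.matrix(expand.grid(t0 = c(-120, 0, 120),
                                  zeta = c(-120, 0, 120),
                                  alpha = c(-120, 0, 120)))
  starts <- t(apply(shifts, 1L, function(s)
    init + c(s[1L], 0, s[2L], s[3L], 0, 0)))
  vals <- apply(starts, 1L, score)
  best <- order(vals)[1:6]
  fits <- lapply(best, function(i)
    stats::optim(starts[i, ], score, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-11)))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  bb <- forwardBackbone(a5, fit$par)
  list(o3 = bb$o3, atoms = completeNucleotide(bb, "T", chi, P, tau_m))
}

#' Build a full synthetic G4 coordinate model
#'
#' Stacks idealized tetrads per the build specification, threads the four
#' G-columns 5' to 3' along the stacking axis, inserts bulge thymines
#' (torsion-driven, projecting radially out of the core), propeller loops,
#' block linkers and 3' overhangs, closes the phosphodiester backbone
#' between sequence neighbours, and finally applies seeded Gaussian noise.
#'
#' @param spec A [g4BuildSpec()].
#' @return A [StructureModel-class]; attribute "groundTruth" holds the spec
#'   and the per-residue role table.
#' @export
buildG4 <- function(spec = g4BuildSpec()) {
  stopifnot(inherits(spec, "g4BuildSpec"))
  nb <- length(spec$blocks)
  blockOf <- rep(seq_len(nb), spec$blocks)
  ## the topmost block keeps its tetrad faces up; polarity alternates at
  ## every 5'-5'-type interface going down
  polarity <- ifelse((nb - seq_len(nb)) %% 2L == 0L, 1, -1)
  if (any(polarity < 0 & spec$blocks > 2L))
    stop("polarity-flipped blocks support at most 2 tetrads ",
         "(as in deposited left-handed G4s)")
  ## tetrad frames
  phi <- numeric(spec$n_tetrads)
  for (t in seq_len(spec$n_tetrads)[-1L]) {
    dphi <- if (blockOf[t] == blockOf[t - 1L]) spec$twist
            else spec$interface_twist
    phi[t] <- phi[t - 1L] + dphi
  }
  zs <- (seq_len(spec$n_tetrads) - 1L) * spec$rise
  nt0 <- attachSugarToBase(tetradGuanine(), "G", spec$chi, spec$sugar_P,
                           spec$sugar_tau_m)
  flip <- rotX(180)
  coreAtoms <- function(t, col) {
    x <- nt0 %*% t(rotZ(90 * (col - 1L)))
    if (polarity[blockOf[t]] < 0) x <- x %*% t(flip)
    x <- x %*% t(rotZ(phi[t]))
    sweep(x, 2L, -c(0, 0, zs[t]))
  }
  ## ------------------------------------------------ sequence assembly
  residues <- list()
  push <- function(r) residues[[length(residues) + 1L]] <<- r
  bulgeAfter <- function(col, t) {
    for (b in spec$bulges)
      if (b[1L] == col && b[2L] == t) return(TRUE)
    FALSE
  }
  ## Threading: face-up blocks run each column 5'->3' top-to-bottom (the
  ## sugar C5' face points up in the tetrad frame, so the 5' neighbour of a
  ## stacked guanine sits above it); polarity-flipped blocks are woven the
  ## way deposited left-handed blocks are: enter the first column at its
  ## top, run the remaining columns bottom-to-top, and exit through the
  ## first column's bottom guanine, which has no intra-column backbone
  ## link. Blocks are visited top-down so every block junction is short.
  pushG <- function(b, col, t) push(list(
    role = "coreG", base = "G", block = b, column = col, tetrad = t,
    atoms = coreAtoms(t, col)))
  pushT <- function(role, b, col, i) push(list(
    role = role, base = "T", block = b,
    column = if (is.na(col)) NA_integer_ else as.integer(col),
    tetrad = NA_integer_, atoms = NULL, loop_i = i))
  pushBulge <- function(b, col) push(list(
    role = "bulge", base = "T", block = b, column = col,
    tetrad = NA_integer_, atoms = NULL))
  lastExit <- NULL   # atoms of the previous block's exit guanine
  for (b in rev(seq_len(nb))) {
    tets <- which(blockOf == b)
    ## enter the block at the column slot spatially closest to the
    ## previous block's exit, so the linker stays short
    entryStart <- if (is.null(lastExit)) 1L else
      which.min(vapply(1:4, function(s)
        vnorm(lastExit["C3'", ] - coreAtoms(max(tets), s)["C5'", ]),
        numeric(1L)))
    ## traverse the columns in the rotational sense that keeps each
    ## propeller loop short: ascending slots for left-handed twists,
    ## descending for right-handed ones
    ord <- if (spec$twist >= 0) ((entryStart - 1L - 0:3) %% 4L) + 1L
           else ((entryStart - 1L + 0:3) %% 4L) + 1L
    if (polarity[b] > 0) {
      for (ci in seq_len(4L)) {
        col <- ord[ci]
        for (t in rev(tets)) {
          pushG(b, col, t)
          if (t > min(tets) && bulgeAfter(col, t - 1L))
            pushBulge(b, col)
        }
        if (ci < 4L) for (i in seq_len(spec$loop_len))
          pushT("loop", b, col, i)
      }
    } else {
      tTop <- max(tets); tBot <- min(tets)
      for (bl in spec$bulges)
        if (bl[1L] == ord[1L] && blockOf[bl[2L]] == b)
          stop("a bulge cannot sit in the entry column of a ",
               "polarity-flipped block (its guanines share no backbone ",
               "step)")
      pushG(b, ord[1L], tTop)
      for (ci in 2:4) {
        col <- ord[ci]
        for (i in seq_len(spec$loop_len)) pushT("loop", b, ord[ci - 1L], i)
        if (length(tets) == 2L) {
          pushG(b, col, tBot)
          if (bulgeAfter(col, tBot)) pushBulge(b, col)
          pushG(b, col, tTop)
        } else pushG(b, col, tTop)
      }
      if (length(tets) == 2L) {
        for (i in seq_len(spec$loop_len)) pushT("loop", b, ord[4L], i)
        pushG(b, ord[1L], tBot)
      }
    }
    lastExit <- residues[[length(residues)]]$atoms
    if (b > 1L) for (i in seq_len(spec$linker_len))
      pushT("linker", b, NA, i)
  }
  for (i in seq_len(spec$overhang_len))
    push(list(role = "overhang", base = "T", block = 1L,
              column = NA_integer_, tetrad = NA_integer_, atoms = NULL,
              loop_i = i))
  n <- length(residues)
  isCore <- vapply(residues, function(x) x$role == "coreG", logical(1L))
  coreXYZ <- do.call(rbind, lapply(residues[isCore], `[[`, "atoms"))
  ## ------------------------------------------------ backbone closure
  ## core-core steps first (they define the torsion baseline)
  linked <- rep(FALSE, n - 1L)
  baseline <- NULL
  coreCore <- which(vapply(seq_len(n - 1L), function(i)
    isCore[i] && isCore[i + 1L], logical(1L)))
  for (i in coreCore) {
    cl <- closeLinkage(residues[[i]]$atoms, residues[[i + 1L]]$atoms)
    residues[[i]]$atoms <- rbind(residues[[i]]$atoms, "O3'" = cl$o3)
    residues[[i + 1L]]$atoms <- rbind(residues[[i + 1L]]$atoms,
                                      "P" = cl$p, "O5'" = cl$o5)
    linked[i] <- TRUE
    if (is.null(baseline)) baseline <- cl$torsions
  }
  if (is.null(baseline))
    baseline <- c(epsilon = 180, zeta = 260, alpha = 300, beta = 180,
                  gamma = 60)
  ## bulges and loop-like residues, 5' to 3': forward torsion-driven
  ## placement (the 5' linkage is exact), then spin closure where a
  ## placed run rejoins the core
  for (i in seq_len(n)) {
    r <- residues[[i]]
    if (r$role == "bulge") {
      tors <- if (!is.null(spec$bulge_torsions))
        spec$bulge_torsions else wrap360(baseline + DEFAULT_BULGE_OFFSETS)
      pb <- placeBulge(residues[[i - 1L]]$atoms, tors, chi = spec$chi,
                       P = spec$sugar_P, tau_m = spec$sugar_tau_m,
                       nextC5 = residues[[i + 1L]]$atoms["C5'", ])
      residues[[i - 1L]]$atoms <- rbind(residues[[i - 1L]]$atoms,
                                        "O3'" = pb$o3)
      residues[[i]]$atoms <- pb$atoms
      linked[i - 1L] <- TRUE
    } else if (r$role %in% c("loop", "linker", "overhang")) {
      nextCore <- which(isCore)
      nextCore <- nextCore[nextCore > i]
      nGapRes <- if (length(nextCore)) nextCore[1L] - i - 1L else 0L
      nxtC5 <- if (length(nextCore))
        residues[[nextCore[1L]]]$atoms["C5'", ] else NULL
      pl <- placeLoopForward(residues[[i - 1L]]$atoms, baseline, coreXYZ,
                             nextC5 = nxtC5,
                             d2target = 4.4 + 6 * nGapRes,
                             chi = spec$chi, P = spec$sugar_P,
                             tau_m = spec$sugar_tau_m)
      residues[[i - 1L]]$atoms <- rbind(residues[[i - 1L]]$atoms,
                                        "O3'" = pl$o3)
      residues[[i]]$atoms <- pl$atoms
      linked[i - 1L] <- TRUE
    }
  }
  ## closures where a bulge or loop run rejoins the core: the run's last
  ## residue gets its O3' from the spin closure (bulges additionally keep
  ## the uncontrolled next-side torsions near the core baseline)
  for (i in which(!linked)) {
    tg <- if (residues[[i]]$role %in% c("bulge", "loop", "linker"))
      baseline else NULL
    cl <- closeLinkage(residues[[i]]$atoms, residues[[i + 1L]]$atoms,
                       targets = tg)
    residues[[i]]$atoms <- rbind(residues[[i]]$atoms, "O3'" = cl$o3)
    residues[[i + 1L]]$atoms <- rbind(residues[[i + 1L]]$atoms,
                                      "P" = cl$p, "O5'" = cl$o5)
  }
  ## chain termini: 5'-OH (O5' only) and 3'-OH (O3')
  a1 <- residues[[1L]]$atoms
  if (!"O5'" %in% rownames(a1))
    residues[[1L]]$atoms <- rbind(a1, "O5'" = nerfPlace(
      a1["C3'", ], a1["C4'", ], a1["C5'", ], NUC_GEOM$bond_c5_o5,
      NUC_GEOM$ang_c4_c5_o5, baseline[["gamma"]]))
  an <- residues[[n]]$atoms
  if (!"O3'" %in% rownames(an))
    residues[[n]]$atoms <- rbind(an, "O3'" = nerfPlace(
      an["C5'", ], an["C4'", ], an["C3'", ], NUC_GEOM$bond_c3_o3,
      NUC_GEOM$ang_c4_c3_o3, -100))
  ## ------------------------------------------------------------ noise
  gt <- list(spec = spec,
             residues = data.frame(
               resno = seq_len(n),
               role = vapply(residues, `[[`, character(1L), "role"),
               base = vapply(residues, `[[`, character(1L), "base"),
               block = vapply(residues, function(r)
                 as.integer(r$block), integer(1L)),
               column = vapply(residues, function(r)
                 as.integer(r$column), integer(1L)),
               tetrad = vapply(residues, function(r)
                 as.integer(r$tetrad), integer(1L))))
  m <- modelFromResidues(residues, sourceId = "synthetic-g4",
                         groundTruth = gt)
  if (spec$noise_sd > 0) {
    xyz <- modelXYZ(m)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sd),
                        nrow(xyz), 3L)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    modelXYZ(m) <- xyz
    attr(m, "groundTruth") <- gt
  }
  m
}

## per-atom minimum distance from rows of a to rows of b
fieldsMinDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Mirror a structure model
#'
#' Reflects all coordinates through the yz plane. Chirality-dependent
#' quantities negate: handedness flips, every torsion changes sign, and
#' pseudorotation phases shift by 180 degrees (C2'-endo becomes C2'-exo).
#'
#' @param model A [StructureModel-class].
#' @return The mirrored model.
#' @export
mirrorModel <- function(model) {
  xyz <- modelXYZ(model)
  xyz[, 1L] <- -xyz[, 1L]
  out <- model
  modelXYZ(out) <- xyz
  attr(out, "groundTruth") <- attr(model, "groundTruth")
  out
}
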