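## Assembly of full nucleotides: sugar attachment to a placed base (tetrad
## path), base attachment to a placed sugar (torsion-driven path), and the
## Hoogsteen tetrad placement solver.
##
## Fixed local geometry (degrees / Angstrom): the same constants are used by
## both attachment directions so the two constructions are congruent.

NUC_GEOM <- list(
  bond_n_c1 = 1.47,    # glycosidic N - C1'
  ang_n_c1_o4 = 108.2, # N - C1' - O4'
  ang_n_c1_c2 = 113.7, # N - C1' - C2'
  bond_c4_c5 = 1.51,   # C4' - C5'
  ang_c3_c4_c5 = 114.7,
  ang_o4_c4_c5 = 109.4,
  bond_c3_o3 = 1.423,
  ang_c4_c3_o3 = 110.6,
  bond_c5_o5 = 1.440,
  ang_c4_c5_o5 = 110.2,
  bond_p_o3 = 1.607,
  bond_p_o5 = 1.593,
  ang_c3_o3_p = 119.7,
  ang_o3_p_o5 = 104.0,
  ang_p_o5_c5 = 120.9,
  ## chirality of C1' (sign of det[u_N, u_O4', u_C2']) fixing which face of
  ## the sugar carries the base; C5' is placed on the same face as the base
  chir_c1 = 1
)

## rotation taking unit vector u onto unit vector v
rotBetween <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  c_ <- sum(u * v)
  ax <- vcross(u, v)
  if (vnorm(ax) < 1e-12) {
    if (c_ > 0) return(diag(3L))
    ## 180 degrees about any perpendicular axis
    p <- vcross(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    return(rotAxis(p, 180))
  }
  rotAxis(ax, atan2(vnorm(ax), c_) * DEG)
}

## Rigidly place a ring template: atom `a` at posA, bond a->b along
## posB - posA, spin about that axis solved so that the angle
## ref-posA-(atom cnm) equals angTarget, root selected by the chirality sign
## sign(det[u_ref, u_ab, u_c]) == chir.
placeRingOnBond <- function(ring, a, bnm, posA, posB, refPos, cnm,
                            angTarget, chir) {
  u_t <- vunit(ring[bnm, ] - ring[a, ])
  u_a <- vunit(posB - posA)
  R0 <- rotBetween(u_t, u_a)
  base0 <- t(R0 %*% t(sweep(ring, 2L, ring[a, ])))
  u_ref <- vunit(refPos - posA)
  cvec <- function(th) as.numeric(rotAxis(u_a, th) %*% base0[cnm, ])
  f <- function(th) vangle(u_ref, cvec(th)) - angTarget
  grid <- seq(0, 360, by = 3)
  fv <- vapply(grid, f, numeric(1L))
  roots <- c()
  for (i in seq_len(length(grid) - 1L)) {
    if (is.finite(fv[i]) && is.finite(fv[i + 1L]) &&
        fv[i] * fv[i + 1L] <= 0 && fv[i] != fv[i + 1L]) {
      r <- tryCatch(stats::uniroot(f, c(grid[i], grid[i + 1L]),
                                   tol = 1e-10)$root,
                    error = function(e) NULL)
      if (!is.null(r)) roots <- c(roots, r)
    }
  }
  if (!length(roots)) stop("ring placement: angle condition has no solution")
  pick <- NULL
  for (r in roots) {
    uc <- vunit(cvec(r))
    s <- sign(sum(vcross(u_ref, u_a) * uc))
    if (s == chir) { pick <- r; break }
  }
  if (is.null(pick)) pick <- roots[1L]
  placed <- t(rotAxis(u_a, pick) %*% t(base0))
  sweep(placed, 2L, -posA)
}

## the two tetrahedral completions at a center with two known substituents;
## returns the unit direction on the face selected by `faceSign` relative to
## normal `n`
tetrahedralDir <- function(u1, u2, ang1, ang2, n, faceSign) {
  e1 <- vunit(-(u1 + u2))
  e2 <- vunit(vcross(u1, u2))
  obj <- function(w) {
    d <- cos(w) * e1 + sin(w) * e2
    (vangle(d, u1) - ang1)^2 + (vangle(d, u2) - ang2)^2
  }
  w1 <- stats::optimize(obj, c(0, pi))$minimum
  w2 <- stats::optimize(obj, c(-pi, 0))$minimum
  d1 <- cos(w1) * e1 + sin(w1) * e2
  d2 <- cos(w2) * e1 + sin(w2) * e2
  if (sign(sum(d1 * n)) == faceSign) vunit(d1) else vunit(d2)
}

## direction at C1' with given angles to O4' and C2' and chirality sign
glycosidicDir <- function(u_o4, u_c2, chir = NUC_GEOM$chir_c1) {
  c12 <- sum(u_o4 * u_c2)
  t1 <- cos(NUC_GEOM$ang_n_c1_o4 / DEG)
  t2 <- cos(NUC_GEOM$ang_n_c1_c2 / DEG)
  ## d = x u_o4 + y u_c2 + z unit(u_o4 x u_c2)
  A <- matrix(c(1, c12, c12, 1), 2L, 2L)
  xy <- solve(A, c(t1, t2))
  zz2 <- 1 - (xy[1L]^2 + xy[2L]^2 + 2 * xy[1L] * xy[2L] * c12)
  if (zz2 < 0) zz2 <- 0
  z <- chir * sqrt(zz2)
  vunit(xy[1L] * u_o4 + xy[2L] * u_c2 + z * vunit(vcross(u_o4, u_c2)))
}

## template-derived constants for the base-from-sugar path
baseAttachConsts <- function(base) {
  key <- paste0("attach_", base)
  cacheGet(key, function() {
    tmpl <- baseTemplate(base)
    glyN <- if (base == "G") "N9" else "N1"
    nb <- if (base == "G") c("C4", "C8") else c("C2", "C6")
    N <- tmpl[glyN, ]
    u1 <- vunit(tmpl[nb[1L], ] - N)
    u2 <- vunit(tmpl[nb[2L], ] - N)
    c1v <- N + NUC_GEOM$bond_n_c1 * vunit(-(u1 + u2))
    list(glyN = glyN, chiAtom = nb[1L], otherAtom = nb[2L],
         bond_n_cchi = vnorm(tmpl[nb[1L], ] - N),
         ang_c1_n_cchi = vangle(c1v - N, tmpl[nb[1L], ] - N),
         c1v = c1v)
  })
}

#' Attach an idealized deoxyribose (and C5') to a placed base
#'
#' Builds the sugar of a nucleotide whose base coordinates are already
#' placed: C1' along the external bisector at the glycosidic nitrogen, O4'
#' by the glycosidic torsion chi, the ring spin by the fixed C1' valence
#' geometry and chirality, C5' on the base face of the ring.
#'
#' @param baseXYZ Named coordinate matrix of the placed base.
#' @param base "G" or "T".
#' @param chi Glycosidic torsion, degrees.
#' @param P,tau_m Sugar pucker.
#' @return Named matrix: base atoms plus C1', C2', C3', C4', O4', C5'.
#' @keywords internal
attachSugarToBase <- function(baseXYZ, base, chi, P, tau_m) {
  k <- baseAttachConsts(base)
  N <- baseXYZ[k$glyN, ]
  u1 <- vunit(baseXYZ[k$chiAtom, ] - N)
  u2 <- vunit(baseXYZ[k$otherAtom, ] - N)
  c1 <- N + NUC_GEOM$bond_n_c1 * vunit(-(u1 + u2))
  o4 <- nerfPlace(baseXYZ[k$chiAtom, ], N, c1, SUGAR_BONDS[["o4c1"]],
                  NUC_GEOM$ang_n_c1_o4, chi)
  ring <- sugarRingTemplate(P, tau_m)
  placed <- placeRingOnBond(ring, "C1'", "O4'", c1, o4, N, "C2'",
                            NUC_GEOM$ang_n_c1_c2, NUC_GEOM$chir_c1)
  ## C5' on the same face of the sugar ring as the base
  rp <- fitPlane(placed)
  faceSign <- sign(sum((N - c1) * rp$normal))
  u_c3 <- vunit(placed["C3'", ] - placed["C4'", ])
  u_o4 <- vunit(placed["O4'", ] - placed["C4'", ])
  d5 <- tetrahedralDir(u_c3, u_o4, NUC_GEOM$ang_c3_c4_c5,
                       NUC_GEOM$ang_o4_c4_c5, rp$normal, faceSign)
  c5 <- placed["C4'", ] + NUC_GEOM$bond_c4_c5 * d5
  rbind(baseXYZ, placed, "C5'" = c5)
}

#' Attach a rigid base to a placed sugar via chi (torsion-driven path)
#'
#' @param sugarXYZ Named matrix with at least C1', C2', O4' (ring placed).
#' @param base "G" or "T".
#' @param chi Glycosidic torsion, degrees.
#' @return Named matrix of the base atoms in place.
#' @keywords internal
placeBaseOnSugar <- function(sugarXYZ, base, chi) {
  k <- baseAttachConsts(base)
  c1 <- sugarXYZ["C1'", ]
  u_o4 <- vunit(sugarXYZ["O4'", ] - c1)
  u_c2 <- vunit(sugarXYZ["C2'", ] - c1)
  N <- c1 + NUC_GEOM$bond_n_c1 * glycosidicDir(u_o4, u_c2)
  cchi <- nerfPlace(sugarXYZ["O4'", ], c1, N, k$bond_n_cchi,
                    k$ang_c1_n_cchi, chi)
  tmpl <- baseTemplate(base)
  ref <- rbind(tmpl[k$glyN, ], tmpl[k$chiAtom, ], k$c1v)
  act <- rbind(N, cchi, c1)
  fit <- superposeRmsd(act, ref)
  placed <- t(fit$rotation %*% t(tmpl)) +
    matrix(fit$translation, nrow(tmpl), 3L, byrow = TRUE)
  rownames(placed) <- rownames(tmpl)
  placed
}

## ------------------------------------------------------------------
## Hoogsteen tetrad placement

#' Solve the C4-symmetric Hoogsteen placement of four guanines
#'
#' Finds the planar placement (translation + in-plane rotation) of an
#' idealized guanine such that its four-fold rotation copies about the z
#' axis close the cyclic Hoogsteen pattern with N2(i)->N7(i+1) and
#' N1(i)->O6(i+1) donor-acceptor distances of 2.9 A.
#'
#' @param hbond Target heavy-atom H-bond length (Angstrom).
#' @param radius Soft target for the N9 distance from the stack axis.
#' @return Named matrix: guanine 0 base coordinates in the tetrad frame
#'   (plane z = 0, axis = z); copies are Rz(90 k) rotations.
#' @keywords internal
tetradGuanine <- function(hbond = 2.9, radius = 6.7) {
  key <- sprintf("tetrad_%.3f_%.3f", hbond, radius)
  cacheGet(key, function() {
    tmpl <- baseTemplate("G")
    place <- function(par) {
      sweep(tmpl %*% t(rotZ(par[3L])), 2L, -c(par[1L], par[2L], 0))
    }
    ## donor neighbour is the Rz(-90) copy; both Hoogsteen distances are
    ## satisfiable exactly, with the whole-tetrad rotation as the only
    ## redundancy, so minimize the distance errors alone and select the
    ## branch whose N9 radius is closest to the realistic value
    obj <- function(par) {
      g0 <- place(par)
      g1 <- g0 %*% t(rotZ(-90))
      (vnorm(g0["N2", ] - g1["N7", ]) - hbond)^2 +
        (vnorm(g0["N1", ] - g1["O6", ]) - hbond)^2
    }
    best <- NULL
    for (th in seq(0, 330, by = 30)) for (tx in c(2, 4, 6))
      for (ty in c(-5, 0, 5)) {
        fit <- stats::optim(c(tx, ty, th), obj, method = "Nelder-Mead",
                            control = list(maxit = 4000, reltol = 1e-16))
        if (fit$value > 1e-12) next
        r <- vnorm(place(fit$par)["N9", c(1L, 2L)])
        if (is.null(best) || abs(r - radius) < abs(best$r - radius))
          best <- list(par = fit$par, r = r)
      }
    if (is.null(best))
      stop("tetrad placement failed to satisfy the Hoogsteen distances")
    g0 <- place(best$par)
    ## gauge fix: rotate the tetrad so N9 of copy 0 sits on the +x axis
    ang <- atan2(g0["N9", 2L], g0["N9", 1L]) * DEG
    g0 %*% t(rotZ(-ang))
  })
}
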