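## Idealized planar base templates and the deoxyribose ring embedding.
## Templates are constructed from standard bond lengths by exact polygon
## geometry (hexagonal pyrimidine ring, fused pentagon for purines) so they
## are planar by construction; they are unit-tested for planarity and bond
## sanity. Frame convention: base in the z = 0 plane, glycosidic nitrogen
## at the origin, ring centroid along +x.

.g4geom_cache <- new.env(parent = emptyenv())

cacheGet <- function(key, compute) {
  if (!is.null(.g4geom_cache[[key]])) return(.g4geom_cache[[key]])
  val <- compute()
  assign(key, val, envir = .g4geom_cache)
  val
}

## regular polygon helper: vertices of the fused pentagon sharing edge A-B,
## built on the side away from `awayFrom`
fusedPentagon <- function(A, B, awayFrom) {
  edge <- vnorm(B - A)
  mid <- (A + B) / 2
  perp <- c(-(B - A)[2L], (B - A)[1L], 0) / edge
  if (sum(perp * (mid - awayFrom)) < 0) perp <- -perp
  apothem <- edge / (2 * tan(36 / DEG))
  center <- mid + apothem * perp
  R <- edge / (2 * sin(36 / DEG))
  angA <- atan2(A[2L] - center[2L], A[1L] - center[1L])
  angB <- atan2(B[2L] - center[2L], B[1L] - center[1L])
  ## step direction from A away from B
  step <- if (sin(angB - angA) > 0) -72 / DEG else 72 / DEG
  t(vapply(1:3, function(k)
    center + R * c(cos(angA + k * step), sin(angA + k * step), 0),
    numeric(3L)))
}

#' Idealized planar base template
#'
#' Heavy-atom coordinates of an idealized guanine or thymine base: regular
#' hexagon six-ring (edge 1.36 A), fused regular pentagon for the purine
#' five-ring, exocyclic substituents along the exterior bisectors. Planar in
#' z = 0, glycosidic nitrogen at the origin, ring centroid towards +x.
#'
#' @param base "G" or "T".
#' @return Named numeric matrix (atoms x 3), Angstrom.
#' @export
baseTemplate <- function(base = c("G", "T")) {
  base <- match.arg(base)
  cacheGet(paste0("base_", base), function() .baseTemplate(base))
}

.baseTemplate <- function(base) {
  edge <- 1.36
  hex <- t(vapply(0:5, function(k)
    edge * c(cos(k * 60 / DEG), sin(k * 60 / DEG), 0), numeric(3L)))
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ctr <- colMeans(hex)
  exo <- function(at, bond) hex[at, ] + bond * vunit(hex[at, ] - ctr)
  if (base == "G") {
    pent <- fusedPentagon(hex["C4", ], hex["C5", ], ctr)
    rownames(pent) <- c("N9", "C8", "N7")
    xyz <- rbind(hex, pent,
                 O6 = exo("C6", 1.24),
                 N2 = exo("C2", 1.34))
    glyN <- "N9"
  } else {
    xyz <- rbind(hex,
                 O2 = exo("C2", 1.22),
                 O4 = exo("C4", 1.23),
                 C7 = exo("C5", 1.50))
    glyN <- "N1"
  }
  ## normalize frame: glycosidic N at origin, ring centroid along +x
  xyz <- sweep(xyz, 2L, xyz[glyN, ])
  ringc <- colMeans(xyz[intersect(rownames(xyz),
                                  c(rownames(hex), "N9", "C8", "N7")), ])
  ang <- atan2(ringc[2L], ringc[1L]) * DEG
  xyz %*% t(rotZ(-ang))
}

## ------------------------------------------------------------------
## Sugar ring embedding from the pseudorotation description

SUGAR_BONDS <- c(o4c1 = 1.414, c1c2 = 1.528, c2c3 = 1.525,
                 c3c4 = 1.528, c4o4 = 1.446)

#' 3D deoxyribose ring for a given pucker
#'
#' Embeds the five-membered furanose ring so its endocyclic torsions equal
#' the Altona-Sundaralingam values nu_j = tau_m cos(P + 144(j-2)). The five
#' bond lengths are fixed at standard values; the three free bond angles are
#' solved numerically for ring closure (deterministic initialization,
#' closure tolerance ~1e-4 A).
#'
#' @param P Pseudorotation phase angle, degrees.
#' @param tau_m Puckering amplitude, degrees.
#' @return 5 x 3 matrix with rows O4', C1', C2', C3', C4'; attribute
#'   "closure" holds the residual closure error.
#' @export
sugarRingTemplate <- function(P, tau_m) {
  key <- sprintf("ring_%.4f_%.4f", wrap360(P), tau_m)
  cacheGet(key, function() .sugarRing(wrap360(P), tau_m))
}

.sugarRing <- function(P, tau_m) {
  nu <- puckerTorsions(P, tau_m)
  b <- SUGAR_BONDS
  build <- function(ang) {
    o4 <- c(0, 0, 0)
    c1 <- c(b[["o4c1"]], 0, 0)
    c2 <- c1 + b[["c1c2"]] * c(-cos(ang[1L] / DEG), sin(ang[1L] / DEG), 0)
    c3 <- nerfPlace(o4, c1, c2, b[["c2c3"]], ang[2L], nu[2L])
    c4 <- nerfPlace(c1, c2, c3, b[["c3c4"]], ang[3L], nu[3L])
    rbind("O4'" = o4, "C1'" = c1, "C2'" = c2, "C3'" = c3, "C4'" = c4)
  }
  obj <- function(ang) {
    r <- build(ang)
    closure <- vnorm(r["C4'", ] - r["O4'", ]) - b[["c4o4"]]
    m3 <- dihedral(r["C2'", ], r["C3'", ], r["C4'", ], r["O4'", ], "180")
    m4 <- dihedral(r["C3'", ], r["C4'", ], r["O4'", ], r["C1'", ], "180")
    m0 <- dihedral(r["C4'", ], r["O4'", ], r["C1'", ], r["C2'", ], "180")
    (1000 * closure)^2 + (m3 - nu[4L])^2 + (m4 - nu[5L])^2 +
      (m0 - nu[1L])^2
  }
  fit <- stats::optim(c(105, 103, 103), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  ring <- build(fit$par)
  ## the five torsions slightly over-determine a fixed-bond five-ring
  ## (4 internal degrees of freedom), so a sub-degree torsion residual is
  ## intrinsic; the closure bond is enforced tightly
  meas <- c(dihedral(ring["C4'", ], ring["O4'", ], ring["C1'", ],
                     ring["C2'", ], "180"),
            dihedral(ring["C2'", ], ring["C3'", ], ring["C4'", ],
                     ring["O4'", ], "180"),
            dihedral(ring["C3'", ], ring["C4'", ], ring["O4'", ],
                     ring["C1'", ], "180"))
  attr(ring, "closure") <-
    abs(vnorm(ring["C4'", ] - ring["O4'", ]) - b[["c4o4"]])
  attr(ring, "torsion_error") <-
    max(abs(meas - nu[c(1L, 4L, 5L)]))
  ring
}
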