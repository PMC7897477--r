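## Sugar pucker: pseudorotation phase angle, puckering amplitude, the
## 36-degree sector classes, and the z-deviation alternative descriptor.

PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Pucker class from the pseudorotation phase angle
#'
#' The pseudorotation wheel is divided into ten 36-degree sectors with
#' C3'-endo centered at P = 18 deg and C2'-endo centered at P = 162 deg.
#'
#' @param P Phase angle(s), degrees.
#' @return Character vector of sector names.
#' @export
puckerClass <- function(P) {
  PUCKER_CLASSES[(floor(wrap360(P) / 36) %% 10) + 1L]
}

#' Pseudorotation analysis of the five endocyclic sugar torsions
#'
#' Computes the phase angle P and amplitude tau_m of the
#' Altona-Sundaralingam pseudorotation description:
#' \deqn{\tan P = \frac{(\nu_4+\nu_1) - (\nu_3+\nu_0)}{2\nu_2(\sin 36^\circ + \sin 72^\circ)},\qquad \tau_m = \nu_2 / \cos P}
#' with 180 deg added when \eqn{\nu_2 < 0} and P mapped into [0, 360).
#'
#' @param nu Numeric length-5 vector of endocyclic torsions
#'   (nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
#'   nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1'), degrees, each expected
#'   in (-90, 90).
#' @return List with `P` (degrees in [0, 360), NA for a planar ring),
#'   `tau_m` (degrees, >= 0) and `pucker_class` (sector name, or "planar").
#' @export
pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5L)
  nu <- wrap180(nu)
  num <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  den <- 2 * nu[3L] * (sin(36 / DEG) + sin(72 / DEG))
  if (abs(den) < 1e-9 && abs(num) < 1e-9)
    return(list(P = NA_real_, tau_m = 0, pucker_class = "planar"))
  P <- wrap360(atan2(num, den) * DEG)  # atan2 handles the nu2 < 0 branch
  ## resultant form of the amplitude: exact for generated torsions and,
  ## unlike nu2/cos(P), stable near P = 90 or 270
  s <- 2 * (sin(36 / DEG) + sin(72 / DEG))
  tau_m <- sqrt(nu[3L]^2 + (num / s)^2)
  list(P = P, tau_m = tau_m, pucker_class = puckerClass(P))
}

#' Endocyclic torsions for a given pucker (generator inverse)
#'
#' Returns nu_j = tau_m * cos(P + 144 * (j - 2)) for j = 0..4; feeding the
#' result to [pseudorotation()] recovers (P, tau_m) exactly.
#'
#' @param P Phase angle, degrees.
#' @param tau_m Amplitude, degrees (>= 0).
#' @return Numeric length-5 vector (nu0..nu4), degrees.
#' @export
puckerTorsions <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) / DEG)
}

#' Measure the five endocyclic torsions of a residue's sugar
#'
#' @param res Residue atom table from [getResidue()].
#' @return Numeric length-5 vector (nu0..nu4), signed degrees, or NULL when
#'   a ring atom is missing.
#' @export
sugarTorsions <- function(res) {
  nm <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  xyz <- lapply(nm, atomXYZ, res = res)
  if (any(vapply(xyz, is.null, logical(1L)))) return(NULL)
  ring <- do.call(rbind, xyz)        # C4' O4' C1' C2' C3'
  idx <- rbind(c(1, 2, 3, 4),        # nu0 C4'-O4'-C1'-C2'
               c(2, 3, 4, 5),        # nu1 O4'-C1'-C2'-C3'
               c(3, 4, 5, 1),        # nu2 C1'-C2'-C3'-C4'
               c(4, 5, 1, 2),        # nu3 C2'-C3'-C4'-O4'
               c(5, 1, 2, 3))        # nu4 C3'-C4'-O4'-C1'
  vapply(seq_len(5L), function(k)
    dihedral(ring[idx[k, 1L], ], ring[idx[k, 2L], ],
             ring[idx[k, 3L], ], ring[idx[k, 4L], ], range = "180"),
    numeric(1L))
}

#' z-deviation of the sugar ring
#'
#' Signed perpendicular distances of C2' and C3' from the plane through
#' C4', O4' and C1'. The plane normal is
#' n = unit((C1' - C4') x (O4' - C4')) and z(X) = n . (X - C4'). The
#' cross-product order is fixed so that, for a natural D-deoxyribose,
#' positive z points towards the C5'/base face: an ideal C2'-endo sugar
#' gives z_c2 > 0 and an ideal C3'-endo sugar gives z_c3 > 0.
#'
#' @param res Residue atom table from [getResidue()].
#' @return List with `z_c2` and `z_c3` (Angstrom, signed).
#' @export
zDeviation <- function(res) {
  need <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  xyz <- lapply(need, atomXYZ, res = res)
  miss <- need[vapply(xyz, is.null, logical(1L))]
  if (length(miss))
    stop("z-deviation needs sugar atom(s): ", paste(miss, collapse = ", "))
  names(xyz) <- need
  n <- vunit(vcross(xyz[["C1'"]] - xyz[["C4'"]], xyz[["O4'"]] - xyz[["C4'"]]))
  list(z_c2 = sum(n * (xyz[["C2'"]] - xyz[["C4'"]])),
       z_c3 = sum(n * (xyz[["C3'"]] - xyz[["C4'"]])))
}

#' Glycosidic bond class from the chi torsion
#'
#' anti for chi in (170, 310) degrees (the anti restraint window 240 +/- 70
#' widened symmetrically to a closed decision rule), syn otherwise.
#'
#' @param chi Glycosidic torsion(s), degrees.
#' @return "anti", "syn" or NA.
#' @export
glycosidicClass <- function(chi) {
  ifelse(is.na(chi), NA_character_,
         ifelse(wrap360(chi) > 170 & wrap360(chi) < 310, "anti", "syn"))
}
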