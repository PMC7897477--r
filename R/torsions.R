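## Per-residue backbone/glycosidic torsions and the model-level geometry
## table. Standard nucleic-acid torsion definitions:
##   alpha:   O3'(i-1) - P - O5' - C5'
##   beta:    P - O5' - C5' - C4'
##   gamma:   O5' - C5' - C4' - C3'
##   delta:   C5' - C4' - C3' - O3'
##   epsilon: C4' - C3' - O3' - P(i+1)
##   zeta:    C3' - O3' - P(i+1) - O5'(i+1)
##   chi:     O4' - C1' - N9 - C4 (purine) / O4' - C1' - N1 - C2 (pyrimidine)

BACKBONE_DEFS <- list(
  alpha   = list(c("O3'", -1L), c("P", 0L), c("O5'", 0L), c("C5'", 0L)),
  beta    = list(c("P", 0L), c("O5'", 0L), c("C5'", 0L), c("C4'", 0L)),
  gamma   = list(c("O5'", 0L), c("C5'", 0L), c("C4'", 0L), c("C3'", 0L)),
  delta   = list(c("C5'", 0L), c("C4'", 0L), c("C3'", 0L), c("O3'", 0L)),
  epsilon = list(c("C4'", 0L), c("C3'", 0L), c("O3'", 0L), c("P", 1L)),
  zeta    = list(c("C3'", 0L), c("O3'", 0L), c("P", 1L), c("O5'", 1L))
)

#' Backbone and glycosidic torsions of one nucleotide
#'
#' @param res Residue atom table ([getResidue()]).
#' @param prev,nxt Atom tables of the 5' and 3' sequence neighbours, or NULL
#'   at chain termini.
#' @return Named list (alpha, beta, gamma, delta, epsilon, zeta, chi) of
#'   angles in degrees in [0, 360); NA where an angle is undefined (chain
#'   terminus or missing atom), with the reasons in attribute "undefined".
#' @export
backboneTorsions <- function(res, prev = NULL, nxt = NULL) {
  tabs <- list(`-1` = prev, `0` = res, `1` = nxt)
  reasons <- character(0)
  get1 <- function(spec) {
    tab <- tabs[[as.character(spec[2L])]]
    if (is.null(tab) || !nrow(tab)) return(NULL)
    atomXYZ(tab, spec[1L])
  }
  out <- lapply(names(BACKBONE_DEFS), function(ang) {
    pts <- lapply(BACKBONE_DEFS[[ang]], get1)
    bad <- vapply(pts, is.null, logical(1L))
    if (any(bad)) {
      which_bad <- vapply(BACKBONE_DEFS[[ang]][bad], `[`, character(1L), 1L)
      reasons[ang] <<- paste("missing", paste(which_bad, collapse = "/"))
      return(NA_real_)
    }
    tryCatch(dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]]),
             error = function(e) {
               reasons[ang] <<- conditionMessage(e)
               NA_real_
             })
  })
  names(out) <- names(BACKBONE_DEFS)
  out$chi <- tryCatch(chiTorsion(res), error = function(e) {
    reasons["chi"] <<- conditionMessage(e)
    NA_real_
  })
  structure(out, undefined = reasons)
}

#' Glycosidic torsion chi of a nucleotide
#'
#' O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param res Residue atom table.
#' @return chi in degrees in [0, 360).
#' @export
chiTorsion <- function(res) {
  nm <- if (isPurine(res)) c("O4'", "C1'", "N9", "C4")
        else c("O4'", "C1'", "N1", "C2")
  pts <- lapply(nm, atomXYZ, res = res)
  bad <- vapply(pts, is.null, logical(1L))
  if (any(bad)) stop("missing ", paste(nm[bad], collapse = "/"))
  dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}

PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Least-squares base plane of a residue
#'
#' Fits the ring atoms (purine 9-ring, pyrimidine 6-ring) by SVD; the normal
#' is oriented by the cyclic ring atom order (right-hand rule around the
#' ring traversal), so it is consistent for a given base type.
#'
#' @param res Residue atom table.
#' @return List with `centroid`, unit `normal` and out-of-plane `rms`
#'   (Angstrom).
#' @export
basePlane <- function(res) {
  ringnames <- if (isPurine(res)) PURINE_RING else PYRIMIDINE_RING
  xyz <- lapply(ringnames, atomXYZ, res = res)
  keep <- !vapply(xyz, is.null, logical(1L))
  if (sum(keep) < 3L)
    stop("base plane needs >= 3 ring atoms; found ", sum(keep))
  m <- do.call(rbind, xyz[keep])
  ## orientation from the ring traversal (first three present atoms)
  orient <- vcross(m[2L, ] - m[1L, ], m[3L, ] - m[2L, ])
  fitPlane(m, orient = orient)
}

#' Per-residue geometry table of a model
#'
#' Computes, for every nucleotide residue, the backbone torsions, chi,
#' pseudorotation (P, tau_m, pucker class), z-deviations and glycosidic
#' class. Sequence neighbours are the residues adjacent in deposited
#' numbering on the same chain (checked against O3'-P connectivity).
#'
#' @param model A [StructureModel-class].
#' @return data.frame with the fixed column order chain, resnum, base,
#'   alpha, beta, gamma, delta, epsilon, zeta, chi, P, tau_m, pucker_class,
#'   z_c2, z_c3, glycosidic.
#' @export
geometryTable <- function(model) {
  rt <- residueTable(model, nucOnly = TRUE)
  n <- nrow(rt)
  res_list <- lapply(seq_len(n), function(i)
    getResidue(model, rt$chain[i], rt$resno[i]))
  neighbour <- function(i, d) {
    j <- i + d
    if (j < 1L || j > n) return(NULL)
    if (rt$chain[j] != rt$chain[i] || rt$resno[j] != rt$resno[i] + d)
      return(NULL)
    res_list[[j]]
  }
  rows <- lapply(seq_len(n), function(i) {
    res <- res_list[[i]]
    tor <- backboneTorsions(res, neighbour(i, -1L), neighbour(i, 1L))
    nu <- sugarTorsions(res)
    pr <- if (is.null(nu)) list(P = NA_real_, tau_m = NA_real_,
                                pucker_class = NA_character_)
          else pseudorotation(nu)
    zd <- tryCatch(zDeviation(res),
                   error = function(e) list(z_c2 = NA_real_, z_c3 = NA_real_))
    data.frame(chain = rt$chain[i], resnum = rt$resno[i], base = rt$base[i],
               alpha = tor$alpha, beta = tor$beta, gamma = tor$gamma,
               delta = tor$delta, epsilon = tor$epsilon, zeta = tor$zeta,
               chi = tor$chi, P = pr$P, tau_m = pr$tau_m,
               pucker_class = pr$pucker_class, z_c2 = zd$z_c2,
               z_c3 = zd$z_c3, glycosidic = glycosidicClass(tor$chi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a geometry table as TSV
#'
#' @param tab Output of [geometryTable()].
#' @param path Output file.
#' @export
writeGeometryTSV <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
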