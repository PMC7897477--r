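## Central S4 containers. Atom and residue records live as rows of the
## `atoms` data.frame slot (bio3d-style) rather than one object per atom;
## residue-level views are provided by accessors.

#' @import methods
NULL

REQUIRED_ATOM_COLS <- c("chain", "resno", "resid", "base", "elety", "elem",
                        "x", "y", "z", "o", "is_nuc", "is_h")

#' StructureModel: one coordinate model of a nucleic-acid structure
#'
#' Holds the atom table of a single model (chains, residues, named atoms with
#' positions in Angstrom). Atom names are stored in the primed convention
#' (C1', O4', ...); residues keep their deposited numbering.
#'
#' @slot atoms data.frame with columns chain, resno, resid, base, elety,
#'   elem, x, y, z, o (occupancy), is_nuc, is_h.
#' @slot modelIndex Integer model number (1-based).
#' @slot sourceId Free-text origin (file name, accession or "synthetic").
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", modelIndex = "integer",
                 sourceId = "character"),
  prototype(modelIndex = 1L, sourceId = "")
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  miss <- setdiff(REQUIRED_ATOM_COLS, names(a))
  if (length(miss)) return(paste("atom table lacks columns:",
                                 paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(!nzchar(a$elety))) return("empty atom names")
    key <- paste(a$chain, a$resno, a$elety)
    if (anyDuplicated(key))
      return("duplicate atom name within a residue")
  }
  TRUE
})

#' Construct a StructureModel from an atom table
#' @param atoms Atom data.frame (see [StructureModel-class]).
#' @param modelIndex Integer model number.
#' @param sourceId Origin string.
#' @return A [StructureModel-class] object.
#' @export
StructureModel <- function(atoms, modelIndex = 1L, sourceId = "") {
  atoms <- as.data.frame(atoms)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, modelIndex = as.integer(modelIndex),
      sourceId = sourceId)
}

#' Tetrad: a planar cyclic Hoogsteen-bonded guanine quartet
#'
#' @slot members data.frame (chain, resno) of the four guanines in cyclic
#'   donor-to-acceptor order (member i donates N2-H/N1-H to member i+1 mod 4).
#' @slot planarityRms Out-of-plane RMS of the 36 ring atoms (Angstrom).
#' @slot layer "outer", "inner" or "unassigned".
#' @slot centroid,normal Fitted-plane centroid and unit normal.
#' @export
setClass("Tetrad",
  representation(members = "data.frame", planarityRms = "numeric",
                 layer = "character", centroid = "numeric",
                 normal = "numeric"),
  prototype(layer = "unassigned")
)

setValidity("Tetrad", function(object) {
  if (nrow(object@members) != 4L) return("a tetrad has exactly 4 members")
  if (length(object@planarityRms) && object@planarityRms >= 1.0)
    return("tetrad planarity RMS must be < 1.0 Angstrom")
  TRUE
})

#' G4Core: the assembled stacked tetrad core
#'
#' @slot tetrads List of [Tetrad-class], ordered bottom-to-top along the
#'   stacking axis (axis oriented 5' to 3' by majority column direction).
#' @slot columns data.frame (column, block, position, chain, resno): core
#'   guanines grouped into the four G-columns of each block.
#' @slot stepTwists data.frame (step, twist, interface): per-step mean signed
#'   twist (degrees) and whether the step is a block-block interface.
#' @slot blocks Integer vector: block id of each tetrad.
#' @slot handedness "left", "right" or "mixed".
#' @slot axis Unit stacking axis (5' to 3').
#' @export
setClass("G4Core",
  representation(tetrads = "list", columns = "data.frame",
                 stepTwists = "data.frame", blocks = "integer",
                 handedness = "character", axis = "numeric")
)

#' ReferenceProfile: circular torsion/pucker statistics of non-bulged cores
#'
#' @slot stats data.frame (angle, mean, sd, n) with circular mean and
#'   circular sd in degrees per angle name (epsilon, zeta, alpha+1, beta+1,
#'   gamma+1, chi, P).
#' @slot majorityPucker Majority sugar pucker class of the core guanines.
#' @slot sourceIds Structures pooled into the profile.
#' @slot handedness "left" or "right".
#' @export
setClass("ReferenceProfile",
  representation(stats = "data.frame", majorityPucker = "character",
                 sourceIds = "character", handedness = "character")
)

setValidity("ReferenceProfile", function(object) {
  s <- object@stats
  if (!all(c("angle", "mean", "sd", "n") %in% names(s)))
    return("stats must have columns angle, mean, sd, n")
  if (nrow(s) && any(s$mean < 0 | s$mean >= 360, na.rm = TRUE))
    return("circular means must lie in [0, 360)")
  if (!object@handedness %in% c("left", "right"))
    return("profile handedness must be left or right")
  TRUE
})

## ------------------------------------------------------------------
## Accessors

#' @describeIn StructureModel-class the atom table
#' @param x A StructureModel.
#' @export
atomTable <- function(x) x@atoms

#' Source identifier of a model
#' @param x A StructureModel.
#' @export
sourceId <- function(x) x@sourceId

#' Model index of a model
#' @param x A StructureModel.
#' @export
modelIndex <- function(x) x@modelIndex

#' Residue-level summary of a model
#'
#' @param x A [StructureModel-class].
#' @param nucOnly Keep only nucleotide residues.
#' @return data.frame with one row per residue (chain, resno, resid, base,
#'   is_nuc), in file order.
#' @export
residueTable <- function(x, nucOnly = FALSE) {
  a <- atomTable(x)
  key <- !duplicated(paste(a$chain, a$resno))
  r <- a[key, c("chain", "resno", "resid", "base", "is_nuc")]
  rownames(r) <- NULL
  if (nucOnly) r <- r[r$is_nuc, , drop = FALSE]
  r
}

#' Extract one residue's atoms
#'
#' @param x A [StructureModel-class].
#' @param chain Chain identifier.
#' @param resno Residue number (deposited numbering).
#' @return data.frame of the residue's atom rows (possibly empty).
#' @export
getResidue <- function(x, chain, resno) {
  a <- atomTable(x)
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

#' Coordinates of one named atom in a residue table
#'
#' @param res Residue atom table from [getResidue()].
#' @param name Canonical atom name (primed convention).
#' @return Numeric length-3 vector, or NULL when the atom is absent.
#' @export
atomXYZ <- function(res, name) {
  i <- which(res$elety == name)
  if (!length(i)) return(NULL)
  as.numeric(res[i[1L], c("x", "y", "z")])
}

#' Is a residue a purine?
#' @param res Residue atom table.
#' @keywords internal
isPurine <- function(res) {
  b <- res$base[1L]
  if (!is.na(b) && b %in% c("G", "A")) return(TRUE)
  if (!is.na(b) && b %in% c("T", "C", "U")) return(FALSE)
  ## fall back on atom content
  "N9" %in% res$elety
}

## Coordinate matrix of a model (n x 3)
modelXYZ <- function(x) {
  a <- atomTable(x)
  cbind(a$x, a$y, a$z)
}

## Replace the coordinates of a model
`modelXYZ<-` <- function(x, value) {
  a <- atomTable(x)
  stopifnot(nrow(value) == nrow(a), ncol(value) == 3L)
  a$x <- value[, 1L]; a$y <- value[, 2L]; a$z <- value[, 3L]
  initialize(x, atoms = a)
}

## ------------------------------------------------------------------
## show methods

setMethod("show", "StructureModel", function(object) {
  r <- residueTable(object)
  cat("StructureModel", if (nzchar(object@sourceId))
        paste0("[", object@sourceId, "]") else "",
      "model", object@modelIndex, "\n")
  cat(" ", nrow(object@atoms), "atoms,", nrow(r), "residues,",
      length(unique(r$chain)), "chain(s)\n")
  nuc <- r[r$is_nuc, ]
  if (nrow(nuc))
    cat("  nucleotides:", paste0(table(nuc$base), " ",
        names(table(nuc$base)), collapse = ", "), "\n")
})

setMethod("show", "Tetrad", function(object) {
  m <- object@members
  cat("Tetrad:", paste0(m$chain, m$resno, collapse = " -> "),
      sprintf("(planarity RMS %.3f A, %s)\n",
              object@planarityRms, object@layer))
})

setMethod("show", "G4Core", function(object) {
  cat("G4Core:", length(object@tetrads), "tetrad(s),",
      length(unique(object@blocks)), "block(s), handedness:",
      object@handedness, "\n")
  if (nrow(object@stepTwists)) {
    st <- object@stepTwists
    cat("  step twists (deg):",
        paste(sprintf("%.1f%s", st$twist,
                      ifelse(st$interface, "*", "")), collapse = ", "),
        "(* = block interface)\n")
  }
})

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile (", object@handedness, "-handed, ",
      length(object@sourceIds), " structure(s))\n", sep = "")
  print(object@stats, row.names = FALSE, digits = 4)
  cat("  majority pucker:", object@majorityPucker, "\n")
})
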