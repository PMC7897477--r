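## Rigid-body least-squares superposition (Kabsch closed form, proper
## rotations only) and ensemble pairwise RMSD.

#' Optimal rigid-body superposition of two corresponding atom sets
#'
#' Kabsch SVD closed form restricted to proper rotations (the determinant
#' correction forbids reflections). The returned transform maps the mobile
#' set onto the reference: `t(rotation %*% t(mobile)) + translation`.
#'
#' @param reference,mobile Numeric n x 3 coordinate matrices in atom
#'   correspondence order, n >= 3.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3 proper rotation),
#'   `translation` (length-3) and `fitted` (the transformed mobile set).
#' @export
superposeRmsd <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!identical(dim(reference), dim(mobile)))
    stop("correspondence error: reference has ", nrow(reference),
         " atoms but mobile has ", nrow(mobile))
  if (nrow(reference) < 3L)
    stop("superposition needs at least 3 atoms")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2L, cr)
  B <- sweep(mobile, 2L, cm)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- t(R %*% t(B)) + matrix(cr, nrow(B), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rmsd = rmsd, rotation = R,
       translation = as.numeric(cr - R %*% cm), fitted = fitted)
}

#' Mean pairwise RMSD over a coordinate ensemble
#'
#' Superposes every unordered pair of models on the atoms chosen by
#' `selector` and summarizes the pairwise RMSD distribution, as is done for
#' NMR ensembles.
#'
#' @param models List of [StructureModel-class] with identical residue
#'   content.
#' @param selector Predicate `function(atoms)` returning a logical vector
#'   over the atom-table rows; defaults to all heavy (non-hydrogen) atoms.
#' @return List with `mean`, `sd` (Angstrom), `n_pairs` and the vector of
#'   pairwise `rmsds`.
#' @export
ensemblePairwiseRmsd <- function(models, selector = NULL) {
  if (length(models) < 2L) stop("ensemble RMSD needs >= 2 models")
  if (is.null(selector)) selector <- function(atoms) !atoms$is_h
  sel_xyz <- lapply(models, function(m) {
    a <- atomTable(m)
    keep <- selector(a)
    if (sum(keep) < 3L) stop("atom selector yields fewer than 3 atoms")
    ## fixed correspondence order: chain, residue number, atom name
    a <- a[keep, , drop = FALSE]
    a <- a[order(a$chain, a$resno, a$elety), , drop = FALSE]
    cbind(a$x, a$y, a$z)
  })
  nref <- vapply(sel_xyz, nrow, integer(1L))
  if (length(unique(nref)) != 1L)
    stop("models select different atom counts: ",
         paste(unique(nref), collapse = ", "))
  pairs <- utils::combn(length(models), 2L)
  rmsds <- apply(pairs, 2L, function(p)
    superposeRmsd(sel_xyz[[p[1L]]], sel_xyz[[p[2L]]])$rmsd)
  list(mean = mean(rmsds), sd = stats::sd(rmsds),
       n_pairs = ncol(pairs), rmsds = rmsds)
}

#' Superpose two models on corresponding named atoms
#'
#' Builds the atom correspondence by (chain, residue number, atom name),
#' optionally restricted by a selector, then calls [superposeRmsd()].
#'
#' @param reference,mobile [StructureModel-class] objects.
#' @param selector Predicate on atom-table rows (default: heavy atoms).
#' @return As [superposeRmsd()], plus `n_atoms` used.
#' @export
superposeModels <- function(reference, mobile, selector = NULL) {
  if (is.null(selector)) selector <- function(atoms) !atoms$is_h
  key <- function(a) paste(a$chain, a$resno, a$elety, sep = "|")
  ar <- atomTable(reference); am <- atomTable(mobile)
  ar <- ar[selector(ar), , drop = FALSE]
  am <- am[selector(am), , drop = FALSE]
  common <- intersect(key(ar), key(am))
  if (length(common) < 3L)
    stop("correspondence error: only ", length(common), " shared atoms; ",
         "unmatched e.g. ", paste(utils::head(setdiff(key(ar), key(am)), 3L),
                                  collapse = ", "))
  ar <- ar[match(common, key(ar)), ]
  am <- am[match(common, key(am)), ]
  out <- superposeRmsd(cbind(ar$x, ar$y, ar$z), cbind(am$x, am$y, am$z))
  out$n_atoms <- length(common)
  out
}
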