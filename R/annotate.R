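## G4 annotation: Hoogsteen tetrad detection, core assembly into columns
## and blocks, handedness classification, and classification of non-core
## nucleotides into bulges, loops, linkers and overhangs.

#' Detect Hoogsteen-bonded G-tetrads
#'
#' Builds the directed guanine donor-acceptor graph from heavy-atom
#' criteria (N2 -> N7 and N1 -> O6 both within `cutoff`; when hydrogens are
#' present, H21 -> N7 and H1 -> O6 must additionally be within
#' `hCutoff`), enumerates directed 4-cycles, filters them by tetrad
#' planarity, and resolves shared-guanine conflicts greedily by best
#' planarity.
#'
#' @param model A [StructureModel-class].
#' @param cutoff Heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param hCutoff Hydrogen-acceptor cutoff (used only when hydrogens
#'   exist), Angstrom.
#' @param planarityMax Maximum out-of-plane RMS of the 4 x 9 ring atoms.
#' @return List of [Tetrad-class] (possibly empty).
#' @export
detectTetrads <- function(model, cutoff = 3.5, hCutoff = 2.5,
                          planarityMax = 1.0) {
  rt <- residueTable(model)
  gs <- rt[rt$base %in% "G", , drop = FALSE]
  if (nrow(gs) < 4L) return(list())
  res <- lapply(seq_len(nrow(gs)), function(i)
    getResidue(model, gs$chain[i], gs$resno[i]))
  getA <- function(i, nm) atomXYZ(res[[i]], nm)
  n <- nrow(gs)
  ## directed Hoogsteen edges i -> j (i donates N2-H/N1-H to j)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    n2 <- getA(i, "N2"); n1 <- getA(i, "N1")
    h21 <- getA(i, "H21"); h1 <- getA(i, "H1")
    if (is.null(n2) || is.null(n1)) next
    for (j in seq_len(n)) {
      if (i == j) next
      n7 <- getA(j, "N7"); o6 <- getA(j, "O6")
      if (is.null(n7) || is.null(o6)) next
      ok <- vnorm(n2 - n7) <= cutoff && vnorm(n1 - o6) <= cutoff
      if (ok && !is.null(h21)) ok <- vnorm(h21 - n7) <= hCutoff
      if (ok && !is.null(h1)) ok <- vnorm(h1 - o6) <= hCutoff
      if (ok) adj[[i]] <- c(adj[[i]], j)
    }
  }
  ## enumerate directed 4-cycles i -> j -> k -> l -> i
  cands <- list()
  seen <- character(0)
  for (i in seq_len(n)) for (j in adj[[i]]) for (k in adj[[j]]) {
    if (k %in% c(i, j)) next
    for (l in adj[[k]]) {
      if (l %in% c(i, j, k)) next
      if (!(i %in% adj[[l]])) next
      cyc <- c(i, j, k, l)
      rot <- which.min(cyc)
      cyc <- cyc[((seq_len(4L) + rot - 2L) %% 4L) + 1L]
      key <- paste(cyc, collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- cyc
    }
  }
  if (!length(cands)) return(list())
  ## planarity of each candidate
  mk <- function(cyc) {
    ringxyz <- do.call(rbind, lapply(cyc, function(i) {
      nm <- intersect(PURINE_RING, res[[i]]$elety)
      do.call(rbind, lapply(nm, atomXYZ, res = res[[i]]))
    }))
    pl <- fitPlane(ringxyz)
    ## orient the tetrad normal along the mean member base normal
    bn <- rowMeans(vapply(cyc, function(i) basePlane(res[[i]])$normal,
                          numeric(3L)))
    if (sum(pl$normal * bn) < 0) pl$normal <- -pl$normal
    new("Tetrad",
        members = data.frame(chain = gs$chain[cyc], resno = gs$resno[cyc],
                             stringsAsFactors = FALSE),
        planarityRms = pl$rms, layer = "unassigned",
        centroid = pl$centroid, normal = pl$normal)
  }
  tets <- lapply(cands, mk)
  tets <- tets[vapply(tets, function(t) t@planarityRms < planarityMax,
                      logical(1L))]
  if (!length(tets)) return(list())
  ## greedy conflict resolution by planarity
  tets <- tets[order(vapply(tets, slot, numeric(1L), "planarityRms"))]
  used <- character(0)
  keep <- list()
  for (t in tets) {
    ids <- paste(t@members$chain, t@members$resno)
    if (any(ids %in% used)) next
    used <- c(used, ids)
    keep[[length(keep) + 1L]] <- t
  }
  keep
}

#' Assemble detected tetrads into a G4 core
#'
#' Orders the tetrads along the mean stacking axis, links guanines of
#' adjacent tetrads into G-columns by minimal C1' distance assignment,
#' labels outer/inner layers, computes per-step signed twists about the
#' local inter-tetrad axis (oriented 5' to 3' by the majority column
#' sequence direction), splits blocks where the stacking polarity inverts,
#' and classifies handedness from the intra-block twists.
#'
#' @param tetrads List of [Tetrad-class] from [detectTetrads()].
#' @param model The [StructureModel-class] they came from.
#' @param maxSeparation Maximum centroid separation of stacked tetrads
#'   (Angstrom); farther tetrads are reported as separate cores.
#' @param allCores Return all stacked cores instead of the largest.
#' @return A [G4Core-class] (the largest stack), or a list of them when
#'   `allCores = TRUE`. A warning reports left-out tetrads.
#' @export
assembleCore <- function(tetrads, model, maxSeparation = 6,
                         allCores = FALSE) {
  if (!length(tetrads)) stop("no tetrads to assemble")
  nt <- length(tetrads)
  cent <- t(vapply(tetrads, slot, numeric(3L), "centroid"))
  ## stacking adjacency graph -> connected components
  adjacent <- function(i, j)
    vnorm(cent[i, ] - cent[j, ]) <= maxSeparation
  comp <- seq_len(nt)
  for (i in seq_len(nt)) for (j in seq_len(nt))
    if (i < j && adjacent(i, j)) comp[comp == comp[j]] <- comp[i]
  groups <- split(seq_len(nt), comp)
  groups <- groups[order(-lengths(groups))]
  cores <- lapply(groups, function(idx)
    buildCoreFromStack(tetrads[idx], model))
  if (length(groups) > 1L && !allCores)
    warning(length(groups) - 1L,
            " tetrad group(s) not stacked with the main core; ",
            "use allCores = TRUE to get them all")
  if (allCores) cores else cores[[1L]]
}

buildCoreFromStack <- function(tetrads, model) {
  nt <- length(tetrads)
  cent <- t(vapply(tetrads, slot, numeric(3L), "centroid"))
  ## order along the principal axis of the centroids
  axis <- if (nt > 1L) {
    sv <- svd(sweep(cent, 2L, colMeans(cent)))
    sv$v[, 1L]
  } else tetrads[[1L]]@normal
  ord <- order(cent %*% axis)
  tetrads <- tetrads[ord]
  cent <- cent[ord, , drop = FALSE]
  memberRes <- function(t) lapply(seq_len(4L), function(k)
    getResidue(model, t@members$chain[k], t@members$resno[k]))
  resL <- lapply(tetrads, memberRes)
  ## columns: assign members of adjacent tetrads by minimal C1' distance
  perms <- permutations4()
  colId <- matrix(NA_integer_, nt, 4L)
  colId[1L, ] <- 1:4
  if (nt > 1L) for (t in seq_len(nt - 1L)) {
    c1a <- t(vapply(resL[[t]], atomXYZ, numeric(3L), name = "C1'"))
    c1b <- t(vapply(resL[[t + 1L]], atomXYZ, numeric(3L), name = "C1'"))
    cost <- vapply(seq_len(nrow(perms)), function(p)
      sum(vapply(1:4, function(k)
        vnorm(c1a[k, ] - c1b[perms[p, k], ]), numeric(1L))), numeric(1L))
    pm <- perms[which.min(cost), ]
    colId[t + 1L, pm] <- colId[t, ]
  }
  ## 5'->3' axis orientation by majority column sequence direction
  if (nt > 1L) {
    dirs <- vapply(1:4, function(cc) {
      rn <- vapply(seq_len(nt), function(t)
        tetrads[[t]]@members$resno[match(cc, colId[t, ])], numeric(1L))
      proj <- cent[, , drop = FALSE] %*% axis
      sign(stats::cor(rn, as.numeric(proj)))
    }, numeric(1L))
    if (sum(dirs, na.rm = TRUE) < 0) {
      axis <- -axis
      ord2 <- rev(seq_len(nt))
      tetrads <- tetrads[ord2]
      resL <- resL[ord2]
      colId <- colId[ord2, , drop = FALSE]
      cent <- cent[ord2, , drop = FALSE]
    }
  }
  ## polarity (block splits) from tetrad normals
  normals <- t(vapply(tetrads, slot, numeric(3L), "normal"))
  blocks <- integer(nt)
  blocks[1L] <- 1L
  if (nt > 1L) for (t in seq_len(nt - 1L)) {
    inv <- sum(normals[t, ] * normals[t + 1L, ]) < 0
    blocks[t + 1L] <- blocks[t] + as.integer(inv)
  }
  ## layer labels: stack ends are outer
  for (t in seq_len(nt))
    tetrads[[t]]@layer <- if (t == 1L || t == nt) "outer" else "inner"
  ## per-step twists (mean over the four columns)
  steps <- if (nt > 1L) data.frame(
    step = seq_len(nt - 1L),
    twist = vapply(seq_len(nt - 1L), function(t) {
      ax <- cent[t + 1L, ] - cent[t, ]
      if (vnorm(ax) < 1e-6) ax <- axis
      if (sum(ax * axis) < 0) ax <- -ax
      mean(vapply(1:4, function(cc) {
        ka <- match(cc, colId[t, ]); kb <- match(cc, colId[t + 1L, ])
        stackingTwist(resL[[t]][[ka]], resL[[t + 1L]][[kb]], ax)
      }, numeric(1L)))
    }, numeric(1L)),
    interface = blocks[-nt] != blocks[-1L])
  else data.frame(step = integer(0), twist = numeric(0),
                  interface = logical(0))
  ## columns table (per block: a column is broken at interfaces)
  cols <- do.call(rbind, lapply(seq_len(nt), function(t)
    data.frame(column = colId[t, ], block = blocks[t], position = t,
               chain = tetrads[[t]]@members$chain,
               resno = tetrads[[t]]@members$resno,
               stringsAsFactors = FALSE)))
  cols <- cols[order(cols$block, cols$column, cols$position), ]
  rownames(cols) <- NULL
  core <- new("G4Core", tetrads = tetrads, columns = cols,
              stepTwists = steps, blocks = blocks,
              handedness = "mixed", axis = as.numeric(axis))
  core@handedness <- classifyHandedness(core)
  core
}

permutations4 <- function() {
  m <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  m[apply(m, 1L, function(r) length(unique(r)) == 4L), , drop = FALSE]
}

#' Classify helical handedness of a G4 core
#'
#' left when the mean intra-block signed stacking twist is below -10
#' degrees, right when above +10, otherwise mixed. Block-interface steps
#' are excluded from the statistic.
#'
#' @param core A [G4Core-class].
#' @return "left", "right" or "mixed".
#' @export
classifyHandedness <- function(core) {
  st <- core@stepTwists
  intra <- st$twist[!st$interface]
  if (!length(intra)) {
    warning("no intra-block steps; handedness is undetermined")
    return("mixed")
  }
  m <- mean(intra)
  if (m < -10) "left" else if (m > 10) "right" else "mixed"
}

coreMemberKeys <- function(core) {
  unlist(lapply(core@tetrads, function(t)
    paste(t@members$chain, t@members$resno)))
}

#' Classify non-core nucleotides into structural elements
#'
#' Partitions every nucleotide outside the tetrad core into maximal
#' connected runs and classifies each run from its anchoring core
#' guanines: bulge (anchors are consecutive members of the same G-column),
#' loop (different columns of the same block), linker (different blocks),
#' overhang (an anchor is missing). Runs are split at backbone breaks
#' (O3'-P distance above `bondCutoff`) with a warning.
#'
#' @param core A [G4Core-class].
#' @param model The [StructureModel-class].
#' @param bondCutoff O3'-P connectivity cutoff, Angstrom.
#' @param cappingPlane,cappingLateral Capping-flag thresholds: maximum
#'   distance from an outer tetrad plane and maximum lateral centroid
#'   offset, Angstrom.
#' @return data.frame with one row per element: element id, kind,
#'   residues (comma-joined), previous/next core anchors, capping flag and
#'   sugar orientation of the first residue.
#' @export
classifyElements <- function(core, model, bondCutoff = 2.5,
                             cappingPlane = 4.5, cappingLateral = 4) {
  rt <- residueTable(model, nucOnly = TRUE)
  keys <- paste(rt$chain, rt$resno)
  coreKeys <- coreMemberKeys(core)
  isCore <- keys %in% coreKeys
  n <- nrow(rt)
  connected <- function(i, j) {
    ## sequence neighbours on the same chain, checked for a backbone bond
    if (rt$chain[i] != rt$chain[j] || rt$resno[j] != rt$resno[i] + 1L)
      return(FALSE)
    o3 <- atomXYZ(getResidue(model, rt$chain[i], rt$resno[i]), "O3'")
    p <- atomXYZ(getResidue(model, rt$chain[j], rt$resno[j]), "P")
    if (is.null(o3) || is.null(p)) return(TRUE)
    vnorm(o3 - p) <= bondCutoff
  }
  ## maximal connected non-core runs (split at backbone breaks)
  elements <- list()
  i <- 1L
  while (i <= n) {
    if (isCore[i]) { i <- i + 1L; next }
    run <- i
    while (i < n && !isCore[i + 1L] && connected(i, i + 1L)) {
      i <- i + 1L
      run <- c(run, i)
    }
    if (i < n && !isCore[i + 1L])
      warning("backbone break after residue ", rt$resno[i],
              "; splitting element")
    elements[[length(elements) + 1L]] <- run
    i <- i + 1L
  }
  cols <- core@columns
  colKey <- paste(cols$chain, cols$resno)
  anchorInfo <- function(idx) {
    if (is.na(idx)) return(NULL)
    k <- match(paste(rt$chain[idx], rt$resno[idx]), colKey)
    if (is.na(k)) return(NULL)
    cols[k, ]
  }
  out <- lapply(seq_along(elements), function(e) {
    run <- elements[[e]]
    prevIdx <- if (run[1L] > 1L && isCore[run[1L] - 1L] &&
                   connected(run[1L] - 1L, run[1L]))
      run[1L] - 1L else NA_integer_
    lastR <- utils::tail(run, 1L)
    nextIdx <- if (lastR < n && isCore[lastR + 1L] &&
                   connected(lastR, lastR + 1L))
      lastR + 1L else NA_integer_
    ap <- anchorInfo(prevIdx); an <- anchorInfo(nextIdx)
    kind <- if (is.null(ap) || is.null(an)) "overhang"
      else if (ap$block != an$block) "linker"
      else if (ap$column != an$column) "loop"
      else if (abs(ap$position - an$position) == 1L) "bulge"
      else "linker"
    ## capping: base centroid close to an outer tetrad plane
    capping <- FALSE
    ctrs <- lapply(run, function(ri) {
      r <- getResidue(model, rt$chain[ri], rt$resno[ri])
      tryCatch(basePlane(r)$centroid, error = function(e) NULL)
    })
    for (tt in core@tetrads) {
      if (tt@layer != "outer") next
      for (ctr in ctrs) {
        if (is.null(ctr)) next
        d <- ctr - tt@centroid
        dz <- abs(sum(d * tt@normal))
        lat <- vnorm(d - sum(d * tt@normal) * tt@normal)
        if (dz <= cappingPlane && lat < cappingLateral) capping <- TRUE
      }
    }
    so <- sugarOrientation(
      getResidue(model, rt$chain[run[1L]], rt$resno[run[1L]]), core, model)
    data.frame(element = e, kind = kind,
               residues = paste(rt$resno[run], collapse = ","),
               chain = rt$chain[run[1L]],
               previous_core = if (is.null(ap)) NA_integer_ else
                 as.integer(rt$resno[prevIdx]),
               next_core = if (is.null(an)) NA_integer_ else
                 as.integer(rt$resno[nextIdx]),
               capping = capping, sugar_orientation = so,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(element = integer(0), kind = character(0),
                      residues = character(0), chain = character(0),
                      previous_core = integer(0), next_core = integer(0),
                      capping = logical(0), sugar_orientation = character(0))
  rownames(out) <- NULL
  out
}

#' Local sugar orientation of a residue relative to the nearest tetrad
#'
#' The orientation vector is C5' -> C3'. It is compared against the mean
#' C5' -> C3' vector of the guanines of the nearest tetrad: parallel for a
#' positive dot product, antiparallel for negative, undefined when the
#' absolute cosine is below 0.1 or atoms are missing.
#'
#' @param res Residue atom table.
#' @param core A [G4Core-class].
#' @param model The model the core came from.
#' @return "parallel", "antiparallel" or "undefined".
#' @export
sugarOrientation <- function(res, core, model) {
  c5 <- atomXYZ(res, "C5'"); c3 <- atomXYZ(res, "C3'")
  if (is.null(c5) || is.null(c3)) return("undefined")
  v <- c3 - c5
  ctr <- tryCatch(basePlane(res)$centroid,
                  error = function(e) (c5 + c3) / 2)
  dmin <- vapply(core@tetrads, function(t) vnorm(t@centroid - ctr),
                 numeric(1L))
  tt <- core@tetrads[[which.min(dmin)]]
  ref <- rowMeans(vapply(seq_len(4L), function(k) {
    r <- getResidue(model, tt@members$chain[k], tt@members$resno[k])
    a <- atomXYZ(r, "C5'"); b <- atomXYZ(r, "C3'")
    if (is.null(a) || is.null(b)) return(c(0, 0, 0))
    b - a
  }, numeric(3L)))
  if (vnorm(ref) < 1e-6) return("undefined")
  cosang <- sum(vunit(v) * vunit(ref))
  if (abs(cosang) < 0.1) "undefined"
  else if (cosang > 0) "parallel" else "antiparallel"
}

#' One-call annotation of a structure model
#'
#' Runs tetrad detection, core assembly and element classification and
#' returns the combined annotation.
#'
#' @param model A [StructureModel-class].
#' @param ... Passed to [detectTetrads()].
#' @return List with `tetrads`, `core` (or NULL when fewer than one tetrad
#'   is found), `elements`, and `handedness`.
#' @export
annotateG4 <- function(model, ...) {
  tets <- detectTetrads(model, ...)
  if (!length(tets))
    return(list(tetrads = list(), core = NULL,
                elements = NULL, handedness = "none"))
  core <- suppressWarnings(assembleCore(tets, model))
  list(tetrads = core@tetrads, core = core,
       elements = classifyElements(core, model),
       handedness = core@handedness)
}
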