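## Transition-angle and sugar-pucker comparison of bulged G4s against
## reference profiles built from non-bulged structures.

TRANSITION_ANGLES <- c("epsilon", "zeta", "alpha+1", "beta+1", "gamma+1")

## torsions of one core step (5' residue g5 -> 3' residue g3), named by the
## transition-angle convention
transitionValues <- function(model, chain5, res5, chain3, res3) {
  gtab <- NULL
  r5 <- getResidue(model, chain5, res5)
  r3 <- getResidue(model, chain3, res3)
  n5 <- getResidue(model, chain5, res5 + 1L)
  p3 <- getResidue(model, chain3, res3 - 1L)
  t5 <- backboneTorsions(r5, NULL, n5)
  t3 <- backboneTorsions(r3, p3, NULL)
  c("epsilon" = t5$epsilon, "zeta" = t5$zeta, "alpha+1" = t3$alpha,
    "beta+1" = t3$beta, "gamma+1" = t3$gamma)
}

#' Build a reference torsion/pucker profile from non-bulged structures
#'
#' Annotates each structure, rejects any containing a bulge or whose
#' handedness differs from the declared one, then pools the transition
#' angles of every intra-block core step whose guanines are sequence
#' neighbours, plus chi and the pseudorotation phase P of every core
#' guanine, into circular means and circular standard deviations.
#'
#' @param models A [StructureModel-class] or list of them.
#' @param handedness "left" or "right".
#' @return A [ReferenceProfile-class].
#' @export
buildReferenceProfile <- function(models, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  if (inherits(models, "StructureModel")) models <- list(models)
  pools <- stats::setNames(
    vector("list", length(TRANSITION_ANGLES) + 2L),
    c(TRANSITION_ANGLES, "chi", "P"))
  classes <- character(0)
  ids <- character(0)
  for (m in models) {
    ann <- annotateG4(m)
    if (is.null(ann$core))
      stop("reference structure ", sourceId(m), " contains no G4 core")
    if (any(ann$elements$kind == "bulge"))
      stop("reference structure ", sourceId(m), " contains bulge(s) (",
           paste(ann$elements$residues[ann$elements$kind == "bulge"],
                 collapse = "; "),
           ") and cannot enter a non-bulged profile")
    if (ann$handedness != handedness)
      stop("reference structure ", sourceId(m), " is ", ann$handedness,
           "-handed, not ", handedness)
    ids <- c(ids, sourceId(m))
    st <- coreSteps(ann$core)
    for (k in seq_len(nrow(st))) {
      tv <- transitionValues(m, st$chain5[k], st$res5[k],
                             st$chain3[k], st$res3[k])
      for (nm in TRANSITION_ANGLES)
        pools[[nm]] <- c(pools[[nm]], tv[[nm]])
    }
    gt <- geometryTable(m)
    ck <- coreMemberKeys(ann$core)
    gcore <- gt[paste(gt$chain, gt$resnum) %in% ck, ]
    pools[["chi"]] <- c(pools[["chi"]], gcore$chi)
    pools[["P"]] <- c(pools[["P"]], gcore$P)
    classes <- c(classes, gcore$pucker_class)
  }
  stats <- do.call(rbind, lapply(names(pools), function(nm) {
    v <- pools[[nm]][!is.na(pools[[nm]])]
    data.frame(angle = nm, mean = circularMean(v), sd = circularSd(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  maj <- names(sort(table(classes), decreasing = TRUE))[1L]
  new("ReferenceProfile", stats = stats, majorityPucker = maj,
      sourceIds = ids, handedness = handedness)
}

## intra-block core steps with sequence-adjacent guanines:
## data.frame(chain5, res5, chain3, res3)
coreSteps <- function(core) {
  cols <- core@columns
  out <- list()
  for (key in unique(paste(cols$block, cols$column))) {
    cc <- cols[paste(cols$block, cols$column) == key, ]
    cc <- cc[order(cc$position), ]
    if (nrow(cc) < 2L) next
    for (i in seq_len(nrow(cc) - 1L)) {
      a <- cc[i, ]; b <- cc[i + 1L, ]
      if (a$chain != b$chain) next
      if (b$resno == a$resno + 1L)
        out[[length(out) + 1L]] <- data.frame(
          chain5 = a$chain, res5 = a$resno, chain3 = b$chain,
          res3 = b$resno, stringsAsFactors = FALSE)
      else if (a$resno == b$resno + 1L)
        out[[length(out) + 1L]] <- data.frame(
          chain5 = b$chain, res5 = b$resno, chain3 = a$chain,
          res3 = a$resno, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chain5 = character(0),
                                      res5 = integer(0),
                                      chain3 = character(0),
                                      res3 = integer(0)))
  do.call(rbind, out)
}

#' Extract the transition records around every bulge
#'
#' With the default "step" convention, each bulge yields two records: the
#' previous side measures the backbone step from the core guanine on the
#' 5' side into the first bulge residue (epsilon, zeta on the guanine;
#' alpha, beta, gamma on the bulge residue), the next side the step from
#' the last bulge residue into the 3'-side core guanine. The "skip"
#' convention instead measures all five angles on the flanking guanines
#' themselves, ignoring the bulge backbone (one record, side "skip").
#'
#' @param core A [G4Core-class].
#' @param elements Output of [classifyElements()].
#' @param model The [StructureModel-class].
#' @param convention "step" or "skip".
#' @return data.frame with columns bulge_id, side, core_residue and the
#'   five transition angles (NA where undefined).
#' @export
extractTransitions <- function(core, elements, model,
                               convention = c("step", "skip")) {
  convention <- match.arg(convention)
  bulges <- elements[elements$kind == "bulge", , drop = FALSE]
  empty <- data.frame(bulge_id = character(0), side = character(0),
                      core_residue = integer(0))
  if (!nrow(bulges)) {
    for (nm in TRANSITION_ANGLES) empty[[nm]] <- numeric(0)
    return(empty)
  }
  rows <- list()
  for (k in seq_len(nrow(bulges))) {
    b <- bulges[k, ]
    resnos <- as.integer(strsplit(b$residues, ",")[[1L]])
    bid <- paste0(b$chain, paste(resnos, collapse = "+"))
    if (convention == "step") {
      tvPrev <- transitionValues(model, b$chain, b$previous_core,
                                 b$chain, resnos[1L])
      tvNext <- transitionValues(model, b$chain,
                                 resnos[length(resnos)],
                                 b$chain, b$next_core)
      rows[[length(rows) + 1L]] <- data.frame(
        bulge_id = bid, side = "previous", core_residue = b$previous_core,
        t(tvPrev), check.names = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bulge_id = bid, side = "next", core_residue = b$next_core,
        t(tvNext), check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      tv <- transitionValues(model, b$chain, b$previous_core,
                             b$chain, b$next_core)
      rows[[length(rows) + 1L]] <- data.frame(
        bulge_id = bid, side = "skip", core_residue = b$previous_core,
        t(tv), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare transition records against a reference profile
#'
#' One deviation row per (record, angle): the absolute circular difference
#' between the observed angle and the profile's circular mean, flagged
#' when it exceeds the threshold.
#'
#' @param records Output of [extractTransitions()].
#' @param profile A [ReferenceProfile-class].
#' @param threshold Flagging threshold, degrees (default 60).
#' @return data.frame with bulge_id, side, angle, observed, reference,
#'   deviation and flagged; undefined observations keep deviation NA and
#'   flagged FALSE.
#' @export
compareToReference <- function(records, profile, threshold = 60) {
  stats <- profile@stats
  rows <- list()
  for (k in seq_len(nrow(records))) {
    for (ang in TRANSITION_ANGLES) {
      ref <- stats$mean[stats$angle == ang]
      obs <- records[[ang]][k]
      dev <- if (is.na(obs) || is.na(ref)) NA_real_
             else circularDiff(obs, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        bulge_id = records$bulge_id[k], side = records$side[k],
        angle = ang, observed = obs, reference = ref, deviation = dev,
        flagged = !is.na(dev) && dev > threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bulge_id = character(0), side = character(0),
               angle = character(0), observed = numeric(0),
               reference = numeric(0), deviation = numeric(0),
               flagged = logical(0))
  rownames(out) <- NULL
  out
}

#' Sugar pucker comparison of bulge-adjacent core residues
#'
#' Reports P, pucker class and z-deviations of the previous/next core
#' guanine of every bulge, with `altered` flagging a pucker class that
#' differs from the reference profile's majority class.
#'
#' @param core A [G4Core-class].
#' @param elements Output of [classifyElements()].
#' @param model The [StructureModel-class].
#' @param profile A [ReferenceProfile-class].
#' @return data.frame with bulge_id, side, core_residue, P, pucker_class,
#'   z_c2, z_c3 and altered.
#' @export
comparePucker <- function(core, elements, model, profile) {
  bulges <- elements[elements$kind == "bulge", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(bulges))) {
    b <- bulges[k, ]
    resnos <- as.integer(strsplit(b$residues, ",")[[1L]])
    bid <- paste0(b$chain, paste(resnos, collapse = "+"))
    for (side in c("previous", "next")) {
      rn <- if (side == "previous") b$previous_core else b$next_core
      res <- getResidue(model, b$chain, rn)
      nu <- sugarTorsions(res)
      pr <- if (is.null(nu)) list(P = NA_real_, tau_m = NA_real_,
                                  pucker_class = NA_character_)
            else pseudorotation(nu)
      zd <- tryCatch(zDeviation(res),
                     error = function(e) list(z_c2 = NA_real_,
                                              z_c3 = NA_real_))
      altered <- if (is.na(pr$pucker_class) ||
                     pr$pucker_class == "planar") NA
                 else pr$pucker_class != profile@majorityPucker
      rows[[length(rows) + 1L]] <- data.frame(
        bulge_id = bid, side = side, core_residue = rn, P = pr$P,
        pucker_class = pr$pucker_class, z_c2 = zd$z_c2, z_c3 = zd$z_c3,
        altered = altered, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bulge_id = character(0), side = character(0),
               core_residue = integer(0), P = numeric(0),
               pucker_class = character(0), z_c2 = numeric(0),
               z_c3 = numeric(0), altered = logical(0))
  rownames(out) <- NULL
  out
}

#' Assemble (and optionally write) the comparison report
#'
#' @param deviations Output of [compareToReference()].
#' @param puckers Output of [comparePucker()].
#' @param core A [G4Core-class].
#' @param threshold Deviation threshold used, degrees.
#' @param profile The [ReferenceProfile-class] used.
#' @param jsonPath,tsvPath Optional output files.
#' @return The report as a list (schema_version, provenance, summary,
#'   deviations, puckers).
#' @export
renderReport <- function(deviations, puckers, core, threshold = 60,
                         profile = NULL, jsonPath = NULL, tsvPath = NULL) {
  report <- list(
    schema_version = "1.0",
    provenance = list(
      threshold_deg = threshold,
      handedness = core@handedness,
      n_tetrads = length(core@tetrads),
      profile_sources = if (is.null(profile)) character(0) else
        profile@sourceIds,
      profile_stats = if (is.null(profile)) NULL else profile@stats),
    summary = list(
      n_deviation_rows = nrow(deviations),
      n_flagged = sum(deviations$flagged, na.rm = TRUE),
      flagged_angles = sort(unique(deviations$angle[deviations$flagged])),
      n_pucker_altered = sum(puckers$altered, na.rm = TRUE)),
    deviations = deviations,
    puckers = puckers)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(tsvPath))
    utils::write.table(deviations, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report)
}
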