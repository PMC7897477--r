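## Reading and writing atomic coordinate files (PDB via bio3d, mmCIF via a
## minimal atom_site reader/writer) into the uniform StructureModel view.

NUC_RESIDS <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U",
                "ADE", "CYT", "GUA", "THY", "URA")

## canonical atom-name normalization: star dialect -> primed, legacy
## phosphate oxygens, thymine methyl
normalizeAtomName <- function(x) {
  x <- gsub("*", "'", trimws(x), fixed = TRUE)
  x <- gsub('"', "", x, fixed = TRUE)
  map <- c("O1P" = "OP1", "O2P" = "OP2", "C5M" = "C7")
  hit <- x %in% names(map)
  x[hit] <- map[x[hit]]
  x
}

baseTypeOf <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- rep("other", length(resid))
  out[resid %in% c("DG", "G", "GUA")] <- "G"
  out[resid %in% c("DT", "T", "THY")] <- "T"
  out[resid %in% c("DA", "A", "ADE")] <- "A"
  out[resid %in% c("DC", "C", "CYT")] <- "C"
  out[resid %in% c("DU", "U", "URA")] <- "U"
  out
}

## assemble the canonical atom data.frame from parallel vectors
makeAtomTable <- function(chain, resno, resid, elety, elem, x, y, z, o) {
  elety <- normalizeAtomName(elety)
  resid <- toupper(trimws(resid))
  chain <- ifelse(is.na(chain) | !nzchar(chain), "A", chain)
  elem <- trimws(ifelse(is.na(elem), "", elem))
  noel <- !nzchar(elem)
  elem[noel] <- substr(gsub("[^A-Za-z]", "", elety[noel]), 1L, 1L)
  base <- baseTypeOf(resid)
  data.frame(chain = chain, resno = as.integer(resno), resid = resid,
             base = base, elety = elety, elem = toupper(elem),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             o = ifelse(is.na(o), 1, as.numeric(o)),
             is_nuc = base != "other",
             is_h = toupper(elem) %in% c("H", "D"),
             stringsAsFactors = FALSE)
}

## keep the highest-occupancy alternate location per (chain, resno, elety)
resolveAltLoc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$o[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a coordinate file into StructureModel objects
#'
#' Accepts PDB and mmCIF (PDBx), single- or multi-model. Alternate
#' locations are resolved to the highest-occupancy copy; waters, ions and
#' other non-nucleotide entities are retained but tagged (`is_nuc = FALSE`).
#' Atom names are normalized to the primed convention (C1' not C1*).
#'
#' @param path Coordinate file.
#' @param format "pdb", "mmcif" or "auto" (by file extension).
#' @return List of [StructureModel-class], one per coordinate model.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  models <- if (format == "pdb") readPdbModels(path) else readCifModels(path)
  if (!length(models))
    stop("no models: ", path, " contains no coordinate records")
  models
}

readPdbModels <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("format error reading PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (!nrow(a)) stop("no models: ", path, " contains no ATOM/HETATM records")
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    at <- makeAtomTable(a$chain, a$resno, a$resid, a$elety, a$elesy,
                        xyz[, 1L], xyz[, 2L], xyz[, 3L], a$o)
    StructureModel(resolveAltLoc(at), modelIndex = m,
                   sourceId = basename(path))
  })
}

## quote-aware tokenizer for one mmCIF data line
cifTokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1L]]
  toks <- regmatches(line, list(m))[[1L]]
  gsub("^['\"]|['\"]$", "", toks)
}

readCifModels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## locate the atom_site loop
  tagIdx <- grep("^_atom_site\\.", lines)
  if (!length(tagIdx))
    stop("format error reading mmCIF file ", path,
         ": no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagIdx]))
  dataStart <- max(tagIdx) + 1L
  rows <- list()
  for (i in dataStart:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(#|_|loop_|data_)", ln)) break
    rows[[length(rows) + 1L]] <- cifTokens(ln)
  }
  if (!length(rows))
    stop("no models: ", path, " has an empty _atom_site loop")
  bad <- which(vapply(rows, length, integer(1L)) != length(tags))
  if (length(bad))
    stop("format error reading mmCIF file ", path, ": _atom_site row ",
         bad[1L], " has ", length(rows[[bad[1L]]]), " fields, expected ",
         length(tags))
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- tags
  field <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    rep(NA_character_, nrow(tab))
  }
  modnum <- field("pdbx_PDB_model_num")
  modnum <- ifelse(is.na(modnum) | modnum %in% c(".", "?"), "1", modnum)
  at_all <- makeAtomTable(
    chain = field("auth_asym_id", "label_asym_id"),
    resno = field("auth_seq_id", "label_seq_id"),
    resid = field("auth_comp_id", "label_comp_id"),
    elety = field("auth_atom_id", "label_atom_id"),
    elem = field("type_symbol"),
    x = field("Cartn_x"), y = field("Cartn_y"), z = field("Cartn_z"),
    o = suppressWarnings(as.numeric(field("occupancy"))))
  split_models <- split(seq_len(nrow(at_all)), as.integer(modnum))
  models <- lapply(seq_along(split_models), function(k) {
    at <- at_all[split_models[[k]], , drop = FALSE]
    StructureModel(resolveAltLoc(at), modelIndex = k,
                   sourceId = basename(path))
  })
  models
}

#' Write a StructureModel to disk
#'
#' @param model A [StructureModel-class].
#' @param path Output file.
#' @param format "pdb" or "mmcif".
#' @return The path, invisibly.
#' @export
writeStructure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- atomTable(model)
  if (!nrow(a)) stop("refusing to write an empty model")
  if (format == "pdb") {
    if (nrow(a) > 99999L)
      stop("PDB capacity error: ", nrow(a),
           " atoms exceed the 99999 serial limit; use format = \"mmcif\"")
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
                       type = ifelse(a$is_nuc, "ATOM", "HETATM"),
                       resno = a$resno, resid = a$resid, chain = a$chain,
                       elety = a$elety, o = a$o, b = rep(0, nrow(a)),
                       elesy = a$elem)
      TRUE
    }, error = function(e) stop("I/O error writing ", path, ": ",
                                conditionMessage(e)))
  } else {
    writeCifModel(a, path)
  }
  invisible(path)
}

writeCifModel <- function(a, path, modelnum = 1L) {
  quoteName <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  hdr <- c("data_g4geom",
           "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_alt_id",
                                   "label_comp_id", "label_asym_id",
                                   "label_entity_id", "label_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "occupancy", "B_iso_or_equiv",
                                   "auth_seq_id", "auth_comp_id",
                                   "auth_asym_id", "auth_atom_id",
                                   "pdbx_PDB_model_num")))
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.4f %.4f %.4f %.2f 0.00 %d %s %s %s %d",
                  ifelse(a$is_nuc, "ATOM", "HETATM"), seq_len(nrow(a)),
                  a$elem, quoteName(a$elety), a$resid, a$chain, a$resno,
                  a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain,
                  quoteName(a$elety), modelnum)
  ok <- tryCatch(writeLines(c(hdr, rows, "#"), path),
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}
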