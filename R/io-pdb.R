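#' @name pdb_io
#' @title Read and write protein structures in PDB format
#'
#' @description
#' `read_pdb()` parses ATOM records of a (possibly multi-model) PDB file
#' into a list of backbone models, one per MODEL record. Hydrogen and
#' deuterium atoms are discarded; alternate locations are resolved to the
#' highest-occupancy copy; MSE selenomethionine is read as methionine.
#' Residues are re-indexed consecutively per chain and a jump in the
#' author residue numbering is recorded as a gap, which later breaks triad
#' and dihedral continuity (missing disordered residues must not create
#' spurious triads across the break).
#'
#' A `backbone_model` is a list with elements `atoms` (data.frame: chain,
#' resno, ires, code, atom, element, x, y, z), `residues` (data.frame:
#' ires, chain, resno, code, gap_before, complete), and `model` (index).
NULL

.AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
          GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
          MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
          SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
          MSE = "M")

.AA1TO3 <- stats::setNames(names(.AA3)[1:20], .AA3[1:20])

#' @rdname pdb_io
#' @param path PDB file.
#' @param keep_nonstandard if FALSE (default) residues whose name is not a
#'   standard amino acid (or MSE) are dropped with a warning.
#' @return `read_pdb`: list of `backbone_model` objects.
#' @export
read_pdb <- function(path, keep_nonstandard = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_id <- cumsum(rec == "MODEL ") # 0 when no MODEL records
  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(keep)) stop("no ATOM/HETATM records in ", path)
  at <- lines[keep]
  mid <- model_id[keep]
  if (all(mid == 0)) mid <- rep(1L, length(at)) else mid <- as.integer(mid)

  df <- data.frame(
    record  = substr(at, 1, 6),
    atom    = trimws(substr(at, 13, 16)),
    altloc  = substr(at, 17, 17),
    resname = trimws(substr(at, 18, 20)),
    chain   = substr(at, 22, 22),
    resno   = suppressWarnings(as.integer(substr(at, 23, 26))),
    icode   = substr(at, 27, 27),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(at, 55, 60))),
    element = trimws(substr(at, 77, 78)),
    model = mid)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z)) {
    stop("non-numeric coordinates in ", path)
  }
  # HETATM contributes only MSE (read as MET)
  df <- df[df$record == "ATOM  " | df$resname == "MSE", ]
  # infer element from the atom name when columns 77-78 are blank
  noel <- !nzchar(df$element)
  df$element[noel] <- substr(gsub("[0-9']", "", df$atom[noel]), 1, 1)
  df <- df[!(df$element %in% c("H", "D")), ]

  std <- df$resname %in% names(.AA3)
  if (any(!std)) {
    if (!keep_nonstandard) {
      warning("dropping nonstandard residue(s): ",
              paste(unique(df$resname[!std]), collapse = ", "))
      df <- df[std, ]
    }
  }
  if (nrow(df) == 0L || !any(df$atom == "CA")) {
    stop("no CA atoms found in ", path)
  }

  # altloc: keep the highest-occupancy copy of each atom
  df$occ[is.na(df$occ)] <- 1
  ord <- order(df$model, df$chain, df$resno, df$icode, df$atom, -df$occ)
  df <- df[ord, ]
  dup <- duplicated(df[, c("model", "chain", "resno", "icode", "atom")])
  df <- df[!dup, ]
  df <- df[order(df$model, df$chain, df$resno, df$icode), ]

  lapply(split(df, df$model), function(m) .make_backbone_model(m))
}

.make_backbone_model <- function(df) {
  df$code <- unname(.AA3[df$resname])
  rkey <- paste(df$chain, df$resno, df$icode, sep = "|")
  ukey <- unique(rkey)
  ires <- match(rkey, ukey)
  df$ires <- ires
  first <- !duplicated(ires)
  residues <- data.frame(
    ires  = ires[first],
    chain = df$chain[first],
    resno = df$resno[first],
    code  = unname(.AA3[df$resname[first]]))
  # a gap: chain change or non-consecutive author numbering
  n <- nrow(residues)
  residues$gap_before <- c(TRUE, residues$chain[-1] != residues$chain[-n] |
                             residues$resno[-1] != residues$resno[-n] + 1L)
  has <- function(a) tapply(df$atom == a, df$ires, any)[as.character(residues$ires)]
  residues$complete <- as.vector(has("N") & has("CA") & has("C"))
  structure(list(
    atoms = df[, c("chain", "resno", "ires", "code", "atom", "element",
                   "x", "y", "z")],
    residues = residues,
    model = df$model[1]), class = "backbone_model")
}

#' @exportS3Method base::print
print.backbone_model <- function(x, ...) {
  cat(sprintf("backbone_model: %d residues, %d heavy atoms (model %d)\n",
              nrow(x$residues), nrow(x$atoms), x$model))
  invisible(x)
}

#' @rdname pdb_io
#' @param models a single `backbone_model`, a list of them, or a list of
#'   coordinate data.frames with columns chain, resno, code, atom, x, y, z.
#' @param path output PDB path.
#' @return `write_pdb`: the path, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "backbone_model") || is.data.frame(models)) {
    models <- list(models)
  }
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  serial_fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  for (k in seq_along(models)) {
    m <- models[[k]]
    at <- if (inherits(m, "backbone_model")) m$atoms else m
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    nm <- ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom)
    res3 <- .AA1TO3[at$code]
    res3[is.na(res3)] <- "UNK"
    ch <- at$chain %||% "A"
    writeLines(sprintf(serial_fmt, seq_len(nrow(at)), nm, res3, ch,
                       at$resno, at$x, at$y, at$z, 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
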