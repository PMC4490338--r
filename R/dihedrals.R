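#' Torsion angle of four points
#'
#' IUPAC-signed dihedral (degrees in \[-180, 180)) defined by atoms
#' p1-p2-p3-p4. Returns NA with a warning when an inner atom triplet is
#' collinear and the torsion is undefined.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    warning("undefined torsion: collinear atom triplet")
    return(NA_real_)
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Backbone phi/psi dihedrals of a model
#'
#' For each residue i with a complete backbone: phi(i) is the
#' C(i-1)-N(i)-CA(i)-C(i) torsion and psi(i) the N(i)-CA(i)-C(i)-N(i+1)
#' torsion. Terminal residues, residues flanking a chain gap, and residues
#' with missing backbone atoms yield no record. Each record also carries
#' the residue's triad context (the i-1, i, i+1 one-letter codes), defined
#' only when both sequence neighbours are present without a gap.
#'
#' @param model a `backbone_model` from [read_pdb()] or
#'   [gen_helix_coordinates()].
#' @param exclude_pre_pro drop residues that precede a proline (and
#'   prolines themselves) from the output; both are known exceptions to
#'   the isolated-pair hypothesis. Default FALSE: all residues kept.
#' @return data.frame with columns `model`, `index`, `residue`, `triad`,
#'   `phi`, `psi` (degrees in \[-180, 180)).
#' @export
compute_dihedrals <- function(model, exclude_pre_pro = FALSE) {
  stopifnot(inherits(model, "backbone_model"))
  res <- model$residues
  n <- nrow(res)
  if (n < 3L) {
    return(data.frame(model = integer(0), index = integer(0),
                      residue = character(0), triad = character(0),
                      phi = numeric(0), psi = numeric(0)))
  }
  at <- model$atoms
  coord <- function(ires, name) {
    i <- which(at$ires == ires & at$atom == name)
    if (length(i) == 0L) return(NULL)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  out <- vector("list", n)
  for (i in 2:(n - 1L)) {
    # neighbours must be physically contiguous (no numbering gap)
    if (res$gap_before[i] || res$gap_before[i + 1L]) next
    if (!res$complete[i]) next
    Cm <- coord(res$ires[i - 1L], "C")
    Ni <- coord(res$ires[i], "N"); CAi <- coord(res$ires[i], "CA")
    Ci <- coord(res$ires[i], "C"); Np <- coord(res$ires[i + 1L], "N")
    if (is.null(Cm) || is.null(Np)) next
    phi <- torsion_angle(Cm, Ni, CAi, Ci)
    psi <- torsion_angle(Ni, CAi, Ci, Np)
    if (is.na(phi) || is.na(psi)) next
    out[[i]] <- data.frame(
      model = model$model, index = i, residue = res$code[i],
      triad = paste0(res$code[i - 1L], res$code[i], res$code[i + 1L]),
      phi = phi, psi = psi)
  }
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs)) {
    recs <- data.frame(model = integer(0), index = integer(0),
                       residue = character(0), triad = character(0),
                       phi = numeric(0), psi = numeric(0))
  }
  if (exclude_pre_pro && nrow(recs)) {
    pro <- recs$residue == "P" | substr(recs$triad, 3, 3) == "P"
    recs <- recs[!pro, , drop = FALSE]
  }
  rownames(recs) <- NULL
  recs
}

#' Dihedral records for a whole ensemble
#'
#' Applies [compute_dihedrals()] to every model of a multi-model structure
#' and binds the records, so each conformation contributes to the ensemble
#' statistics.
#'
#' @param models list of `backbone_model` objects.
#' @param ... passed to [compute_dihedrals()].
#' @export
ensemble_dihedrals <- function(models, ...) {
  do.call(rbind, lapply(models, compute_dihedrals, ...))
}

#' Write dihedral records to TSV
#'
#' @param records data.frame from [compute_dihedrals()].
#' @param path output file.
#' @export
write_dihedrals <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dihedrals
#' @export
read_dihedrals <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
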