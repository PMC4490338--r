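#' Two-body contacts of a conformation
#'
#' A residue pair (i, j) is in contact when any pair of non-hydrogen atoms
#' across the two residues is separated by strictly less than `cutoff`
#' Angstrom. Sequence neighbours within the exclusion window (|i - j| <=
#' `exclusion`, default i +/- 1 and i +/- 2) are ignored, since those
#' contacts persist even in denatured chains. Globular proteins owe their
#' stability to many such contacts; disordered ensembles show markedly
#' fewer.
#'
#' @param model a `backbone_model` (all retained heavy atoms are used).
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @param exclusion neighbour window half-width excluded from counting
#'   (default 2).
#' @param mode `"residue"` counts each residue pair once however many atom
#'   pairs are within the cutoff; `"atom"` counts individual atom pairs.
#' @return object of class `contact_result`: list with `per_residue`
#'   (named integer vector of per-residue partner or atom-pair counts),
#'   `total` (pair count), `mean_per_residue`, `pairs` (data.frame i, j),
#'   `cutoff`, `exclusion`, `mode`.
#' @export
count_contacts <- function(model, cutoff = 8.0, exclusion = 2,
                           mode = c("residue", "atom")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "backbone_model"))
  at <- model$atoms
  if (nrow(at) == 0L) stop("empty model")
  xyz <- cbind(at$x, at$y, at$z)
  ires <- at$ires
  nres <- max(ires)

  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(ires, ires, "-"))
  hit <- d < cutoff & sep > exclusion
  hit[lower.tri(hit, diag = TRUE)] <- FALSE

  idx <- which(hit, arr.ind = TRUE)
  pi_ <- ires[idx[, 1]]; pj <- ires[idx[, 2]]
  if (mode == "residue") {
    key <- paste(pmin(pi_, pj), pmax(pi_, pj))
    first <- !duplicated(key)
    pi_ <- pi_[first]; pj <- pj[first]
  }
  per <- tabulate(c(pi_, pj), nbins = nres)
  names(per) <- as.character(seq_len(nres))
  structure(list(per_residue = per,
                 total = length(pi_),
                 mean_per_residue = length(pi_) * 2 / nres,
                 pairs = data.frame(i = pmin(pi_, pj), j = pmax(pi_, pj)),
                 cutoff = cutoff, exclusion = exclusion, mode = mode),
            class = "contact_result")
}

#' @exportS3Method base::print
print.contact_result <- function(x, ...) {
  cat(sprintf("contact_result: %d %s-pair contacts (<%g A, |i-j|>%d), %.2f per residue\n",
              x$total, x$mode, x$cutoff, x$exclusion, x$mean_per_residue))
  invisible(x)
}

#' Contact-count distribution over an ensemble
#'
#' Counts contacts in every conformation and summarises their
#' distribution.
#'
#' @param models list of `backbone_model` objects (one per frame).
#' @inheritParams count_contacts
#' @return list with `per_frame` (data.frame: model, total,
#'   mean_per_residue), `mean_total`, and `histogram` (a [table] of
#'   per-frame totals).
#' @export
contact_distribution <- function(models, cutoff = 8.0, exclusion = 2,
                                 mode = c("residue", "atom")) {
  mode <- match.arg(mode)
  if (length(models) == 0L) stop("empty ensemble")
  rows <- lapply(seq_along(models), function(k) {
    cc <- count_contacts(models[[k]], cutoff = cutoff,
                         exclusion = exclusion, mode = mode)
    data.frame(model = k, total = cc$total,
               mean_per_residue = cc$mean_per_residue)
  })
  per_frame <- do.call(rbind, rows)
  list(per_frame = per_frame,
       mean_total = mean(per_frame$total),
       histogram = table(per_frame$total))
}

#' Write contact counts to TSV
#' @param result a `contact_result`.
#' @param path output file.
#' @export
write_contacts <- function(result, path) {
  df <- data.frame(residue = names(result$per_residue),
                   contacts = as.integer(result$per_residue))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff=%g exclusion=%d mode=%s total=%d",
                     result$cutoff, result$exclusion, result$mode,
                     result$total), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
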