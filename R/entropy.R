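#' @name rama_entropy
#' @title Ramachandran-grid Shannon conformational entropy
#'
#' @description
#' Backbone conformational entropy is estimated from the distribution of
#' phi/psi dihedral angles over an equally spaced grid on the Ramachandran
#' torus: S = -sum_i P_i ln(P_i), where P_i is the fraction of
#' observations in bin i (plug-in estimator; 0 ln 0 = 0). Two grid widths
#' matter in practice: 4 degrees (90 x 90 bins) for residuewise entropy,
#' and 30 degrees (12 x 12 bins) for triad entropy, where the coarser bin
#' keeps per-triad statistics reliable. Entropies are reported in nats;
#' the maximum over a width-w grid is ln((360/w)^2).
#'
#' Bins are half-open `[low, high)` with origin at -180 on both axes, so a
#' record at exactly -180 falls in the first bin.
NULL

bin_index <- function(angle, width) {
  i <- floor((angle + 180) / width) + 1L
  nb <- as.integer(round(360 / width))
  pmin.int(pmax.int(as.integer(i), 1L), nb)
}

new_rama_grid <- function(counts, width, key = NA_character_) {
  structure(list(counts = counts, width = width, key = key,
                 total = sum(counts)),
            class = "rama_grid")
}

#' @exportS3Method base::print
print.rama_grid <- function(x, ...) {
  cat(sprintf("rama_grid: %g deg bins (%d x %d), %d observations, key=%s\n",
              x$width, nrow(x$counts), ncol(x$counts), x$total, x$key))
  invisible(x)
}

#' Grid bin fractions
#' @param grid a `rama_grid`.
#' @return matrix of per-bin fractions P_i (phi along rows, psi along
#'   columns), summing to 1.
#' @export
grid_fractions <- function(grid) {
  if (grid$total == 0) stop("empty grid")
  grid$counts / grid$total
}

#' Bin dihedral records on Ramachandran grids
#'
#' Assigns each (phi, psi) record to one bin of a square grid of the given
#' width. In `"triad"` key mode, records are grouped by their triad and the
#' middle residue's dihedrals define the triad's conformational state; in
#' `"residue"` mode they are grouped by residue code; `"none"` pools all
#' records into one grid.
#'
#' @param records data.frame with `phi`, `psi`, and (per key mode)
#'   `residue` or `triad` columns, e.g. from [compute_dihedrals()].
#' @param width bin width in degrees; must divide 360. Defaults: 4 for
#'   residue grids, 30 for triad grids.
#' @param key_mode `"residue"`, `"triad"`, or `"none"`.
#' @return named list of `rama_grid` objects (a single unnamed grid for
#'   `"none"`).
#' @export
bin_dihedrals <- function(records, width = NULL,
                          key_mode = c("triad", "residue", "none")) {
  key_mode <- match.arg(key_mode)
  if (is.null(width)) width <- switch(key_mode, residue = 4, 30)
  if (abs(360 / width - round(360 / width)) > 1e-9) {
    stop("bin width ", width, " does not divide 360")
  }
  nb <- as.integer(round(360 / width))
  records <- records[!is.na(records$phi) & !is.na(records$psi), , drop = FALSE]
  keys <- switch(key_mode,
                 residue = records$residue,
                 triad = records$triad,
                 none = rep("all", nrow(records)))
  if (key_mode == "triad") {
    ok <- !is.na(keys)
    records <- records[ok, , drop = FALSE]
    keys <- keys[ok]
  }
  ip <- bin_index(wrap_angle(records$phi), width)
  is <- bin_index(wrap_angle(records$psi), width)
  cell <- (ip - 1L) * nb + is
  out <- lapply(split(cell, keys), function(cells) {
    counts <- matrix(tabulate(cells, nbins = nb * nb), nrow = nb,
                     byrow = TRUE)
    counts
  })
  grids <- Map(function(counts, key) new_rama_grid(counts, width, key),
               out, names(out))
  if (key_mode == "none") grids[[1]] else grids
}

#' Shannon entropy of a Ramachandran grid
#'
#' Plug-in estimator S = -sum_i P_i log(P_i) over occupied bins.
#'
#' @param grid a `rama_grid` (or a numeric vector/matrix of counts or
#'   probabilities).
#' @param base logarithm base; default e (nats).
#' @export
shannon_entropy <- function(grid, base = exp(1)) {
  p <- if (inherits(grid, "rama_grid")) grid_fractions(grid) else {
    s <- sum(grid)
    if (s <= 0) stop("empty distribution")
    grid / s
  }
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Build a triad entropy reference table from an ensemble
#'
#' Bins the ensemble's dihedral records per triad (30-degree grid by
#' default) and computes each triad's Shannon entropy. Observation counts
#' are retained so sparse triads can be filtered downstream; triads never
#' observed are absent from the table, not zero-entropy.
#'
#' @param records ensemble dihedral records carrying a `triad` column.
#' @param width grid width in degrees (default 30).
#' @param min_count drop triads with fewer observations (default 1: keep
#'   all).
#' @param source label describing the source ensemble.
#' @return object of class `entropy_table`: data.frame with columns
#'   `triad`, `entropy` (nats), `count`; attributes `width`, `base`,
#'   `source`.
#' @export
build_entropy_table <- function(records, width = 30, min_count = 1,
                                source = "ensemble") {
  grids <- bin_dihedrals(records, width = width, key_mode = "triad")
  if (length(grids) == 0L) stop("no triad-keyed dihedral records")
  df <- data.frame(
    triad = names(grids),
    entropy = vapply(grids, shannon_entropy, numeric(1)),
    count = vapply(grids, function(g) g$total, numeric(1)))
  df <- df[df$count >= min_count, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, width = width, base = exp(1), source = source,
            class = c("entropy_table", "data.frame"))
}

#' Entropy ratios between two triad tables
#'
#' Ratio S_ensemble / S_reference per triad shared by both tables.
#' Globular ensembles concentrate each triad into roughly half of its
#' accessible phi/psi range and show mean ratios near 0.65; fully
#' disordered ensembles sample the reference's whole range (mean near 1)
#' and loosely restrained coarse-grained ensembles can exceed 1 — ratios
#' are deliberately not clamped. Triads missing from either table, or with
#' zero reference entropy, are excluded and counted.
#'
#' @param ensemble_table,reference_table `entropy_table` objects built at
#'   the same grid width.
#' @return list with `ratios` (data.frame: triad, ratio, s_ensemble,
#'   s_reference), `mean_ratio`, `n_excluded`.
#' @export
entropy_ratio <- function(ensemble_table, reference_table) {
  stopifnot(inherits(ensemble_table, "entropy_table"),
            inherits(reference_table, "entropy_table"))
  if (!isTRUE(all.equal(attr(ensemble_table, "width"),
                        attr(reference_table, "width")))) {
    stop("tables built at different grid widths")
  }
  m <- match(ensemble_table$triad, reference_table$triad)
  shared <- !is.na(m)
  sref <- reference_table$entropy[m[shared]]
  sens <- ensemble_table$entropy[shared]
  usable <- sref > 0
  n_excluded <- sum(!shared) + sum(!usable) +
    sum(!(reference_table$triad %in% ensemble_table$triad))
  if (!any(usable)) stop("no shared triads with nonzero reference entropy")
  ratios <- data.frame(triad = ensemble_table$triad[shared][usable],
                       ratio = sens[usable] / sref[usable],
                       s_ensemble = sens[usable],
                       s_reference = sref[usable])
  list(ratios = ratios, mean_ratio = mean(ratios$ratio),
       n_excluded = n_excluded)
}

#' Residuewise conformational entropy of a query protein
#'
#' Each residue of the query is located in the reference's 4-degree
#' Ramachandran grid for its residue type; with P_i the reference fraction
#' of that bin, the residue contributes -P_i ln(P_i) (default `"bin"`
#' reading) and the protein entropy is the sum over residues. The
#' alternative `"type"` reading charges each residue the full Shannon
#' entropy of its residue type's reference distribution, ignoring where
#' the query residue actually sits. Residue types absent from the
#' reference are flagged and excluded from the sum.
#'
#' @param records query dihedral records (one conformation).
#' @param reference_grids named list of per-residue `rama_grid`s, from
#'   [bin_dihedrals()] with `key_mode = "residue"`.
#' @param mode `"bin"` (default) or `"type"`.
#' @return list with `per_residue` (data.frame: index, residue, p_ref,
#'   contribution) and `total` (nats).
#' @export
residuewise_entropy <- function(records, reference_grids,
                                mode = c("bin", "type")) {
  mode <- match.arg(mode)
  width <- reference_grids[[1]]$width
  n <- nrow(records)
  p_ref <- numeric(n); contrib <- numeric(n)
  for (r in seq_len(n)) {
    g <- reference_grids[[records$residue[r]]]
    if (is.null(g) || g$total == 0) {
      p_ref[r] <- NA_real_; contrib[r] <- NA_real_
      next
    }
    if (mode == "type") {
      contrib[r] <- shannon_entropy(g)
      p_ref[r] <- NA_real_
    } else {
      P <- grid_fractions(g)
      p <- P[bin_index(wrap_angle(records$phi[r]), width),
             bin_index(wrap_angle(records$psi[r]), width)]
      p_ref[r] <- p
      contrib[r] <- if (p > 0) -p * log(p) else 0
    }
  }
  per <- data.frame(index = records$index, residue = records$residue,
                    p_ref = p_ref, contribution = contrib)
  list(per_residue = per, total = sum(contrib, na.rm = TRUE),
       n_flagged = sum(is.na(contrib)))
}

#' Serialise a triad entropy table
#'
#' JSON layout: `{"metadata": {width, base, source}, "entropies":
#' {triad: {entropy, count}, ...}}`. TSV layout: three columns.
#'
#' @param table an `entropy_table`.
#' @param path output path; format inferred from the extension unless
#'   given.
#' @param format `"json"` or `"tsv"`.
#' @export
write_entropy_table <- function(table, path, format = NULL) {
  format <- format %||% ifelse(grepl("\\.tsv$", path), "tsv", "json")
  if (format == "tsv") {
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    ent <- lapply(seq_len(nrow(table)), function(i) {
      list(entropy = table$entropy[i], count = table$count[i])
    })
    names(ent) <- table$triad
    jsonlite::write_json(
      list(metadata = list(width = attr(table, "width"),
                           base = "e",
                           source = attr(table, "source")),
           entropies = ent),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_entropy_table
#' @export
read_entropy_table <- function(path, format = NULL) {
  format <- format %||% ifelse(grepl("\\.tsv$", path), "tsv", "json")
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(structure(df, width = NA_real_, base = exp(1), source = path,
                     class = c("entropy_table", "data.frame")))
  }
  x <- jsonlite::read_json(path)
  df <- data.frame(
    triad = names(x$entropies),
    entropy = vapply(x$entropies, function(e) as.numeric(e$entropy),
                     numeric(1)),
    count = vapply(x$entropies, function(e) as.numeric(e$count),
                   numeric(1)))
  rownames(df) <- NULL
  structure(df, width = x$metadata$width, base = exp(1),
            source = x$metadata$source,
            class = c("entropy_table", "data.frame"))
}
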