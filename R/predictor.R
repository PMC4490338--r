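#' Predict backbone conformational entropy from sequence alone
#'
#' Under Flory's isolated-pair hypothesis the phi/psi state of each
#' residue is independent of its neighbours', so the conformational
#' entropy of a disordered chain is the sum, over its overlapping triads,
#' of the reference (non-redundant database) entropy of each triad:
#' S = sum_j S_j. Globular chains populate only about 65% of each triad's
#' accessible range, so their average entropy is estimated as the same sum
#' scaled by a globular factor (default 0.65).
#'
#' Triads absent from the reference table are handled per `missing`:
#' `"mean"` substitutes the table-wide mean entropy (default), `"skip"`
#' drops them, `"error"` aborts. The number affected is always reported.
#'
#' @param seq sequence string (length >= 3).
#' @param table an `entropy_table` reference.
#' @param mode `"disordered"` (plain sum) or `"globular"` (scaled).
#' @param factor globular scale factor (default 0.65).
#' @param missing missing-triad policy.
#' @param id identifier carried through.
#' @return list of class `entropy_prediction`: `id`, `entropy` (nats),
#'   `n_triads` (used), `n_missing`, `mode`, `factor`.
#' @export
predict_entropy <- function(seq, table, mode = c("disordered", "globular"),
                            factor = 0.65,
                            missing = c("mean", "skip", "error"),
                            id = NA_character_) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  stopifnot(inherits(table, "entropy_table"), nrow(table) > 0)
  tri <- enumerate_triads(seq)$triad
  if (length(tri) == 0L) stop("sequence shorter than 3 residues")
  s <- table$entropy[match(tri, table$triad)]
  n_missing <- sum(is.na(s))
  if (n_missing == length(tri)) {
    stop("every triad of the sequence is missing from the table")
  }
  if (n_missing > 0L) {
    if (missing == "error") {
      stop(n_missing, " triad(s) missing from the entropy table")
    }
    if (missing == "mean") s[is.na(s)] <- mean(table$entropy)
  }
  used <- !is.na(s)
  total <- sum(s[used])
  if (mode == "globular") total <- factor * total
  structure(list(id = id, entropy = total, n_triads = sum(used),
                 n_missing = n_missing, mode = mode,
                 factor = if (mode == "globular") factor else NA_real_),
            class = "entropy_prediction")
}

#' @exportS3Method base::print
print.entropy_prediction <- function(x, ...) {
  cat(sprintf("entropy_prediction [%s]: S = %.4f nats (%d triads, %d missing, mode=%s)\n",
              x$id, x$entropy, x$n_triads, x$n_missing, x$mode))
  invisible(x)
}

#' Assemble a dihedral series from ensemble records
#'
#' Reshapes ensemble dihedral records (long format with a `model` column)
#' into a frames x variables matrix, variables interleaved along the chain
#' as phi_1, psi_1, phi_2, psi_2, ... Only residue indices present in
#' every frame are kept.
#'
#' @param records data.frame from [ensemble_dihedrals()].
#' @return numeric matrix (class `dihedral_series`), one row per frame.
#' @export
as_dihedral_series <- function(records) {
  models <- sort(unique(records$model))
  idx <- Reduce(intersect, lapply(split(records$index, records$model),
                                  unique))
  idx <- sort(idx)
  if (length(idx) == 0L) stop("no residue index common to all frames")
  cols <- vector("list", 2L * length(idx))
  for (k in seq_along(idx)) {
    sub <- records[records$index == idx[k], ]
    sub <- sub[order(sub$model), ]
    cols[[2L * k - 1L]] <- sub$phi
    cols[[2L * k]] <- sub$psi
  }
  m <- do.call(cbind, cols)
  colnames(m) <- as.vector(rbind(paste0("phi_", idx), paste0("psi_", idx)))
  structure(m, class = c("dihedral_series", "matrix"))
}

discretize_series <- function(series, width = 30) {
  if (abs(360 / width - round(360 / width)) > 1e-9) {
    stop("bin width ", width, " does not divide 360")
  }
  apply(unclass(series), 2, function(col) bin_index(wrap_angle(col), width))
}

marginal_entropies <- function(disc, nb) {
  apply(disc, 2, function(col) shannon_entropy(tabulate(col, nbins = nb)))
}

joint_entropy2 <- function(ci, cj, nb) {
  shannon_entropy(tabulate((ci - 1L) * nb + cj, nbins = nb * nb))
}

#' Second-order mutual-information-expansion entropy
#'
#' Discretises each dihedral variable on a 30-degree grid (default) and
#' evaluates S = sum_i S1(x_i) - sum_pairs I2(x_i, x_j), with
#' I2 = S1(x_i) + S1(x_j) - S2(x_i, x_j) and pairs restricted to chain
#' neighbours up to `order` steps apart on the interleaved phi/psi index.
#' Truncation at nearest neighbour (order 1) suffices in practice because
#' dihedral correlations decay quickly with sequence separation; third and
#' higher orders converge poorly at realistic sampling anyway.
#'
#' @param series a `dihedral_series` matrix (frames x variables), or any
#'   numeric matrix of angles in degrees.
#' @param order largest neighbour separation entering the correction
#'   (default 1 = nearest neighbour).
#' @param width discretisation bin width in degrees.
#' @return list: `total` (nats), `sum_marginals`, `marginals`, `pairs`
#'   (data.frame i, j, I2).
#' @export
mie_entropy <- function(series, order = 1, width = 30) {
  m <- as.matrix(series)
  if (nrow(m) < 2L) stop("need at least 2 frames")
  nb <- as.integer(round(360 / width))
  disc <- discretize_series(m, width)
  s1 <- marginal_entropies(disc, nb)
  nv <- ncol(disc)
  pairs <- list()
  if (order >= 1 && nv >= 2) {
    for (k in seq_len(min(order, nv - 1L))) {
      for (i in seq_len(nv - k)) {
        j <- i + k
        s2 <- joint_entropy2(disc[, i], disc[, j], nb)
        pairs[[length(pairs) + 1L]] <-
          data.frame(i = i, j = j, I2 = s1[i] + s1[j] - s2)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(0), j = integer(0), I2 = numeric(0))
  list(total = sum(s1) - sum(pairs$I2), sum_marginals = sum(s1),
       marginals = s1, pairs = pairs)
}

#' Mutual information as a function of chain separation
#'
#' Mean pairwise mutual information I2 between dihedral variables i and
#' i+k for each separation k (k = 0 returns the mean self-information,
#' i.e. the mean marginal entropy). Correlations between backbone
#' dihedrals decay with separation along the chain.
#'
#' @inheritParams mie_entropy
#' @param separations integer vector of separations (default 1:3).
#' @return data.frame with `separation`, `mean_I2`, `n_pairs`.
#' @export
correlation_profile <- function(series, separations = 1:3, width = 30) {
  m <- as.matrix(series)
  nb <- as.integer(round(360 / width))
  disc <- discretize_series(m, width)
  s1 <- marginal_entropies(disc, nb)
  nv <- ncol(disc)
  rows <- lapply(separations, function(k) {
    if (k == 0) {
      return(data.frame(separation = 0, mean_I2 = mean(s1), n_pairs = nv))
    }
    if (k >= nv) {
      warning("chain shorter than separation ", k, "; dropped")
      return(NULL)
    }
    i2 <- vapply(seq_len(nv - k), function(i) {
      s1[i] + s1[i + k] - joint_entropy2(disc[, i], disc[, i + k], nb)
    }, numeric(1))
    data.frame(separation = k, mean_I2 = mean(i2), n_pairs = nv - k)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Histogram entropy of an ensemble
#'
#' The plain binned estimate without inter-residue correlation
#' corrections. With `joint = TRUE` (default) consecutive variable pairs
#' (phi_i, psi_i) are binned on the 2D Ramachandran grid and the
#' per-residue joint entropies are summed — the grid histogram method.
#' With `joint = FALSE` every dihedral contributes its 1D marginal
#' entropy, the zeroth-order truncation of the mutual-information
#' expansion.
#'
#' @inheritParams mie_entropy
#' @param joint bin each residue's (phi, psi) jointly (requires the
#'   interleaved phi/psi layout of [as_dihedral_series()]).
#' @export
histogram_entropy <- function(series, width = 30, joint = TRUE) {
  m <- as.matrix(series)
  nb <- as.integer(round(360 / width))
  disc <- discretize_series(m, width)
  if (joint) {
    if (ncol(disc) %% 2L != 0L) {
      stop("joint mode needs interleaved phi/psi columns (even count)")
    }
    return(sum(vapply(seq_len(ncol(disc) / 2L), function(r) {
      joint_entropy2(disc[, 2L * r - 1L], disc[, 2L * r], nb)
    }, numeric(1))))
  }
  sum(marginal_entropies(disc, nb))
}

#' Percent differences between entropy estimates
#'
#' Compares a sequence-based prediction with ensemble-derived MIE and
#' histogram values: 100 * |a - b| / b, with the ensemble value as the
#' denominator.
#'
#' @param prediction predicted entropy (nats), or an `entropy_prediction`.
#' @param mie_value,histogram_value ensemble-derived entropies (nats).
#' @return list with `vs_mie` and `vs_histogram` (percent).
#' @export
compare_methods <- function(prediction, mie_value, histogram_value) {
  p <- if (inherits(prediction, "entropy_prediction")) prediction$entropy
       else prediction
  pct <- function(a, b) {
    if (b == 0) stop("zero reference entropy in percent difference")
    100 * abs(a - b) / b
  }
  list(vs_mie = pct(p, mie_value), vs_histogram = pct(p, histogram_value))
}
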