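#' @name composition
#' @title Amino-acid and triad composition of sequence datasets
#'
#' @description
#' Disordered and globular proteins differ systematically in composition:
#' disordered sequences carry fewer hydrophobic and more charged residues.
#' These functions quantify that contrast at the single-residue level and,
#' with more discriminating power, at the level of amino-acid triads
#' (ordered windows of three consecutive residues, 20^3 = 8000 of them).
#'
#' The pipeline is: pool each dataset into a composition profile
#' ([dataset_composition()]); form the relative composition Delta of each
#' key as its fraction in the disordered (target) set over its fraction in
#' the globular (reference) set ([relative_composition()]); score each
#' sequence by the mean Delta over its residues or triads
#' ([sequence_score()]); attach bootstrap confidence intervals by
#' resampling whole sequences ([bootstrap_ci()]); and classify
#' ([classify_disorder()]).
NULL

unit_keys <- function(unit) {
  if (unit == "residue") AA_CODES else all_triads()
}

unit_count_vector <- function(seq, unit, keys) {
  if (unit == "residue") {
    u <- strsplit(seq, "")[[1]]
  } else {
    u <- enumerate_triads(seq)$triad
  }
  tabulate(match(u, keys), nbins = length(keys))
}

#' Pooled composition of a sequence dataset
#'
#' Counts every residue (or every overlapping triad) across all sequences
#' of the dataset and normalises to fractions that sum to 1. Keys never
#' observed have fraction exactly 0.
#'
#' @param seqs character vector of sequences (one-letter codes).
#' @param unit `"residue"` or `"triad"`.
#' @return object of class `composition_profile`: list with `unit`,
#'   `fractions` (named over the full key space), `counts`, `total`.
#' @export
dataset_composition <- function(seqs, unit = c("residue", "triad")) {
  unit <- match.arg(unit)
  if (length(seqs) == 0L) stop("empty sequence dataset")
  keys <- unit_keys(unit)
  counts <- Reduce(`+`, lapply(seqs, unit_count_vector, unit = unit,
                               keys = keys))
  total <- sum(counts)
  if (total == 0L) stop("no ", unit, " units in dataset (sequences too short?)")
  structure(list(unit = unit,
                 fractions = stats::setNames(counts / total, keys),
                 counts = stats::setNames(counts, keys),
                 total = total),
            class = "composition_profile")
}

#' @exportS3Method base::print
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: unit=%s, %d/%d keys observed, %d units\n",
              x$unit, sum(x$counts > 0), length(x$counts), x$total))
  invisible(x)
}

#' Relative composition between two datasets
#'
#' Delta(key) = P_target(key) / P_reference(key), the fraction of the key
#' in the target (typically disordered) dataset relative to the reference
#' (typically globular) dataset. Keys absent from the reference have
#' undefined Delta and are flagged (`defined = FALSE`), never silently
#' infinite; no pseudocount is applied.
#'
#' @param target,reference `composition_profile` objects with the same unit.
#' @param target_label,reference_label dataset labels kept as attributes.
#' @return object of class `relative_composition`: data.frame with columns
#'   `key`, `delta`, `target_frac`, `ref_frac`, `defined`.
#' @export
relative_composition <- function(target, reference,
                                 target_label = "target",
                                 reference_label = "reference") {
  stopifnot(inherits(target, "composition_profile"),
            inherits(reference, "composition_profile"))
  if (target$unit != reference$unit) {
    stop("profiles have different units: ", target$unit, " vs ",
         reference$unit)
  }
  defined <- reference$fractions > 0
  delta <- ifelse(defined, target$fractions / reference$fractions, NA_real_)
  out <- data.frame(key = names(target$fractions),
                    delta = unname(delta),
                    target_frac = unname(target$fractions),
                    ref_frac = unname(reference$fractions),
                    defined = unname(defined))
  attr(out, "unit") <- target$unit
  attr(out, "target_label") <- target_label
  attr(out, "reference_label") <- reference_label
  class(out) <- c("relative_composition", "data.frame")
  out
}

#' Normalised relative-composition score of one sequence
#'
#' The mean Delta over the sequence's R units (R = length for residues,
#' length - 2 for triads). Units whose Delta is undefined are excluded
#' from both numerator and denominator; their count is reported.
#'
#' @param seq one sequence string.
#' @param table a `relative_composition` object.
#' @param id sequence identifier carried through to the result.
#' @return list with `id`, `score`, `n_units`, `n_undefined`.
#' @export
sequence_score <- function(seq, table, id = NA_character_) {
  stopifnot(inherits(table, "relative_composition"))
  unit <- attr(table, "unit")
  u <- if (unit == "residue") strsplit(seq, "")[[1]] else
    enumerate_triads(seq)$triad
  if (length(u) == 0L) stop("sequence too short for unit '", unit, "'")
  d <- table$delta[match(u, table$key)]
  usable <- !is.na(d)
  if (!any(usable)) stop("no usable units: every unit has undefined Delta")
  list(id = id, score = mean(d[usable]), n_units = length(u),
       n_undefined = sum(!usable))
}

#' Score every sequence of a dataset
#'
#' @param seqs named character vector of sequences.
#' @inheritParams sequence_score
#' @return data.frame with one row per sequence.
#' @export
score_dataset <- function(seqs, table) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  rows <- mapply(function(s, id) sequence_score(s, table, id),
                 seqs, ids, SIMPLIFY = FALSE)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence intervals for relative composition
#'
#' Resamples whole sequences with replacement, independently in the target
#' and reference datasets, and recomputes Delta for every key in each
#' replicate; percentile intervals at the requested level are attached to
#' the plug-in table. Whole sequences (not individual triads) are the
#' resampling unit because triads within a sequence are not independent.
#' Defaults follow the analysis protocol this package implements: 2000
#' iterations, 99% intervals. Deterministic under `set.seed()`.
#'
#' @param target_seqs,reference_seqs character vectors of sequences.
#' @param unit `"residue"` or `"triad"`.
#' @param n_iter bootstrap iterations (>= 1).
#' @param level confidence level in (0, 1).
#' @return a `relative_composition` table with extra columns `lower` and
#'   `upper`; attribute `n_iter` and `level` record the protocol. A key's
#'   interval is NA when its Delta was undefined in a majority of
#'   replicates.
#' @export
bootstrap_ci <- function(target_seqs, reference_seqs,
                         unit = c("residue", "triad"),
                         n_iter = 2000, level = 0.99) {
  unit <- match.arg(unit)
  stopifnot(n_iter >= 1, level > 0, level < 1)
  if (length(target_seqs) < 2L || length(reference_seqs) < 2L) {
    warning("single-sequence dataset: bootstrap intervals are degenerate")
  }
  keys <- unit_keys(unit)
  tab <- relative_composition(dataset_composition(target_seqs, unit),
                              dataset_composition(reference_seqs, unit))

  cmat <- function(seqs) {
    m <- vapply(seqs, unit_count_vector, integer(length(keys)),
                unit = unit, keys = keys)
    Matrix::Matrix(m, sparse = TRUE)
  }
  Ct <- cmat(target_seqs)
  Cr <- cmat(reference_seqs)
  nt <- length(target_seqs); nr <- length(reference_seqs)

  # multiplicity of each sequence in each replicate, as a dense matrix;
  # replicate fractions then come from two sparse-dense products
  Mt <- matrix(0, nt, n_iter)
  Mr <- matrix(0, nr, n_iter)
  for (b in seq_len(n_iter)) {
    Mt[, b] <- tabulate(sample.int(nt, nt, replace = TRUE), nbins = nt)
    Mr[, b] <- tabulate(sample.int(nr, nr, replace = TRUE), nbins = nr)
  }
  Tt <- as.matrix(Ct %*% Mt)   # key x replicate counts
  Tr <- as.matrix(Cr %*% Mr)
  Pt <- sweep(Tt, 2, colSums(Tt), "/")
  Pr <- sweep(Tr, 2, colSums(Tr), "/")
  D <- Pt / Pr                 # NaN/Inf where reference count is 0
  D[!is.finite(D)] <- NA

  alpha <- (1 - level) / 2
  qs <- t(apply(D, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < n_iter / 2) return(c(NA_real_, NA_real_))
    stats::quantile(r, c(alpha, 1 - alpha), names = FALSE, type = 6)
  }))
  tab$lower <- qs[, 1]
  tab$upper <- qs[, 2]
  attr(tab, "n_iter") <- n_iter
  attr(tab, "level") <- level
  tab
}

#' Rank triads by compositional preference
#'
#' Splits a CI-carrying relative-composition table into triads
#' significantly enriched in the target set (interval above 1),
#' significantly depleted (interval below 1), showing no preference
#' (interval spans 1), and absent from the target dataset.
#'
#' @param table output of [bootstrap_ci()].
#' @param k report the top k of each ranked bucket (default 50).
#' @return list with data.frames `most_preferred` (by decreasing Delta),
#'   `least_preferred` (by increasing Delta), `no_preference`, and
#'   `absent_from_target`.
#' @export
rank_triads <- function(table, k = 50) {
  stopifnot(inherits(table, "relative_composition"))
  if (is.null(table$lower)) stop("table carries no confidence intervals")
  obs <- table[table$defined & table$target_frac > 0 & !is.na(table$lower), ]
  up <- obs[obs$lower > 1, ]
  dn <- obs[obs$upper < 1, ]
  np <- obs[obs$lower <= 1 & obs$upper >= 1, ]
  absent <- table[table$defined & table$target_frac == 0 &
                    table$ref_frac > 0, ]
  list(most_preferred = utils::head(up[order(-up$delta), ], k),
       least_preferred = utils::head(dn[order(dn$delta), ], k),
       no_preference = np,
       absent_from_target = absent)
}

#' Fit a disorder classification threshold
#'
#' Max-margin midpoint between the highest-scoring globular sequence and
#' the lowest-scoring disordered sequence (the boundary is drawn, not
#' printed, in the source analysis, so it is a fitted parameter here).
#'
#' @param globular_scores,disordered_scores numeric score vectors.
#' @export
fit_threshold <- function(globular_scores, disordered_scores) {
  (max(globular_scores) + min(disordered_scores)) / 2
}

#' Classify a sequence score as globular or disordered
#'
#' Strict inequality: a score exactly at the threshold is globular.
#'
#' @param score numeric score(s) from [sequence_score()].
#' @param threshold decision boundary.
#' @return character vector of labels `"globular"` / `"disordered"`.
#' @export
classify_disorder <- function(score, threshold) {
  ifelse(score > threshold, "disordered", "globular")
}
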