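#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' package's sequence alphabet policy. Sequences are returned as a plain
#' named character vector over the 20 standard one-letter codes.
#'
#' The policy for nonstandard codes (X, B, Z, U, ...) is configurable:
#' \describe{
#'   \item{`"strict"`}{any character outside the 20 standard codes is an
#'     error (selenomethionine U and the PDB's MSE are first mapped to M).}
#'   \item{`"skip"`}{nonstandard characters are dropped with a warning.}
#' }
#'
#' @param path FASTA file.
#' @param policy `"strict"` or `"skip"`.
#' @return named character vector of sequences; names are the full FASTA
#'   headers.
#' @export
read_fasta <- function(path, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings so the package's own alphabet policy (not the
  # AAStringSet alphabet) decides how nonstandard codes are handled
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  clean_sequences(seqs, policy)
}

clean_sequences <- function(seqs, policy = "strict") {
  # U (Sec) is read as M, matching the MSE -> MET convention for structures
  seqs <- gsub("U", "M", seqs, fixed = TRUE)
  bad <- gsub(paste0("[", paste(AA_CODES, collapse = ""), "]"), "", seqs)
  if (any(nzchar(bad))) {
    offenders <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    if (policy == "strict") {
      stop("nonstandard residue code(s) ", paste(offenders, collapse = ", "),
           " in sequence(s) ", paste(names(seqs)[nzchar(bad)], collapse = ", "),
           " (use policy = \"skip\" to drop them)")
    }
    warning("dropping nonstandard residue code(s): ",
            paste(offenders, collapse = ", "))
    seqs <- gsub(paste0("[^", paste(AA_CODES, collapse = ""), "]"), "", seqs)
  }
  if (any(!nzchar(seqs))) stop("empty sequence after filtering")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  set <- Biostrings::AAStringSet(unname(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Enumerate overlapping amino-acid triads of a sequence
#'
#' Every window of three consecutive residues is a triad; the window is
#' indexed by its middle residue. A sequence of length n yields
#' max(0, n - 2) triads.
#'
#' @param seq a single character string of one-letter codes.
#' @return data.frame with columns `triad` and `index` (position of the
#'   middle residue, 1-based); zero rows when `nchar(seq) < 3`.
#' @examples
#' enumerate_triads("ACDEF")
#' @export
enumerate_triads <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 3L) {
    return(data.frame(triad = character(0), index = integer(0)))
  }
  starts <- seq_len(n - 2L)
  data.frame(triad = substring(seq, starts, starts + 2L),
             index = starts + 1L)
}
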