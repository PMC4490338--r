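#' Standard amino-acid alphabet and residue-level scales
#'
#' `AA_CODES` is the vector of the 20 standard one-letter amino-acid codes.
#' `kd_hydrophobicity()` returns the Kyte-Doolittle hydropathy scale min-max
#' normalised to \[0, 1\]; `residue_charges()` returns net side-chain charges
#' at neutral pH in elementary units (K/R = +1, D/E = -1, H = +0.1 by
#' default); `residue_masses()` returns residue molecular weights (Da),
#' optionally min-max normalised. All three feed the coarse-grained energy
#' function and can be overridden there.
#'
#' @name aa_scales
NULL

#' @rdname aa_scales
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy indices
.KD_RAW <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
             G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
             M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
             S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# free amino-acid molecular weights (Da)
.MW_RAW <- c(A =  89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
             G =  75.07, H = 155.16, I = 131.17, K = 146.19, L = 131.17,
             M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
             S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19)

#' @rdname aa_scales
#' @export
kd_hydrophobicity <- function() {
  x <- .KD_RAW[AA_CODES]
  (x - min(x)) / (max(x) - min(x))
}

#' @rdname aa_scales
#' @param his_charge fractional charge assigned to histidine.
#' @export
residue_charges <- function(his_charge = 0.1) {
  q <- stats::setNames(numeric(20), AA_CODES)
  q[c("K", "R")] <- 1
  q[c("D", "E")] <- -1
  q["H"] <- his_charge
  q
}

#' @rdname aa_scales
#' @param normalize min-max normalise to \[0, 1\].
#' @export
residue_masses <- function(normalize = TRUE) {
  x <- .MW_RAW[AA_CODES]
  if (normalize) (x - min(x)) / (max(x) - min(x)) else x
}

#' Enumerate the full amino-acid triad space
#'
#' All ordered triples over the 20 standard residues: 20^3 = 8000 triads,
#' in lexicographic order.
#'
#' @return character vector of length 8000.
#' @examples
#' length(all_triads())
#' head(all_triads())
#' @export
all_triads <- function() {
  g <- expand.grid(third = AA_CODES, second = AA_CODES, first = AA_CODES,
                   stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

# wrap angles (degrees) into [-180, 180)
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

`%||%` <- function(a, b) if (is.null(a)) b else a
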