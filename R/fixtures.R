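#' @name synthetic_fixtures
#' @title Synthetic inputs with known ground truth
#'
#' @description
#' Generators for dihedral ensembles, sequence datasets, and ideal-geometry
#' coordinates whose statistical ground truth is known by construction, so
#' the entropy, composition, and sampling machinery can be validated
#' without any external database. Every generator is deterministic under
#' `set.seed()` and returns its ground truth alongside the data.
NULL

# Best-Fisher (1979) rejection sampler for the von Mises distribution;
# arguments and result in degrees.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f) * 180 / pi
      i <- i + 1L
    }
  }
  wrap_angle(out)
}

# per-axis bin probabilities of a von Mises density by fine-grid quadrature
vm_bin_probs <- function(mu, kappa, width, grid_step = 0.05) {
  theta <- seq(-180 + grid_step / 2, 180 - grid_step / 2, by = grid_step)
  dens <- exp(kappa * cos((theta - mu) * pi / 180))
  dens <- dens / sum(dens)
  bins <- bin_index(theta, width)
  as.vector(tapply(dens, bins, sum))
}

#' Synthetic dihedral ensemble with known binned entropy
#'
#' Draws per-triad (phi, psi) samples from one of three generating
#' distributions and returns the exact binned Shannon entropy of the
#' generator on the requested grid alongside the samples:
#' \itemize{
#'   \item uniform over the full torus (`components` and `bins` both NULL):
#'     entropy ln((360/width)^2);
#'   \item uniform over a stated subset of K grid bins (`bins`): entropy
#'     ln(K);
#'   \item a von Mises mixture (`components`): entropy of the exact bin
#'     probabilities obtained by quadrature.
#' }
#' Mixture concentrations around kappa = 5-50 with a few components span
#' roughly the 1.5-3 nats range observed for real triads on a 30-degree
#' grid.
#'
#' @param triads character vector of triad labels to emulate.
#' @param n_frames samples per triad.
#' @param width grid width in degrees (default 30).
#' @param components NULL, or a data.frame (recycled to every triad, or a
#'   named list of data.frames per triad) with columns `weight`, `mu_phi`,
#'   `mu_psi`, `kappa_phi`, `kappa_psi`; weights must sum to 1; phi and
#'   psi are independent within a component.
#' @param bins NULL, or an integer vector of allowed bin indices (1 ..
#'   (360/width)^2, psi fastest), or a named list per triad.
#' @return list with `records` (data.frame: model, index, residue, triad,
#'   phi, psi), `true_entropy` (named per triad, nats), `width`.
#' @export
gen_dihedral_ensemble <- function(triads, n_frames, width = 30,
                                  components = NULL, bins = NULL) {
  nb <- as.integer(round(360 / width))
  per_triad <- function(spec_default, arg) {
    if (is.null(arg)) return(stats::setNames(rep(list(NULL), length(triads)),
                                             triads))
    if (is.list(arg) && !is.data.frame(arg) && !is.null(names(arg))) {
      return(arg[triads])
    }
    stats::setNames(rep(list(arg), length(triads)), triads)
  }
  comp <- per_triad(NULL, components)
  bn <- per_triad(NULL, bins)

  all_rec <- vector("list", length(triads))
  truth <- stats::setNames(numeric(length(triads)), triads)
  for (t in seq_along(triads)) {
    tri <- triads[t]
    cmp <- comp[[tri]]; bset <- bn[[tri]]
    if (!is.null(cmp)) {
      if (abs(sum(cmp$weight) - 1) > 1e-9) {
        stop("mixture weights must sum to 1 for triad ", tri)
      }
      pick <- sample.int(nrow(cmp), n_frames, replace = TRUE,
                         prob = cmp$weight)
      phi <- psi <- numeric(n_frames)
      for (c_ in seq_len(nrow(cmp))) {
        idx <- pick == c_
        if (!any(idx)) next
        phi[idx] <- rvonmises(sum(idx), cmp$mu_phi[c_], cmp$kappa_phi[c_])
        psi[idx] <- rvonmises(sum(idx), cmp$mu_psi[c_], cmp$kappa_psi[c_])
      }
      pphi <- vapply(seq_len(nrow(cmp)), function(c_) {
        vm_bin_probs(cmp$mu_phi[c_], cmp$kappa_phi[c_], width)
      }, numeric(nb))
      ppsi <- vapply(seq_len(nrow(cmp)), function(c_) {
        vm_bin_probs(cmp$mu_psi[c_], cmp$kappa_psi[c_], width)
      }, numeric(nb))
      P <- matrix(0, nb, nb)
      for (c_ in seq_len(nrow(cmp))) {
        P <- P + cmp$weight[c_] * outer(pphi[, c_], ppsi[, c_])
      }
      truth[tri] <- shannon_entropy(P)
    } else if (!is.null(bset)) {
      stopifnot(all(bset >= 1), all(bset <= nb * nb))
      cells <- bset[sample.int(length(bset), n_frames, replace = TRUE)]
      ip <- (cells - 1L) %/% nb + 1L
      is_ <- (cells - 1L) %% nb + 1L
      phi <- -180 + (ip - 1L) * width + stats::runif(n_frames) * width
      psi <- -180 + (is_ - 1L) * width + stats::runif(n_frames) * width
      truth[tri] <- log(length(unique(bset)))
    } else {
      phi <- stats::runif(n_frames, -180, 180)
      psi <- stats::runif(n_frames, -180, 180)
      truth[tri] <- log(nb * nb)
    }
    all_rec[[t]] <- data.frame(model = seq_len(n_frames), index = 2L,
                               residue = substr(tri, 2, 2), triad = tri,
                               phi = wrap_angle(phi), psi = wrap_angle(psi))
  }
  list(records = do.call(rbind, all_rec), true_entropy = truth,
       width = width)
}

# background residue frequencies of folded proteins (approximate natural
# abundances), used as the globular composition
.BG_FREQ <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1,
              H = 2.3, I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1,
              P = 4.7, Q = 3.9, R = 5.5, S = 6.6, T = 5.4, V = 6.9,
              W = 1.1, Y = 2.9) / 100

.DISORDER_PROMOTING <- c("A", "R", "G", "Q", "S", "P", "E", "K")
.ORDER_PROMOTING <- c("W", "C", "F", "I", "Y", "V", "L", "N")

#' Paired globular-like and disordered-like sequence datasets
#'
#' Sequences are drawn residue-wise i.i.d. from group-specific
#' compositions. The globular group uses approximate natural residue
#' abundances; the disordered group up-weights disorder-promoting residues
#' (A, R, G, Q, S, P, E, K) and down-weights order-promoting ones (W, C,
#' F, I, Y, V, L, N) by a factor (1 + 0.6 * bias) — with `bias = 0` the
#' two groups share one composition exactly. Specific triads can
#' additionally be planted into the disordered set at a stated enrichment:
#' extra copies are written over the sequence at non-overlapping
#' positions, with the number of copies Poisson-distributed so the
#' expected triad frequency is `enrichment` times its background
#' frequency.
#'
#' @param n_globular,n_disordered dataset sizes.
#' @param length sequence length (single value or per-sequence vector,
#'   recycled within each group; honoured exactly).
#' @param bias composition contrast between the groups (0 = none).
#' @param planted NULL or data.frame with columns `triad`, `enrichment`.
#' @return list with `globular` and `disordered` (named character
#'   vectors), `truth` (data.frame: triad, enrichment, expected_delta),
#'   `p_globular`, `p_disordered`.
#' @export
gen_sequence_datasets <- function(n_globular = 100, n_disordered = 50,
                                  length = 150, bias = 1, planted = NULL) {
  stopifnot(n_globular >= 1, n_disordered >= 1, all(length >= 3))
  p_glob <- .BG_FREQ / sum(.BG_FREQ)
  w <- rep(1, 20); names(w) <- AA_CODES
  w[.DISORDER_PROMOTING] <- 1 + 0.6 * bias
  w[.ORDER_PROMOTING] <- 1 / (1 + 0.6 * bias)
  p_dis <- p_glob * w
  p_dis <- p_dis / sum(p_dis)

  draw <- function(n, p, lens) {
    lens <- rep_len(lens, n)
    vapply(seq_len(n), function(i) {
      paste(sample(AA_CODES, lens[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  }
  glob <- draw(n_globular, p_glob, length)
  dis <- draw(n_disordered, p_dis, length)

  truth <- data.frame(triad = character(0), enrichment = numeric(0),
                      expected_delta = numeric(0))
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      tri <- planted$triad[r]
      f <- planted$enrichment[r]
      aa <- strsplit(tri, "")[[1]]
      bg_dis <- prod(p_dis[aa])
      for (i in seq_along(dis)) {
        L <- nchar(dis[i])
        n_extra <- stats::rpois(1, (f - 1) * bg_dis * (L - 2))
        if (n_extra == 0) next
        starts <- seq(1, L - 2, by = 3)
        pos <- sample(starts, min(n_extra, base::length(starts)))
        for (p_ in pos) {
          substr(dis[i], p_, p_ + 2) <- tri
        }
      }
      truth <- rbind(truth, data.frame(
        triad = tri, enrichment = f,
        expected_delta = f * bg_dis / prod(p_glob[aa])))
    }
  }
  names(glob) <- sprintf("glob_%03d", seq_along(glob))
  names(dis) <- sprintf("dis_%03d", seq_along(dis))
  list(globular = glob, disordered = dis, truth = truth,
       p_globular = p_glob, p_disordered = p_dis)
}

# natural extension reference frame: place atom D bonded to C, with the
# stated B-C-D angle and A-B-C-D torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Ideal-geometry backbone at fixed torsions
#'
#' Builds an N/CA/C backbone with standard bond lengths (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 Angstrom) and angles (N-CA-C 111.2, CA-C-N
#' 116.2, C-N-CA 121.7 degrees) at exactly the requested (phi, psi)
#' torsions (omega fixed at 180). Serves as the round-trip oracle for
#' [compute_dihedrals()]: the torsions recovered from the coordinates must
#' match the request.
#'
#' @param n number of residues (>= 3).
#' @param phi,psi backbone torsions in degrees (single values or length-n
#'   vectors; phi\[1\] and psi\[n\] are undefined and ignored).
#' @param sequence residue string (default poly-alanine).
#' @param omega peptide-bond torsion (degrees).
#' @return a `backbone_model`.
#' @export
gen_helix_coordinates <- function(n, phi = -57, psi = -47,
                                  sequence = NULL, omega = 180) {
  stopifnot(n >= 3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  sequence <- sequence %||% paste(rep("A", n), collapse = "")
  codes <- strsplit(sequence, "")[[1]]
  stopifnot(length(codes) == n)

  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7

  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  alpha <- (180 - a_NCAC) * pi / 180
  C[1, ] <- CA[1, ] + b_CAC * c(cos(alpha), sin(alpha), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_CN, a_CACN,
                              psi[i])
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], b_NCA,
                               a_CNCA, omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], b_CAC,
                              a_NCAC, phi[i + 1L])
  }
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(n), each = 3L),
    ires = rep(seq_len(n), each = 3L),
    code = rep(codes, each = 3L),
    atom = rep(c("N", "CA", "C"), n),
    element = rep(c("N", "C", "C"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3]))))
  residues <- data.frame(ires = seq_len(n), chain = "A",
                         resno = seq_len(n), code = codes,
                         gap_before = c(TRUE, rep(FALSE, n - 1L)),
                         complete = TRUE)
  structure(list(atoms = atoms, residues = residues, model = 1L),
            class = "backbone_model")
}

#' Planar zigzag C-alpha chain satisfying the pseudo-bond windows
#'
#' All Ca(i)-Ca(i+1) distances are exactly 3.8 A and all Ca(i)-Ca(i+2)
#' distances exactly 6.0 A, the centres of the sampler's constraint
#' windows; a valid Monte Carlo starting structure for any sequence.
#'
#' @param seq sequence string.
#' @return a `ca_chain`.
#' @export
gen_ca_chain <- function(seq) {
  n <- nchar(seq)
  stopifnot(n >= 1)
  # bond angle theta with 2 * 3.8^2 * (1 - cos(theta)) = 6^2
  gamma <- acos(6 / (2 * 3.8))
  steps <- cbind(3.8 * cos(gamma),
                 3.8 * sin(gamma) * (-1)^(seq_len(max(n - 1L, 0L)) + 1L),
                 0)
  coords <- rbind(c(0, 0, 0),
                  if (n > 1L) apply(steps, 2, cumsum))
  if (n == 2L) coords <- matrix(coords, ncol = 3)
  ca_chain(seq, coords[seq_len(n), , drop = FALSE])
}
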