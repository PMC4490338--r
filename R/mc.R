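#' @name cg_mc
#' @title Coarse-grained C-alpha Monte Carlo sampling
#'
#' @description
#' Disordered-chain ensembles are generated with a one-bead-per-residue
#' Metropolis Monte Carlo scheme. Chain geometry is maintained by hard
#' pseudo-bond constraints — Ca(i)-Ca(i+1) within 3.8 +/- 0.15 A and
#' Ca(i)-Ca(i+2) within 6.0 +/- 1.5 A; any proposal leaving either window
#' is rejected outright. Non-local interactions (sequence separation >= 3)
#' contribute four energy terms, each with a named coefficient defaulting
#' to 1 (energies are in arbitrary reduced units; temperature is the
#' dimensionless Metropolis parameter):
#' \describe{
#'   \item{Lennard-Jones}{4 eps \[(sigma/r)^12 - (sigma/r)^6\] van der
#'     Waals term; r is floored at 0.1 sigma against overlap divergence.}
#'   \item{hydrophobic}{-c_h (H_j + H_k - 1) / r with H the \[0, 1\]
#'     normalised hydrophobicities: hydrophobic-hydrophobic pairs
#'     (H near 1) are attracted, polar-polar pairs (H near 0) repelled.}
#'   \item{electrostatic}{c_el Q_j Q_k / r, unscreened Coulomb form over
#'     the residue charges.}
#'   \item{steric}{c_st sum_j nmw(j) ncn(j), coupling normalised residue
#'     molecular weight to the site's normalised coordination number so
#'     heavy residues are preferred at low-coordination (surface) sites
#'     and light residues at buried ones.}
#' }
NULL

#' Default energy coefficients for the coarse-grained model
#'
#' @param lj_epsilon,lj_sigma Lennard-Jones well depth and length scale.
#' @param c_hydrophobic,c_electrostatic,c_steric term weights.
#' @param cn_cutoff coordination-number cutoff (Angstrom).
#' @param r_floor_factor minimum r, as a fraction of sigma, used in the
#'   pair terms to guard the LJ divergence.
#' @export
mc_params <- function(lj_epsilon = 1, lj_sigma = 1, c_hydrophobic = 1,
                      c_electrostatic = 1, c_steric = 1, cn_cutoff = 8,
                      r_floor_factor = 0.1) {
  list(lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
       c_hydrophobic = c_hydrophobic, c_electrostatic = c_electrostatic,
       c_steric = c_steric, cn_cutoff = cn_cutoff,
       r_floor_factor = r_floor_factor)
}

#' Build a coarse-grained C-alpha chain
#'
#' Attaches per-residue hydrophobicity, charge, and normalised molecular
#' weight to a Ca trace. Scales default to min-max normalised
#' Kyte-Doolittle hydropathies, unit charges on K/R/D/E (+0.1 on H), and
#' min-max normalised residue masses; all three are overridable.
#'
#' @param seq sequence string.
#' @param coords n x 3 matrix of Ca coordinates (Angstrom).
#' @param hydrophobicity,charges,masses named per-residue-type vectors.
#' @return object of class `ca_chain`.
#' @export
ca_chain <- function(seq, coords, hydrophobicity = kd_hydrophobicity(),
                     charges = residue_charges(),
                     masses = residue_masses()) {
  res <- strsplit(seq, "")[[1]]
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(res), ncol(coords) == 3,
            all(is.finite(coords)))
  structure(list(coords = unname(coords), seq = seq,
                 H = unname(hydrophobicity[res]),
                 Q = unname(charges[res]),
                 nmw = unname(masses[res])),
            class = "ca_chain")
}

#' @exportS3Method base::print
print.ca_chain <- function(x, ...) {
  cat(sprintf("ca_chain: %d residues, net charge %+.1f\n",
              nrow(x$coords), sum(x$Q)))
  invisible(x)
}

#' Check the pseudo-bond constraint windows of a chain
#'
#' @param chain a `ca_chain` or coordinate matrix.
#' @param bond,bond_tol nearest-neighbour window (default 3.8 +/- 0.15 A).
#' @param d13,d13_tol next-nearest window (default 6.0 +/- 1.5 A).
#' @return logical: TRUE when every pseudo-bond is inside its window.
#' @export
chain_satisfies_constraints <- function(chain, bond = 3.8, bond_tol = 0.15,
                                        d13 = 6.0, d13_tol = 1.5) {
  xyz <- if (inherits(chain, "ca_chain")) chain$coords else as.matrix(chain)
  n <- nrow(xyz)
  if (n < 2L) return(TRUE)
  d1 <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                        xyz[-n, , drop = FALSE])^2))
  ok <- all(abs(d1 - bond) <= bond_tol + 1e-9)
  if (n >= 3L) {
    d2 <- sqrt(rowSums((xyz[-(1:2), , drop = FALSE] -
                          xyz[seq_len(n - 2L), , drop = FALSE])^2))
    ok <- ok && all(abs(d2 - d13) <= d13_tol + 1e-9)
  }
  ok
}

#' Normalised coordination numbers
#'
#' Counts, for each site, the non-local sites (sequence separation >= 3)
#' within `cutoff` Angstrom and normalises by the chain's maximum count,
#' giving values in \[0, 1\] (all zero when no site has a spatial
#' neighbour).
#'
#' @param chain a `ca_chain` or coordinate matrix.
#' @param site optional single site index; default all sites.
#' @param cutoff neighbour cutoff in Angstrom.
#' @export
coordination_number <- function(chain, site = NULL, cutoff = 8) {
  xyz <- if (inherits(chain, "ca_chain")) chain$coords else as.matrix(chain)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  cnt <- unname(rowSums(d < cutoff & sep >= 3))
  mx <- max(cnt)
  ncn <- if (mx > 0) cnt / mx else cnt
  if (!is.null(site)) ncn[site] else ncn
}

#' Energy of a coarse-grained chain
#'
#' Evaluates the four-term energy described in \link{cg_mc} and reports
#' each term separately. Pure-R reference implementation; the sampler's
#' C++ core computes the identical quantity.
#'
#' @param chain a `ca_chain`.
#' @param params coefficient list from [mc_params()].
#' @return list with `lj`, `hydrophobic`, `electrostatic`, `steric`,
#'   `total`.
#' @export
total_energy <- function(chain, params = mc_params()) {
  stopifnot(inherits(chain, "ca_chain"))
  xyz <- chain$coords
  n <- nrow(xyz)
  lj <- hp <- el <- 0
  rfloor <- params$r_floor_factor * params$lj_sigma
  floored <- FALSE
  if (n >= 4L) {
    for (j in seq_len(n - 3L)) {
      for (k in (j + 3L):n) {
        r <- sqrt(sum((xyz[j, ] - xyz[k, ])^2))
        if (r < rfloor) { r <- rfloor; floored <- TRUE }
        sr6 <- (params$lj_sigma / r)^6
        lj <- lj + 4 * params$lj_epsilon * (sr6^2 - sr6)
        hp <- hp - params$c_hydrophobic *
          (chain$H[j] + chain$H[k] - 1) / r
        el <- el + params$c_electrostatic * chain$Q[j] * chain$Q[k] / r
      }
    }
  }
  if (floored) warning("overlapping sites: pair distance floored at ",
                       signif(rfloor, 3), " A")
  st <- params$c_steric *
    sum(chain$nmw * coordination_number(chain, cutoff = params$cn_cutoff))
  list(lj = lj, hydrophobic = hp, electrostatic = el, steric = st,
       total = lj + hp + el + st)
}

#' Metropolis Monte Carlo run
#'
#' Single-site displacement sampler: each step perturbs one random site by
#' a uniform displacement in a cube of half-width `max_disp`; proposals
#' violating a pseudo-bond window are rejected outright, others accepted
#' with probability min(1, exp(-dE / T)). Snapshots (and their energy
#' breakdown) are recorded every `stride` steps. Fully reproducible for a
#' fixed `seed`.
#'
#' @param chain initial `ca_chain`; must satisfy the constraint windows.
#' @param steps number of MC steps (>= 1).
#' @param temperature dimensionless Metropolis temperature.
#' @param seed RNG seed (integer); NULL leaves the RNG state alone.
#' @param stride snapshot interval in steps.
#' @param max_disp proposal cube half-width (Angstrom, default 0.5).
#' @param params coefficients from [mc_params()].
#' @return list of class `mc_run`: `ensemble` (list of `ca_chain`
#'   snapshots), `energies` (data.frame per snapshot: step, lj,
#'   hydrophobic, electrostatic, steric, total), `acceptance_rate` (over
#'   all proposals), `constraint_rejections` (proposals discarded at the
#'   pseudo-bond windows, before the Metropolis test), `final` chain, and
#'   the run settings.
#' @export
metropolis_run <- function(chain, steps, temperature = 1, seed = NULL,
                           stride = 100, max_disp = 0.5,
                           params = mc_params()) {
  stopifnot(inherits(chain, "ca_chain"), steps >= 1)
  if (!chain_satisfies_constraints(chain)) {
    stop("initial chain violates the pseudo-bond constraint windows")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cg_mc_run(chain$coords, chain$H, chain$Q, chain$nmw,
                   params$lj_epsilon, params$lj_sigma,
                   params$c_hydrophobic, params$c_electrostatic,
                   params$c_steric, params$cn_cutoff,
                   params$r_floor_factor * params$lj_sigma,
                   as.integer(steps), as.integer(stride),
                   temperature, max_disp,
                   3.8 - 0.15, 3.8 + 0.15, 6.0 - 1.5, 6.0 + 1.5)
  snap <- lapply(res$snapshots, function(m) {
    ca_chain(chain$seq, m,
             hydrophobicity = stats::setNames(chain$H,
                                              strsplit(chain$seq, "")[[1]]),
             charges = stats::setNames(chain$Q, strsplit(chain$seq, "")[[1]]),
             masses = stats::setNames(chain$nmw, strsplit(chain$seq, "")[[1]]))
  })
  energies <- as.data.frame(res$energies)
  names(energies) <- c("step", "lj", "hydrophobic", "electrostatic",
                       "steric", "total")
  structure(list(ensemble = snap, energies = energies,
                 acceptance_rate = res$accepted / steps,
                 constraint_rejections = res$constraint_rejected,
                 final = snap[[length(snap)]],
                 settings = list(steps = steps, temperature = temperature,
                                 seed = seed, stride = stride,
                                 max_disp = max_disp, params = params)),
            class = "mc_run")
}

#' @exportS3Method base::print
print.mc_run <- function(x, ...) {
  cat(sprintf("mc_run: %d steps, %d snapshots, acceptance %.1f%%\n",
              x$settings$steps, length(x$ensemble),
              100 * x$acceptance_rate))
  invisible(x)
}

#' Write an MC ensemble as a multi-model C-alpha PDB
#'
#' The output file is consumable by [read_pdb()], so the contact and
#' dihedral machinery applies to sampled ensembles.
#'
#' @param run an `mc_run` (or list of `ca_chain`s).
#' @param path output PDB path.
#' @export
write_ensemble_pdb <- function(run, path) {
  chains <- if (inherits(run, "mc_run")) run$ensemble else run
  models <- lapply(chains, function(ch) {
    res <- strsplit(ch$seq, "")[[1]]
    data.frame(chain = "A", resno = seq_along(res), code = res,
               atom = "CA", x = ch$coords[, 1], y = ch$coords[, 2],
               z = ch$coords[, 3])
  })
  write_pdb(models, path)
}

#' Write the energy trace of an MC run to TSV
#' @param run an `mc_run`.
#' @param path output file.
#' @export
write_energy_trace <- function(run, path) {
  utils::write.table(run$energies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
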