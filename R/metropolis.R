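#' Metropolis acceptance rule
#'
#' The acceptance probability used by the sampler: proposals lowering the
#' energy are always accepted, otherwise accepted with probability
#' exp(-dE / T). Exposed so the rule can be exercised in isolation.
#'
#' @param delta_e energy change of the proposal.
#' @param temperature dimensionless temperature (> 0; at T = 0 only
#'   downhill moves are accepted).
#' @param u uniform random number(s) in \[0, 1\]; defaults to fresh draws.
#' @return logical vector of acceptances.
#' @export
metropolis_accept <- function(delta_e, temperature,
                              u = stats::runif(length(delta_e))) {
  if (temperature <= 0) return(delta_e <= 0)
  delta_e <= 0 | u < exp(-delta_e / temperature)
}

#' Two-state Metropolis chain
#'
#' Samples a discrete system with two states (energies 0 and `delta_e`)
#' under the same acceptance rule as the conformational sampler; at
#' equilibrium the occupancy ratio of the excited to the ground state is
#' the Boltzmann factor exp(-delta_e / T). Used as a detailed-balance
#' diagnostic of the acceptance rule.
#'
#' @param delta_e energy of the excited state (ground state has 0).
#' @param steps number of proposal steps.
#' @param temperature dimensionless temperature.
#' @param seed optional RNG seed.
#' @return list with `occupancy` (fraction of steps in the excited
#'   state), `expected_ratio` = exp(-delta_e / T), `observed_ratio`.
#' @export
metropolis_two_state <- function(delta_e, steps, temperature = 1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(steps)
  state <- logical(steps)          # FALSE = ground, TRUE = excited
  cur <- FALSE
  p_up <- if (temperature > 0) exp(-delta_e / temperature) else 0
  for (s in seq_len(steps)) {
    if (cur) {
      # proposal to ground state is always downhill
      cur <- FALSE
    } else if (u[s] < p_up) {
      cur <- TRUE
    }
    state[s] <- cur
  }
  occ <- mean(state)
  list(occupancy = occ,
       expected_ratio = p_up,
       observed_ratio = occ / (1 - occ))
}
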