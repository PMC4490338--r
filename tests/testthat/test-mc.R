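test_that("energy terms honour their stated sign contracts", {
  # zero charges -> electrostatic term exactly 0
  ch <- gen_ca_chain("AGAGAGAG") # A and G carry no charge
  e <- total_energy(ch)
  expect_identical(e$electrostatic, 0)
  expect_equal(e$total, e$lj + e$hydrophobic + e$electrostatic + e$steric)

  # single interacting pair at the LJ minimum: LJ term = -epsilon
  sigma <- 3
  rmin <- 2^(1 / 6) * sigma
  coords <- rbind(c(0, 0, 0), c(1000, 0, 0), c(2000, 0, 0),
                  c(rmin, 0, 0))
  neutral <- stats::setNames(rep(0.5, 20), AA_CODES) # H_j + H_k - 1 = 0
  zeroq <- stats::setNames(rep(0, 20), AA_CODES)
  ch2 <- ca_chain("AAAA", coords, hydrophobicity = neutral,
                  charges = zeroq)
  e2 <- total_energy(ch2, mc_params(lj_epsilon = 2, lj_sigma = sigma))
  expect_equal(e2$lj, -2, tolerance = 1e-9)
  expect_equal(e2$hydrophobic, 0)

  # hydrophobic-hydrophobic attracts, polar-polar repels
  pair <- function(h) {
    hv <- stats::setNames(rep(h, 20), AA_CODES)
    ch <- ca_chain("AAAA", coords, hydrophobicity = hv, charges = zeroq)
    total_energy(ch)$hydrophobic
  }
  expect_lt(pair(1), 0) # hydrophobic pair: favourable
  expect_gt(pair(0), 0) # polar pair: penalised

  # opposite charges attract under the Coulomb-form term
  chq <- ca_chain("KAAD", coords)
  expect_lt(total_energy(chq)$electrostatic, 0)
})

test_that("steric term prefers heavy residues at low-coordination sites", {
  set.seed(71)
  # compact cluster with one exposed terminal site
  coords <- rbind(matrix(stats::rnorm(5 * 3, 0, 2.5), ncol = 3),
                  c(30, 0, 0))
  # W (heaviest) buried vs W exposed, same composition otherwise
  buried <- ca_chain("WAAAAG", coords)
  exposed <- ca_chain("GAAAAW", coords)
  ncn <- coordination_number(buried)
  expect_lt(ncn[6], ncn[1])
  expect_lt(total_energy(exposed)$steric, total_energy(buried)$steric)
})

test_that("coordination numbers match a brute-force count and its limits", {
  set.seed(72)
  coords <- matrix(stats::runif(20 * 3, 0, 15), ncol = 3)
  ncn <- coordination_number(coords, cutoff = 8)
  cnt <- integer(20)
  for (i in 1:20) {
    for (j in 1:20) {
      if (abs(i - j) < 3) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < 8) cnt[i] <- cnt[i] + 1L
    }
  }
  expect_equal(ncn, cnt / max(cnt))
  expect_true(all(ncn >= 0 & ncn <= 1))
  expect_equal(max(ncn), 1)

  # isolated terminal site has no spatial neighbours
  iso <- rbind(matrix(stats::rnorm(15, 0, 2), ncol = 3), c(100, 100, 100))
  expect_equal(coordination_number(iso, site = 6), 0)
})

test_that("constraint windows are enforced on chains and proposals", {
  ch <- gen_ca_chain("ACDEFKLRST")
  expect_true(chain_satisfies_constraints(ch))
  bad <- ch
  bad$coords[5, ] <- bad$coords[5, ] + c(0.5, 0, 0) # bond -> 4.1ish
  expect_false(chain_satisfies_constraints(bad))
  expect_error(metropolis_run(bad, steps = 10), "constraint")

  set.seed(73)
  run <- metropolis_run(ch, steps = 2000, seed = 11, stride = 100)
  expect_true(all(vapply(run$ensemble, chain_satisfies_constraints,
                         logical(1))))
})

test_that("cached energies equal a from-scratch recomputation at every snapshot", {
  set.seed(74)
  ch <- gen_ca_chain("ACDEFKLRSTNQHW")
  run <- metropolis_run(ch, steps = 3000, seed = 5, stride = 250)
  for (k in seq_along(run$ensemble)) {
    e <- total_energy(run$ensemble[[k]])
    expect_equal(run$energies$total[k], e$total, tolerance = 1e-9)
    expect_equal(run$energies$lj[k], e$lj, tolerance = 1e-9)
    expect_equal(run$energies$steric[k], e$steric, tolerance = 1e-9)
  }
})

test_that("runs are bit-reproducible under a fixed seed", {
  ch <- gen_ca_chain("ACDEFKLRST")
  r1 <- metropolis_run(ch, steps = 1500, seed = 42, stride = 100)
  r2 <- metropolis_run(ch, steps = 1500, seed = 42, stride = 100)
  expect_identical(lapply(r1$ensemble, `[[`, "coords"),
                   lapply(r2$ensemble, `[[`, "coords"))
  expect_identical(r1$energies, r2$energies)
  r3 <- metropolis_run(ch, steps = 1500, seed = 43, stride = 100)
  expect_false(identical(r1$energies$total, r3$energies$total))
})

test_that("acceptance of constraint-satisfying proposals approaches 1 at high T", {
  ch <- gen_ca_chain("ACDEFKLRSTNQ")
  run <- metropolis_run(ch, steps = 2000, temperature = 1e9, seed = 2,
                        stride = 500, max_disp = 0.02)
  valid <- run$settings$steps - run$constraint_rejections
  expect_equal(run$acceptance_rate * run$settings$steps, valid)
  # and at T = 0 downhill-only: acceptance strictly below the valid count
  run0 <- metropolis_run(ch, steps = 2000, temperature = 0, seed = 2,
                         stride = 500, max_disp = 0.3)
  expect_lt(run0$acceptance_rate * 2000,
            2000 - run0$constraint_rejections)
})

test_that("the acceptance rule satisfies detailed balance on a two-state system", {
  out <- metropolis_two_state(delta_e = 1.2, steps = 2e5,
                              temperature = 1, seed = 77)
  pi_hi <- out$expected_ratio / (1 + out$expected_ratio)
  se <- sqrt(pi_hi * (1 - pi_hi) / 2e5)
  expect_lt(abs(out$occupancy - pi_hi), 3 * se)
  # T = 0: only downhill moves
  expect_identical(metropolis_accept(c(-1, 0, 1), 0), c(TRUE, TRUE, FALSE))
  expect_true(all(metropolis_accept(rep(5, 10), 1e12)))
})

test_that("MC ensembles round trip through multi-model PDB", {
  ch <- gen_ca_chain("ACDEFKLRST")
  run <- metropolis_run(ch, steps = 500, seed = 3, stride = 100)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(run, pdb)
  models <- read_pdb(pdb)
  expect_length(models, 5)
  expect_equal(models[[1]]$residues$code, strsplit("ACDEFKLRST", "")[[1]])
  got <- cbind(models[[3]]$atoms$x, models[[3]]$atoms$y,
               models[[3]]$atoms$z)
  expect_equal(got, run$ensemble[[3]]$coords, tolerance = 1e-3)
})
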