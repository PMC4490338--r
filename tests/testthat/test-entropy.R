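test_that("binning follows the half-open grid convention", {
  rec <- data.frame(model = 1, index = 2, residue = "A", triad = "AAA",
                    phi = -60, psi = -45)
  g <- bin_dihedrals(rec, width = 30)$AAA
  expect_equal(dim(g$counts), c(12, 12))
  expect_equal(sum(g$counts), 1)
  expect_equal(g$counts[5, 5], 1) # phi in [-60,-30), psi in [-60,-30)

  # exact boundary: -180 falls in the lowest bin; +180 wraps to -180
  rec$phi <- -180; rec$psi <- 180
  g <- bin_dihedrals(rec, width = 30)$AAA
  expect_equal(g$counts[1, 1], 1)

  expect_equal(nrow(bin_dihedrals(rec, width = 4,
                                  key_mode = "residue")$A$counts), 90)
  expect_error(bin_dihedrals(rec, width = 7), "divide")
})

test_that("Shannon entropy matches the direct oracle and its analytic bounds", {
  one <- matrix(0, 12, 12); one[3, 7] <- 10
  expect_equal(shannon_entropy(one), 0)
  expect_equal(shannon_entropy(matrix(1, 12, 12)), log(144),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    p <- stats::runif(5)
    expect_equal(shannon_entropy(p), entropy_oracle(p), tolerance = 1e-12)
  }
  expect_equal(shannon_entropy(c(1, 1, 1, 1), base = 2), 2) # bits option
  expect_error(shannon_entropy(numeric(0)), "empty")
})

test_that("entropy is bounded, relabel-invariant, and decreases under bin merging", {
  set.seed(8)
  for (i in 1:20) {
    counts <- stats::rpois(144, lambda = stats::runif(1, 0.1, 5))
    if (sum(counts) == 0) counts[1] <- 1
    s <- shannon_entropy(counts)
    expect_gte(s, 0)
    expect_lte(s, log(144) + 1e-12)
    expect_equal(shannon_entropy(sample(counts)), s, tolerance = 1e-12)
    merged <- colSums(matrix(counts, nrow = 2)) # merge bin pairs
    expect_lte(shannon_entropy(merged), s + 1e-12)
  }
})

test_that("uniform sampling fills bins evenly within multinomial error", {
  set.seed(12)
  fx <- gen_dihedral_ensemble("AAA", 1e4)
  g <- bin_dihedrals(fx$records, width = 30)$AAA
  expect_equal(sum(g$counts), 1e4)
  p <- grid_fractions(g)
  # 5 sigma of a multinomial cell around 1/144
  tol <- 5 * sqrt((1 / 144) * (143 / 144) / 1e4)
  expect_true(all(abs(p - 1 / 144) < tol))
})

test_that("triad entropy tables record plug-in entropies and counts", {
  rec <- data.frame(model = 1, index = 2, residue = "A", triad = "AAA",
                    phi = rep(-61, 50), psi = rep(-41, 50))
  tab <- build_entropy_table(rec)
  expect_s3_class(tab, "entropy_table")
  expect_equal(tab$entropy, 0) # single occupied bin
  expect_equal(tab$count, 50)

  set.seed(19)
  fx <- gen_dihedral_ensemble("AVA", 2e4, bins = 1:72)
  tab <- build_entropy_table(fx$records)
  expect_equal(tab$entropy, log(72), tolerance = 0.01)
  # min_count filtering
  rec2 <- rbind(rec, data.frame(model = 1, index = 2, residue = "G",
                                triad = "AGA", phi = 10, psi = 10))
  tab2 <- build_entropy_table(rec2, min_count = 10)
  expect_equal(tab2$triad, "AAA")
})

test_that("entropy estimates converge to the generator's binned truth", {
  cmp <- data.frame(weight = c(0.5, 0.5), mu_phi = c(-65, -120),
                    mu_psi = c(-40, 140), kappa_phi = c(6, 12),
                    kappa_psi = c(5, 10))
  set.seed(33)
  errs <- vapply(c(200, 2000, 50000), function(n) {
    fx <- gen_dihedral_ensemble("DAT", n, components = cmp)
    abs(build_entropy_table(fx$records)$entropy - fx$true_entropy)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("entropy ratios compare ensembles against a reference", {
  set.seed(6)
  fx <- gen_dihedral_ensemble(c("AAA", "AVA"), 5000)
  tab <- build_entropy_table(fx$records)
  er <- entropy_ratio(tab, tab)
  expect_equal(er$ratios$ratio, c(1, 1))
  expect_equal(er$mean_ratio, 1)
  expect_equal(er$n_excluded, 0)

  # ratios above 1 are allowed (broader-than-reference ensembles)
  narrow <- build_entropy_table(
    gen_dihedral_ensemble(c("AAA", "AVA"), 5000, bins = 1:36)$records)
  er2 <- entropy_ratio(tab, narrow)
  expect_true(all(er2$ratios$ratio > 1))

  # disjoint triads are excluded and counted
  other <- build_entropy_table(gen_dihedral_ensemble("GGG", 100)$records)
  expect_error(entropy_ratio(other, tab), "no shared")
  mixed <- build_entropy_table(
    gen_dihedral_ensemble(c("AAA", "GGG"), 100)$records)
  er3 <- entropy_ratio(mixed, tab)
  expect_equal(er3$ratios$triad, "AAA")
  expect_gt(er3$n_excluded, 0)
})

test_that("residuewise entropy follows the reference bin fractions", {
  # hand-built reference: alanine mass split over two 4-degree bins
  ref_rec <- data.frame(model = 1, index = 2, residue = "A", triad = NA,
                        phi = c(rep(-58, 3), rep(-178, 1)),
                        psi = c(rep(-46, 3), rep(-178, 1)))
  grids <- bin_dihedrals(ref_rec, width = 4, key_mode = "residue")
  q <- data.frame(model = 1, index = 2:4, residue = "A", triad = NA,
                  phi = c(-58, -178, -58), psi = c(-46, -178, -46))
  out <- residuewise_entropy(q, grids)
  expect_equal(out$per_residue$p_ref, c(0.75, 0.25, 0.75))
  expect_equal(out$per_residue$contribution,
               c(-0.75 * log(0.75), -0.25 * log(0.25), -0.75 * log(0.75)))
  expect_equal(out$total, sum(out$per_residue$contribution))

  # residue in a bin the reference fills completely contributes 0
  ref1 <- data.frame(model = 1, index = 2, residue = "G", triad = NA,
                     phi = 10, psi = 10)
  g1 <- bin_dihedrals(ref1, width = 4, key_mode = "residue")
  out1 <- residuewise_entropy(
    data.frame(model = 1, index = 2, residue = "G", triad = NA,
               phi = 10.5, psi = 10.5), g1)
  expect_equal(out1$total, 0)

  # residue type absent from the reference is flagged, not fatal
  out2 <- residuewise_entropy(
    data.frame(model = 1, index = 2:3, residue = c("G", "W"), triad = NA,
               phi = 10.5, psi = 10.5), g1)
  expect_equal(out2$n_flagged, 1)

  # "type" reading charges the full per-type entropy regardless of bin
  outt <- residuewise_entropy(q, grids, mode = "type")
  expect_equal(outt$per_residue$contribution,
               rep(shannon_entropy(grids$A), 3))
})

test_that("entropy tables serialise to JSON and TSV", {
  set.seed(2)
  fx <- gen_dihedral_ensemble(c("AAA", "GGG"), 500)
  tab <- build_entropy_table(fx$records, source = "fixture")
  js <- withr::local_tempfile(fileext = ".json")
  write_entropy_table(tab, js)
  back <- read_entropy_table(js)
  expect_equal(back$triad, tab$triad)
  expect_equal(back$entropy, tab$entropy, tolerance = 1e-12)
  expect_equal(attr(back, "width"), 30)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_table(tab, tsv)
  back2 <- read_entropy_table(tsv)
  expect_equal(back2$entropy, tab$entropy, tolerance = 1e-12)
})
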