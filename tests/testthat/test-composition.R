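test_that("dataset composition matches a brute-force tally", {
  p <- dataset_composition("AAA", unit = "residue")
  expect_equal(unname(p$fractions["A"]), 1.0)
  expect_equal(sum(p$fractions), 1.0)

  p <- dataset_composition(c("ACDEF", "ACDEF"), unit = "triad")
  expect_equal(unname(p$fractions[c("ACD", "CDE", "DEF")]), rep(1 / 3, 3))
  expect_equal(sum(p$fractions == 0), 8000 - 3)

  # unequal lengths: independent hand tally
  seqs <- c("ACDCA", "CAD")
  p <- dataset_composition(seqs, unit = "residue")
  tally <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
  for (aa in names(tally)) {
    expect_equal(unname(p$fractions[aa]), unname(tally[aa] / 8))
  }
  expect_error(dataset_composition(character(0)), "empty")
})

test_that("composition is invariant under dataset duplication", {
  set.seed(3)
  seqs <- vapply(1:5, function(i) {
    paste(sample(AA_CODES, 30, replace = TRUE), collapse = "")
  }, character(1))
  p1 <- dataset_composition(seqs, unit = "triad")
  p2 <- dataset_composition(c(seqs, seqs), unit = "triad")
  expect_equal(p1$fractions, p2$fractions)
})

test_that("relative composition is a guarded fraction ratio", {
  a <- dataset_composition(c("AG", "GA"), unit = "residue")
  tab <- relative_composition(a, a)
  expect_equal(tab$delta[tab$key %in% c("A", "G")], c(1, 1))

  tgt <- dataset_composition("AAAA", unit = "residue")
  ref <- dataset_composition("AGAG", unit = "residue")
  tab <- relative_composition(tgt, ref)
  expect_equal(tab$delta[tab$key == "A"], 2.0)
  # key in target but absent from reference: flagged, not infinite
  tgt2 <- dataset_composition("AC", unit = "residue")
  tab2 <- relative_composition(tgt2, ref)
  expect_false(tab2$defined[tab2$key == "C"])
  expect_true(is.na(tab2$delta[tab2$key == "C"]))
  expect_false(any(is.infinite(tab2$delta), na.rm = TRUE))

  r <- dataset_composition("ACD", unit = "residue")
  t3 <- dataset_composition(c("AAA"), unit = "triad")
  expect_error(relative_composition(t3, r), "different units")
})

test_that("sequence scores average Delta over usable units", {
  tgt <- dataset_composition(c("ACDEF", "ACDEF", "ACDEA"), unit = "triad")
  ref <- dataset_composition(c("ACDEF", "CDEFA"), unit = "triad")
  tab <- relative_composition(tgt, ref)
  # hand-check: mean of the sequence's defined triad Deltas
  d <- tab$delta[match(c("ACD", "CDE", "DEF"), tab$key)]
  sc <- sequence_score("ACDEF", tab)
  expect_equal(sc$score, mean(d, na.rm = TRUE))
  expect_equal(sc$n_units, 3)
  # undefined keys excluded from numerator and denominator
  tab$delta[tab$key == "DEF"] <- NA
  tab$defined[tab$key == "DEF"] <- FALSE
  sc2 <- sequence_score("ACDEF", tab)
  expect_equal(sc2$score, mean(d[1:2]))
  expect_equal(sc2$n_undefined, 1)
})

test_that("bootstrap CIs are degenerate for identical data and cover the plug-in value", {
  seqs <- rep("ACDEFGHIK", 4)
  expect_silent(bt <- bootstrap_ci(seqs, seqs, unit = "triad",
                                   n_iter = 50, level = 0.99))
  obs <- bt[bt$target_frac > 0, ]
  expect_true(all(obs$lower == obs$delta & obs$upper == obs$delta))

  set.seed(9)
  tgt <- c("ACDEFGHIKL", "MNPQRSTVWY")
  ref <- c("ACDEFGHIKL", "LMNPQRSTVW")
  bt <- bootstrap_ci(tgt, ref, unit = "residue", n_iter = 2000,
                     level = 0.99)
  ok <- !is.na(bt$lower) & bt$defined
  expect_true(all(bt$lower[ok] - 1e-9 <= bt$delta[ok] &
                    bt$delta[ok] <= bt$upper[ok] + 1e-9))
  expect_warning(bootstrap_ci("ACDEF", c("ACDEF", "ACDEG"),
                              unit = "residue", n_iter = 5), "degenerate")
})

test_that("planted triad enrichment is recovered in the preferred bucket", {
  set.seed(21)
  ds <- gen_sequence_datasets(n_globular = 80, n_disordered = 80,
                              length = 400, bias = 0,
                              planted = data.frame(triad = "QPF",
                                                   enrichment = 8))
  bt <- bootstrap_ci(ds$disordered, ds$globular, unit = "triad",
                     n_iter = 400, level = 0.99)
  rk <- rank_triads(bt)
  expect_true("QPF" %in% rk$most_preferred$key)
  # and the point estimate is in the right regime
  expect_gt(bt$delta[bt$key == "QPF"], 2)
})

test_that("rank_triads buckets by CI position and flags target-absent triads", {
  tab <- relative_composition(
    dataset_composition(c("ACDEF"), unit = "triad"),
    dataset_composition(c("ACDEF", "GHIKL"), unit = "triad"))
  tab$lower <- tab$delta
  tab$upper <- tab$delta
  rk <- rank_triads(tab)
  # GHI/HIK/IKL exist only in the reference: absent-from-target bucket
  expect_setequal(rk$absent_from_target$key, c("GHI", "HIK", "IKL"))
  expect_setequal(rk$most_preferred$key, c("ACD", "CDE", "DEF"))

  tab$lower <- tab$delta - 2
  tab$upper <- tab$delta + 2
  rk <- rank_triads(tab)
  expect_equal(nrow(rk$most_preferred), 0)
  expect_setequal(rk$no_preference$key, c("ACD", "CDE", "DEF"))
})

test_that("classification uses a strict threshold and the fitted midpoint separates groups", {
  expect_equal(classify_disorder(0.5, 1), "globular")
  expect_equal(classify_disorder(1.5, 1), "disordered")
  expect_equal(classify_disorder(1, 1), "globular") # tie goes globular

  set.seed(14)
  ds <- gen_sequence_datasets(n_globular = 40, n_disordered = 40,
                              length = 200, bias = 2)
  tab <- relative_composition(
    dataset_composition(ds$disordered, "triad"),
    dataset_composition(ds$globular, "triad"))
  sg <- score_dataset(ds$globular, tab)
  sd_ <- score_dataset(ds$disordered, tab)
  thr <- fit_threshold(sg$score, sd_$score)
  expect_true(all(classify_disorder(sg$score, thr) == "globular"))
  expect_true(all(classify_disorder(sd_$score, thr) == "disordered"))
})

test_that("triad scores separate neighbour-correlated groups better than residue scores", {
  # plant the signal in neighbour correlations: same residue composition,
  # different triad usage
  set.seed(31)
  ds <- gen_sequence_datasets(n_globular = 60, n_disordered = 60,
                              length = 300, bias = 0,
                              planted = data.frame(
                                triad = c("QPF", "PQQ", "QQP", "PHW"),
                                enrichment = c(6, 6, 6, 6)))
  smd <- function(unit) {
    tab <- relative_composition(
      dataset_composition(ds$disordered, unit),
      dataset_composition(ds$globular, unit))
    sg <- score_dataset(ds$globular, tab)$score
    sd_ <- score_dataset(ds$disordered, tab)$score
    (mean(sd_) - mean(sg)) / sqrt((stats::var(sg) + stats::var(sd_)) / 2)
  }
  expect_gt(smd("triad"), smd("residue"))
})
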