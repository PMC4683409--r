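## small noiseless self-generated dataset shared across fitting tests
noiseless_dataset <- function(params = wtRateParameters()) {
  spec <- generatorSpec(params = params, K_mM = c(15, 150),
                        V_mV = c(-100, -50, 50, 100),
                        iv_sd_pA = 0, cr_sd = 0, n_rep = 1)
  mergeDatasets(makeIVDataset(spec, seed = 1),
                makeCRDataset(spec, seed = 1, K_mM = c(15, 150)))
}

test_that("the objective vanishes at the generating truth", {
  ds <- noiseless_dataset()
  expect_lt(fitObjective(wtRateParameters(), ds, kf_diagram), 1e-10)
})

test_that("the weight scales only the coupling-ratio term", {
  ds <- noiseless_dataset()
  k <- wtRateParameters()@k0
  k["k5"] <- k["k5"] * 1.2
  p <- rateParameterSet(k)
  o1 <- fitObjective(p, ds, kf_diagram, weight = 1)
  o2 <- fitObjective(p, ds, kf_diagram, weight = 2)
  o3 <- fitObjective(p, ds, kf_diagram, weight = 3)
  expect_equal(o3 - o2, o2 - o1, tolerance = 1e-9 * o1)
  expect_gt(o2, o1)
  expect_error(fitObjective(p, ds, kf_diagram, weight = 0), "weight")
})

test_that("perturbing any single rate increases the objective", {
  ds <- noiseless_dataset()
  k0 <- wtRateParameters()@k0
  base <- fitObjective(wtRateParameters(), ds, kf_diagram)
  for (l in kf_labels) {
    k <- k0; k[l] <- k[l] * 1.1
    o <- fitObjective(rateParameterSet(k), ds, kf_diagram)
    expect_gt(o, base + 1e-6)
  }
})

test_that("a zero-iteration budget returns the start point", {
  ds <- noiseless_dataset()
  start <- rateParameterSet(wtRateParameters()@k0 * 1.2)
  fit <- fitRates(ds, free = c("k5", "k7"), start = start,
                  diagram = kf_diagram, restarts = 1, weights = 3,
                  seed = 1, maxit = 0)
  expect_equal(fit@params@k0, start@k0, tolerance = 1e-12)
  expect_equal(fit@objective,
               fitObjective(start, ds, kf_diagram, weight = 3),
               tolerance = 1e-9)
})

test_that("fits are reproducible given the seed", {
  ds <- noiseless_dataset()
  f1 <- fitRates(ds, free = c("k5", "k7"), diagram = kf_diagram,
                 restarts = 2, weights = 3, seed = 42, maxit = 50)
  f2 <- fitRates(ds, free = c("k5", "k7"), diagram = kf_diagram,
                 restarts = 2, weights = 3, seed = 42, maxit = 50)
  expect_identical(f1@params@k0, f2@params@k0)
  expect_identical(f1@objective, f2@objective)
})

test_that("identifiable free rates are recovered from noiseless self-data", {
  ## k1 (wide-pore binding), k2 (release) and k7 (pore-filter transfer)
  ## are strongly identifiable from i-V plus coupling-ratio data; the very
  ## fast water-shift and one-ion transfer rates sit near saturation and
  ## are only weakly constrained, so no recovery is claimed for them
  spec <- generatorSpec(params = wtRateParameters(),
                        K_mM = c(15, 50, 150, 300),
                        V_mV = seq(-100, 100, by = 40),
                        iv_sd_pA = 0, cr_sd = 0, n_rep = 1)
  ds <- mergeDatasets(makeIVDataset(spec, seed = 1),
                      makeCRDataset(spec, seed = 1, K_mM = c(15, 50, 150)))
  start <- wtRateParameters()@k0
  start[c("k1", "k2", "k7")] <- start[c("k1", "k2", "k7")] * 1.5
  fit <- fitRates(ds, free = c("k1", "k2", "k7"),
                  start = rateParameterSet(start), diagram = kf_diagram,
                  restarts = 3, weights = 10, seed = 3, maxit = 2000)
  truth <- wtRateParameters()@k0
  for (l in c("k1", "k2", "k7"))
    expect_lt(abs(fit@params@k0[[l]] - truth[[l]]) / truth[[l]], 0.10)
})

test_that("model selection follows the information criterion", {
  mk <- function(aic, k) methods::new(
    "FitResult", params = wtRateParameters(), objective = 0, weight = 1,
    n_free = as.integer(k), logLik = (2 * k - aic) / 2, aic = aic,
    residuals = list(), info = list())
  res <- list(mk(3.45, 4), mk(2.98, 5), mk(4.90, 10))
  expect_identical(selectModel(res)@n_free, 5L)
  ## equal likelihood: the parameter penalty decides
  res2 <- list(mk(2 * 5 - 2 * 1.0, 5), mk(2 * 4 - 2 * 1.0, 4))
  expect_identical(selectModel(res2)@n_free, 4L)
  ## a single candidate is returned unchanged
  expect_identical(selectModel(res[2]), res[[2]])
})

test_that("the mutant comparison reports the embodied directions", {
  rep_ <- qualitativeMutantCheck(wtRateParameters(), mutantRateParameters(),
                                 kf_diagram)
  mult <- mutantRateParameters()@k0 / wtRateParameters()@k0
  expect_gt(mult[["k1"]], 1)
  expect_identical(unname(rep_$direction["k1"]), "up")
  for (l in c("k2", "k5", "k7")) {
    expect_lt(mult[[l]], 1)
    expect_identical(unname(rep_$direction[l]), "down")
  }
  ## the mutant set rectifies inwardly, the wild type much less so
  expect_lt(rep_$rectification[["mut"]], 0.6)
  expect_gt(rep_$rectification[["wt"]] - rep_$rectification[["mut"]], 0.2)
  ## identical parameter sets produce no direction claims
  none <- qualitativeMutantCheck(wtRateParameters(), wtRateParameters(),
                                 kf_diagram)
  expect_true(all(none$direction == "~"))
})

test_that("parameter files round-trip through JSON", {
  p <- mutantRateParameters()
  tmp <- tempfile(fileext = ".json")
  writeParameters(p, tmp)
  p2 <- readParameters(tmp)
  expect_equal(p2@k0, p@k0, tolerance = 1e-12)
  expect_identical(freeParameters(p2), freeParameters(p))
})
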