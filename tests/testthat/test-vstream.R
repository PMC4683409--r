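## a noiseless two-branch ramp sweep with linear current
linear_sweep <- function(g_nS = 0.02 * 1e3, v_rev = -1.5) {
  v <- c(seq(-20, 20, by = 1), seq(19, -19, by = -1))
  data.frame(time_s = seq_along(v) * 1e-3, V_mV = v,
             I_pA = g_nS / 1e3 * (v - v_rev))
}

test_that("reversal potential extraction is exact on noiseless ramps", {
  z <- extractVrev(linear_sweep(v_rev = -1.5))
  expect_equal(z$V_rev_positive, -1.5, tolerance = 1e-9)
  expect_equal(z$V_rev_negative, -1.5, tolerance = 1e-9)
  expect_false(z$flagged)
  ## symmetric iso condition reverses at zero
  z0 <- extractVrev(linear_sweep(v_rev = 0))
  expect_equal(z0$V_rev, 0, tolerance = 1e-9)
  ## no crossing in span is an error
  expect_error(extractVrev(linear_sweep(v_rev = -60)), "zero crossing")
})

test_that("noisy ramp extraction recovers the truth within 0.1 mV", {
  spec <- generatorSpec(ramp_noise_pA = 0.5)
  tr <- makeRampTrain(spec, seed = 1, K_mM = 150, delta_osm = 1,
                      truth_CR = 1.39, junction = NULL)
  iso <- which(tr@schedule$phase == "iso")
  vr <- vapply(iso, function(i) extractVrev(tr@sweeps[[i]])$V_rev,
               numeric(1))
  expect_lt(abs(mean(vr) - 0), 0.1)
  hyper <- which(tr@schedule$phase == "hyper")
  vh <- vapply(hyper, function(i) extractVrev(tr@sweeps[[i]])$V_rev,
               numeric(1))
  expect_lt(abs(mean(vh) - tr@meta$truth_vstream_mV), 0.1)
})

test_that("junction correction is an exact affine shift", {
  spec <- generatorSpec(ramp_noise_pA = 0.2)
  tr <- makeRampTrain(spec, seed = 5, K_mM = 150, delta_osm = 1,
                      truth_CR = 1.39)
  with_corr <- computeVstream(tr)
  without <- computeVstream(tr, junction = NULL)
  ## Table entry at 150 mM / 1.0 M sorbitol is -0.22 mV
  expect_equal(with_corr@vstream$V_stream - without@vstream$V_stream,
               0.22, tolerance = 1e-12)
  expect_true(with_corr@details$recovered)
})

test_that("corrected streaming potential matches the generating truth", {
  spec <- generatorSpec(ramp_noise_pA = 0)
  tr <- makeRampTrain(spec, seed = 1, K_mM = 150, delta_osm = 1,
                      truth_CR = 1.39)
  vs <- computeVstream(tr)
  ## the generator embeds the junction offset; the reduction removes it
  expect_equal(vs@vstream$V_stream, tr@meta$truth_vstream_mV,
               tolerance = 1e-9)
  expect_equal(vs@vstream$V_stream, predictVstream(1.39, 1),
               tolerance = 1e-9)
  ## zero osmotic pulse gives zero shift
  tr0 <- makeRampTrain(spec, seed = 2, K_mM = 150, delta_osm = 0)
  expect_equal(computeVstream(tr0)@vstream$V_stream, 0, tolerance = 1e-9)
})

test_that("the hyper-phase conductance scale-up does not bias V_rev", {
  for (scale in c(1, 1.3, 2)) {
    spec <- generatorSpec(ramp_noise_pA = 0, hyper_g_scale = scale)
    tr <- makeRampTrain(spec, seed = 3, K_mM = 150, delta_osm = 1,
                        truth_CR = 1.39, junction = NULL)
    vs <- computeVstream(tr, junction = NULL)
    expect_equal(vs@vstream$V_stream, predictVstream(1.39, 1),
                 tolerance = 1e-9)
  }
})

test_that("slope regression and conversion behave on exact and edge cases", {
  exact <- data.frame(delta_osm = c(0.5, 1.0, 1.5),
                      V_stream = c(-0.315, -0.63, -0.945))
  reg <- regressVstream(exact)
  expect_equal(reg@slope, -0.63, tolerance = 1e-12)
  expect_lt(abs(reg@CR - 1.39) / 1.39, 0.03)
  ## all-zero shifts give slope and ratio zero
  zero <- data.frame(delta_osm = c(0.5, 1, 1.5), V_stream = 0)
  reg0 <- regressVstream(zero)
  expect_equal(reg0@slope, 0)
  expect_equal(reg0@CR, 0)
  ## degenerate design
  expect_error(regressVstream(data.frame(delta_osm = 1,
                                         V_stream = -0.6)),
               "single osmolality")
})

test_that("ANCOVA slope comparison: null and alternative behave correctly", {
  set.seed(9)
  d_osm <- rep(c(0.5, 1, 1.5), each = 4)
  noisy <- data.frame(delta_osm = d_osm,
                      V_stream = -0.8 * d_osm + rnorm(12, sd = 0.05))
  same <- compareSlopes(noisy, noisy)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(compareSlopes(noisy[noisy$delta_osm == 1, ],
                             noisy[noisy$delta_osm == 1, ]),
               "single osmolality")
  ## truths -0.82 vs -1.08 with measurement noise at the printed scale:
  ## the test should reject in the majority of seeded replicates
  reject <- 0
  for (s in 1:11) {
    set.seed(1000 + s)
    a <- data.frame(delta_osm = d_osm,
                    V_stream = -0.82 * d_osm + rnorm(12, sd = 0.06))
    b <- data.frame(delta_osm = d_osm,
                    V_stream = -1.08 * d_osm + rnorm(12, sd = 0.06))
    if (compareSlopes(a, b)$p_value < 0.05) reject <- reject + 1
  }
  expect_gt(reject, 5)
})

test_that("ramp trains round-trip through the CSV/JSON trace format", {
  spec <- generatorSpec()
  tr <- makeRampTrain(spec, seed = 8, K_mM = 50, delta_osm = 0.5)
  dir <- tempfile()
  writeRampTrain(tr, dir)
  tr2 <- readRampTrain(dir)
  expect_equal(tr2@sweeps[[1]]$I_pA, tr@sweeps[[1]]$I_pA, tolerance = 1e-12)
  expect_identical(tr2@schedule$phase, tr@schedule$phase)
  expect_equal(tr2@meta$truth_CR, tr@meta$truth_CR, tolerance = 1e-12)
  ## reduction gives the same answer from disk
  expect_equal(computeVstream(tr2)@vstream$V_stream,
               computeVstream(tr)@vstream$V_stream, tolerance = 1e-9)
})
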