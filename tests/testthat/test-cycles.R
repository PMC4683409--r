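test_that("cycle stoichiometry is topological and matches the anchors", {
  cyc <- enumerateCycles(kf_diagram)
  expect_identical(nrow(cyc), 59L)
  expect_identical(sum(cyc$conducting), 39L)
  a <- cyc[cyc$sequence == "1>2>3", ]
  expect_equal(c(a$n_ion, a$n_water), c(1, 1))
  expect_equal(a$ccr, 1)
  cc <- cyc[cyc$sequence == "4>6>11>9>7", ]
  expect_equal(c(cc$n_ion, cc$n_water), c(1, 2))
  ## a second enumeration gives identical stoichiometry (pure topology)
  expect_identical(enumerateCycles(kf_diagram)[, c("n_ion", "n_water")],
                   cyc[, c("n_ion", "n_water")])
})

test_that("a triangle graph has exactly one simple cycle", {
  toy <- toy_triangle()
  expect_identical(nrow(enumerateCycles(toy$diagram)), 1L)
})

test_that("triangle cycle flux matches the closed form", {
  toy <- toy_triangle()
  cnd <- permCondition(V_m = -0.05, K_in = 0.15, K_out = 0.15)
  a <- rateMatrix(toy$diagram, toy$params, cnd)$K
  ## closed form for a single loop: (k12 k23 k31 - k21 k32 k13) / S where S
  ## sums the two-edge arborescence products into each state
  num <- a[1, 2] * a[2, 3] * a[3, 1] - a[2, 1] * a[3, 2] * a[1, 3]
  S <- (a[2, 1] * a[3, 1] + a[2, 3] * a[3, 1] + a[3, 2] * a[2, 1]) +
       (a[1, 2] * a[3, 2] + a[1, 3] * a[3, 2] + a[3, 1] * a[1, 2]) +
       (a[2, 3] * a[1, 3] + a[2, 1] * a[1, 3] + a[1, 2] * a[2, 3])
  dec <- decomposeFlux(toy$diagram, toy$params, cnd)
  expect_equal(dec@records$J, num / S, tolerance = 1e-12)
  ## and the master-equation route agrees
  fl <- netFluxes(toy$diagram, toy$params, cnd)
  expect_equal(dec@J_total, fl$J_ion, tolerance = 1e-12)
})

test_that("steady state is a proper probability vector with zero balance", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_params()
    cnd <- permCondition(V_m = stats::runif(1, -0.15, 0.15),
                         K_in = stats::runif(1, 0.01, 0.3),
                         K_out = stats::runif(1, 0.01, 0.3))
    pi_ <- steadyState(kf_diagram, p, cnd)
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
    expect_true(all(pi_ >= 0))
    K <- rateMatrix(kf_diagram, p, cnd)$K
    Q <- K - diag(rowSums(K))
    expect_lt(max(abs(t(Q) %*% pi_)) / max(t(abs(Q)) %*% pi_), 1e-10)
  }
})

test_that("thermodynamic reversibility holds around all 59 cycles", {
  ## the log product ratio around any cycle must equal the cycle's ion
  ## stoichiometry times the electrochemical driving force
  set.seed(7)
  cyc <- enumerateCycles(kf_diagram)
  for (i in 1:5) {
    p <- random_params()
    cnd <- permCondition(V_m = stats::runif(1, -0.1, 0.1),
                         K_in = stats::runif(1, 0.01, 0.3),
                         K_out = stats::runif(1, 0.01, 0.3))
    consts <- physConstants()
    ed <- rateMatrix(kf_diagram, p, cnd)$edges
    key <- paste(ed$from, ed$to)
    drive <- consts$F * cnd$V_m / (consts$R * consts$T) +
      log(cnd$K_in / cnd$K_out)
    for (j in seq_len(nrow(cyc))) {
      v <- as.integer(strsplit(cyc$sequence[j], ">")[[1]])
      pairs <- cbind(v, c(v[-1], v[1]))
      fw <- ed$rate[match(paste(pairs[, 1], pairs[, 2]), key)]
      bw <- ed$rate[match(paste(pairs[, 2], pairs[, 1]), key)]
      expect_equal(sum(log(fw)) - sum(log(bw)), cyc$n_ion[j] * drive,
                   tolerance = 1e-8)
    }
  }
})

test_that("all cycle fluxes vanish at equilibrium", {
  for (K in c(0.015, 0.15)) {
    dec <- decomposeFlux(kf_diagram, wtRateParameters(),
                         permCondition(V_m = 0, K_in = K, K_out = K))
    expect_equal(max(abs(dec@records$J)), 0, tolerance = 1e-6)
    expect_warning(couplingRatio(dec), "equilibrium")
  }
})

test_that("decomposed flux equals the master-equation flux (oracle)", {
  ## full diagram, 100 random parameter sets
  set.seed(2024)
  for (i in 1:100) {
    p <- random_params()
    cnd <- permCondition(V_m = stats::runif(1, -0.15, 0.15),
                         K_in = stats::runif(1, 0.01, 0.3),
                         K_out = stats::runif(1, 0.01, 0.3))
    fl <- netFluxes(kf_diagram, p, cnd)
    dec <- decomposeFlux(kf_diagram, p, cnd)
    expect_equal(dec@J_total, fl$J_ion,
                 tolerance = 1e-8)
    ## the water flux decomposes identically
    expect_equal(sum(dec@records$n_water * dec@records$J), fl$J_water,
                 tolerance = 1e-8 * max(abs(fl$J_water), 1e-12))
  }
})

test_that("oracle equivalence holds on random small diagrams", {
  set.seed(33)
  for (i in 1:20) {
    dia <- random_small_diagram(n_states = sample(4:7, 1),
                                n_chords = sample(1:2, 1))
    p <- random_params()
    cnd <- permCondition(V_m = stats::runif(1, -0.1, 0.1),
                         K_in = stats::runif(1, 0.05, 0.3),
                         K_out = stats::runif(1, 0.05, 0.3))
    fl <- netFluxes(dia, p, cnd)
    dec <- decomposeFlux(dia, p, cnd)
    ## round-off scales with the gross one-way traffic, not the (possibly
    ## nearly cancelled) net flux
    expect_lt(abs(dec@J_total - fl$J_ion),
              1e-8 * max(fl$gross_ion, 1e-9))
  }
})

test_that("steady-state flux is conserved across both membrane cuts", {
  p <- wtRateParameters()
  cnd <- permCondition(V_m = -0.08, K_in = 0.15, K_out = 0.15)
  rm_ <- rateMatrix(kf_diagram, p, cnd)
  pi_ <- steadyState(kf_diagram, p, cnd)
  ed <- rm_$edges
  flux <- pi_[ed$from] * ed$rate
  ## intracellular binding cut equals extracellular release cut
  expect_equal(sum(flux * ed$ion_in), sum(flux * ed$ion_out),
               tolerance = 1e-10 * abs(sum(flux * ed$ion_out)))
})

test_that("flux follows the sign of the electrochemical driving force", {
  p <- wtRateParameters()
  consts <- physConstants()
  ## zero net flux at the Nernst potential despite a 3:1 gradient
  v_nernst <- -consts$R * consts$T / consts$F * log(0.15 / 0.05)
  f0 <- netFluxes(kf_diagram, p,
                  permCondition(V_m = v_nernst, K_in = 0.15, K_out = 0.05))
  expect_lt(abs(f0$J_ion), 1e-8 * f0$gross_ion)
  ## sign antisymmetry of the drive around the reversal point
  fp <- netFluxes(kf_diagram, p,
                  permCondition(V_m = v_nernst + 0.05, K_in = 0.15,
                                K_out = 0.05))
  fm <- netFluxes(kf_diagram, p,
                  permCondition(V_m = v_nernst - 0.05, K_in = 0.15,
                                K_out = 0.05))
  expect_gt(fp$J_ion, 0)
  expect_lt(fm$J_ion, 0)
})

test_that("coupling ratio is a weighted mean of cyclic ratios", {
  dec <- decomposeFlux(kf_diagram, wtRateParameters(),
                       permCondition(V_m = -0.001, K_in = 0.05,
                                     K_out = 0.05))
  r <- dec@records[dec@records$conducting, ]
  cr <- couplingRatio(dec)
  expect_equal(cr, sum(r$rel_contribution * r$ccr), tolerance = 1e-12)
  ## bounded by the extreme cyclic ratios when all contributions share the
  ## flux direction
  if (all(r$rel_contribution >= -1e-12)) {
    expect_gte(cr, min(r$ccr) - 1e-9)
    expect_lte(cr, max(r$ccr) + 1e-9)
  }
})
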