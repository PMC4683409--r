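#' Predicted single-channel current
#'
#' Current is elementary charge times the net ion flux; outward (efflux)
#' current is positive, inward negative.
#'
#' @inheritParams rateMatrix
#' @return current in pA.
#' @examples
#' # 6.24e6 ions/s is almost exactly 1 pA
#' 6.241509e6 * 1.602176634e-19 * 1e12
#' @export
predictCurrent <- function(diagram, params, condition,
                           consts = physConstants()) {
  fl <- netFluxes(diagram, params, condition, consts)
  .e_charge * fl$J_ion * 1e12
}

#' Model current-voltage relationship
#'
#' @param diagram,params,consts as in [rateMatrix()].
#' @param V_mV numeric vector of membrane potentials (mV).
#' @param K_mM symmetric K+ concentration (mM), or use `K_in_mM`/`K_out_mM`.
#' @param K_in_mM,K_out_mM asymmetric concentrations (mM).
#' @return data.frame with `V_mV` and `I_pA`.
#' @export
ivCurve <- function(diagram, params, V_mV = seq(-100, 100, by = 10),
                    K_mM = 150, K_in_mM = K_mM, K_out_mM = K_mM,
                    consts = physConstants()) {
  I <- vapply(V_mV, function(v)
    predictCurrent(diagram, params,
                   permCondition(V_m = v / 1e3, K_in = K_in_mM / 1e3,
                                 K_out = K_out_mM / 1e3), consts),
    numeric(1))
  data.frame(V_mV = V_mV, I_pA = I)
}

#' Chord-conductance versus concentration curve
#'
#' Chord conductance `g = I / (V_m - V_rev)` at a stated potential; for
#' symmetric solutions `V_rev = 0`.
#'
#' @inheritParams ivCurve
#' @param K_mM vector of symmetric K+ concentrations (mM).
#' @param V_mV potential at which conductance is evaluated (mV).
#' @return data.frame with `K_mM` and `g_pS`.
#' @export
conductanceCurve <- function(diagram, params,
                             K_mM = c(15, 50, 150, 300), V_mV = -100,
                             consts = physConstants()) {
  g <- vapply(K_mM, function(k) {
    i <- predictCurrent(diagram, params,
                        permCondition(V_m = V_mV / 1e3, K_in = k / 1e3,
                                      K_out = k / 1e3), consts)
    i / (V_mV / 1e3) # pA per volt is exactly pS
  }, numeric(1))
  data.frame(K_mM = K_mM, g_pS = g)
}

#' Model coupling ratio at a concentration
#'
#' The streaming-potential experiment operates around the reversal
#' potential, where the net flux goes through zero; the model coupling
#' ratio is therefore evaluated at a small offset from `V_rev` (default
#' -1 mV), where the flux-weighted ratio is well defined and effectively
#' equal to its limiting value at `V_rev`.
#'
#' @inheritParams rateMatrix
#' @param K_mM symmetric K+ concentration (mM).
#' @param V_offset_mV offset from the reversal potential (mV).
#' @return coupling ratio (waters per ion).
#' @export
modelCouplingRatio <- function(diagram, params, K_mM,
                               V_offset_mV = -1, consts = physConstants()) {
  fl <- netFluxes(diagram, params,
                  permCondition(V_m = V_offset_mV / 1e3, K_in = K_mM / 1e3,
                                K_out = K_mM / 1e3), consts)
  fl$CR
}

#' Streaming potential from a coupling ratio
#'
#' For a single-file pore carrying `CR` water molecules per ion, an osmotic
#' pressure difference shifts the reversal potential by
#' `V_stream = -CR * v_w * delta_pi / (z * F)`, with
#' `delta_pi = R * T * osmolality * density` the osmotic pressure. A
#' positive `delta_osm` (hyperosmotic outside) drives water efflux and
#' yields a negative streaming potential.
#'
#' @param CR water:ion coupling ratio.
#' @param delta_osm osmolality difference Osm_out - Osm_in (osmol/kg).
#' @param consts from [physConstants()].
#' @return streaming potential in mV.
#' @examples
#' predictVstream(1, 1) # about -0.459 mV at 295 K
#' @export
predictVstream <- function(CR, delta_osm, consts = physConstants()) {
  c_osm <- delta_osm * consts$water_density * 1e3   # osmol / m^3
  delta_pi <- consts$R * consts$T * c_osm           # Pa
  -CR * consts$v_w * delta_pi / (consts$z_ion * consts$F) * 1e3
}

#' Coupling ratio from a streaming-potential slope
#'
#' Inverse of [predictVstream()] applied to the regression slope of
#' V_stream against the osmolality difference:
#' `CR = |slope| * z * F / (v_w * R * T * density)`.
#'
#' @param slope slope in mV per Osm/kg.
#' @param consts from [physConstants()].
#' @return coupling ratio (dimensionless).
#' @examples
#' slopeToCR(-0.63) # about 1.37 waters per ion
#' @export
slopeToCR <- function(slope, consts = physConstants()) {
  stopifnot(is.finite(slope))
  abs(slope) / 1e3 * consts$z_ion * consts$F /
    (consts$v_w * consts$R * consts$T * consts$water_density * 1e3)
}

#' Per-cycle contribution surface
#'
#' Evaluates the cycle decomposition over a grid of voltages and symmetric
#' K+ concentrations, reporting each conducting cycle's relative
#' contribution to the total ion flux and its chord conductance
#' `g_i = e * n_ion * J_i / V_m`.
#'
#' @inheritParams ivCurve
#' @param V_mV,K_mM grid vectors (mV, mM).
#' @return data.frame with one row per (V, K, cycle): `V_mV`, `K_mM`, `id`,
#'   `ccr`, `J`, `rel_contribution`, `g_pS`.
#' @export
cycleContributionSurface <- function(diagram, params,
                                     V_mV = seq(-100, 100, by = 20),
                                     K_mM = c(15, 50, 150, 300),
                                     consts = physConstants()) {
  grid <- expand.grid(V_mV = V_mV, K_mM = K_mM)
  grid <- grid[grid$V_mV != 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$V_mV[i]; k <- grid$K_mM[i]
    dec <- decomposeFlux(diagram, params,
                         permCondition(V_m = v / 1e3, K_in = k / 1e3,
                                       K_out = k / 1e3), consts)
    r <- dec@records[dec@records$conducting, ]
    data.frame(V_mV = v, K_mM = k, id = r$id, ccr = r$ccr, J = r$J,
               rel_contribution = r$rel_contribution,
               g_pS = .e_charge * r$n_ion * r$J / (v / 1e3) * 1e12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Michaelis-Menten fit of a conductance curve
#'
#' Least-squares fit of `g = g_max * K / (K + K_M)`. Optionally the maximum
#' is anchored to the measured conductance at the highest concentration
#' (the convention used for the saturating-concentration normalisation),
#' in which case only `K_M` is fitted.
#'
#' @param curve data.frame with columns `K_mM` and `g_pS` (3+ rows).
#' @param anchor_gmax logical; anchor `g_max` at the highest-concentration
#'   point instead of fitting it.
#' @return list with `g_max`, `K_M` (mM), `fitted`, `residuals`.
#' @export
fitMichaelisMenten <- function(curve, anchor_gmax = FALSE) {
  stopifnot(nrow(curve) >= 3, all(curve$K_mM > 0))
  K <- curve$K_mM; g <- curve$g_pS
  mm <- function(gmax, km) gmax * K / (K + km)
  if (anchor_gmax) {
    imax <- which.max(K)
    gmax0 <- g[imax] * (K[imax] + stats::median(K)) / K[imax]
    obj <- function(lkm) sum((g - mm(g[imax] * (K[imax] + exp(lkm)) /
                                       K[imax], exp(lkm)))^2)
    o <- stats::optimize(obj, c(log(1e-3), log(1e4)))
    km <- exp(o$minimum)
    gmax <- g[imax] * (K[imax] + km) / K[imax]
  } else {
    start <- c(log(max(g) * 1.2), log(stats::median(K)))
    obj <- function(th) sum((g - mm(exp(th[1]), exp(th[2])))^2)
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    gmax <- exp(o$par[1]); km <- exp(o$par[2])
  }
  fit <- mm(gmax, km)
  list(g_max = gmax, K_M = km, fitted = fit, residuals = g - fit)
}
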