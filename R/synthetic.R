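## Synthetic-data generators. Every generator is a pure function of
## (spec, seed): the RNG state is saved and restored, and a fixed seed
## reproduces the dataset bit for bit.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic output")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generator specification for synthetic experiments
#'
#' Collects the ground truth and the experimental design emulated by the
#' generators: symmetric K+ concentrations, voltage grid, osmotic-pulse
#' levels, per-observable Gaussian noise and replicate counts. Defaults
#' follow the study design: K+ in {15, 50, 150, 300} mM, voltages -100..100
#' mV, osmotic pulses of 0.5 / 1.0 / 1.5 Osm/kg, coupling-ratio noise on
#' the order of the printed standard errors (0.04-0.15) and 3-6 replicates.
#'
#' @param params truth [RateParameterSet-class].
#' @param diagram a [PermeationDiagram-class].
#' @param K_mM symmetric K+ concentrations (mM).
#' @param V_mV voltage grid for current-voltage data (mV).
#' @param delta_osm osmotic pulse levels (Osm/kg).
#' @param iv_sd_pA Gaussian SD of single-channel current points (pA).
#' @param cr_sd Gaussian SD of coupling-ratio points.
#' @param n_rep replicates per design point.
#' @param g_nS macroscopic patch conductance for ramp trains (nS).
#' @param ramp_noise_pA current noise SD on ramp traces (pA).
#' @param hyper_g_scale conductance scale-up during the hyper-osmotic
#'   phase (resistance drop in the cytoplasmic pore); must not bias V_rev.
#' @param consts from [physConstants()].
#' @return a generator spec (list).
#' @export
generatorSpec <- function(params = wtRateParameters(),
                          diagram = kir21Diagram(),
                          K_mM = c(15, 50, 150, 300),
                          V_mV = seq(-100, 100, by = 20),
                          delta_osm = c(0.5, 1.0, 1.5),
                          iv_sd_pA = 0.15, cr_sd = 0.08, n_rep = 4,
                          g_nS = 2, ramp_noise_pA = 0.5,
                          hyper_g_scale = 1.3,
                          consts = physConstants()) {
  stopifnot(iv_sd_pA >= 0, cr_sd >= 0, n_rep >= 1)
  list(params = params, diagram = diagram, K_mM = K_mM, V_mV = V_mV,
       delta_osm = delta_osm, iv_sd_pA = iv_sd_pA, cr_sd = cr_sd,
       n_rep = n_rep, g_nS = g_nS, ramp_noise_pA = ramp_noise_pA,
       hyper_g_scale = hyper_g_scale, consts = consts)
}

#' Synthetic current-voltage dataset
#'
#' Model-predicted single-channel currents over the spec's (K, V) design
#' with additive Gaussian noise, averaged over replicates. The generating
#' truth is stored alongside for recovery studies.
#'
#' @param spec from [generatorSpec()].
#' @param seed integer seed (mandatory).
#' @return a fit dataset: list with `iv` (data.frame `K_mM`, `V_mV`, `I_pA`,
#'   `se`), empty `cr`, and `truth`.
#' @export
makeIVDataset <- function(spec, seed) {
  grid <- expand.grid(V_mV = spec$V_mV, K_mM = spec$K_mM)
  mu <- vapply(seq_len(nrow(grid)), function(i)
    predictCurrent(spec$diagram, spec$params,
                   permCondition(V_m = grid$V_mV[i] / 1e3,
                                 K_in = grid$K_mM[i] / 1e3,
                                 K_out = grid$K_mM[i] / 1e3),
                   spec$consts), numeric(1))
  .with_seed(seed, {
    obs <- vapply(mu, function(m)
      mean(m + stats::rnorm(spec$n_rep, sd = spec$iv_sd_pA)), numeric(1))
    list(iv = data.frame(K_mM = grid$K_mM, V_mV = grid$V_mV, I_pA = obs,
                         se = rep(max(spec$iv_sd_pA, 1e-6) /
                                    sqrt(spec$n_rep), nrow(grid))),
         cr = data.frame(K_mM = numeric(), CR = numeric(), se = numeric()),
         truth = spec$params, seed = seed)
  })
}

#' Synthetic coupling-ratio dataset
#'
#' Model coupling ratios near the reversal potential at each K+ of the
#' design, with Gaussian noise, averaged over replicates.
#'
#' @inheritParams makeIVDataset
#' @param K_mM concentrations to include (defaults to the spec's, without
#'   the saturating 300 mM point where streaming measurements were not
#'   taken).
#' @return a fit dataset as in [makeIVDataset()] with the `cr` slot filled.
#' @export
makeCRDataset <- function(spec, seed, K_mM = setdiff(spec$K_mM, 300)) {
  mu <- vapply(K_mM, function(k)
    modelCouplingRatio(spec$diagram, spec$params, k, consts = spec$consts),
    numeric(1))
  .with_seed(seed, {
    obs <- vapply(mu, function(m)
      mean(m + stats::rnorm(spec$n_rep, sd = spec$cr_sd)), numeric(1))
    list(iv = data.frame(K_mM = numeric(), V_mV = numeric(),
                         I_pA = numeric(), se = numeric()),
         cr = data.frame(K_mM = K_mM, CR = obs,
                         se = rep(max(spec$cr_sd, 1e-6) / sqrt(spec$n_rep),
                                  length(K_mM))),
         truth = spec$params, seed = seed)
  })
}

#' Merge the iv and cr parts of two datasets
#' @param a,b fit datasets from the generators.
#' @return combined dataset.
#' @export
mergeDatasets <- function(a, b) {
  list(iv = rbind(a$iv, b$iv), cr = rbind(a$cr, b$cr),
       truth = a$truth, seed = c(a$seed, b$seed))
}

#' Synthetic osmotic-pulse ramp train
#'
#' Emulates the streaming-potential protocol: trains of +-20 mV voltage
#' ramps (1 mV/ms, a positive- then a negative-going branch per sweep)
#' recorded before, during and after an osmotic pulse (6 + 6 + 6 sweeps).
#' Iso-osmotic sweeps reverse at 0 mV; hyper-osmotic sweeps are shifted by
#' the streaming potential implied by the truth coupling ratio plus the
#' liquid junction potential of the matching solution pair, and their
#' conductance is scaled up by `hyper_g_scale`. Gaussian current noise is
#' added throughout.
#'
#' @inheritParams makeIVDataset
#' @param K_mM symmetric K+ concentration (mM).
#' @param delta_osm osmolality difference during the pulse (Osm/kg).
#' @param truth_CR coupling ratio used to generate the shift; defaults to
#'   the model value for the truth parameters at this K+.
#' @param junction junction table ([junctionTable()]) used to embed the
#'   electrode offset; `NULL` for none.
#' @param n_sweeps sweeps per phase.
#' @return a [RampTrain-class]; `meta` records the generating truth.
#' @export
makeRampTrain <- function(spec, seed, K_mM = 150, delta_osm = 1.0,
                          truth_CR = NULL, junction = junctionTable(),
                          n_sweeps = 6) {
  if (is.null(truth_CR))
    truth_CR <- modelCouplingRatio(spec$diagram, spec$params, K_mM,
                                   consts = spec$consts)
  vstream <- predictVstream(truth_CR, delta_osm, spec$consts)
  sorb <- delta_osm # sorbitol molarity ~ osmolality of the pulse
  jp <- if (is.null(junction)) 0 else
    .junction_lookup(junction, K_mM, sorb)
  phases <- rep(c("iso", "hyper", "recovery"), each = n_sweeps)
  dt <- 1e-3 # 1 kHz effective sampling at a 1 mV/ms ramp
  ramp_v <- c(seq(-20, 20, by = 1), seq(19, -19, by = -1))
  tt <- seq_along(ramp_v) * dt
  .with_seed(seed, {
    sweeps <- lapply(seq_along(phases), function(i) {
      hyper <- phases[i] == "hyper"
      vrev <- if (hyper) vstream + jp else 0
      g <- spec$g_nS * if (hyper) spec$hyper_g_scale else 1
      I <- g * (ramp_v - vrev) + # nS * mV = pA
        stats::rnorm(length(ramp_v), sd = spec$ramp_noise_pA)
      data.frame(time_s = tt + (i - 1) * (max(tt) + 0.1),
                 V_mV = ramp_v, I_pA = I)
    })
    methods::new("RampTrain", sweeps = sweeps,
                 schedule = data.frame(
                   sweep = seq_along(phases), phase = phases,
                   delta_osm = ifelse(phases == "hyper", delta_osm, 0)),
                 meta = list(K_mM = K_mM, sorbitol_M = sorb,
                             truth_CR = truth_CR,
                             truth_vstream_mV = vstream,
                             junction_mV = jp, seed = seed))
  })
}
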