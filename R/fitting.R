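#' Weighted fit objective
#'
#' Goodness-of-fit of a parameter set against a dataset of current-voltage
#' points and coupling-ratio points. Residuals are SE-normalised by default
#' and the coupling-ratio term is up-weighted by `weight`, because those
#' points are far fewer than the current points yet constrain the rate
#' constants strongly.
#'
#' @param params a [RateParameterSet-class].
#' @param dataset list with `iv` (`K_mM`, `V_mV`, `I_pA`, `se`) and `cr`
#'   (`K_mM`, `CR`, `se`) data.frames, e.g. from [makeIVDataset()].
#' @param diagram a [PermeationDiagram-class].
#' @param weight positive weight of the coupling-ratio sum of squares.
#' @param normalize divide residuals by their SE.
#' @param consts from [physConstants()].
#' @return scalar objective (non-negative).
#' @export
fitObjective <- function(params, dataset, diagram = kir21Diagram(),
                         weight = 1, normalize = TRUE,
                         consts = physConstants()) {
  stopifnot(weight > 0)
  r <- .fit_residuals(params, dataset, diagram, normalize, consts)
  sum(r$iv^2) + weight * sum(r$cr^2)
}

.fit_residuals <- function(params, dataset, diagram, normalize, consts) {
  iv <- dataset$iv; cr <- dataset$cr
  r_iv <- numeric(0)
  if (nrow(iv)) {
    pred <- vapply(seq_len(nrow(iv)), function(i)
      predictCurrent(diagram, params,
                     permCondition(V_m = iv$V_mV[i] / 1e3,
                                   K_in = iv$K_mM[i] / 1e3,
                                   K_out = iv$K_mM[i] / 1e3), consts),
      numeric(1))
    r_iv <- pred - iv$I_pA
    if (normalize) r_iv <- r_iv / iv$se
  }
  r_cr <- numeric(0)
  if (nrow(cr)) {
    pred <- vapply(cr$K_mM, function(k)
      modelCouplingRatio(diagram, params, k, consts = consts), numeric(1))
    r_cr <- pred - cr$CR
    if (normalize) r_cr <- r_cr / cr$se
  }
  list(iv = r_iv, cr = r_cr)
}

.gaussian_loglik <- function(sse, n) -n / 2 * log(sse / n)

#' Fit rate constants by repeated Nelder-Mead optimisation
#'
#' Optimises the free rate constants (in log space, keeping them positive)
#' against a dataset, restarting from seeded log-normal perturbations of
#' the starting point and sweeping the coupling-ratio weight. The best run
#' is selected by the SE-normalised combined residual (unweighted), and the
#' AIC is computed from the Gaussian log-likelihood surrogate
#' `lnL = -(n/2) log(SSE/n)` with `k` the number of free parameters.
#' Results are reproducible bit for bit given the seed.
#'
#' @param dataset as in [fitObjective()].
#' @param free character vector of free labels (`"k1"`..`"k10"`), e.g.
#'   `c("k1","k2","k5","k7","k8")` for the five-parameter mutant variant.
#' @param start starting [RateParameterSet-class] (the remaining rates stay
#'   fixed at these values).
#' @param diagram a [PermeationDiagram-class].
#' @param restarts number of optimisation starts per weight (the first is
#'   the unperturbed start).
#' @param weights numeric vector of coupling-ratio weights to sweep.
#' @param seed integer seed for the restart perturbations.
#' @param maxit Nelder-Mead iteration budget (0 returns the start point
#'   with its objective).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param perturb half-width of the log10-uniform restart perturbations.
#' @param consts from [physConstants()].
#' @return a [FitResult-class].
#' @export
fitRates <- function(dataset, free, start = wtRateParameters(),
                     diagram = kir21Diagram(), restarts = 20,
                     weights = c(1, 3, 10, 30, 100), seed = 1,
                     maxit = 5000, reltol = 1e-8, perturb = 0.5,
                     consts = physConstants()) {
  stopifnot(all(free %in% .k_labels))
  k0 <- start@k0
  make_params <- function(theta) {
    k <- k0; k[free] <- 10^theta
    rateParameterSet(k, free = free)
  }
  obj_w <- function(theta, w) {
    p <- tryCatch(make_params(theta), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    v <- tryCatch(fitObjective(p, dataset, diagram, weight = w,
                               normalize = TRUE, consts = consts),
                  error = function(e) 1e12)
    if (!is.finite(v)) 1e12 else v
  }
  theta0 <- log10(k0[free])
  runs <- list()
  .with_seed(seed, {
    starts <- c(list(theta0), lapply(seq_len(max(restarts - 1L, 0L)),
                                     function(i) theta0 +
                                       stats::runif(length(theta0),
                                                    -perturb, perturb)))
    for (w in weights) {
      for (th in starts) {
        if (maxit == 0L) {
          runs[[length(runs) + 1L]] <-
            list(theta = th, w = w, value = obj_w(th, w), conv = NA)
        } else {
          o <- stats::optim(th, obj_w, w = w, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = reltol))
          runs[[length(runs) + 1L]] <-
            list(theta = o$par, w = w, value = o$value, conv = o$convergence)
        }
      }
    }
  })
  ## select across weights/restarts by the unweighted normalised residual
  score <- vapply(runs, function(r)
    obj_w(r$theta, 1), numeric(1))
  best <- runs[[which.min(score)]]
  params <- make_params(best$theta)
  res <- .fit_residuals(params, dataset, diagram, TRUE, consts)
  sse <- sum(res$iv^2) + sum(res$cr^2)
  n <- length(res$iv) + length(res$cr)
  lnl <- .gaussian_loglik(max(sse, 1e-300), n)
  methods::new("FitResult", params = params,
               objective = best$value, weight = best$w,
               n_free = length(free), logLik = lnl,
               aic = 2 * length(free) - 2 * lnl,
               residuals = res,
               info = list(seed = seed, restarts = restarts,
                           weights = weights, convergence = best$conv,
                           n_points = n, sse = sse))
}

#' Select the best fit by AIC
#'
#' @param results list of [FitResult-class] objects fitted to the same
#'   dataset.
#' @return the result with minimum AIC; ties go to fewer free parameters.
#' @export
selectModel <- function(results) {
  stopifnot(length(results) >= 1)
  if (length(results) == 1L) return(results[[1L]])
  aic <- vapply(results, function(r) r@aic, numeric(1))
  k <- vapply(results, function(r) r@n_free, integer(1))
  results[[order(aic, k)[1L]]]
}

#' Qualitative wild-type versus mutant comparison
#'
#' Reports the direction of change of the wide-pore-site rate constants
#' between two fits (binding k1, release k2, pore-filter transfers k5, k7,
#' k8) and the rectification index `i(+100 mV) / |i(-100 mV)|` of each
#' parameter set at 150 mM symmetric K+. Changes smaller than
#' `min_change` (fractional) are reported as no claim ("~").
#'
#' @param fit_wt,fit_mut [FitResult-class] objects or
#'   [RateParameterSet-class] parameter sets.
#' @param diagram a [PermeationDiagram-class].
#' @param min_change minimal fractional change for a direction claim.
#' @param consts from [physConstants()].
#' @return list with `direction` (named character), `ratio` (mut/wt),
#'   `rectification` (named numeric for wt and mutant).
#' @export
qualitativeMutantCheck <- function(fit_wt, fit_mut,
                                   diagram = kir21Diagram(),
                                   min_change = 0.1,
                                   consts = physConstants()) {
  getp <- function(x) if (methods::is(x, "FitResult")) x@params else x
  pw <- getp(fit_wt); pm <- getp(fit_mut)
  labs <- c("k1", "k2", "k5", "k7", "k8")
  ratio <- pm@k0[labs] / pw@k0[labs]
  dir <- ifelse(ratio > 1 + min_change, "up",
                ifelse(ratio < 1 - min_change, "down", "~"))
  rect <- vapply(list(wt = pw, mut = pm), function(p) {
    ip <- predictCurrent(diagram, p, permCondition(V_m = 0.1), consts)
    im <- predictCurrent(diagram, p, permCondition(V_m = -0.1), consts)
    ip / abs(im)
  }, numeric(1))
  list(direction = dir, ratio = ratio, rectification = rect)
}
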