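## S4 classes for the permeation model and the experimental data reduction.

.sf_sites <- 4L

## the ten free rate-constant labels and their electrical distances;
## the z values are fixed properties of the model, not fitted
.k_labels <- paste0("k", 1:10)
.k_z <- c(k1 = 0, k2 = 0, k3 = 0.2, k4 = -0.2, k5 = 0.3,
          k6 = 0.2, k7 = 0.2, k8 = -0.2, k9 = 0.1, k10 = -0.1)

#' Eleven-state permeation diagram
#'
#' Holds the state list (selectivity-filter occupancy pattern plus wide-pore
#' flag) and the undirected transition table of the permeation model. Each
#' transition row carries both directed rate labels (or `"dep"` for a
#' direction computed from thermodynamic cyclic reversibility), electrical
#' distances, concentration dependence and the ion/water transfer
#' stoichiometry of the forward direction.
#'
#' @slot states data.frame with columns `index`, `sf`, `pore`.
#' @slot edges data.frame with columns `from`, `to`, `fwd`, `bwd`, `fwd_z`,
#'   `bwd_z`, `fwd_conc`, `bwd_conc`, `ion_out`, `water_out`, `ion_in`.
#' @slot cycleIds named character vector mapping canonical cycle keys to
#'   letter ids (may be empty until assigned).
#' @export
setClass("PermeationDiagram",
         representation(states = "data.frame", edges = "data.frame",
                        cycleIds = "character"))

#' Rate-constant parameter set
#'
#' The ten free rate constants of the permeation model, given at 0 mV.
#' Bimolecular binding rates (marked `"in"`/`"out"` in the diagram edge
#' table) are in 1/(s*M); all others in 1/s. Electrical distances are fixed
#' per label. The free mask records which rates a fit may vary.
#'
#' @slot k0 named numeric, rates at 0 mV for k1..k10.
#' @slot z named numeric, electrical distances for k1..k10.
#' @slot free named logical, free/fixed flag per label.
#' @export
setClass("RateParameterSet",
         representation(k0 = "numeric", z = "numeric", free = "logical"))

#' Cycle-flux decomposition at one condition
#'
#' Result of decomposing the steady-state net ion flux into simple-cycle
#' fluxes. `records` has one row per cycle: id, state sequence, net ions and
#' waters per completion, cyclic coupling ratio, net cycle flux J
#' (completions/s), the ion flux n_ion*J it carries and its relative
#' contribution to the total ion flux.
#'
#' @slot records data.frame of per-cycle results.
#' @slot condition list with `V_m`, `K_in`, `K_out`, `delta_osm`.
#' @slot J_total total net ion flux in ions/s (efflux positive).
#' @slot CR flux-weighted water:ion coupling ratio (NA when J_total == 0).
#' @export
setClass("CycleDecomposition",
         representation(records = "data.frame", condition = "list",
                        J_total = "numeric", CR = "numeric"))

#' Voltage-ramp train
#'
#' A set of current sweeps recorded (or synthesised) under a +-20 mV ramp
#' protocol with an osmotic-pulse schedule. Each sweep is a data.frame with
#' columns `time_s`, `V_mV`, `I_pA` containing a positive-going and a
#' negative-going ramp branch. The schedule marks each sweep as `iso`,
#' `hyper` or `recovery` and records the osmolality difference.
#'
#' @slot sweeps list of data.frames.
#' @slot schedule data.frame with columns `sweep`, `phase`, `delta_osm`.
#' @slot meta list (K in mM, truth values for synthetic trains, seed, ...).
#' @export
setClass("RampTrain",
         representation(sweeps = "list", schedule = "data.frame",
                        meta = "list"))

#' Streaming-potential reduction result
#'
#' @slot vrev data.frame of per-sweep reversal potentials (both branches).
#' @slot vstream data.frame with one row per osmotic pulse: raw and
#'   junction-corrected streaming potential in mV.
#' @slot slope regression slope in mV/(Osm/kg), with `slope_se`.
#' @slot CR water:ion coupling ratio converted from the slope.
#' @slot details list (junction potentials applied, recovery check, ...).
#' @export
setClass("VStreamResult",
         representation(vrev = "data.frame", vstream = "data.frame",
                        slope = "numeric", slope_se = "numeric",
                        CR = "numeric", details = "list"))

#' Rate-constant fit result
#'
#' @slot params fitted RateParameterSet.
#' @slot objective weighted objective value at the optimum.
#' @slot weight CR-term weight used by the winning run.
#' @slot n_free number of free parameters.
#' @slot logLik Gaussian log-likelihood surrogate.
#' @slot aic Akaike information criterion, 2k - 2 lnL.
#' @slot residuals list with per-dataset residual vectors.
#' @slot info list (seed, restarts, convergence, trace of weights).
#' @export
setClass("FitResult",
         representation(params = "RateParameterSet", objective = "numeric",
                        weight = "numeric", n_free = "integer",
                        logLik = "numeric", aic = "numeric",
                        residuals = "list", info = "list"))

setValidity("RateParameterSet", function(object) {
  msg <- character()
  if (!identical(sort(names(object@k0)), sort(.k_labels)))
    msg <- c(msg, "k0 must be named k1..k10")
  if (any(!is.finite(object@k0)) || any(object@k0 <= 0))
    msg <- c(msg, "all k0 must be finite and > 0")
  if (!identical(sort(names(object@z)), sort(.k_labels)))
    msg <- c(msg, "z must be named k1..k10")
  if (!identical(sort(names(object@free)), sort(.k_labels)))
    msg <- c(msg, "free mask must be named k1..k10")
  if (length(msg)) msg else TRUE
})

setValidity("PermeationDiagram", function(object) {
  st <- object@states; ed <- object@edges
  msg <- character()
  if (anyDuplicated(st$index)) msg <- c(msg, "state indices must be unique")
  bad <- !vapply(st$sf, .sf_valid, logical(1))
  if (any(bad))
    msg <- c(msg, paste0("invalid selectivity-filter pattern: ",
                         paste(st$sf[bad], collapse = ", ")))
  key <- paste(st$sf, as.integer(st$pore))
  if (anyDuplicated(key)) msg <- c(msg, "duplicated occupancy states")
  if (!all(ed$from %in% st$index) || !all(ed$to %in% st$index))
    msg <- c(msg, "edge endpoints must be state indices")
  if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
  ek <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  if (anyDuplicated(ek)) msg <- c(msg, "duplicated transitions")
  if (any(ed$fwd == "dep"))
    msg <- c(msg, "the forward direction must carry a rate label")
  known <- c(.k_labels, "dep")
  if (!all(ed$fwd %in% .k_labels) || !all(ed$bwd %in% known))
    msg <- c(msg, "unknown rate label in edge table")
  ## labelled z must match the canonical per-label electrical distance
  lab_f <- ed$fwd %in% .k_labels
  if (any(abs(ed$fwd_z[lab_f] - .k_z[ed$fwd[lab_f]]) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "fwd_z inconsistent with label electrical distances")
  lab_b <- ed$bwd %in% .k_labels
  if (any(abs(ed$bwd_z[lab_b] - .k_z[ed$bwd[lab_b]]) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "bwd_z inconsistent with label electrical distances")
  ## dependent directions must leave a spanning tree of labelled transitions
  dep <- ed$bwd == "dep"
  if (any(dep)) {
    tree <- ed[!dep, , drop = FALSE]
    if (nrow(tree) != nrow(st) - 1L ||
        !.is_spanning_tree(st$index, tree$from, tree$to))
      msg <- c(msg, paste("dependent directions must be the chords of a",
                          "spanning tree (one per independent loop)"))
  }
  if (length(msg)) msg else TRUE
})

.sf_valid <- function(sf) {
  s <- strsplit(sf, "-", fixed = TRUE)[[1]]
  length(s) == .sf_sites && all(s %in% c("i", "w")) &&
    any(s == "i") && !any(s[-length(s)] == "i" & s[-1] == "i")
}

.is_spanning_tree <- function(vertices, from, to) {
  comp <- seq_along(vertices)
  names(comp) <- as.character(vertices)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_along(from)) {
    a <- find(match(from[i], vertices)); b <- find(match(to[i], vertices))
    if (a == b) return(FALSE)
    comp[a] <- b
  }
  length(unique(vapply(seq_along(vertices), find, numeric(1)))) == 1L
}

setMethod("show", "PermeationDiagram", function(object) {
  cat("PermeationDiagram:", nrow(object@states), "states,",
      nrow(object@edges), "transitions (",
      2L * nrow(object@edges), "directed rates ),",
      sum(object@edges$bwd == "dep"), "detailed-balance-dependent rates\n")
  occ <- vapply(strsplit(object@states$sf, "-"), function(s) sum(s == "i"),
                numeric(1))
  cat("  SF ion occupancy:", paste(occ, collapse = " "),
      "| wide pore:", paste(as.integer(object@states$pore), collapse = " "),
      "\n")
})

setMethod("show", "RateParameterSet", function(object) {
  cat("RateParameterSet (0 mV values):\n")
  df <- data.frame(k0 = signif(object@k0[.k_labels], 4),
                   z = object@z[.k_labels],
                   free = object@free[.k_labels])
  print(df)
})

setMethod("show", "CycleDecomposition", function(object) {
  cnd <- object@condition
  cat(sprintf("CycleDecomposition at V_m = %g mV, K_in/K_out = %g/%g mM\n",
              cnd$V_m * 1e3, cnd$K_in * 1e3, cnd$K_out * 1e3))
  cat(sprintf("  J_total = %.4g ions/s, CR_w-i = %s\n", object@J_total,
              ifelse(is.na(object@CR), "undefined (equilibrium)",
                     sprintf("%.3f", object@CR))))
  r <- object@records
  top <- head(r[order(-abs(r$ion_flux)), ], 5)
  cat("  top cycles by |ion flux|:\n")
  print(top[, c("id", "sequence", "n_ion", "n_water", "ccr", "J",
                "rel_contribution")], row.names = FALSE)
})

setMethod("show", "VStreamResult", function(object) {
  cat(sprintf("VStreamResult: slope %.3f +- %.3f mV/(Osm/kg), CR_w-i = %.3f\n",
              object@slope, object@slope_se, object@CR))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d free parameters, objective %.4g, AIC %.3f\n",
              object@n_free, object@objective, object@aic))
})

setMethod("show", "RampTrain", function(object) {
  ph <- table(object@schedule$phase)
  cat("RampTrain:", length(object@sweeps), "sweeps (",
      paste(names(ph), as.integer(ph), collapse = ", "), ")\n")
})
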