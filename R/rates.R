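#' Construct a rate-constant parameter set
#'
#' @param k0 named numeric vector of 0-mV rate constants for k1..k10.
#'   Binding rates (k1; and the extracellular binding directions k4) are
#'   bimolecular and given in 1/(s*M); the rest in 1/s.
#' @param free named logical vector or character vector of free labels;
#'   defaults to all ten free.
#' @return a [RateParameterSet-class].
#' @examples
#' p <- rateParameterSet(c(k1 = 2e8, k2 = 4e7, k3 = 5e7, k4 = 4e8, k5 = 2e7,
#'                         k6 = 1e7, k7 = 8e7, k8 = 2e7, k9 = 1e8, k10 = 5e7))
#' rateAtVoltage(p, "k3", V_m = -0.1)
#' @export
rateParameterSet <- function(k0, free = .k_labels) {
  if (is.character(free)) {
    stopifnot(all(free %in% .k_labels))
    free <- stats::setNames(.k_labels %in% free, .k_labels)
  }
  methods::new("RateParameterSet", k0 = k0[.k_labels], z = .k_z,
               free = free[.k_labels])
}

#' @rdname rateParameterSet
#' @param object a RateParameterSet.
#' @export
freeParameters <- function(object) names(which(object@free))

#' Evaluate a rate constant at a membrane potential
#'
#' Rates follow the single-barrier Eyring form
#' `k(V) = k0 * exp(z * z_ion * F * V_m / (R * T))`, with `z` the electrical
#' distance of the transition. Transitions outside the membrane electric
#' field (the wide-pore binding/release steps k1, k2) have `z = 0` and are
#' voltage independent. The sign convention is physiological: `V_m` is
#' intracellular minus extracellular.
#'
#' @param params a [RateParameterSet-class].
#' @param label one of `"k1"`..`"k10"`.
#' @param V_m membrane potential in volts.
#' @param consts constants from [physConstants()].
#' @return the rate at `V_m` (same units as `k0[label]`).
#' @export
rateAtVoltage <- function(params, label, V_m, consts = physConstants()) {
  if (!label %in% names(params@k0)) stop("unknown rate label: ", label)
  params@k0[[label]] *
    exp(params@z[[label]] * consts$z_ion * consts$F * V_m /
          (consts$R * consts$T))
}

#' Experimental condition
#'
#' @param V_m membrane potential in volts (intracellular minus
#'   extracellular).
#' @param K_in,K_out intracellular / extracellular K+ in mol/L.
#' @param delta_osm osmolality difference Osm_out - Osm_in in osmol/kg.
#' @return a condition list.
#' @export
permCondition <- function(V_m = 0, K_in = 0.15, K_out = 0.15,
                          delta_osm = 0) {
  stopifnot(K_in > 0, K_out > 0)
  list(V_m = V_m, K_in = K_in, K_out = K_out, delta_osm = delta_osm)
}

#' Transition-rate matrix at a condition
#'
#' Evaluates all 34 directed rates of the diagram at a condition: labelled
#' rates get the Eyring voltage factor and, for bimolecular directions, the
#' corresponding K+ concentration; the seven dependent directions (one per
#' independent loop, e.g. the rate from state 3 to state 2) are computed
#' from generalized detailed balance around their fundamental loop, so that
#' the product of rates around every cycle satisfies
#' `prod(forward)/prod(backward) = exp(n_ion * (z*F*V + RT*log(K_in/K_out)) / RT)`,
#' i.e. the only thermodynamic driving force is the K+ electrochemical
#' potential difference. This holds for all 59 cycles by cycle-space
#' linearity.
#'
#' @param diagram a [PermeationDiagram-class].
#' @param params a [RateParameterSet-class].
#' @param condition from [permCondition()].
#' @param consts from [physConstants()].
#' @return list with `K` (n x n matrix of rates, `K[i, j]` = rate i -> j)
#'   and `edges` (the 34-row directed edge table with a `rate` column).
#' @export
rateMatrix <- function(diagram, params, condition,
                       consts = physConstants()) {
  comp <- .compiled(diagram)
  r <- .rates_vector(comp, params@k0, condition, consts)
  K <- matrix(0, comp$n, comp$n)
  K[comp$K_index] <- r
  edges <- comp$de
  edges$rate <- r
  list(K = K, edges = edges)
}

## fast evaluation of the 34 directed rates; labelled rates get the Eyring
## voltage factor and concentration scaling, dependent chords close their
## fundamental loop by generalized detailed balance
.rates_vector <- function(comp, k0, condition, consts) {
  vf <- consts$z_ion * consts$F / (consts$R * consts$T)
  concv <- c(1, condition$K_in, condition$K_out)
  r <- numeric(length(comp$lab))
  li <- comp$lab
  r[li] <- k0[comp$label_idx[li]] *
    exp(comp$z_vec[li] * vf * condition$V_m) * concv[comp$conc_code[li]]
  for (d in comp$deps) {
    drive <- exp(d$n_ion * vf * condition$V_m) *
      (condition$K_in / condition$K_out)^d$n_ion
    r[d$row] <- prod(r[d$fwd]) / (drive * prod(r[d$bwd]))
  }
  r
}

## BFS paths along the spanning tree of fully-labelled transitions;
## returns list keyed "from to" for each chord's (to -> from) closure
.tree_paths <- function(diagram) {
  e <- diagram@edges
  tree <- e[e$bwd != "dep", c("from", "to")]
  chords <- e[e$bwd == "dep", c("from", "to")]
  verts <- diagram@states$index
  adj <- lapply(verts, function(v)
    c(tree$to[tree$from == v], tree$from[tree$to == v]))
  names(adj) <- as.character(verts)
  bfs_path <- function(s, t) {
    prev <- stats::setNames(rep(NA_integer_, length(verts)),
                            as.character(verts))
    seen <- s; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == t) break
      for (u in adj[[as.character(v)]]) if (!(u %in% seen)) {
        seen <- c(seen, u); prev[as.character(u)] <- v
        queue <- c(queue, u)
      }
    }
    path <- t
    while (path[1] != s) path <- c(prev[[as.character(path[1])]], path)
    path
  }
  out <- list()
  for (i in seq_len(nrow(chords)))
    out[[paste(chords$to[i], chords$from[i])]] <-
      bfs_path(chords$to[i], chords$from[i])
  out
}
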