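#' Liquid junction potential table
#'
#' Junction potentials (mV) of the 3 M KCl reference electrode between the
#' normal- and hyper-osmotic solutions, by K+ concentration and sorbitol
#' molarity. The defaults are the measured values used for correcting raw
#' streaming potentials.
#'
#' @return data.frame with columns `K_mM`, `sorbitol_M`, `junction_mV`,
#'   `se_mV`.
#' @export
junctionTable <- function() {
  data.frame(
    K_mM = rep(c(15, 50, 150), each = 3),
    sorbitol_M = rep(c(0.5, 1.0, 1.5), times = 3),
    junction_mV = c(-0.22, -0.14, -0.03,
                    -0.06, -0.12, 0.13,
                    -0.12, -0.22, -0.17),
    se_mV = c(0.199, 0.084, 0.038,
              0.022, 0.028, 0.054,
              0.012, 0.043, 0.057))
}

.junction_lookup <- function(junction, K_mM, sorbitol_M) {
  hit <- junction$K_mM == K_mM &
    abs(junction$sorbitol_M - sorbitol_M) < 1e-9
  if (!any(hit)) return(0)
  junction$junction_mV[which(hit)[1]]
}

#' Extract reversal potentials from one ramp sweep
#'
#' Finds the zero-current crossing separately on the positive-going and the
#' negative-going ramp branch by linear interpolation between the two
#' samples bracketing the sign change (no smoothing). Flags the sweep when
#' the two branches disagree by more than 0.5 mV.
#'
#' @param sweep data.frame with columns `time_s`, `V_mV`, `I_pA`.
#' @return list with `V_rev_positive`, `V_rev_negative`, `V_rev` (their
#'   mean) and `flagged`.
#' @export
extractVrev <- function(sweep) {
  dv <- diff(sweep$V_mV)
  branch <- c(ifelse(dv >= 0, "pos", "neg"), NA)
  branch[length(branch)] <- branch[length(branch) - 1L]
  cross <- function(idx) {
    v <- sweep$V_mV[idx]; i <- sweep$I_pA[idx]
    s <- which(i[-length(i)] * i[-1] <= 0 & i[-length(i)] != i[-1])
    if (!length(s)) stop("no zero crossing within the ramp span")
    ## crossing nearest the middle of the branch is the least noise-prone
    s <- s[which.min(abs(s - length(i) / 2))]
    v[s] + (0 - i[s]) * (v[s + 1] - v[s]) / (i[s + 1] - i[s])
  }
  vp <- cross(which(branch == "pos"))
  vn <- cross(which(branch == "neg"))
  list(V_rev_positive = vp, V_rev_negative = vn,
       V_rev = mean(c(vp, vn)), flagged = abs(vp - vn) > 0.5)
}

#' Streaming potential from a ramp train
#'
#' Reduces a ramp train with an iso / hyper / recovery osmolality schedule:
#' per-sweep reversal potentials are extracted with [extractVrev()], the
#' streaming potential is the difference between the mean reversal
#' potential of the hyper-osmotic sweeps and that of the immediately
#' preceding iso-osmotic sweeps, and the liquid junction potential of the
#' matching K+/sorbitol pair is subtracted. Recovery of the baseline after
#' the pulse is checked against a noise-scaled tolerance.
#'
#' @param train a [RampTrain-class].
#' @param junction junction-potential table as from [junctionTable()];
#'   pass `NULL` to skip the correction.
#' @param recovery_tol_mV tolerance for the baseline recovery check (mV).
#' @return a [VStreamResult-class] (slope slots are NA; see
#'   [regressVstream()]).
#' @export
computeVstream <- function(train, junction = junctionTable(),
                           recovery_tol_mV = 0.5) {
  sch <- train@schedule
  stopifnot(all(c("iso", "hyper") %in% sch$phase))
  vr <- do.call(rbind, lapply(seq_along(train@sweeps), function(i) {
    z <- extractVrev(train@sweeps[[i]])
    data.frame(sweep = i, phase = sch$phase[i], delta_osm = sch$delta_osm[i],
               V_rev_positive = z$V_rev_positive,
               V_rev_negative = z$V_rev_negative, V_rev = z$V_rev,
               flagged = z$flagged)
  }))
  iso_pre <- vr$phase == "iso"
  hyper <- vr$phase == "hyper"
  d_osm <- unique(vr$delta_osm[hyper])
  stopifnot(length(d_osm) == 1L)
  raw <- mean(vr$V_rev[hyper]) - mean(vr$V_rev[iso_pre])
  sorb <- train@meta$sorbitol_M
  jp <- if (is.null(junction) || is.null(sorb)) 0 else
    .junction_lookup(junction, train@meta$K_mM, sorb)
  corrected <- raw - jp
  recovered <- NA
  if (any(vr$phase == "recovery"))
    recovered <- abs(mean(vr$V_rev[vr$phase == "recovery"]) -
                       mean(vr$V_rev[iso_pre])) <= recovery_tol_mV
  vs <- data.frame(delta_osm = d_osm, V_stream_raw = raw,
                   V_stream = corrected, junction_mV = jp)
  methods::new("VStreamResult", vrev = vr, vstream = vs,
               slope = NA_real_, slope_se = NA_real_, CR = NA_real_,
               details = list(recovered = recovered,
                              K_mM = train@meta$K_mM))
}

#' Regress streaming potentials against the osmotic gradient
#'
#' Ordinary least squares of V_stream on the osmolality difference across
#' two or more levels (replicates allowed), with a fitted intercept. The
#' slope (mV per Osm/kg) is converted to the water:ion coupling ratio with
#' [slopeToCR()].
#'
#' @param results list of [VStreamResult-class] objects (one per pulse), or
#'   a data.frame with columns `delta_osm` and `V_stream`.
#' @param consts from [physConstants()].
#' @return a [VStreamResult-class] with `slope`, `slope_se` and `CR` set.
#' @export
regressVstream <- function(results, consts = physConstants()) {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      r@vstream[, c("delta_osm", "V_stream")]))
  if (length(unique(df$delta_osm)) < 2L)
    stop("slope not identifiable from a single osmolality level")
  fit <- stats::lm(V_stream ~ delta_osm, data = df)
  slope <- unname(stats::coef(fit)["delta_osm"])
  ## exact synthetic data gives a perfect fit; the SE is then simply zero
  se <- suppressWarnings(
    summary(fit)$coefficients["delta_osm", "Std. Error"])
  vr <- if (is.data.frame(results)) data.frame() else
    do.call(rbind, lapply(results, function(r) r@vrev))
  methods::new("VStreamResult", vrev = vr, vstream = df,
               slope = slope, slope_se = se,
               CR = slopeToCR(slope, consts),
               details = list(fit = fit))
}

#' Compare streaming-potential slopes between two channels
#'
#' Analysis of covariance: tests the equality of the V_stream-vs-osmolality
#' regression slopes of two groups via the group-by-osmolality interaction
#' term.
#'
#' @param a,b data.frames (or [VStreamResult-class] lists) with columns
#'   `delta_osm`, `V_stream` for each group.
#' @return list with `F`, `df`, `p_value` and the fitted models.
#' @export
compareSlopes <- function(a, b) {
  as_df <- function(x, g) {
    df <- if (is.data.frame(x)) x else
      do.call(rbind, lapply(x, function(r)
        r@vstream[, c("delta_osm", "V_stream")]))
    df$group <- g
    df
  }
  df <- rbind(as_df(a, "A"), as_df(b, "B"))
  if (length(unique(df$delta_osm)) < 2L)
    stop("slope not identifiable from a single osmolality level")
  full <- stats::lm(V_stream ~ delta_osm * group, data = df)
  red <- stats::lm(V_stream ~ delta_osm + group, data = df)
  an <- stats::anova(red, full)
  ## guard the degenerate case of an exactly-zero interaction sum of squares
  ss <- max(an$`Sum of Sq`[2], 0)
  df2 <- an$Res.Df[2]
  Fstat <- if (an$RSS[2] > 0) ss / an$Df[2] / (an$RSS[2] / df2) else 0
  list(F = Fstat, df = c(an$Df[2], df2),
       p_value = stats::pf(Fstat, an$Df[2], df2, lower.tail = FALSE),
       full = full, reduced = red)
}
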