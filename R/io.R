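## Text I/O: CSV for curves and datasets, JSON for parameters, schedules
## and reports.

#' Read / write rate parameters as JSON
#'
#' @param params a [RateParameterSet-class].
#' @param path file path.
#' @return `readParameters()` returns a [RateParameterSet-class].
#' @export
writeParameters <- function(params, path) {
  jsonlite::write_json(list(k0 = as.list(params@k0),
                            z = as.list(params@z),
                            free = as.list(params@free)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParameters
#' @export
readParameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rateParameterSet(unlist(x$k0),
                   free = stats::setNames(unlist(x$free), names(x$free)))
}

#' Read / write a fit dataset as CSV files
#'
#' Writes `<stem>_iv.csv` and `<stem>_cr.csv`.
#'
#' @param dataset list with `iv` and `cr` data.frames.
#' @param stem path stem.
#' @return `readFitDataset()` returns the dataset list.
#' @export
writeFitDataset <- function(dataset, stem) {
  utils::write.csv(dataset$iv, paste0(stem, "_iv.csv"), row.names = FALSE)
  utils::write.csv(dataset$cr, paste0(stem, "_cr.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname writeFitDataset
#' @export
readFitDataset <- function(stem) {
  list(iv = utils::read.csv(paste0(stem, "_iv.csv")),
       cr = utils::read.csv(paste0(stem, "_cr.csv")))
}

#' Read / write a ramp train
#'
#' One CSV per sweep (`time_s`, `V_mV`, `I_pA`) plus a JSON sidecar holding
#' the osmolality schedule and metadata.
#'
#' @param train a [RampTrain-class].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return `readRampTrain()` returns a [RampTrain-class].
#' @export
writeRampTrain <- function(train, dir, stem = "sweep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(train@sweeps))
    utils::write.csv(train@sweeps[[i]],
                     file.path(dir, sprintf("%s_%03d.csv", stem, i)),
                     row.names = FALSE)
  jsonlite::write_json(list(schedule = train@schedule, meta = train@meta),
                       file.path(dir, paste0(stem, "_schedule.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeRampTrain
#' @export
readRampTrain <- function(dir, stem = "sweep") {
  side <- jsonlite::read_json(file.path(dir, paste0(stem, "_schedule.json")),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = paste0("^", stem, "_\\d+\\.csv$"),
                           full.names = TRUE))
  methods::new("RampTrain",
               sweeps = lapply(files, utils::read.csv),
               schedule = as.data.frame(side$schedule),
               meta = as.list(side$meta))
}

#' Export a cycle decomposition as tabular text
#'
#' One row per cycle: id, state sequence, stoichiometry, coupling ratio,
#' net flux and relative contribution.
#'
#' @param decomp a [CycleDecomposition-class].
#' @param path file path (tab-separated).
#' @export
writeDecomposition <- function(decomp, path) {
  utils::write.table(decomp@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
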