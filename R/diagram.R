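#' Enumerate admissible selectivity-filter configurations
#'
#' Brute-force enumeration of the occupancy patterns of the four filter
#' sites S1..S4 (extracellular to intracellular), each holding an ion or a
#' water. Electrostatic repulsion forbids ions on adjacent sites, and the
#' ion-empty filter is excluded. Exactly seven patterns remain.
#'
#' @return character vector of patterns such as `"i-w-i-w"`.
#' @examples
#' length(sfConfigurations()) # 7
#' @export
sfConfigurations <- function() {
  grid <- expand.grid(rep(list(c("i", "w")), .sf_sites),
                      stringsAsFactors = FALSE)
  pat <- apply(grid, 1, paste, collapse = "-")
  pat[vapply(pat, .sf_valid, logical(1))]
}

#' Build a permeation diagram from a topology description
#'
#' Constructs and validates a [PermeationDiagram-class] from a states table
#' and an undirected transition table (the same columnar layout as the
#' shipped model file, see [readDiagramModel()]). Validation rejects
#' inadmissible filter patterns (adjacent ions, ion-empty filter), duplicate
#' states or transitions, missing reverse directions, unknown rate labels,
#' and dependent-rate markings that do not correspond to one chord per
#' independent loop, which would leave some loop without a thermodynamic
#' reversibility constraint (or doubly constrain another).
#'
#' @param states data.frame with columns `index`, `sf`, `pore`.
#' @param edges data.frame with columns `from`, `to`, `fwd`, `bwd`, `fwd_z`,
#'   `bwd_z`, `fwd_conc`, `bwd_conc`, `ion_out`, `water_out`, `ion_in`.
#' @param cycle_ids optional named character vector of cycle letter ids
#'   keyed by canonical cycle key (assigned automatically for the shipped
#'   wild-type topology).
#' @return a validated [PermeationDiagram-class].
#' @seealso [kir21Diagram()] for the shipped Kir2.1 topology.
#' @export
buildDiagram <- function(states, edges, cycle_ids = character()) {
  states$index <- as.integer(states$index)
  states$pore <- as.logical(as.integer(states$pore))
  states <- states[order(states$index), ]
  for (cl in c("from", "to")) edges[[cl]] <- as.integer(edges[[cl]])
  methods::new("PermeationDiagram", states = states, edges = edges,
               cycleIds = cycle_ids)
}

#' Read / write a diagram model file
#'
#' The model topology is shipped as a declarative, human-readable text file
#' with `[states]`, `[edges]` and `[checksum]` sections so the transcription
#' of the permeation diagram can be audited line by line. The reader
#' validates the diagram and verifies the structural checksum (state,
#' transition, directed-rate and simple-cycle counts); the writer emits the
#' same format, so read/write round-trips exactly.
#'
#' @param path file path. `readDiagramModel()` defaults to the model file
#'   installed with the package.
#' @return `readDiagramModel()` returns a [PermeationDiagram-class];
#'   `writeDiagramModel()` returns `path` invisibly.
#' @export
readDiagramModel <- function(path = system.file("extdata",
                                                "kir21_diagram.txt",
                                                package = "kirflux")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sec <- cumsum(grepl("^\\[", lines))
  name <- sub("^\\[(.*)\\]$", "\\1", lines[grepl("^\\[", lines)])
  blocks <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(blocks) <- name
  parse_block <- function(b)
    utils::read.table(text = paste(b, collapse = "\n"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  states <- parse_block(blocks[["states"]])
  edges <- parse_block(blocks[["edges"]])
  dia <- buildDiagram(states, edges)
  if (!is.null(blocks[["checksum"]])) {
    chk <- parse_block(c("what\tvalue", blocks[["checksum"]]))
    want <- stats::setNames(chk$value, chk$what)
    got <- c(states = nrow(dia@states), transitions = nrow(dia@edges),
             directed_rates = 2L * nrow(dia@edges),
             simple_cycles = nrow(enumerateCycles(dia)))
    bad <- names(want)[want != got[names(want)]]
    if (length(bad))
      stop("model file checksum mismatch for: ", paste(bad, collapse = ", "))
  }
  dia
}

#' @rdname readDiagramModel
#' @param diagram a [PermeationDiagram-class].
#' @export
writeDiagramModel <- function(diagram, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# permeation diagram model file", con)
  writeLines("[states]", con)
  st <- diagram@states
  st$pore <- as.integer(st$pore)
  utils::write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("[edges]", con)
  utils::write.table(diagram@edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("[checksum]", con)
  writeLines(paste(c("states", "transitions", "directed_rates",
                     "simple_cycles"),
                   c(nrow(st), nrow(diagram@edges), 2L * nrow(diagram@edges),
                     nrow(enumerateCycles(diagram))), sep = "\t"), con)
  invisible(path)
}

#' The Kir2.1 eleven-state permeation diagram
#'
#' Loads the wild-type topology: the seven admissible selectivity-filter
#' configurations combined with the wide-pore K+ site occupancy, pruned of
#' the three pore-bound states whose filter holds an ion at the innermost
#' site S4 (adjacent to the wide pore), leaving eleven states joined by 17
#' transitions (34 directed rate constants). Cycle letter ids are assigned
#' by descending ion-flux magnitude under the reference condition of the
#' shipped wild-type parameters (150 mM symmetric K+, -100 mV).
#'
#' @return a [PermeationDiagram-class].
#' @examples
#' d <- kir21Diagram()
#' validateStructure(d)
#' @export
kir21Diagram <- function() {
  dia <- readDiagramModel()
  dia@cycleIds <- .kir21_cycle_ids(dia)
  dia
}

#' Structural validation report
#'
#' Counts states, directed rates, undirected transitions and simple cycles
#' of a diagram, and (for the eleven-state Kir2.1 topology) raises an error
#' naming the failing invariant when a count deviates from the expected
#' {11, 34, 17, 59}.
#'
#' @param diagram a [PermeationDiagram-class].
#' @param expected named numeric vector of expected counts, or `NULL` to
#'   skip checking (counts are then just reported).
#' @return named list of counts, invisibly a list; raises on mismatch.
#' @export
validateStructure <- function(diagram,
                              expected = c(states = 11, directed_rates = 34,
                                           undirected_transitions = 17,
                                           simple_cycles = 59)) {
  counts <- list(states = nrow(diagram@states),
                 directed_rates = 2L * nrow(diagram@edges),
                 undirected_transitions = nrow(diagram@edges),
                 simple_cycles = nrow(enumerateCycles(diagram)))
  if (!is.null(expected)) {
    for (nm in names(expected)) {
      if (counts[[nm]] != expected[[nm]])
        stop(sprintf("structural invariant violated: %s is %d, expected %d",
                     nm, counts[[nm]], as.integer(expected[[nm]])))
    }
  }
  counts
}

## directed edge table: 34 rows with per-direction label, z (NA when the
## direction is detailed-balance dependent), concentration dependence and
## signed transfer stoichiometry
.directed_edges <- function(diagram) {
  e <- diagram@edges
  fwd <- data.frame(from = e$from, to = e$to, label = e$fwd, z = e$fwd_z,
                    conc = e$fwd_conc, ion_out = e$ion_out,
                    water_out = e$water_out, ion_in = e$ion_in,
                    pair = seq_len(nrow(e)), stringsAsFactors = FALSE)
  bwd <- data.frame(from = e$to, to = e$from, label = e$bwd, z = e$bwd_z,
                    conc = e$bwd_conc, ion_out = -e$ion_out,
                    water_out = -e$water_out, ion_in = -e$ion_in,
                    pair = seq_len(nrow(e)), stringsAsFactors = FALSE)
  rbind(fwd, bwd)
}
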