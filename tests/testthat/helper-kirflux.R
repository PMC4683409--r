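## shared fixtures: the diagram is loaded once per test run

kf_diagram <- kir21Diagram()
kf_labels <- paste0("k", 1:10)

## a three-state single-loop toy diagram; five rates free, the sixth
## (reverse of the k5 edge) closed by detailed balance
toy_triangle <- function(k = c(k1 = 120, k2 = 35, k3 = 80, k4 = 15,
                               k5 = 60)) {
  states <- data.frame(index = 1:3,
                       sf = c("i-w-i-w", "w-i-w-i", "w-w-i-w"),
                       pore = c(0, 0, 0))
  edges <- data.frame(
    from = c(1, 2, 3), to = c(2, 3, 1),
    fwd = c("k1", "k3", "k5"), bwd = c("k2", "k4", "dep"),
    fwd_z = c(0, 0.2, 0.3), bwd_z = c(0, -0.2, NA),
    fwd_conc = "none", bwd_conc = "none",
    ion_out = c(0, 1, 0), water_out = c(0, 0, 1), ion_in = c(1, 0, 0))
  k0 <- c(k, k6 = 1, k7 = 1, k8 = 1, k9 = 1, k10 = 1)
  list(diagram = buildDiagram(states, edges),
       params = rateParameterSet(k0))
}

## random positive parameter set (log-uniform over two decades around the
## wild-type values)
random_params <- function(base = wtRateParameters()) {
  k <- base@k0 * 10^stats::runif(10, -1, 1)
  rateParameterSet(k)
}

## random small single-file-like diagram: a random spanning tree plus up to
## two chords, random labels and random transfer stoichiometry
random_small_diagram <- function(n_states = 5, n_chords = 2) {
  sf_pool <- sfConfigurations()
  combos <- expand.grid(sf = sf_pool, pore = c(0, 1),
                        stringsAsFactors = FALSE)
  pick <- combos[sample(nrow(combos), n_states), ]
  states <- data.frame(index = seq_len(n_states), sf = pick$sf,
                       pore = pick$pore)
  ## random tree
  from <- to <- integer(0)
  for (v in 2:n_states) { from <- c(from, sample(v - 1L, 1)); to <- c(to, v) }
  ## chords between non-adjacent pairs
  have <- paste(pmin(from, to), pmax(from, to))
  all_pairs <- t(utils::combn(n_states, 2))
  free_pairs <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have),
                          , drop = FALSE]
  n_chords <- min(n_chords, nrow(free_pairs))
  ch <- free_pairs[sample(nrow(free_pairs), n_chords), , drop = FALSE]
  n_tree <- length(from)
  from <- c(from, ch[, 1]); to <- c(to, ch[, 2])
  m <- length(from)
  lab <- sample(kf_labels, m, replace = TRUE)
  rev_lab <- sample(kf_labels, m, replace = TRUE)
  z <- c(k1 = 0, k2 = 0, k3 = 0.2, k4 = -0.2, k5 = 0.3,
         k6 = 0.2, k7 = 0.2, k8 = -0.2, k9 = 0.1, k10 = -0.1)
  edges <- data.frame(
    from = from, to = to, fwd = lab,
    bwd = c(rev_lab[seq_len(n_tree)], rep("dep", m - n_tree)),
    fwd_z = unname(z[lab]),
    bwd_z = c(unname(z[rev_lab[seq_len(n_tree)]]), rep(NA, m - n_tree)),
    fwd_conc = sample(c("none", "in", "out"), m, replace = TRUE),
    bwd_conc = sample(c("none", "in", "out"), m, replace = TRUE),
    ion_out = sample(-1:1, m, replace = TRUE),
    water_out = sample(-1:1, m, replace = TRUE),
    ion_in = sample(-1:1, m, replace = TRUE))
  buildDiagram(states, edges)
}
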