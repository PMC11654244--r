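# shared small fixtures, all generated in code

# a tiny paired screen: 8x12 plate, known lethals
tiny_screen <- function(seed = 42, ...) {
  sim_plate_pair(n_strains = 96, layout = c(8, 12), seed = seed, ...)
}

# per-cell populations for one strain before/after induction
tiny_populations <- function(depletion = 0.3, n_cells = 150, seed = 7) {
  list(
    before = sim_cell_population(n_cells, induced = FALSE,
                                 seed = seed),
    after = sim_cell_population(n_cells, induced = TRUE,
                                depletion_factor = depletion,
                                seed = seed + 1)
  )
}

# band built from dim (autofluorescence-only) control populations
tiny_band <- function(n_controls = 5, n_cells = 150, seed = 99) {
  gms <- vapply(seq_len(n_controls), function(i) {
    pop <- sim_cell_population(n_cells, log_mean = log(1), log_sd = 0,
                               seed = seed + i)
    summarize_cells(pop$mean_intensity)$geo_mean
  }, numeric(1))
  autofluorescence_band(gms)
}

# brute-force oracles -------------------------------------------------------

# oracle: trim outside mean +/- k SD, then geometric mean of survivors
oracle_trim_summary <- function(x, k = 2) {
  keep <- abs(x - mean(x)) <= k * sd(x)
  if (!any(keep)) keep <- rep(TRUE, length(x))
  s <- x[keep]
  list(geo_mean = exp(mean(log(s))), n = length(s))
}

# oracle: Venn region for each element by direct membership enumeration
oracle_venn <- function(sets) {
  all_el <- unique(unlist(sets))
  vapply(all_el, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
}

# oracle: per-term hit count by looping over every (gene, term) row
oracle_term_counts <- function(annotation, hits) {
  terms <- unique(annotation$term_id)
  setNames(vapply(terms, function(t) {
    genes <- annotation$gene_id[annotation$term_id == t]
    sum(genes %in% hits)
  }, numeric(1)), terms)
}

# oracle: dense descending rank by explicit comparison counting
oracle_dense_rank <- function(x) {
  ux <- sort(unique(x), decreasing = TRUE)
  unname(vapply(x, function(v) which(ux == v), integer(1)))
}
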