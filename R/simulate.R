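#' Simulate a paired induced/uninduced colony plate screen
#'
#' Generates an arrayed colony-size screen with planted induction-lethal
#' strains, emulating a high-density (e.g. 1,536-format) degron library
#' pinned with and without the inducer. Colony sizes are multiplicative:
#' a per-strain baseline times an edge factor (outermost ring only, applied
#' to both conditions so that induced/uninduced ratios cancel it) times
#' log-normal pin-to-pin noise. Induction-lethal strains have their induced
#' baseline scaled by `effect_size`; sizes are areas and never negative.
#'
#' @param n_strains Number of strains to array (row-major placement).
#' @param layout Integer vector `c(rows, cols)`; capacity must hold
#'   `n_strains`. Default `c(32, 48)`, the 1,536 format.
#' @param lethal_fraction Fraction of strains planted as induction-lethal.
#' @param effect_size Mean induced/uninduced size ratio for lethal strains.
#' @param noise_cv Coefficient of variation of colony sizes (log-normal).
#' @param edge_boost Multiplicative size factor for border positions.
#' @param baseline Mean uninduced colony size, arbitrary units.
#' @param media Media label stamped on the plates.
#' @param n_rep Replicate plates per condition.
#' @param plate_id Plate identifier prefix.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with `plates`, a long tibble of colony records
#'   (`plate_id, media, induced, replicate, row, col, strain_id, size`),
#'   and `truth`, a tibble of `strain_id, lethal` planted flags.
#' @examples
#' sim <- sim_plate_pair(n_strains = 96, layout = c(8, 12), seed = 1)
#' dplyr::count(sim$plates, induced, replicate)
#' @export
sim_plate_pair <- function(n_strains,
                           layout = c(32L, 48L),
                           lethal_fraction = 0.1,
                           effect_size = 0.05,
                           noise_cv = 0.1,
                           edge_boost = 1.2,
                           baseline = 1000,
                           media = "rich",
                           n_rep = 2L,
                           plate_id = "P1",
                           seed = NULL) {
  check_fraction(lethal_fraction, "lethal_fraction")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (length(layout) != 2L || any(layout < 1)) {
    abort("`layout` must be two positive integers c(rows, cols).")
  }
  capacity <- prod(layout)
  if (n_strains > capacity) {
    abort(sprintf("layout capacity %d cannot hold %d strains.",
                  capacity, n_strains))
  }
  if (!is.null(seed)) set.seed(seed)

  strain_id <- sprintf("S%04d", seq_len(n_strains))
  n_lethal <- round(lethal_fraction * n_strains)
  lethal <- rep(FALSE, n_strains)
  if (n_lethal > 0) lethal[sample.int(n_strains, n_lethal)] <- TRUE
  truth <- tibble(strain_id = strain_id, lethal = lethal)

  pos <- tibble(
    row = rep(seq_len(layout[1]), each = layout[2]),
    col = rep(seq_len(layout[2]), times = layout[1])
  )[seq_len(n_strains), ]
  on_edge <- pos$row == 1 | pos$row == layout[1] |
    pos$col == 1 | pos$col == layout[2]
  edge_factor <- ifelse(on_edge, edge_boost, 1)

  base <- rep(baseline, n_strains)
  one_plate <- function(induced, rep_idx) {
    mu <- base * edge_factor
    if (induced) mu <- mu * ifelse(lethal, effect_size, 1)
    size <- ifelse(mu > 0, rlnorm_cv(n_strains, pmax(mu, .Machine$double.xmin), noise_cv), 0)
    size[mu == 0] <- 0
    tibble(
      plate_id = plate_id, media = media, induced = induced,
      replicate = rep_idx, row = pos$row, col = pos$col,
      strain_id = strain_id, size = size
    )
  }
  plates <- bind_rows(
    purrr::map(seq_len(n_rep), ~ one_plate(FALSE, .x)),
    purrr::map(seq_len(n_rep), ~ one_plate(TRUE, .x))
  )
  list(plates = plates, truth = truth)
}

#' Simulate a per-cell fluorescence population
#'
#' Draws single-cell mean intensities as an additive autofluorescence
#' background plus a multiplicative log-normal GFP signal. Induction scales
#' the signal component (not the background) by `depletion_factor`,
#' mirroring how degradation removes tagged protein while cellular
#' autofluorescence persists.
#'
#' @param n_cells Number of cells.
#' @param log_mean,log_sd Log-scale location and spread of the true signal.
#' @param af_mean,af_sd Autofluorescence background mean and SD
#'   (normal, floored at a tiny positive value so intensities stay > 0).
#' @param depletion_factor Multiplicative signal drop after induction, in
#'   `[0, 1]`; `1` means unresponsive.
#' @param induced Whether this population is post-induction.
#' @param strain_id,condition,channel Labels stamped on the output.
#' @param seed Integer seed.
#' @return Tibble of `strain_id, condition, channel, cell_id,
#'   mean_intensity`, one row per cell.
#' @examples
#' pop <- sim_cell_population(100, induced = TRUE, depletion_factor = 0.3,
#'                            seed = 1)
#' geo_mean(pop$mean_intensity)
#' @export
sim_cell_population <- function(n_cells,
                                log_mean = log(1000),
                                log_sd = 0.3,
                                af_mean = 100,
                                af_sd = 10,
                                depletion_factor = 1,
                                induced = FALSE,
                                strain_id = "S0001",
                                condition = if (induced) "t24h" else "t0",
                                channel = "GFP",
                                seed = NULL) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  check_fraction(depletion_factor, "depletion_factor")
  if (!is.null(seed)) set.seed(seed)
  af <- pmax(rnorm(n_cells, af_mean, af_sd), .Machine$double.eps)
  signal <- if (log_sd == 0) rep(exp(log_mean), n_cells) else
    rlnorm(n_cells, meanlog = log_mean, sdlog = log_sd)
  if (induced) signal <- signal * depletion_factor
  tibble(
    strain_id = strain_id, condition = condition, channel = channel,
    cell_id = seq_len(n_cells), mean_intensity = af + signal
  )
}

#' Simulate a degradation time course
#'
#' Generates replicate one-phase decay series
#' `y(t) = plateau + (1 - plateau) * 2^(-t / t50)` with multiplicative
#' log-normal noise of coefficient of variation `noise_cv` per observation,
#' so the expected signal at `t = 0` is 1 (fraction of initial).
#'
#' @param t50 Half-life in minutes, > 0.
#' @param plateau Asymptotic remaining fraction in `[0, 1]`.
#' @param timepoints Sampling times in minutes; must include 0.
#' @param noise_cv Per-observation coefficient of variation.
#' @param n_rep Number of replicates.
#' @param strain_id,modality Labels stamped on the output.
#' @param seed Integer seed.
#' @return Tibble of `strain_id, modality, replicate, time_min, signal`.
#' @examples
#' tc <- sim_timecourse(t50 = 30, plateau = 0, noise_cv = 0)
#' tc$signal[tc$time_min == 30] # 0.5
#' @export
sim_timecourse <- function(t50,
                           plateau = 0,
                           timepoints = c(0, 15, 30, 60, 120, 180),
                           noise_cv = 0.05,
                           n_rep = 3L,
                           strain_id = "S0001",
                           modality = "microscopy",
                           seed = NULL) {
  if (!is.numeric(t50) || t50 <= 0) abort("`t50` must be > 0.")
  check_fraction(plateau, "plateau")
  if (!any(timepoints == 0)) abort("`timepoints` must include 0.")
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(replicate = seq_len(n_rep), time_min = timepoints)
  mu <- plateau + (1 - plateau) * 2^(-grid$time_min / t50)
  noise <- rlnorm_cv(nrow(grid), 1, noise_cv)
  tibble(
    strain_id = strain_id, modality = modality,
    replicate = grid$replicate, time_min = grid$time_min,
    signal = mu * noise
  )
}

#' Simulate a gene-to-term annotation table
#'
#' Builds a flattened (GO-slim-like) annotation table in which each term is
#' assigned to exactly its stated number of genes, sampled without
#' replacement from the gene universe. Terms may overlap on genes.
#'
#' @param n_genes Size of the gene universe (ids `G0001`, ...).
#' @param terms Named integer vector or two-column data frame
#'   (`term_id, size`) giving each term's genome-wide annotation count.
#' @param seed Integer seed.
#' @return Tibble of `gene_id, term_id` rows.
#' @examples
#' ann <- sim_annotation_table(500, c(`GO:0001` = 50, `GO:0002` = 10), seed = 1)
#' dplyr::count(ann, term_id)
#' @export
sim_annotation_table <- function(n_genes, terms, seed = NULL) {
  if (is.data.frame(terms)) {
    term_id <- as.character(terms[[1]])
    size <- as.integer(terms[[2]])
  } else {
    term_id <- names(terms)
    size <- as.integer(terms)
  }
  if (is.null(term_id) || any(!nzchar(term_id))) {
    abort("`terms` must carry term ids (names or first column).")
  }
  if (any(size < 1) || any(size > n_genes)) {
    abort("each term size must be in [1, n_genes].")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  purrr::map2_dfr(term_id, size, function(tid, k) {
    tibble(gene_id = sort(sample(genes, k)), term_id = tid)
  })
}

#' Simulate a single-channel cell image with known centroids
#'
#' Places non-overlapping uniform-intensity disks on a constant background,
#' returning the image and the ground-truth centroid table consumable by
#' [crop_cells()]. Placement retries are bounded; failure to place all
#' cells raises an error rather than returning overlapping cells.
#'
#' @param n_cells Number of cells (0 gives a blank image and empty table).
#' @param image_size Integer vector `c(rows, cols)` or a single side length.
#' @param cell_radius Disk radius in pixels.
#' @param intensity Disk intensity (single value recycled, or per-cell).
#' @param background Background intensity.
#' @param max_tries Placement attempts per cell before giving up.
#' @param seed Integer seed.
#' @return List with `image` (numeric matrix) and `centroids`
#'   (tibble `cell_id, row, col, intensity`), 1-based pixel coordinates.
#' @examples
#' img <- sim_cell_image(n_cells = 3, image_size = 128, seed = 1)
#' nrow(img$centroids)
#' @export
sim_cell_image <- function(n_cells,
                           image_size = 512L,
                           cell_radius = 8L,
                           intensity = 10000,
                           background = 100,
                           max_tries = 1000L,
                           seed = NULL) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(background, nrow = image_size[1], ncol = image_size[2])
  cents <- tibble(cell_id = integer(), row = integer(), col = integer(),
                  intensity = numeric())
  if (n_cells == 0) return(list(image = img, centroids = cents))
  intensity <- rep_len(intensity, n_cells)
  r <- cell_radius
  lo_r <- r + 1L; hi_r <- image_size[1] - r
  lo_c <- r + 1L; hi_c <- image_size[2] - r
  if (hi_r < lo_r || hi_c < lo_c) {
    abort("`cell_radius` too large for `image_size`.")
  }
  placed <- matrix(NA_integer_, nrow = n_cells, ncol = 2)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(sample(lo_r:hi_r, 1L), sample(lo_c:hi_c, 1L))
      if (i == 1L || all(sqrt(rowSums((placed[seq_len(i - 1L), , drop = FALSE] -
            matrix(cand, i - 1L, 2, byrow = TRUE))^2)) > 2 * r)) {
        placed[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf("could not place cell %d without overlap after %d tries.",
                    i, max_tries))
    }
  }
  for (i in seq_len(n_cells)) {
    rr <- (placed[i, 1] - r):(placed[i, 1] + r)
    cc <- (placed[i, 2] - r):(placed[i, 2] + r)
    disk <- outer(rr - placed[i, 1], cc - placed[i, 2],
                  function(dr, dc) dr^2 + dc^2 <= r^2)
    block <- img[rr, cc]
    block[disk] <- intensity[i]
    img[rr, cc] <- block
  }
  cents <- tibble(cell_id = seq_len(n_cells),
                  row = placed[, 1], col = placed[, 2],
                  intensity = intensity)
  list(image = img, centroids = cents)
}
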