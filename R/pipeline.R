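#' Run the full synthetic screen pipeline
#'
#' Chains the stages end to end on synthetic data generated from the
#' config: plate simulation and growth scoring, per-cell fluorescence
#' simulation and responsiveness classification, degradation-kinetics
#' fitting, media partition and GO-slim term recovery, grouped
#' responsiveness, and a cell-grid montage. Every stage writes a TSV into
#' `out_dir`; a `provenance.yaml` records the package version, the config,
#' and its hash. All randomness flows from `config$seed`, so identical
#' configs produce byte-identical TSVs.
#'
#' @param config A [default_run_config()] list.
#' @param out_dir Output directory (created if missing).
#' @param stages Character subset of
#'   `c("growth", "fluorescence", "kinetics", "enrichment", "grouping",
#'   "montage")`; default all.
#' @return Invisible named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("degronscreen_run_"),
                         stages = c("growth", "fluorescence", "kinetics",
                                    "enrichment", "grouping", "montage")) {
  all_stages <- c("growth", "fluorescence", "kinetics", "enrichment",
                  "grouping", "montage")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  seed <- as.integer(config$seed)
  stage_seed <- function(i) (seed * 101L + i * 7919L) %% .Machine$integer.max

  run_stage <- function(name, fn) {
    inform(sprintf("[degronscreen:%s] running", name))
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  hits_by_media <- NULL
  calls <- NULL

  if ("growth" %in% stages || "enrichment" %in% stages) {
    results$growth <- run_stage("growth", function() {
      medias <- c("rich", "minimal", "respiration")
      sims <- purrr::imap(setNames(medias, medias), function(m, i) {
        sim_plate_pair(
          n_strains = config$n_strains, layout = config$layout,
          lethal_fraction = config$lethal_fraction,
          effect_size = config$effect_size, noise_cv = config$noise_cv,
          edge_boost = config$edge_boost, media = m,
          seed = stage_seed(match(m, medias))
        )
      })
      plates <- bind_rows(purrr::map(sims, "plates"))
      scores <- score_relative_growth(
        plates, presence_threshold = config$presence_threshold)
      normed <- normalize_scores(scores, trim_k = config$trim_outliers_k)
      calls <- classify_essentiality(
        normed, permissive = config$permissive, stringent = config$stringent)
      write_plate_table(plates, file.path(out_dir, "plates.tsv"))
      readr::write_tsv(calls, file.path(out_dir, "growth_calls.tsv"))
      list(plates = plates, scores = normed, calls = calls,
           truth = sims[[1]]$truth)
    })
    hb <- results$growth$calls %>% filter(.data$severe)
    hits_by_media <- split(hb$strain_id, hb$media)
  }

  if ("fluorescence" %in% stages || "grouping" %in% stages) {
    results$fluorescence <- run_stage("fluorescence", function() {
      n_strain <- min(config$n_strains, 50L)
      responder <- rep(c(TRUE, FALSE), length.out = n_strain)
      controls <- purrr::map_dbl(1:6, function(i) {
        pop <- sim_cell_population(
          config$n_cells, log_mean = log(1), log_sd = 0,
          depletion_factor = 1, seed = stage_seed(100L + i))
        summarize_cells(pop$mean_intensity, trim_k = config$trim_k)$geo_mean
      })
      band <- autofluorescence_band(controls, k = config$band_k)
      cells <- purrr::map_dfr(seq_len(n_strain), function(i) {
        sid <- sprintf("S%04d", i)
        bind_rows(
          sim_cell_population(config$n_cells, induced = FALSE,
                              strain_id = sid, seed = stage_seed(200L + i)),
          sim_cell_population(config$n_cells, induced = TRUE,
                              depletion_factor =
                                if (responder[i]) config$depletion_factor else 1,
                              strain_id = sid, seed = stage_seed(400L + i))
        )
      })
      calls <- purrr::map_dfr(unique(cells$strain_id), function(sid) {
        classify_strain(
          before = cells %>% filter(.data$strain_id == sid,
                                    .data$condition == "t0"),
          after = cells %>% filter(.data$strain_id == sid,
                                   .data$condition == "t24h"),
          band = band, alpha = config$alpha,
          min_effect = config$min_effect,
          death_fraction = config$death_fraction, trim_k = config$trim_k)
      }) %>%
        adjust_strain_calls(alpha = config$alpha,
                            min_effect = config$min_effect)
      write_cell_table(cells, file.path(out_dir, "cells.tsv"))
      readr::write_tsv(calls, file.path(out_dir, "fluorescence_calls.tsv"))
      readr::write_tsv(library_summary(calls),
                       file.path(out_dir, "library_summary.tsv"))
      list(band = band, calls = calls, summary = library_summary(calls))
    })
    calls <- results$fluorescence$calls
  }

  if ("kinetics" %in% stages) {
    results$kinetics <- run_stage("kinetics", function() {
      tc <- sim_timecourse(
        t50 = config$t50, plateau = config$plateau,
        noise_cv = config$tc_noise_cv, n_rep = config$n_rep,
        seed = stage_seed(500L))
      fit <- fit_one_phase_decay(normalize_timecourse(tc))
      write_timecourse_table(tc, file.path(out_dir, "timecourse.tsv"))
      readr::write_tsv(glance(fit), file.path(out_dir, "decay_fit.tsv"))
      list(timecourse = tc, fit = fit)
    })
  }

  if ("enrichment" %in% stages) {
    results$enrichment <- run_stage("enrichment", function() {
      ann <- sim_annotation_table(
        n_genes = config$n_strains,
        terms = c(`GO:0001` = max(2L, config$n_strains %/% 5L),
                  `GO:0002` = max(2L, config$n_strains %/% 10L)),
        seed = stage_seed(600L))
      # gene universe shares strain ids with the plates
      ann$gene_id <- sprintf("S%s", substring(ann$gene_id, 2))
      part <- media_partition(hits_by_media)
      rankings <- purrr::imap_dfr(part$exclusive, function(ex, m) {
        r <- rank_exclusive_terms(ann, ex, k = config$top_k,
                                  all_hits = hits_by_media[[m]])
        if (nrow(r)) r$media <- m
        r
      })
      shared <- shared_hits_recovery(
        ann, part$membership$strain_id[
          part$membership$n_media == length(hits_by_media)])
      readr::write_tsv(part$regions, file.path(out_dir, "venn_regions.tsv"))
      readr::write_tsv(rankings, file.path(out_dir, "exclusive_terms.tsv"))
      readr::write_tsv(shared, file.path(out_dir, "shared_recovery.tsv"))
      list(partition = part, rankings = rankings, shared = shared)
    })
  }

  if ("grouping" %in% stages) {
    results$grouping <- run_stage("grouping", function() {
      set.seed(stage_seed(700L))
      meta <- tibble(
        strain_id = unique(calls$strain_id),
        localization = sample(c("cytosol", "nucleolus", "early Golgi",
                                "vacuole", "mitochondria"),
                              dplyr::n_distinct(calls$strain_id),
                              replace = TRUE)
      ) %>%
        mutate(compartment = collapse_compartment(.data$localization),
               abundance_rank = sample(dplyr::n()))
      groups <- group_responsiveness(calls, meta, "compartment")
      bins <- quantile_bins(
        meta %>% select(dplyr::all_of(c("strain_id", "abundance_rank"))), 5L)
      readr::write_tsv(groups, file.path(out_dir, "group_responsiveness.tsv"))
      readr::write_tsv(bins, file.path(out_dir, "abundance_bins.tsv"))
      list(metadata = meta, groups = groups, bins = bins)
    })
  }

  if ("montage" %in% stages) {
    results$montage <- run_stage("montage", function() {
      img <- sim_cell_image(n_cells = 12L, image_size = 512L,
                            cell_radius = 8L, seed = stage_seed(800L))
      crops <- crop_cells(img$image, img$centroids,
                          box_size = config$box_size)
      m <- assemble_grid(crops, grid_dims = config$grid_dims) %>%
        adjust_contrast(saturate_fraction = config$saturate_fraction)
      write_image(m$pixels, file.path(out_dir, "montage.tif"), bits = 16L)
      write_centroid_table(img$centroids,
                           file.path(out_dir, "centroids.tsv"))
      m
    })
  }

  yaml::write_yaml(
    list(package = "degronscreen",
         version = as.character(utils::packageVersion("degronscreen")),
         timestamp = format(Sys.time(), tz = "UTC"),
         config_hash = config_hash(unclass(config)),
         config = unclass(config)),
    file.path(out_dir, "provenance.yaml"))
  inform(sprintf("[degronscreen] outputs written to %s", out_dir))
  invisible(results)
}
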