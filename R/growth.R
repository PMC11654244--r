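#' Score relative growth from paired induced/uninduced plates
#'
#' For each strain and media, averages colony sizes across replicate plates
#' within each condition and takes the ratio mean(induced) / mean(uninduced).
#' The ratio is the essentiality score: induction-lethal strains grow little
#' or not at all with the inducer, giving scores near zero. Because both
#' conditions share plate geometry, positional effects (such as better
#' growth at plate edges) cancel in the ratio.
#'
#' Strains whose uninduced mean size does not exceed `presence_threshold`
#' never grew in the first place and are marked `absent` (`raw_ratio = NA`)
#' rather than scored: a strain missing without induction is unscorable,
#' not essential.
#'
#' @param plates Long plate tibble with columns
#'   `plate_id, media, induced, replicate, row, col, strain_id, size`
#'   (as produced by [sim_plate_pair()] or [read_plate_table()]).
#' @param presence_threshold Colony presence cut-off in the same arbitrary
#'   units as `size`; a colony is present only if its size is strictly over
#'   this value (default 50 A.U.).
#' @return Tibble of `strain_id, media, plate_id, raw_ratio, n_induced,
#'   n_uninduced, absent`, one row per strain x media x plate.
#' @examples
#' sim <- sim_plate_pair(n_strains = 96, layout = c(8, 12), seed = 1)
#' score_relative_growth(sim$plates)
#' @export
score_relative_growth <- function(plates, presence_threshold = 50) {
  required <- c("plate_id", "media", "induced", "replicate",
                "row", "col", "strain_id", "size")
  missing <- setdiff(required, names(plates))
  if (length(missing)) {
    abort(paste0("`plates` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(plates$size)) || any(plates$size < 0)) {
    abort("colony sizes must be finite and >= 0.")
  }
  # same position must map to one strain across the induced/uninduced pair
  bad <- plates %>%
    distinct(.data$plate_id, .data$media, .data$row, .data$col,
             .data$strain_id) %>%
    count(.data$plate_id, .data$media, .data$row, .data$col) %>%
    filter(.data$n > 1)
  if (nrow(bad)) {
    abort("induced and uninduced plates disagree on the strain map.")
  }
  conditions <- plates %>% distinct(.data$media, .data$induced)
  if (!all(c(TRUE, FALSE) %in% conditions$induced)) {
    abort("both induced and uninduced plates are required.")
  }

  plates %>%
    group_by(.data$plate_id, .data$media, .data$strain_id, .data$induced) %>%
    summarise(mean_size = mean(.data$size), n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "induced",
                       values_from = c("mean_size", "n"),
                       names_glue = "{.value}_{ifelse(induced, 'ind', 'unind')}") %>%
    mutate(
      absent = is.na(.data$mean_size_unind) |
        .data$mean_size_unind <= presence_threshold,
      raw_ratio = if_else(.data$absent, NA_real_,
                          .data$mean_size_ind / .data$mean_size_unind)
    ) %>%
    select(dplyr::all_of(c("strain_id", "media", "plate_id", "raw_ratio",
                           n_induced = "n_ind", n_uninduced = "n_unind",
                           "absent"))) %>%
    arrange(.data$media, .data$plate_id, .data$strain_id)
}

#' Normalize relative-growth scores by the robust plate median
#'
#' Divides each raw ratio by the median of its plate x media group,
#' computed after outlier removal, so that the typical (unaffected) strain
#' scores 1 on every plate and plates/medias are comparable. Outliers are
#' trimmed outside `median +/- trim_k * (1.4826 * MAD)` — a robust,
#' parameter-free rule; the trimmed set is used only to compute the
#' normalization factor, never dropped from the output.
#'
#' @param scores Output of [score_relative_growth()].
#' @param trim_k Width of the robust trimming window in SD-equivalents.
#' @return `scores` with a `normalized_score` column (NA for absent
#'   strains) and a `norm_factor` column recording the plate median used.
#'   Groups with fewer than 3 scorable strains are skipped with a warning
#'   (scores pass through unnormalized, `norm_factor = NA`).
#' @export
normalize_scores <- function(scores, trim_k = 2) {
  plate_factor <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L) return(NA_real_)
    med <- median(x)
    s <- mad(x) # 1.4826 * median absolute deviation
    keep <- if (s == 0) rep(TRUE, length(x)) else abs(x - med) <= trim_k * s
    median(x[keep])
  }
  out <- scores %>%
    group_by(.data$media, .data$plate_id) %>%
    mutate(norm_factor = plate_factor(.data$raw_ratio)) %>%
    ungroup() %>%
    mutate(normalized_score = if_else(
      is.na(.data$norm_factor), .data$raw_ratio,
      .data$raw_ratio / .data$norm_factor
    ))
  skipped <- out %>%
    filter(is.na(.data$norm_factor)) %>%
    distinct(.data$media, .data$plate_id)
  if (nrow(skipped)) {
    warn(sprintf(
      "%d plate group(s) had < 3 scorable strains; left unnormalized.",
      nrow(skipped)))
  }
  out
}

#' Classify essentiality from normalized relative-growth scores
#'
#' Applies strict-inequality thresholds to the normalized score:
#' `stringent_severe` below the stringent threshold (default 0.1, i.e.
#' <10% relative growth), `severe` below the permissive threshold
#' (default 0.5), `none` otherwise; non-finite scores are `absent`.
#' `stringent_severe` strains are by construction also severe; the
#' `severe` logical column records the permissive call for both.
#'
#' @param scores Output of [normalize_scores()] (or any tibble with
#'   `strain_id, media, normalized_score`).
#' @param permissive,stringent Threshold values; classification uses
#'   strict `<`.
#' @param moderate Optional third threshold above `permissive` for a
#'   `moderate` class; disabled (`NA`) by default since the screen design
#'   defines only the two published thresholds.
#' @return Tibble of `strain_id, media, normalized_score, class, severe,
#'   stringent_severe` where `class` is a factor with levels
#'   `stringent_severe, severe, moderate, none, absent`.
#' @examples
#' df <- tibble::tibble(strain_id = c("a", "b", "c"), media = "rich",
#'                      normalized_score = c(0.45, 0.05, 1))
#' classify_essentiality(df)$class
#' @export
classify_essentiality <- function(scores, permissive = 0.5, stringent = 0.1,
                                  moderate = NA_real_) {
  if (stringent >= permissive) {
    abort("`stringent` must be below `permissive`.")
  }
  s <- scores$normalized_score
  cls <- case_when(
    !is.finite(s) ~ "absent",
    s < stringent ~ "stringent_severe",
    s < permissive ~ "severe",
    !is.na(moderate) & s < moderate ~ "moderate",
    TRUE ~ "none"
  )
  scores %>%
    select(dplyr::all_of(c("strain_id", "media", "normalized_score"))) %>%
    mutate(
      class = factor(cls, levels = c("stringent_severe", "severe",
                                     "moderate", "none", "absent")),
      severe = is.finite(s) & s < permissive,
      stringent_severe = is.finite(s) & s < stringent
    )
}

#' Partition hit sets across media into exhaustive Venn regions
#'
#' Assigns every strain in the union of the per-media hit sets to exactly
#' one Venn region (the combination of medias it is a hit in), so region
#' sizes always sum to the union cardinality. Exclusive (single-media)
#' sets feed the GO-slim exclusive-hit ranking.
#'
#' @param hit_sets Named list of character vectors, one strain set per
#'   media; at least 2 media.
#' @return List with `membership` (tibble `strain_id, region, n_media,
#'   exclusive` where `region` joins media names with `&` in input order),
#'   `regions` (tibble `region, n`), and `exclusive` (named list of
#'   single-media strain sets, one per media, possibly empty).
#' @examples
#' media_partition(list(A = c("x", "y"), B = c("y", "z"), C = "y"))$regions
#' @export
media_partition <- function(hit_sets) {
  if (length(hit_sets) < 2L || is.null(names(hit_sets))) {
    abort("`hit_sets` must be a named list of >= 2 media.")
  }
  medias <- names(hit_sets)
  all_strains <- unique(unlist(hit_sets, use.names = FALSE))
  membership <- tibble(strain_id = all_strains)
  for (m in medias) membership[[m]] <- all_strains %in% hit_sets[[m]]
  flags <- as.matrix(membership[medias])
  region <- apply(flags, 1L, function(f) paste(medias[f], collapse = "&"))
  membership <- membership %>%
    mutate(region = region, n_media = rowSums(flags),
           exclusive = .data$n_media == 1L)
  regions <- membership %>%
    count(.data$region, name = "n") %>%
    arrange(desc(.data$n))
  exclusive <- setNames(
    lapply(medias, function(m) {
      membership$strain_id[membership$region == m]
    }), medias)
  list(membership = membership, regions = regions, exclusive = exclusive)
}

#' Colony presence and SWATting survival rate
#'
#' A colony is considered present if its quantified size is strictly over
#' the threshold (default 50 A.U.); the survival rate is the fraction of
#' attempted positions with a present colony.
#'
#' @param sizes Numeric vector of colony quantifications, arbitrary units.
#' @param threshold Presence cut-off in the same units.
#' @return List with `present` (logical vector) and `survival_rate`
#'   (fraction in `[0, 1]`).
#' @examples
#' colony_presence(c(0, 50, 51, 400))$survival_rate # 0.5
#' @export
colony_presence <- function(sizes, threshold = 50) {
  present <- sizes > threshold
  list(present = present, survival_rate = mean(present))
}
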