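#' Collapse raw localization categories to the canonical compartment list
#'
#' Deterministic collapsing of fine-grained localization labels:
#' "early Golgi" and "late Golgi" fold into "Golgi"; "nucleolus" into
#' "nucleus"; "actin", "endosome", "ER to Golgi", "microtubule" and
#' "spindle pole" into "punctate composite". Any other category passes
#' through unchanged. Idempotent and vectorized.
#'
#' @param raw Character vector of localization categories.
#' @return Character vector of canonical compartments.
#' @examples
#' collapse_compartment(c("early Golgi", "nucleolus", "vacuole"))
#' @export
collapse_compartment <- function(raw) {
  map <- c(
    "early Golgi" = "Golgi",
    "late Golgi" = "Golgi",
    "nucleolus" = "nucleus",
    "actin" = "punctate composite",
    "endosome" = "punctate composite",
    "ER to Golgi" = "punctate composite",
    "microtubule" = "punctate composite",
    "spindle pole" = "punctate composite"
  )
  out <- unname(map[raw])
  ifelse(is.na(out), raw, out)
}

#' Aggregate responsiveness by a metadata grouping
#'
#' Joins strain calls to metadata and reports, per group, the percentage
#' of responsive strains among fluorescent strains. Because dead strains
#' are fluorescent but uninformative, two percentages are emitted: `pct`
#' excludes dead strains from the denominator, `pct_incl_dead` counts them
#' as responding. Strains missing metadata are excluded; empty groups are
#' omitted.
#'
#' @param calls Adjusted strain calls (see [adjust_strain_calls()]).
#' @param metadata Tibble keyed by `strain_id` with grouping fields (e.g.
#'   `compartment`, `translocation`, `c_prime_orientation`, `bin`).
#' @param group_by Name of the metadata column to group on.
#' @return Tibble of `<group_by>, n_fluorescent, n_responsive, n_dead,
#'   pct, pct_incl_dead`.
#' @export
group_responsiveness <- function(calls, metadata, group_by) {
  if (!group_by %in% names(metadata)) {
    abort(sprintf("unknown grouping field '%s'.", group_by))
  }
  joined <- calls %>%
    dplyr::inner_join(metadata, by = "strain_id") %>%
    filter(!is.na(.data[[group_by]]), .data$fluorescent)
  joined %>%
    group_by(.data[[group_by]]) %>%
    summarise(
      n_fluorescent = dplyr::n(),
      n_responsive = sum(.data$status == "responsive"),
      n_dead = sum(.data$status == "dead"),
      .groups = "drop"
    ) %>%
    mutate(
      pct = 100 * .data$n_responsive /
        pmax(.data$n_fluorescent - .data$n_dead, 1L),
      pct_incl_dead = 100 * (.data$n_responsive + .data$n_dead) /
        .data$n_fluorescent
    )
}

#' Ratio of responsiveness between two groups
#'
#' E.g. how many times more likely posttranslationally translocated
#' proteins are to respond than cotranslational ones.
#'
#' @param groups Output of [group_responsiveness()].
#' @param a,b Group labels (numerator, denominator).
#' @param column Which percentage column to compare.
#' @return A single number `pct_a / pct_b`; `NA` when `pct_b` is 0.
#' @export
group_ratio <- function(groups, a, b, column = "pct") {
  key <- names(groups)[1]
  pa <- groups[[column]][groups[[key]] == a]
  pb <- groups[[column]][groups[[key]] == b]
  if (length(pa) != 1L || length(pb) != 1L) {
    abort("both groups must be present exactly once.")
  }
  if (pb == 0) return(NA_real_)
  pa / pb
}

#' Split ranked items into near-equal quantile bins
#'
#' Orders items by rank (1 = most abundant) and cuts them into `n_bins`
#' bins of as-equal-as-possible size; when the count does not divide
#' evenly the remainder goes to the lowest-index (most abundant) bins, so
#' bin sizes differ by at most 1. Bin 1 holds the most abundant items.
#'
#' @param items Tibble with an id column and a `rank` column (unique,
#'   comparable ranks), or a named numeric vector of ranks.
#' @param n_bins Number of bins (deciles: 10, quintiles: 5).
#' @return Tibble of `id, rank, bin`.
#' @examples
#' x <- tibble::tibble(id = letters[1:11], rank = 1:11)
#' table(quantile_bins(x, 5)$bin) # 3 2 2 2 2
#' @export
quantile_bins <- function(items, n_bins) {
  if (!is.data.frame(items)) {
    items <- tibble(id = names(items), rank = as.numeric(items))
  } else {
    names(items)[1:2] <- c("id", "rank")
  }
  n <- nrow(items)
  if (n_bins < 1L || n_bins > n) {
    abort("`n_bins` must be between 1 and the item count.")
  }
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  items %>%
    arrange(.data$rank) %>%
    mutate(bin = rep(seq_len(n_bins), times = sizes))
}

#' Rank strains by mitochondrial dye signal
#'
#' Dense ranks by descending intensity (rank 1 = brightest); ties share
#' the better rank. Output order is by rank, invariant to input
#' permutation.
#'
#' @param mito Tibble with `strain_id` and an intensity column (second
#'   column used), or a named numeric vector.
#' @return Tibble of `strain_id, intensity, rank`.
#' @export
rank_mito_signal <- function(mito) {
  if (!is.data.frame(mito)) {
    mito <- tibble(strain_id = names(mito), intensity = as.numeric(mito))
  } else {
    names(mito)[1:2] <- c("strain_id", "intensity")
  }
  if (any(!is.finite(mito$intensity))) {
    abort("intensities must be finite.")
  }
  mito %>%
    mutate(rank = dplyr::dense_rank(desc(.data$intensity))) %>%
    arrange(.data$rank, .data$strain_id)
}
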