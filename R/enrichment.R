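#' Read a gene-to-term annotation table
#'
#' Accepts either a minimal two-column TSV (`gene_id`, `term_id`, header
#' optional) or a GAF-like dialect (comment lines starting with `!`; gene
#' identifier in column 2 with column 3 as fallback symbol, term in column
#' 5; evidence codes ignored). Duplicate (gene, term) pairs are dropped.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default), `"tsv"`, or `"gaf"`.
#' @return Tibble of unique `gene_id, term_id` rows.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "!")]
  ncol_first <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (format == "auto") {
    format <- if (ncol_first >= 5L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    fields <- strsplit(body, "\t", fixed = TRUE)
    ann <- tibble(
      gene_id = purrr::map_chr(fields, function(f) {
        if (nzchar(f[2] %||% "")) f[2] else f[3]
      }),
      term_id = purrr::map_chr(fields, ~ .x[5])
    )
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    ann <- tibble(
      gene_id = purrr::map_chr(fields, ~ .x[1]),
      term_id = purrr::map_chr(fields, ~ .x[2])
    )
    # tolerate an optional header row
    if (tolower(ann$gene_id[1]) %in% c("gene_id", "gene") &&
        tolower(ann$term_id[1]) %in% c("term_id", "term", "go_term")) {
      ann <- ann[-1, ]
    }
  }
  distinct(ann, .data$gene_id, .data$term_id)
}

#' Rank GO-slim terms within a media-exclusive hit set
#'
#' Counts, for each term, how many strains of the exclusive hit set (hits
#' found in exactly one media) carry its annotation, and returns the top
#' `k` terms. Ties on the exclusive count break by larger genome-wide
#' recovery percentage, then lexical term id. The reported pair
#' (`exclusive_count`, `exclusive_total`) matches the screen's
#' "count/exclusive-set-size" presentation.
#'
#' @param annotation Tibble of `gene_id, term_id` (see
#'   [read_annotation()]).
#' @param exclusive_hits Character vector of strain/gene ids exclusive to
#'   one media (from [media_partition()]).
#' @param k Number of top terms to return.
#' @param all_hits Optional full hit list of the media, used only for the
#'   tie-break recovery percentage; defaults to `exclusive_hits`.
#' @return Tibble of `term_id, exclusive_count, exclusive_total,
#'   term_size, recovery_pct` ordered by the ranking, at most `k` rows
#'   (empty for an empty exclusive set).
#' @export
rank_exclusive_terms <- function(annotation, exclusive_hits, k = 3,
                                 all_hits = exclusive_hits) {
  if (length(exclusive_hits) == 0L) {
    return(tibble(term_id = character(), exclusive_count = integer(),
                  exclusive_total = integer(), term_size = integer(),
                  recovery_pct = numeric()))
  }
  sizes <- annotation %>% count(.data$term_id, name = "term_size")
  annotation %>%
    filter(.data$gene_id %in% exclusive_hits) %>%
    count(.data$term_id, name = "exclusive_count") %>%
    left_join(sizes, by = "term_id") %>%
    mutate(
      exclusive_total = length(exclusive_hits),
      all_hits_count = purrr::map_int(.data$term_id, function(t) {
        sum(annotation$gene_id[annotation$term_id == t] %in% all_hits)
      }),
      recovery_pct = round(100 * .data$all_hits_count / .data$term_size, 1)
    ) %>%
    arrange(desc(.data$exclusive_count), desc(.data$recovery_pct),
            .data$term_id) %>%
    slice_head(n = k) %>%
    select(dplyr::all_of(c("term_id", "exclusive_count", "exclusive_total",
                           "all_hits_count", "term_size", "recovery_pct")))
}

#' Whole-term recovery for one GO-slim term
#'
#' The recovery percentage of a term is the share of its genome-wide
#' annotations that appear in the hit list —
#' `100 * |hits intersect term genes| / term_size` — reported to one
#' decimal, regardless of whether those genes are present in the library.
#' Library-presence and responsive-certified counts are carried as
#' metadata.
#'
#' @param annotation Tibble of `gene_id, term_id`.
#' @param term_id A term present in `annotation`.
#' @param hits Character vector: the full hit list in play.
#' @param library_genes,responsive_genes Optional character vectors used
#'   for the metadata counts (`NA` if not supplied).
#' @return One-row tibble: `term_id, all_hits_count, term_size,
#'   recovery_pct, in_library, responsive_in_library`.
#' @examples
#' ann <- sim_annotation_table(200, c(`GO:1` = 151), seed = 1)
#' hits <- ann$gene_id[1:27]
#' term_recovery(ann, "GO:1", hits)$recovery_pct # 17.9
#' @export
term_recovery <- function(annotation, term_id, hits,
                          library_genes = NULL, responsive_genes = NULL) {
  term_genes <- annotation$gene_id[annotation$term_id == term_id]
  if (length(term_genes) == 0L) {
    abort(sprintf("term '%s' is not in the annotation.", term_id))
  }
  n_hit <- sum(term_genes %in% hits)
  tibble(
    term_id = term_id,
    all_hits_count = n_hit,
    term_size = length(term_genes),
    recovery_pct = round(100 * n_hit / length(term_genes), 1),
    in_library = if (is.null(library_genes)) NA_integer_ else
      sum(term_genes %in% library_genes),
    responsive_in_library = if (is.null(responsive_genes)) NA_integer_ else
      sum(term_genes %in% responsive_genes)
  )
}

#' Term recovery for the all-media shared hit set
#'
#' For hits shared across every media, recovery is quantified against the
#' shared set only: each term annotated to at least one shared hit gets a
#' [term_recovery()] record computed with the shared hits as the hit list.
#'
#' @param annotation Tibble of `gene_id, term_id`.
#' @param intersection_hits Character vector: the strains hit in all
#'   medias (the triple-intersection Venn region).
#' @param library_genes,responsive_genes Optional metadata vectors.
#' @return Tibble of [term_recovery()] rows, one per term touched by the
#'   shared hits, ordered by decreasing recovery; empty if no shared hits.
#' @export
shared_hits_recovery <- function(annotation, intersection_hits,
                                 library_genes = NULL,
                                 responsive_genes = NULL) {
  terms <- annotation %>%
    filter(.data$gene_id %in% intersection_hits) %>%
    distinct(.data$term_id) %>%
    pull(.data$term_id)
  if (length(terms) == 0L) {
    return(term_recovery(annotation, annotation$term_id[1],
                         character())[0, ])
  }
  purrr::map_dfr(terms, term_recovery, annotation = annotation,
                 hits = intersection_hits, library_genes = library_genes,
                 responsive_genes = responsive_genes) %>%
    arrange(desc(.data$recovery_pct), .data$term_id)
}
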