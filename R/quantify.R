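#' Count unambiguous clean tags per gene
#'
#' Assigns every clean tag through [assign_tags()] and sums the copies of
#' uniquely mapping tags into per-gene raw counts (the library's "raw
#' intensity" values). Copies of ambiguous and unmapped tags are tallied
#' separately and attached as attributes, so the mapping budget always
#' closes: `sum(counts) + ambiguous + unmapped == sum(clean$count)`.
#'
#' @param clean Clean tag library tibble (`tag`, `count`).
#' @param index A [extract_virtual_tags()] index.
#' @param gene_ids Optional character vector defining the reporting
#'   universe. Defaults to the genes present in the index; pass the full
#'   reference gene set to keep genes without any usable anchor (which can
#'   never acquire counts) in the table at zero.
#' @return Tibble with one row per gene in the universe: `gene_id`,
#'   `raw_count` (genes with no uniquely mapping tag get 0). Attributes
#'   `ambiguous_copies` and `unmapped_copies` carry the excluded tallies.
#' @export
count_genes <- function(clean, index, gene_ids = NULL) {
  assert_tag_library(clean, "clean")
  if (!inherits(index, "virtual_tag_index")) {
    abort("`index` must be a virtual_tag_index")
  }
  if (is.null(gene_ids)) gene_ids <- unique(index$tags$gene_id)
  if (nrow(clean) == 0L) {
    out <- tibble(gene_id = gene_ids, raw_count = 0L)
    attr(out, "ambiguous_copies") <- 0L
    attr(out, "unmapped_copies") <- 0L
    return(out)
  }
  asg <- assign_tags(clean$tag, index)
  asg$count <- clean$count
  counts <- asg %>%
    filter(.data$status == "unique") %>%
    group_by(.data$gene_id) %>%
    summarise(raw_count = sum(.data$count), .groups = "drop")
  out <- tibble(gene_id = gene_ids) %>%
    left_join(counts, by = "gene_id") %>%
    mutate(raw_count = dplyr::coalesce(.data$raw_count, 0L))
  attr(out, "ambiguous_copies") <- sum(asg$count[asg$status == "ambiguous"])
  attr(out, "unmapped_copies") <- sum(asg$count[asg$status == "unmapped"])
  out
}

#' Normalise raw tag counts to tags per million clean tags (TPM)
#'
#' `tpm = raw_count / clean_total * 1e6`. The denominator is the *clean*
#' total of the library (all clean tags, including ambiguous and unmapped
#' copies), not the mapped total. Genes with zero counts are reported at the
#' conventional floor value (default 0.01) so fold changes stay finite; the
#' `detected` flag keeps true zeros distinguishable from tiny counts.
#'
#' @param counts Tibble with `gene_id` and `raw_count`.
#' @param clean_total Total clean tags of the library (> 0).
#' @param floor TPM value reported for zero-count genes.
#' @return The input tibble with added columns `tpm` and `detected`.
#' @export
#' @examples
#' tpm_normalize(tibble::tibble(gene_id = "g", raw_count = 50L), 5e6)
tpm_normalize <- function(counts, clean_total, floor = 0.01) {
  if (!is.data.frame(counts) || !all(c("gene_id", "raw_count") %in% names(counts))) {
    abort("`counts` must have columns `gene_id` and `raw_count`")
  }
  if (!is.numeric(clean_total) || length(clean_total) != 1L || clean_total <= 0) {
    abort("`clean_total` must be a single positive number")
  }
  counts %>%
    mutate(
      tpm = if_else(.data$raw_count > 0,
                    .data$raw_count / clean_total * 1e6, floor),
      detected = .data$raw_count > 0
    )
}

#' Quantify one clean library against a tag index
#'
#' Convenience wrapper: [count_genes()] then [tpm_normalize()] with the
#' library's own clean total as denominator.
#'
#' @inheritParams count_genes
#' @inheritParams tpm_normalize
#' @return Tibble `gene_id`, `raw_count`, `tpm`, `detected`, with attribute
#'   `clean_total` plus the mapping tallies from [count_genes()].
#' @export
quantify_library <- function(clean, index, floor = 0.01, gene_ids = NULL) {
  counts <- count_genes(clean, index, gene_ids = gene_ids)
  clean_total <- sum(clean$count)
  out <- tpm_normalize(counts, clean_total, floor = floor)
  attr(out, "clean_total") <- clean_total
  attr(out, "ambiguous_copies") <- attr(counts, "ambiguous_copies")
  attr(out, "unmapped_copies") <- attr(counts, "unmapped_copies")
  out
}
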