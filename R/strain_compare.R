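#' Partition genes by detection pattern across three strains
#'
#' A gene is "expressed" in a strain when its unambiguous clean tag count
#' meets `detect_min` (default 1, the weakest count-based rule). The eight
#' detection patterns across the triad form the Venn regions; the headline
#' number is the percentage of the gene universe expressed in at least one
#' strain.
#'
#' @param expr Long expression table: tibble with columns `gene_id`,
#'   `strain`, `raw_count`, containing exactly three strains and the same
#'   gene universe in each.
#' @param strains Optional character vector of the three strain names in
#'   display order (defaults to their order of appearance).
#' @param detect_min Minimum raw count for a gene to count as expressed.
#' @return A list of class `strain_venn`: `regions` (8-row tibble with one
#'   logical column per strain plus `n`), `pct_expressed_any` (rounded to 2
#'   decimals), `total` and `strains`.
#' @export
#' @examples
#' expr <- tidyr::expand_grid(gene_id = c("g1", "g2"),
#'                            strain = c("p1", "p2", "h"))
#' expr$raw_count <- c(5L, 0L, 2L, 0L, 0L, 0L)
#' venn_partition(expr)$pct_expressed_any
venn_partition <- function(expr, strains = NULL, detect_min = 1L) {
  if (!is.data.frame(expr) ||
      !all(c("gene_id", "strain", "raw_count") %in% names(expr))) {
    abort("`expr` must have columns `gene_id`, `strain`, `raw_count`")
  }
  if (is.null(strains)) strains <- unique(expr$strain)
  if (length(strains) != 3L) abort("exactly three strains are required")
  wide <- expr %>%
    filter(.data$strain %in% strains) %>%
    mutate(detected = .data$raw_count >= detect_min) %>%
    select("gene_id", "strain", "detected") %>%
    tidyr::pivot_wider(names_from = "strain", values_from = "detected")
  if (any(is.na(wide[strains])) || nrow(wide) * 3L !=
      nrow(expr[expr$strain %in% strains, ])) {
    abort("all three strains must cover the same gene universe exactly once")
  }
  regions <- tidyr::expand_grid(!!!setNames(rep(list(c(TRUE, FALSE)),
                                                3), strains)) %>%
    left_join(
      wide %>% count(across(all_of(strains))),
      by = strains
    ) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  total <- nrow(wide)
  none <- regions$n[!regions[[strains[1]]] & !regions[[strains[2]]] &
                      !regions[[strains[3]]]]
  structure(
    list(
      regions = regions,
      pct_expressed_any = round((total - none) / total * 100, 2),
      total = total,
      strains = strains
    ),
    class = "strain_venn"
  )
}

#' @export
print.strain_venn <- function(x, ...) {
  cat("<strain_venn>\n")
  print(x$regions, n = Inf)
  cat(sprintf("  %d genes; %.2f%% expressed in at least one strain\n",
              x$total, x$pct_expressed_any))
  invisible(x)
}

#' Classify genes by TPM fold difference between two strains
#'
#' Uses floored TPM so zero-count genes have finite ratios. A gene is "up"
#' when `tpm2 / tpm1 >= k` and "down" when `tpm1 / tpm2 >= k`.
#'
#' @param pair Tibble with columns `gene_id`, `tpm1`, `tpm2` (floored TPM).
#' @param k Fold threshold (> 1; default 3, the conventional descriptive
#'   cutoff).
#' @return List with character vectors `up` and `down`.
#' @export
#' @examples
#' fold_classify(tibble::tibble(gene_id = "g", tpm1 = 0.01, tpm2 = 775.83))
fold_classify <- function(pair, k = 3) {
  if (!is.data.frame(pair) || !all(c("gene_id", "tpm1", "tpm2") %in% names(pair))) {
    abort("`pair` must have columns `gene_id`, `tpm1`, `tpm2`")
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 1) {
    abort("`k` must be a single fold threshold > 1")
  }
  list(
    up = pair$gene_id[pair$tpm2 / pair$tpm1 >= k],
    down = pair$gene_id[pair$tpm1 / pair$tpm2 >= k]
  )
}

#' Classify heterokaryon complementation categories
#'
#' Labels each gene of a parent1/parent2/heterokaryon triad:
#' * **A** — no detectable expression in parent 1 and TPM of at least
#'   `high_tpm` in parent 2;
#' * **B** — the mirror image (silent in parent 2, expressed in parent 1);
#' * **C** — "complementation boost": at most `low_tpm` in both parents,
#'   at least `high_tpm` in the heterokaryon, and the heterokaryon at least
#'   `min_fold` times both parents;
#' * **none** — everything else.
#'
#' "No detectable expression" means a raw count of zero when raw counts are
#' supplied (columns `raw_p1`/`raw_p2`), otherwise TPM at or below
#' `undetected_tpm` (the reporting floor). Categories are mutually
#' exclusive by construction (A and B require one silent parent; C requires
#' both parents below `low_tpm` but the other parent of an A/B gene is at
#' `high_tpm` or more).
#'
#' @param triad Tibble with columns `gene_id`, `tpm_p1`, `tpm_p2`, `tpm_h`
#'   (floored TPM) and optionally `raw_p1`, `raw_p2`.
#' @param undetected_tpm TPM at or below which a gene counts as undetected
#'   when raw counts are absent (default 0.01, the floor).
#' @param low_tpm Upper TPM bound for "extreme low expression" in both
#'   parents (default 20).
#' @param high_tpm Minimum TPM for the expressed side (default 50).
#' @param min_fold Minimum heterokaryon/parent fold for category C
#'   (default 3).
#' @return The input tibble with an added `category` column
#'   (`"A"`, `"B"`, `"C"` or `"none"`).
#' @export
#' @examples
#' complementation_classify(tibble::tibble(
#'   gene_id = c("a", "b", "c"),
#'   tpm_p1 = c(0.01, 263.32, 0.01),
#'   tpm_p2 = c(775.83, 0.01, 0.01),
#'   tpm_h = c(48.93, 48.06, 3284.76)
#' ))
complementation_classify <- function(triad,
                                     undetected_tpm = 0.01,
                                     low_tpm = 20,
                                     high_tpm = 50,
                                     min_fold = 3) {
  need <- c("gene_id", "tpm_p1", "tpm_p2", "tpm_h")
  if (!is.data.frame(triad) || !all(need %in% names(triad))) {
    abort("`triad` must have columns gene_id, tpm_p1, tpm_p2, tpm_h")
  }
  undet1 <- if ("raw_p1" %in% names(triad)) triad$raw_p1 == 0 else
    triad$tpm_p1 <= undetected_tpm
  undet2 <- if ("raw_p2" %in% names(triad)) triad$raw_p2 == 0 else
    triad$tpm_p2 <= undetected_tpm
  is_a <- undet1 & triad$tpm_p2 >= high_tpm
  is_b <- undet2 & triad$tpm_p1 >= high_tpm
  is_c <- !is_a & !is_b &
    triad$tpm_p1 <= low_tpm & triad$tpm_p2 <= low_tpm &
    triad$tpm_h >= high_tpm &
    triad$tpm_h >= min_fold * triad$tpm_p1 &
    triad$tpm_h >= min_fold * triad$tpm_p2
  triad$category <- dplyr::case_when(
    is_a ~ "A",
    is_b ~ "B",
    is_c ~ "C",
    .default = "none"
  )
  triad
}
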