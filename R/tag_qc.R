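#' Filter a raw tag library into clean tags with a full accounting ledger
#'
#' Applies the standard DGE cleaning cascade, in this order: (1) tags
#' containing at least one `N` (the "low quality" class), (2) tags matching
#' an adaptor sequence, (3) tags whose remaining copy number is exactly 1
#' (sequencing-noise singletons). Singleton status is evaluated *after* the
#' first two removals, so a tag is attributed to exactly one removal class.
#' The returned ledger mirrors the classic library-characteristics table:
#' raw, the three removal classes, clean, and copy-number-threshold rows.
#'
#' @param raw Tibble with columns `tag` and `count` (one row per distinct
#'   tag).
#' @param adaptor_sequences Character vector of adaptor sequences.
#' @param adaptor_prefix If `TRUE`, a tag is an adaptor hit when it *starts
#'   with* any adaptor sequence; default is exact full-tag equality.
#' @param thresholds Copy-number thresholds for the ledger rows. The first
#'   is inclusive (`>= t`), the rest strict (`> t`), matching the
#'   conventional table labels `CopyNum >= 2`, `CopyNum > 5`, ...
#' @return A list of class `tag_qc` with `clean` (surviving `tag`/`count`
#'   tibble) and `accounting` (a `qc_accounting` tibble with columns `row`,
#'   `distinct`, `total`).
#' @export
#' @examples
#' raw <- tibble::tibble(tag = c("CATGA", "CATGN", "CATGC"),
#'                       count = c(10L, 2L, 1L))
#' filter_tags(raw, adaptor_sequences = character())$accounting
filter_tags <- function(raw,
                        adaptor_sequences = default_adaptors(),
                        adaptor_prefix = FALSE,
                        thresholds = c(2, 5, 10, 20, 50, 100)) {
  assert_tag_library(raw, "raw")
  raw_distinct <- nrow(raw)
  raw_total <- sum(raw$count)

  is_n <- grepl("N", raw$tag, fixed = TRUE)
  after_n <- raw[!is_n, ]

  if (length(adaptor_sequences) == 0) {
    is_adaptor <- rep(FALSE, nrow(after_n))
  } else if (adaptor_prefix) {
    pat <- paste0("^(", paste(adaptor_sequences, collapse = "|"), ")")
    is_adaptor <- grepl(pat, after_n$tag)
  } else {
    is_adaptor <- after_n$tag %in% adaptor_sequences
  }
  after_adaptor <- after_n[!is_adaptor, ]

  is_singleton <- after_adaptor$count == 1L
  clean <- after_adaptor[!is_singleton, ]

  acc <- tibble(
    row = c("raw", "n_containing", "adaptor", "singleton", "clean"),
    distinct = c(raw_distinct, sum(is_n), sum(is_adaptor),
                 sum(is_singleton), nrow(clean)),
    total = c(raw_total, sum(raw$count[is_n]),
              sum(after_n$count[is_adaptor]),
              sum(after_adaptor$count[is_singleton]), sum(clean$count))
  )
  acc <- bind_rows(acc, threshold_table(clean, thresholds))
  class(acc) <- c("qc_accounting", class(acc))
  structure(list(clean = clean, accounting = acc), class = "tag_qc")
}

#' Copy-number-threshold rows of the library ledger
#'
#' For a clean (singleton-free) library, reports how many distinct tags and
#' how many total tag copies survive each copy-number threshold. The first
#' threshold is inclusive (`>=`), subsequent ones strict (`>`), matching the
#' conventional ledger labels.
#'
#' @param clean Tibble with `tag` and `count` columns (already
#'   singleton-free).
#' @param thresholds Numeric vector of thresholds.
#' @return Tibble with columns `row` (e.g. `"copynum_ge_2"`,
#'   `"copynum_gt_5"`), `distinct` and `total`.
#' @export
#' @examples
#' threshold_table(tibble::tibble(tag = c("a", "b", "c"),
#'                                count = c(2L, 6L, 101L)))
threshold_table <- function(clean, thresholds = c(2, 5, 10, 20, 50, 100)) {
  assert_tag_library(clean, "clean")
  purrr::imap_dfr(as.list(thresholds), function(t, i) {
    keep <- if (i == 1L) clean$count >= t else clean$count > t
    tibble(
      row = sprintf("copynum_%s_%g", if (i == 1L) "ge" else "gt", t),
      distinct = sum(keep),
      total = sum(clean$count[keep])
    )
  })
}

#' @export
print.tag_qc <- function(x, ...) {
  cat("<tag_qc>\n")
  print(as_tibble(x$accounting), n = Inf)
  invisible(x)
}

#' @describeIn filter_tags Bar chart of the accounting ledger (distinct and
#'   total tags per ledger row).
#' @param object A `qc_accounting` tibble.
#' @param ... Unused.
#' @export
autoplot.qc_accounting <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("distinct", "total"),
                            names_to = "measure", values_to = "n")
  df$row <- factor(df$row, levels = unique(object$row))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_y_continuous(labels = scales_comma) +
    ggplot2::labs(x = NULL, y = "tags", title = "Tag library accounting") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# minimal comma formatter so we do not depend on the scales package directly
scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE)
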