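#' Audic-Claverie tag-count probability mass
#'
#' Probability of observing `y` tags for a gene in a library of depth `N2`
#' given `x` tags in a library of depth `N1`, under the exact model for
#' comparing two digital (SAGE-style) tag libraries:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' This is the posterior predictive of a Poisson rate under a flat prior and
#' equals a negative-binomial mass with size `x + 1` and success probability
#' `N1/(N1+N2)`. Evaluated in log space via `lgamma` for stability;
#' vectorised over all arguments.
#'
#' @param x,y Tag counts (non-negative integers).
#' @param N1,N2 Library depths (clean totals, > 0).
#' @return Probability mass, same length as the longest argument.
#' @export
#' @examples
#' ac_probability(0, 0, 1e6, 1e6)  # 0.5
ac_probability <- function(x, y, N1, N2) {
  check_ac_args(x, y, N1, N2)
  r <- N2 / N1
  exp(lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) +
        y * log(r) - (x + y + 1) * log1p(r))
}

#' Two-sided Audic-Claverie p-value
#'
#' Doubles the smaller of the two tails of the conditional distribution of
#' `y` given `x` (lower tail \eqn{\sum_{k \le y} p(k|x)}, upper tail
#' \eqn{\sum_{k \ge y} p(k|x)}), capped at 1. Tails are computed through the
#' negative-binomial/regularised-incomplete-beta identity, so they are
#' stable at genome-scale depths without explicit summation. The statistic
#' is symmetric under swapping `(x, N1)` with `(y, N2)`.
#'
#' @inheritParams ac_probability
#' @return Two-sided p-value in (0, 1], vectorised.
#' @export
#' @examples
#' ac_pvalue_two_sided(10, 30, 1e6, 1e6)
ac_pvalue_two_sided <- function(x, y, N1, N2) {
  check_ac_args(x, y, N1, N2)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  p <- N1 / (N1 + N2)
  # P(Y <= y) = I_p(x + 1, y + 1); P(Y >= y) = 1 - I_p(x + 1, y)
  lower <- pbeta(p, x + 1, y + 1)
  upper <- ifelse(y == 0, 1,
                  pbeta(p, x + 1, pmax(y, 1), lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

check_ac_args <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) abort("tag counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) abort("library depths must be positive")
  invisible(TRUE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up procedure: order p-values, multiply by `n / rank`, then
#' enforce monotonicity with a cumulative minimum from the largest rank
#' down, capping at 1. Input order is preserved in the output.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order and length as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * pvalues[o]))
  adj[ro]
}

#' Call differentially expressed genes between two tag libraries
#'
#' Implements the full two-library calling rule for digital tag counts:
#' genes with raw count at or below `intensity_floor` in *both* libraries
#' are prefiltered (they receive no p-value and can never be significant);
#' the remaining genes are tested with the two-sided Audic-Claverie exact
#' test and BH-adjusted over the tested set only. Fold changes are computed
#' on floored TPM so zero-count genes have finite log-ratios. A gene is
#' significant when `p < p_threshold`, `fdr <= fdr_threshold` and
#' `|log2fc| > fc_threshold_log2`.
#'
#' @param counts Tibble with columns `gene_id`, `x` (counts in library 1)
#'   and `y` (counts in library 2).
#' @param N1,N2 Clean totals of libraries 1 and 2.
#' @param fc_threshold_log2 Minimum absolute log2 fold change (default 2,
#'   i.e. 4-fold).
#' @param p_threshold P-value cutoff (default 0.005).
#' @param fdr_threshold FDR cutoff (default 0.001).
#' @param intensity_floor Raw-count prefilter (default 40): genes at or
#'   below this in both libraries are excluded from testing.
#' @param tpm_floor TPM floor used for fold changes (default 0.01).
#' @return A tibble of class `dge_de` with columns `gene_id`, `x`, `y`,
#'   `tpm1`, `tpm2`, `log2fc` (library 2 over library 1), `p`, `fdr`,
#'   `prefiltered`, `significant`; thresholds and depths in attributes.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), x = c(0L, 30L),
#'                          y = c(500L, 35L))
#' call_de(counts, N1 = 1e6, N2 = 1e6)
call_de <- function(counts, N1, N2,
                    fc_threshold_log2 = 2,
                    p_threshold = 0.005,
                    fdr_threshold = 0.001,
                    intensity_floor = 40,
                    tpm_floor = 0.01) {
  if (!is.data.frame(counts) || !all(c("gene_id", "x", "y") %in% names(counts))) {
    abort("`counts` must have columns `gene_id`, `x`, `y`")
  }
  out <- as_tibble(counts[, c("gene_id", "x", "y")])
  out <- out %>%
    mutate(
      tpm1 = if_else(.data$x > 0, .data$x / N1 * 1e6, tpm_floor),
      tpm2 = if_else(.data$y > 0, .data$y / N2 * 1e6, tpm_floor),
      log2fc = log2(.data$tpm2 / .data$tpm1),
      prefiltered = .data$x <= intensity_floor & .data$y <= intensity_floor,
      p = NA_real_,
      fdr = NA_real_
    )
  tested <- !out$prefiltered
  if (any(tested)) {
    out$p[tested] <- ac_pvalue_two_sided(out$x[tested], out$y[tested], N1, N2)
    out$fdr[tested] <- bh_fdr(out$p[tested])
  }
  out <- out %>%
    mutate(significant = !.data$prefiltered &
             !is.na(.data$p) & .data$p < p_threshold &
             .data$fdr <= fdr_threshold &
             abs(.data$log2fc) > fc_threshold_log2)
  attr(out, "N1") <- N1
  attr(out, "N2") <- N2
  attr(out, "thresholds") <- list(
    fc_threshold_log2 = fc_threshold_log2, p_threshold = p_threshold,
    fdr_threshold = fdr_threshold, intensity_floor = intensity_floor,
    tpm_floor = tpm_floor
  )
  class(out) <- c("dge_de", class(out))
  out
}

#' @export
tidy.dge_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dge_de")
  attr(out, "N1") <- attr(out, "N2") <- attr(out, "thresholds") <- NULL
  as_tibble(out)
}

#' @export
glance.dge_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x),
    n_prefiltered = sum(x$prefiltered),
    n_tested = sum(!x$prefiltered),
    n_significant = sum(x$significant),
    N1 = attr(x, "N1"),
    N2 = attr(x, "N2"),
    p_threshold = th$p_threshold,
    fdr_threshold = th$fdr_threshold,
    fc_threshold_log2 = th$fc_threshold_log2,
    intensity_floor = th$intensity_floor
  )
}

#' MA-style plot of a two-library comparison
#'
#' Mean floored TPM (log10) against log2 fold change, coloured by
#' significance; prefiltered genes are drawn hollow.
#'
#' @param object A `dge_de` result from [call_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dge_de <- function(object, ...) {
  df <- tidy(object)
  df$mean_tpm <- (df$tpm1 + df$tpm2) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_tpm, y = .data$log2fc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant,
                                     shape = .data$prefiltered),
                        alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "mean TPM (floored)", y = "log2 fold change",
                  title = "Two-library tag-count comparison") +
    ggplot2::theme_minimal()
}
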