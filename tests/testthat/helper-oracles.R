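# Independent brute-force oracles used across the suite. These deliberately
# share no code path with the package implementation they check.

# Exhaustive Hamming-distance computation between one query and every index
# key, applying the exact-first priority rule by scanning, not hashing.
oracle_assign <- function(tag, index_tbl) {
  keys <- index_tbl$tag
  d <- vapply(keys, function(k) {
    sum(utf8ToInt(k) != utf8ToInt(tag))
  }, integer(1), USE.NAMES = FALSE)
  level <- if (any(d == 0L)) 0L else if (any(d == 1L)) 1L else NA_integer_
  if (is.na(level)) {
    return(list(status = "unmapped", gene = NA_character_))
  }
  genes <- unique(index_tbl$gene_id[d == level])
  if (length(genes) == 1L) {
    list(status = "unique", gene = genes)
  } else {
    list(status = "ambiguous", gene = NA_character_)
  }
}

# Audic-Claverie mass by direct log-space evaluation (no shared helper).
oracle_ac_mass <- function(x, y, N1, N2) {
  r <- N2 / N1
  exp(lchoose(x + y, y) + y * log(r) - (x + y + 1) * log(1 + r))
}

# Tail sums by brute-force accumulation of the mass. The upper tail is
# summed until terms fall below machine noise relative to the total.
oracle_ac_tails <- function(x, y, N1, N2) {
  lower <- sum(oracle_ac_mass(x, 0:y, N1, N2))
  k <- y
  upper <- 0
  repeat {
    term <- oracle_ac_mass(x, k, N1, N2)
    upper <- upper + term
    k <- k + 1
    if (term < 1e-18 * max(upper, 1e-300) && k > y + 50) break
    if (k > y + 500000) break
  }
  list(lower = lower, upper = upper)
}

# Brute-force agglomerative clustering: repeatedly merge the closest pair
# of clusters under the requested linkage, recomputing all pairwise
# point distances each round. Returns merge heights and member sets.
oracle_agglomerate <- function(m, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  merges <- list()
  pdist <- as.matrix(dist(m))
  cluster_d <- function(a, b) {
    vals <- pdist[a, b, drop = FALSE]
    if (linkage == "average") mean(vals) else min(vals)
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- cluster_d(clusters[[i]], clusters[[j]])
          if (d < bestd) {
            bestd <- d
            best <- c(i, j)
          }
        }
      }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Fast generation of n random distinct 21-mers.
rand_tags <- function(n, L = 21L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(c("A", "C", "G", "T"), (need + 50) * L, replace = TRUE),
                ncol = L)
    out <- unique(c(out, do.call(paste0, as.data.frame(m))))
  }
  out[seq_len(n)]
}

# Build a raw library with prescribed ledger marginals: `n_n` distinct
# N-containing tags totalling `t_n` copies, `n_ad` distinct adaptor tags
# totalling `t_ad`, `n_single` singletons, and `n_clean` clean tags
# totalling `t_clean` (each clean tag gets at least 2 copies). Returns the
# library plus its adaptor list. Used to exercise the accounting arithmetic
# on library-scale inputs where only the ledger marginals are prescribed.
make_ledger_library <- function(n_n, t_n, n_ad, t_ad, n_single,
                                n_clean, t_clean, seed = 1) {
  stopifnot(t_n >= n_n, t_ad >= n_ad, t_clean >= 2 * n_clean)
  withr::with_seed(seed, {
    pool <- rand_tags(n_ad + n_single + n_clean)
    ad <- pool[seq_len(n_ad)]
    singles <- pool[n_ad + seq_len(n_single)]
    cleans <- pool[n_ad + n_single + seq_len(n_clean)]
    clean_counts <- rep(2L, n_clean)
    if (n_clean > 0) clean_counts[1] <- clean_counts[1] + (t_clean - 2L * n_clean)
    ntags <- paste0("N", substr(rand_tags(n_n), 1L, 20L))
    n_counts <- rep(1L, n_n)
    if (n_n > 0) n_counts[1] <- n_counts[1] + (t_n - n_n)
    ad_counts <- rep(1L, n_ad)
    if (n_ad > 0) ad_counts[1] <- ad_counts[1] + (t_ad - n_ad)
    list(
      raw = tibble::tibble(
        tag = c(ntags, ad, singles, cleans),
        count = c(n_counts, ad_counts, rep(1L, n_single), clean_counts)
      ),
      adaptors = ad
    )
  })
}

# Small deterministic toy gene set with hand-placed CATG anchors.
toy_genes <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:5),
    sequence = c(
      paste0("TT", "CATG", strrep("A", 17), "GG"),             # one site
      paste0("CATG", strrep("C", 17), "CATG", strrep("G", 17)),# two sites
      paste0("AAAA", "CATG", paste(rep(c("A","C","G","T"), 5)[1:17],
                                   collapse = ""), "T"),
      paste0("GG", "CATG", strrep("T", 17)),                   # one site
      paste0("TTTT", strrep("A", 30))                          # no site
    )
  )
}
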