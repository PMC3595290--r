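#' Build a virtual tag index from predicted gene models
#'
#' Scans every transcript on the sense strand for the NlaIII anchor `CATG`
#' and records each anchor that has at least `tag_length - 4` nt of
#' downstream sequence as one virtual tag (anchor + downstream bases).
#' Windows containing `N` are skipped. A tag found in two or more genes maps
#' to the set of those genes; such tags can only ever be called ambiguous.
#'
#' All anchors are indexed, not only the 3'-most one: observed tags come
#' from the 3'-most site by construction of the assay, but mapping against
#' every site is the permissive reading and extra sites only add ambiguity,
#' which is excluded downstream anyway.
#'
#' @param genes Tibble with columns `gene_id` and `sequence` (A/C/G/T/N).
#' @param tag_length Tag length in nucleotides (>= 5; default 21 = CATG + 17).
#' @return An object of class `virtual_tag_index`: a list with `tags` (tibble
#'   `tag`, `gene_id`, one row per tag-gene pair), `tag_length` and
#'   `n_genes`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1",
#'                         sequence = "AACATGAAAAAAAAAAAAAAAAAGG")
#' extract_virtual_tags(genes)$tags
extract_virtual_tags <- function(genes, tag_length = 21L) {
  assert_count(tag_length, "tag_length", min = 5L)
  if (!is.data.frame(genes) || !all(c("gene_id", "sequence") %in% names(genes))) {
    abort("`genes` must have columns `gene_id` and `sequence`")
  }
  tag_length <- as.integer(tag_length)
  entries <- purrr::map2(genes$gene_id, genes$sequence, function(id, seq) {
    hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    hits <- hits[hits + tag_length - 1L <= nchar(seq)]
    if (length(hits) == 0L) return(NULL)
    tags <- substring(seq, hits, hits + tag_length - 1L)
    tags <- tags[!grepl("N", tags, fixed = TRUE)]
    if (length(tags) == 0L) return(NULL)
    tibble(tag = unique(tags), gene_id = id)
  })
  tags <- bind_rows(entries)
  if (nrow(tags) == 0L) {
    tags <- tibble(tag = character(), gene_id = character())
  }
  structure(
    list(tags = tags, tag_length = tag_length, n_genes = nrow(genes)),
    class = "virtual_tag_index"
  )
}

#' @export
print.virtual_tag_index <- function(x, ...) {
  n_multi <- sum(table(x$tags$tag) > 1L)
  cat("<virtual_tag_index>\n")
  cat(sprintf("  %d tag-gene entries (%d distinct tags, %d shared) from %d genes; tag length %d\n",
              nrow(x$tags), length(unique(x$tags$tag)), n_multi,
              x$n_genes, x$tag_length))
  invisible(x)
}

#' Assign observed tags to genes with exact-first, one-mismatch fallback
#'
#' Each query tag is looked up in the virtual tag index. Exact hits take
#' strict priority; only tags with no exact hit are searched against the
#' Hamming-distance-1 neighbourhood. A tag is `unique` when the gene set at
#' the winning priority level has exactly one member, `ambiguous` when it
#' has two or more (such tags are excluded from counting), and `unmapped`
#' when it is empty.
#'
#' @param tags Character vector of query tags (all of the index tag length).
#' @param index A [extract_virtual_tags()] index.
#' @return A tibble with one row per query: `tag`, `status`
#'   (`unique`/`ambiguous`/`unmapped`), `gene_id` (`NA` unless unique) and
#'   `match_type` (`exact`/`one_mismatch`/`NA`).
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1",
#'                         sequence = "AACATGAAAAAAAAAAAAAAAAAGG")
#' idx <- extract_virtual_tags(genes)
#' assign_tags("CATGAAAAAAAAAAAAAAAAA", idx)
assign_tags <- function(tags, index) {
  if (!inherits(index, "virtual_tag_index")) {
    abort("`index` must be a virtual_tag_index")
  }
  if (length(tags) == 0L) {
    return(tibble(tag = character(), status = character(),
                  gene_id = character(), match_type = character()))
  }
  if (any(nchar(tags) != index$tag_length)) {
    abort(sprintf("all query tags must have length %d", index$tag_length))
  }

  res <- tibble(
    tag = tags,
    status = "unmapped",
    gene_id = NA_character_,
    match_type = NA_character_
  )

  idx_tags <- index$tags
  # exact level
  exact <- tibble(tag = tags, .q = seq_along(tags)) %>%
    inner_join(idx_tags, by = "tag", relationship = "many-to-many") %>%
    group_by(.data$.q) %>%
    summarise(n_gene = dplyr::n_distinct(.data$gene_id),
              gene_id = .data$gene_id[1], .groups = "drop")
  if (nrow(exact)) {
    res$status[exact$.q] <- if_else(exact$n_gene == 1L, "unique", "ambiguous")
    res$gene_id[exact$.q] <- if_else(exact$n_gene == 1L, exact$gene_id,
                                     NA_character_)
    res$match_type[exact$.q] <- "exact"
  }

  # one-mismatch level for tags with no exact hit, in memory-bounded chunks
  miss <- which(res$status == "unmapped")
  chunk <- 20000L
  while (length(miss)) {
    take <- miss[seq_len(min(chunk, length(miss)))]
    miss <- miss[-seq_len(min(chunk, length(miss)))]
    nb <- hamming1_neighbours(res$tag[take], index$tag_length)
    hits <- nb %>%
      inner_join(idx_tags, by = c(neighbour = "tag"),
                 relationship = "many-to-many") %>%
      group_by(.data$.q) %>%
      summarise(n_gene = dplyr::n_distinct(.data$gene_id),
                gene_id = .data$gene_id[1], .groups = "drop")
    if (nrow(hits)) {
      q <- take[hits$.q]
      res$status[q] <- if_else(hits$n_gene == 1L, "unique", "ambiguous")
      res$gene_id[q] <- if_else(hits$n_gene == 1L, hits$gene_id, NA_character_)
      res$match_type[q] <- "one_mismatch"
    }
  }
  res
}

#' @rdname assign_tags
#' @param tag A single query tag.
#' @export
assign_tag <- function(tag, index) {
  if (length(tag) != 1L) abort("`tag` must be a single sequence")
  assign_tags(tag, index)
}

# All 3*L Hamming-distance-1 variants of each query, as a tibble
# (.q = query position, neighbour = variant sequence). Variants containing
# the original base are skipped so exactly the distance-1 shell is produced.
hamming1_neighbours <- function(tags, L) {
  m <- length(tags)
  reps <- 3L * L
  q <- rep(seq_len(m), each = reps)
  seqs <- rep(tags, each = reps)
  pos <- rep(rep(seq_len(L), each = 3L), times = m)
  orig <- substr(seqs, pos, pos)
  # per position, the three substitute bases are the non-original ones;
  # pick them by offsetting within DNA_BASES
  slot <- rep(rep(1:3, times = L), times = m)
  base_idx <- match(orig, DNA_BASES)
  base_idx[is.na(base_idx)] <- 0L  # N etc.: all four bases are substitutes
  sub <- DNA_BASES[((base_idx %% 4L) + slot - 1L) %% 4L + 1L]
  keep <- sub != orig
  seqs <- seqs[keep]
  substr(seqs, pos[keep], pos[keep]) <- sub[keep]
  tibble(.q = q[keep], neighbour = seqs)
}
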