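CAZY_CLASSES <- c("GH", "GT", "PL", "CE")

#' CAZy class of a family label
#'
#' Extracts the enzyme class (`GH`, `GT`, `PL`, `CE`) from family labels
#' such as `"GH10"`, `"PL1"`, or bare class labels like `"GH"`.
#'
#' @param family Character vector of family labels.
#' @return Character vector of classes; `NA` for unrecognised labels.
#' @export
#' @examples
#' cazy_class(c("GH10", "CE12", "PL1"))
cazy_class <- function(family) {
  cls <- stringr::str_extract(family, "^(GH|GT|PL|CE)")
  cls
}

#' Per-class CAZyme gene counts from an annotation table
#'
#' Sums a gene-to-family annotation into counts per enzyme class
#' (glycoside hydrolases GH, glycosyltransferases GT, polysaccharide lyases
#' PL, carbohydrate esterases CE) plus the grand total.
#'
#' @param annotation Tibble with columns `gene_id` and `family`.
#' @return Tibble with columns `class` (the four classes, fixed order) and
#'   `n`; the grand total is the attribute `total` and also the `total`
#'   column of `glance`-style use via `sum(out$n)`.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = paste0("g", 1:3),
#'                       family = c("GH10", "GH43", "PL1"))
#' class_totals(ann)
class_totals <- function(annotation) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "family") %in% names(annotation))) {
    abort("`annotation` must have columns `gene_id` and `family`")
  }
  cls <- cazy_class(annotation$family)
  if (any(is.na(cls))) {
    bad <- annotation[is.na(cls), ]
    abort(paste0(
      "unresolvable CAZy families: ",
      paste(sprintf("%s (%s)", bad$family, bad$gene_id), collapse = ", ")
    ))
  }
  out <- tibble(class = factor(cls, levels = CAZY_CLASSES)) %>%
    count(.data$class, .drop = FALSE) %>%
    mutate(class = as.character(.data$class))
  attr(out, "total") <- sum(out$n)
  out
}

assert_family_matrix <- function(mat) {
  if (!is.data.frame(mat) ||
      !all(c("genome", "family", "count") %in% names(mat))) {
    abort("a family abundance matrix must have columns `genome`, `family`, `count`")
  }
  if (any(mat$count < 0)) abort("family counts must be non-negative")
  invisible(TRUE)
}

# Class totals per genome from a tidy genome x family count table.
genome_class_totals <- function(mat, class) {
  cls <- cazy_class(mat$family)
  if (any(is.na(cls))) {
    abort(paste0("unresolvable CAZy families: ",
                 paste(unique(mat$family[is.na(cls)]), collapse = ", ")))
  }
  mat %>%
    mutate(.class = cls) %>%
    filter(.data$.class == class) %>%
    group_by(.data$genome) %>%
    summarise(n = sum(.data$count), .groups = "drop")
}

#' Average class count across a genome lineage
#'
#' Arithmetic mean of one enzyme class's total gene count over a subset of
#' genomes, rounded half away from zero to an integer (the convention that
#' turns 160.75 into 161 and 65.375 into 65).
#'
#' @param mat Tidy family abundance matrix: tibble with columns `genome`,
#'   `family`, `count`. Family labels may be family-level (`GH10`) or
#'   class-level (`GH`).
#' @param genomes Non-empty character vector: the lineage subset.
#' @param class One of `"GH"`, `"GT"`, `"PL"`, `"CE"`.
#' @return A single integer.
#' @export
lineage_average <- function(mat, genomes, class) {
  assert_family_matrix(mat)
  if (length(genomes) == 0L) abort("`genomes` must be non-empty")
  if (!class %in% CAZY_CLASSES) abort("`class` must be one of GH, GT, PL, CE")
  missing <- setdiff(genomes, unique(mat$genome))
  if (length(missing)) {
    abort(paste0("genomes not in matrix: ", paste(missing, collapse = ", ")))
  }
  totals <- genome_class_totals(mat, class)
  vals <- totals$n[match(genomes, totals$genome)]
  vals[is.na(vals)] <- 0
  as.integer(round_half_away(mean(vals)))
}

#' Rank a genome by its total CAZyme count
#'
#' Descending rank of the genome's grand total among all genomes in the
#' matrix (1 = largest repertoire); ties share the minimum rank.
#'
#' @inheritParams lineage_average
#' @param genome A genome label present in the matrix.
#' @return Integer rank.
#' @export
rank_by_total <- function(mat, genome) {
  assert_family_matrix(mat)
  totals <- mat %>%
    group_by(.data$genome) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (!genome %in% totals$genome) {
    abort(sprintf("unknown genome: %s", genome))
  }
  ranks <- rank(-totals$total, ties.method = "min")
  as.integer(ranks[match(genome, totals$genome)])
}

#' Genome(s) with the largest class count in a lineage
#'
#' @inheritParams lineage_average
#' @return List with `genomes` (character vector; length > 1 on ties) and
#'   `count`.
#' @export
max_in_lineage <- function(mat, genomes, class) {
  assert_family_matrix(mat)
  if (length(genomes) == 0L) abort("`genomes` must be non-empty")
  if (!class %in% CAZY_CLASSES) abort("`class` must be one of GH, GT, PL, CE")
  totals <- genome_class_totals(mat, class)
  vals <- totals$n[match(genomes, totals$genome)]
  vals[is.na(vals)] <- 0
  best <- max(vals)
  list(genomes = genomes[vals == best], count = best)
}

#' Double hierarchical clustering of a family abundance matrix
#'
#' Clusters rows (families) and columns (genomes) independently by
#' agglomerative hierarchical clustering, the standard presentation of
#' comparative CAZyme repertoires as a doubly ordered heatmap.
#'
#' @param mat Tidy family abundance matrix (`genome`, `family`, `count`),
#'   at least 2 genomes and 2 families (a single-row/column dimension is
#'   returned as a single leaf without a dendrogram).
#' @param distance Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`, on raw counts).
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return A list of class `cazy_bicluster`: `matrix` (families x genomes,
#'   input counts), `row_order`/`col_order` (leaf-ordered labels),
#'   `row_hclust`/`col_hclust` (`hclust` objects or `NULL` for single
#'   leaves), and `constant` (flag: all counts equal, ordering arbitrary).
#' @export
bicluster <- function(mat, distance = "euclidean", linkage = "average") {
  assert_family_matrix(mat)
  wide <- mat %>%
    tidyr::pivot_wider(names_from = "genome", values_from = "count",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$family
  constant <- length(unique(as.vector(m))) == 1L
  if (constant) {
    warn("constant abundance matrix: cluster order is arbitrary")
  }
  cluster_dim <- function(x) {
    if (nrow(x) < 2L) {
      return(list(hc = NULL, order = rownames(x)))
    }
    hc <- hclust(dist(x, method = distance), method = linkage)
    list(hc = hc, order = rownames(x)[hc$order])
  }
  rows <- cluster_dim(m)
  cols <- cluster_dim(t(m))
  structure(
    list(matrix = m,
         row_order = rows$order, col_order = cols$order,
         row_hclust = rows$hc, col_hclust = cols$hc,
         constant = constant,
         distance = distance, linkage = linkage),
    class = "cazy_bicluster"
  )
}

#' @export
print.cazy_bicluster <- function(x, ...) {
  cat("<cazy_bicluster>\n")
  cat(sprintf("  %d families x %d genomes (%s distance, %s linkage)\n",
              nrow(x$matrix), ncol(x$matrix), x$distance, x$linkage))
  cat("  genome order:", paste(x$col_order, collapse = ", "), "\n")
  invisible(x)
}

#' Write a bicluster dendrogram as Newick
#'
#' @param x A [bicluster()] result.
#' @param which `"row"` (families) or `"col"` (genomes).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(x, which = c("col", "row"), path) {
  which <- match.arg(which)
  hc <- if (which == "col") x$col_hclust else x$row_hclust
  if (is.null(hc)) abort("that dimension is a single leaf; no dendrogram")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Heatmap of a double-clustered family abundance matrix
#'
#' Rows and columns follow the cluster leaf orders; the fill scale is
#' clipped at 20 counts (everything above 20 shares the top colour), the
#' conventional presentation for family-level CAZyme heatmaps.
#'
#' @param object A [bicluster()] result.
#' @param clip Upper clip of the colour scale (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cazy_bicluster <- function(object, clip = 20, ...) {
  df <- as_tibble(object$matrix, rownames = "family") %>%
    tidyr::pivot_longer(-"family", names_to = "genome", values_to = "count") %>%
    mutate(
      family = factor(.data$family, levels = rev(object$row_order)),
      genome = factor(.data$genome, levels = object$col_order),
      clipped = pmin(.data$count, clip)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome, y = .data$family,
                                   fill = .data$clipped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "red",
                                 limits = c(0, clip),
                                 name = sprintf("genes\n(clip >%d)", clip)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Double clustering of CAZyme families") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bundled CAZyme class counts for 15 sequenced fungal genomes
#'
#' Loads the packaged genome-by-class CAZyme gene count table (8
#' basidiomycetes and 7 ascomycetes) used in the comparative examples: for
#' each genome, the number of annotated glycoside hydrolase (GH),
#' glycosyltransferase (GT), polysaccharide lyase (PL) and carbohydrate
#' esterase (CE) genes.
#'
#' @return Tidy tibble with columns `genome`, `family` (class-level labels),
#'   `count` and `lineage` (`basidiomycete`/`ascomycete`).
#' @export
fungal_cazyme_counts <- function() {
  path <- system.file("extdata", "fungal_cazyme_class_counts.tsv",
                      package = "tagdge", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Bundled heterokaryon complementation example TPM triples
#'
#' Loads the packaged table of representative genes with their TPM in two
#' homokaryotic parents and the heterokaryon, grouped by complementation
#' panel (silent in parent 1, silent in parent 2, extreme low in both).
#'
#' @return Tibble with columns `gene_id`, `panel`, `tpm_p1`, `tpm_p2`,
#'   `tpm_h`.
#' @export
complementation_examples <- function() {
  path <- system.file("extdata", "heterokaryon_complementation_tpm.tsv",
                      package = "tagdge", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
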