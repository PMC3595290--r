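#' Read gene models from a FASTA file
#'
#' @param path FASTA file of predicted transcript sequences.
#' @return Tibble with `gene_id` (FASTA record name up to the first space)
#'   and `sequence`.
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    gene_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' Write gene models to a FASTA file
#'
#' @param genes Tibble with `gene_id` and `sequence`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(setNames(genes$sequence, genes$gene_id))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a tag library from a tag-count TSV
#'
#' Expects two columns `tag` and `count`; duplicate tag rows are aggregated.
#'
#' @param path TSV path.
#' @return Tibble with `tag` and `count`.
#' @export
read_tag_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("tag TSV not found: %s", path))
  lib <- readr::read_tsv(path, col_types = readr::cols(
    tag = readr::col_character(), count = readr::col_integer()
  ))
  lib %>%
    group_by(.data$tag) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Write a tag library as TSV
#'
#' @param lib Tibble with `tag` and `count`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tag_tsv <- function(lib, path) {
  assert_tag_library(lib, "lib")
  readr::write_tsv(lib, path)
  invisible(path)
}

#' Read a tag library from FASTQ
#'
#' Only the sequence lines are used (tag protocols carry no per-base
#' quality information worth modelling here); identical reads are tallied
#' into copy counts.
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return Tibble with `tag` and `count`.
#' @export
read_tags_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readr::read_lines(path)
  if (length(lines) %% 4L != 0L) {
    abort("FASTQ file is truncated (line count not a multiple of 4)")
  }
  tally_tags(lines[seq(2L, length(lines), by = 4L)])
}

#' Write a tag library as FASTQ with dummy qualities
#'
#' Each copy of each tag becomes one read; qualities are a constant `I`.
#'
#' @param lib Tibble with `tag` and `count`.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @return The path, invisibly.
#' @export
write_tags_fastq <- function(lib, path, prefix = "tag") {
  assert_tag_library(lib, "lib")
  reads <- rep(lib$tag, lib$count)
  qual <- strrep("I", nchar(reads))
  out <- paste0("@", prefix, "_", seq_along(reads), "\n", reads, "\n+\n", qual)
  readr::write_lines(out, path)
  invisible(path)
}

#' Read a gene-to-CAZy-family annotation TSV
#'
#' @param path TSV with columns `gene_id` and `family`.
#' @return Tibble.
#' @export
read_cazy_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation TSV not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), family = readr::col_character()
  ))
}

#' Read a tidy genome-by-family abundance TSV
#'
#' @param path TSV with columns `genome`, `family`, `count`.
#' @return Tibble.
#' @export
read_family_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("family matrix TSV not found: %s", path))
  mat <- readr::read_tsv(path, show_col_types = FALSE)
  assert_family_matrix(mat)
  mat
}
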