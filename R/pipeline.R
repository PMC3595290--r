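#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end tag pipeline with defaults that
#' match the module-level defaults exactly: tag geometry, QC thresholds,
#' the TPM floor, differential-expression calling thresholds, the detection
#' rule, complementation thresholds and clustering choices.
#'
#' @param simulation A [simulation_params()] object, or `NULL` to run from
#'   files (`gene_fasta` plus `tag_files`).
#' @param gene_fasta Path to transcript FASTA (ignored when simulating).
#' @param tag_files Named list/vector of three tag TSV paths (`p1`, `p2`,
#'   `h`); ignored when simulating.
#' @param cazy_annotation Optional path to a gene-to-family TSV; enables the
#'   CAZyme summary stage.
#' @param tag_length Tag length (nt).
#' @param adaptor_sequences Adaptor list for QC.
#' @param copy_thresholds Ledger copy-number thresholds.
#' @param tpm_floor Reporting floor for undetected genes.
#' @param p_threshold,fdr_threshold,fc_threshold_log2,intensity_floor
#'   Differential-expression calling thresholds.
#' @param detect_min Detection rule (minimum raw count).
#' @param fold_k Descriptive fold threshold for pairwise up/down sets.
#' @param comp_low_tpm,comp_high_tpm,comp_min_fold Complementation
#'   category thresholds.
#' @param cluster_distance,cluster_linkage Double-clustering choices.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed forwarded to the simulation when `simulation` is given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_params(),
                            gene_fasta = NULL,
                            tag_files = NULL,
                            cazy_annotation = NULL,
                            tag_length = 21L,
                            adaptor_sequences = default_adaptors(),
                            copy_thresholds = c(2, 5, 10, 20, 50, 100),
                            tpm_floor = 0.01,
                            p_threshold = 0.005,
                            fdr_threshold = 0.001,
                            fc_threshold_log2 = 2,
                            intensity_floor = 40,
                            detect_min = 1L,
                            fold_k = 3,
                            comp_low_tpm = 20,
                            comp_high_tpm = 50,
                            comp_min_fold = 3,
                            cluster_distance = "euclidean",
                            cluster_linkage = "average",
                            out_dir = tempfile("tagdge_run_"),
                            seed = NULL) {
  if (is.null(simulation) && (is.null(gene_fasta) || is.null(tag_files))) {
    abort("either `simulation` or both `gene_fasta` and `tag_files` must be given")
  }
  if (!is.null(simulation) && !is.null(seed)) {
    simulation$seed <- as.integer(seed)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full three-strain tag pipeline
#'
#' Orchestrates every stage over one configuration: (optional) simulation of
#' gene models and raw libraries, virtual-tag index construction, QC with
#' full accounting, per-gene quantification, the three pairwise
#' differential-expression comparisons (parent 1 vs heterokaryon, parent 2
#' vs heterokaryon, parent 1 vs parent 2), the three-strain Venn partition,
#' complementation classification, and (when an annotation is supplied) the
#' CAZyme summary. Every table is written under `config$out_dir` together
#' with a manifest of MD5 checksums and the resolved configuration, so a
#' rerun with the same seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`genes`, `index`,
#'   `qc`, `expression`, `de`, `venn`, `complementation`, `cazy`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  ## inputs ------------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_params <- config$simulation
    sim_params$tag_length <- as.integer(config$tag_length)
    genes <- stage("simulate", simulate_genes(sim_params))
    triad <- stage("simulate", simulate_triad(genes, sim_params))
    raw <- triad$libraries
    truth <- triad$truth
  } else {
    genes <- stage("read_genes", read_gene_fasta(config$gene_fasta))
    if (length(config$tag_files) != 3L) {
      abort("`tag_files` must name three libraries (p1, p2, h)")
    }
    raw <- stage("read_tags", lapply(config$tag_files, read_tag_tsv))
    names(raw) <- names(config$tag_files) %||% c("p1", "p2", "h")
    truth <- NULL
  }

  ## index -------------------------------------------------------------------
  index <- stage("extract", extract_virtual_tags(genes, config$tag_length))

  ## qc + quantify -----------------------------------------------------------
  qc <- stage("qc", lapply(raw, filter_tags,
                           adaptor_sequences = config$adaptor_sequences,
                           thresholds = config$copy_thresholds))
  expr <- stage("quantify", purrr::imap(qc, function(q, nm) {
    quantify_library(q$clean, index, floor = config$tpm_floor,
                     gene_ids = genes$gene_id)
  }))
  clean_totals <- vapply(expr, attr, numeric(1), "clean_total")

  ## differential expression over the three strain pairs ---------------------
  pairs <- list(c("p1", "h"), c("p2", "h"), c("p1", "p2"))
  de <- stage("diffexpr", lapply(pairs, function(pr) {
    counts <- tibble(
      gene_id = expr[[pr[1]]]$gene_id,
      x = expr[[pr[1]]]$raw_count,
      y = expr[[pr[2]]]$raw_count[match(expr[[pr[1]]]$gene_id,
                                        expr[[pr[2]]]$gene_id)]
    )
    call_de(counts, N1 = clean_totals[[pr[1]]], N2 = clean_totals[[pr[2]]],
            fc_threshold_log2 = config$fc_threshold_log2,
            p_threshold = config$p_threshold,
            fdr_threshold = config$fdr_threshold,
            intensity_floor = config$intensity_floor,
            tpm_floor = config$tpm_floor)
  }))
  names(de) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  ## strain comparison -------------------------------------------------------
  long <- purrr::imap_dfr(expr, function(e, nm) {
    tibble(gene_id = e$gene_id, strain = nm, raw_count = e$raw_count,
           tpm = e$tpm)
  })
  venn <- stage("compare", venn_partition(long, strains = names(expr),
                                          detect_min = config$detect_min))
  triad_tbl <- tibble(
    gene_id = expr$p1$gene_id,
    raw_p1 = expr$p1$raw_count,
    raw_p2 = expr$p2$raw_count[match(expr$p1$gene_id, expr$p2$gene_id)],
    tpm_p1 = expr$p1$tpm,
    tpm_p2 = expr$p2$tpm[match(expr$p1$gene_id, expr$p2$gene_id)],
    tpm_h = expr$h$tpm[match(expr$p1$gene_id, expr$h$gene_id)]
  )
  comp <- stage("compare", complementation_classify(
    triad_tbl, undetected_tpm = config$tpm_floor,
    low_tpm = config$comp_low_tpm, high_tpm = config$comp_high_tpm,
    min_fold = config$comp_min_fold))

  ## optional CAZyme summary -------------------------------------------------
  cazy <- NULL
  if (!is.null(config$cazy_annotation)) {
    ann <- stage("cazy", read_cazy_annotation(config$cazy_annotation))
    cazy <- stage("cazy", class_totals(ann))
  }

  ## write bundle ------------------------------------------------------------
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(obj, path)
    outputs <<- c(outputs, path)
  }
  emit(genes, "gene_models.tsv")
  if (!is.null(truth)) emit(truth, "truth.tsv")
  for (nm in names(raw)) emit(raw[[nm]], sprintf("raw_tags_%s.tsv", nm))
  for (nm in names(qc)) {
    emit(qc[[nm]]$clean, sprintf("clean_tags_%s.tsv", nm))
    emit(as_tibble(qc[[nm]]$accounting), sprintf("qc_accounting_%s.tsv", nm))
  }
  emit(long, "expression_long.tsv")
  for (nm in names(de)) emit(tidy(de[[nm]]), sprintf("de_%s.tsv", nm))
  emit(venn$regions, "venn_regions.tsv")
  emit(comp, "complementation_categories.tsv")
  if (!is.null(cazy)) emit(cazy, "cazy_class_totals.tsv")

  summary_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(
    list(
      pct_expressed_any = venn$pct_expressed_any,
      clean_totals = as.list(clean_totals),
      n_significant = lapply(de, function(d) sum(d$significant)),
      categories = as.list(table(comp$category))
    ),
    summary_json, auto_unbox = TRUE, pretty = TRUE
  )
  outputs <- c(outputs, summary_json)

  manifest <- tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(
    genes = genes, truth = truth, index = index, qc = qc,
    expression = expr, de = de, venn = venn, complementation = comp,
    cazy = cazy, manifest = manifest, config = config
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
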