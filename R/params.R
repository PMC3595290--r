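#' Parameters for the synthetic three-strain DGE simulation
#'
#' Bundles every knob of the synthetic-data generator: gene-model geometry,
#' sequencing depth, noise processes (base-call errors, N-containing tags,
#' adaptor contamination, singleton junk tags), the planted biology of the
#' three-strain design (strain-specific silent genes, allele divergence
#' between the two homokaryons, heterokaryon complementation boosts) and the
#' count model.
#'
#' Defaults describe a scaled-down but structurally faithful version of a
#' real NlaIII/MmeI tag experiment on a mushroom triad (two homokaryons plus
#' their hybrid heterokaryon): 1,000 genes and 200,000 tags per library
#' rather than ~11,500 genes and ~5.9 million tags, with allele divergence
#' of about 1 SNP per kilobase.
#'
#' @param n_genes Number of gene models to simulate.
#' @param gene_length_mean,gene_length_sd Transcript length distribution
#'   (nucleotides, normal, truncated at 25 nt).
#' @param library_size Expected total tag count per strain library.
#' @param base_error_rate Per-base probability of a sequencing substitution
#'   error in an emitted tag.
#' @param n_rate Probability that an emitted tag copy is rendered
#'   low-quality by replacing one of its bases with `N`.
#' @param adaptor_rate Probability that an emitted tag copy is replaced by an
#'   adaptor sequence.
#' @param adaptor_sequences Character vector of adaptor tag sequences
#'   (tag-length strings). The defaults are arbitrary fixed sequences; real
#'   adaptor sequences are instrument-specific.
#' @param singleton_noise Number of distinct junk tags planted with copy
#'   number exactly 1.
#' @param frac_silent_p1,frac_silent_p2 Fractions of genes with zero
#'   expression in homokaryon 1 / homokaryon 2 (disjoint sets; these are the
#'   planted complementation categories A and B).
#' @param silent_expr_tpm Expression (TPM) of a silent-in-one-parent gene in
#'   the other parent.
#' @param frac_boost Fraction of genes planted as "complementation boost"
#'   (category C): low expression in both parents, boosted in the
#'   heterokaryon.
#' @param boost_factor Multiplicative rate increase of boosted genes in the
#'   heterokaryon relative to the parental mean.
#' @param snp_rate Per-base divergence between the two parental alleles.
#' @param dispersion Negative-binomial overdispersion of per-gene tag counts
#'   (variance = mu + dispersion * mu^2); 0 collapses to Poisson.
#' @param catg_fraction Fraction of transcripts guaranteed to carry at least
#'   one CATG anchor with a full tag window downstream; the remainder are
#'   scrubbed of usable anchors and are unmeasurable by design.
#' @param tag_length Tag length in nucleotides (CATG anchor + downstream).
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical libraries.
#'
#' @return A list of class `simulation_params`.
#' @seealso [simulate_genes()], [simulate_triad()]
#' @export
#' @examples
#' p <- simulation_params(n_genes = 50, library_size = 5000, seed = 1)
#' p$n_genes
simulation_params <- function(n_genes = 1000,
                              gene_length_mean = 1500,
                              gene_length_sd = 500,
                              library_size = 200000,
                              base_error_rate = 0.005,
                              n_rate = 0.002,
                              adaptor_rate = 5e-4,
                              adaptor_sequences = default_adaptors(),
                              singleton_noise = 5000,
                              frac_silent_p1 = 0.05,
                              frac_silent_p2 = 0.05,
                              silent_expr_tpm = 500,
                              frac_boost = 0.02,
                              boost_factor = 40,
                              snp_rate = 0.001,
                              dispersion = 0.1,
                              catg_fraction = 0.95,
                              tag_length = 21,
                              seed = 1L) {
  assert_count(n_genes, "n_genes")
  if (n_genes > 0) assert_count(library_size, "library_size", min = 1L)
  assert_count(singleton_noise, "singleton_noise")
  assert_count(tag_length, "tag_length", min = 5L)
  for (nm in c("base_error_rate", "n_rate", "adaptor_rate", "frac_silent_p1",
               "frac_silent_p2", "frac_boost", "snp_rate", "catg_fraction")) {
    assert_rate(get(nm), nm)
  }
  if (frac_silent_p1 + frac_silent_p2 + frac_boost > 1) {
    abort("planted fractions (silent + boost) must sum to at most 1")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("`dispersion` must be >= 0")
  }
  if (!is.numeric(boost_factor) || boost_factor < 1) {
    abort("`boost_factor` must be >= 1")
  }
  if (any(nchar(adaptor_sequences) != tag_length)) {
    abort("`adaptor_sequences` must all have length `tag_length`")
  }
  assert_count(seed, "seed", min = -2147483647)
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_length_mean = gene_length_mean,
      gene_length_sd = gene_length_sd,
      library_size = as.integer(library_size),
      base_error_rate = base_error_rate,
      n_rate = n_rate,
      adaptor_rate = adaptor_rate,
      adaptor_sequences = adaptor_sequences,
      singleton_noise = as.integer(singleton_noise),
      frac_silent_p1 = frac_silent_p1,
      frac_silent_p2 = frac_silent_p2,
      silent_expr_tpm = silent_expr_tpm,
      frac_boost = frac_boost,
      boost_factor = boost_factor,
      snp_rate = snp_rate,
      dispersion = dispersion,
      catg_fraction = catg_fraction,
      tag_length = as.integer(tag_length),
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

#' Default adaptor tag sequences used by the simulator and QC examples
#'
#' Two fixed 21-nt sequences standing in for sequencing-adaptor
#' contamination. They begin with CATG so that, like real adaptor artefacts,
#' they survive anchor-based checks and must be removed by explicit adaptor
#' matching.
#'
#' @return Character vector of adaptor sequences.
#' @export
default_adaptors <- function() {
  c("CATGCGGCCGCTCGAGTCGAC", "CATGAGATCGGAAGAGCGTCG")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params>\n")
  cat(sprintf("  %d genes, library size %d, tag length %d, seed %d\n",
              x$n_genes, x$library_size, x$tag_length, x$seed))
  cat(sprintf("  noise: base error %.4g, N rate %.4g, adaptor rate %.4g, %d singletons\n",
              x$base_error_rate, x$n_rate, x$adaptor_rate, x$singleton_noise))
  cat(sprintf("  planted: silent %.2f/%.2f, boost %.2f x%g, snp rate %.4g, dispersion %g\n",
              x$frac_silent_p1, x$frac_silent_p2, x$frac_boost,
              x$boost_factor, x$snp_rate, x$dispersion))
  invisible(x)
}
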