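#' Simulate predicted gene models (transcripts) for the tag pipeline
#'
#' Generates random transcript sequences whose lengths follow a truncated
#' normal distribution. A fixed fraction of transcripts (`catg_fraction`) is
#' guaranteed to carry at least one CATG restriction-anchor with a full tag
#' window downstream; the remaining transcripts are scrubbed of every usable
#' anchor, emulating the minority of real genes that a 3'-tag assay cannot
#' measure at all.
#'
#' @param params A [simulation_params()] object.
#' @return A tibble with columns `gene_id` and `sequence`.
#' @export
#' @examples
#' genes <- simulate_genes(simulation_params(n_genes = 20, seed = 1))
#' nrow(genes)
simulate_genes <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params")) {
    abort("`params` must be created with simulation_params()")
  }
  n <- params$n_genes
  if (n == 0L) {
    return(tibble(gene_id = character(), sequence = character()))
  }
  with_seed(params$seed, {
    lengths <- pmax(25L, as.integer(round(
      rnorm(n, params$gene_length_mean, params$gene_length_sd)
    )))
    seqs <- random_dna(lengths)
    n_anchor <- round(params$catg_fraction * n)
    anchored <- seq_len(n) %in% sample.int(n, n_anchor)
    seqs[anchored] <- vapply(seqs[anchored], plant_anchor,
                             character(1), tag_length = params$tag_length,
                             USE.NAMES = FALSE)
    seqs[!anchored] <- vapply(seqs[!anchored], scrub_anchors,
                              character(1), USE.NAMES = FALSE)
    tibble(
      gene_id = sprintf("G%05d", seq_len(n)),
      sequence = seqs
    )
  })
}

# Guarantee one CATG anchor with a full tag window downstream by overwriting
# four bases at a random valid position.
plant_anchor <- function(seq, tag_length) {
  len <- nchar(seq)
  last_start <- len - tag_length + 1L
  if (last_start < 1L) last_start <- 1L
  pos <- sample.int(last_start, 1L)
  substr(seq, pos, pos + 3L) <- "CATG"
  seq
}

# Remove every CATG occurrence (replace the G so no anchor survives;
# re-scan because a replacement can in principle create a new CATG).
scrub_anchors <- function(seq) {
  while (grepl("CATG", seq, fixed = TRUE)) {
    pos <- regexpr("CATG", seq, fixed = TRUE)
    substr(seq, pos + 3L, pos + 3L) <- "T"
  }
  seq
}

# Per-base substitution of a single sequence at rate `rate`; returns the
# mutated sequence and the number of substituted positions.
mutate_sequence <- function(seq, rate) {
  len <- nchar(seq)
  n_mut <- rbinom(1L, len, rate)
  if (n_mut == 0L) {
    return(list(sequence = seq, n_snps = 0L))
  }
  pos <- sample.int(len, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  list(sequence = paste(chars, collapse = ""), n_snps = n_mut)
}

# The tag a transcript emits under oligo-dT + NlaIII/MmeI chemistry: the
# 3'-most CATG anchor with >= tag_length - 4 nt downstream. NA if the
# transcript has no usable anchor.
emission_tag <- function(seq, tag_length) {
  hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_character_)
  usable <- hits[hits + tag_length - 1L <= nchar(seq)]
  if (length(usable) == 0L) return(NA_character_)
  p <- max(usable)
  tag <- substr(seq, p, p + tag_length - 1L)
  if (grepl("N", tag, fixed = TRUE)) NA_character_ else tag
}

#' Simulate a three-strain tag-library triad with known ground truth
#'
#' Given simulated gene models, generates raw tag libraries for two
#' homokaryotic parents (`p1`, `p2`) and their heterokaryon (`h`), together
#' with a truth table recording every planted label. Parent 2 carries a
#' diverged allele of every gene (per-base SNP rate `snp_rate`); the
#' heterokaryon carries both alleles and emits tags from each with equal
#' probability. Expression is sampled per gene from a negative-binomial (or
#' Poisson) count model around planted per-strain rates; emitted tag copies
#' are then corrupted by base-call errors, N-replacement and adaptor
#' contamination, and singleton junk tags are appended.
#'
#' Planted structure:
#' * category **A** genes are silent in parent 1, expressed at
#'   `silent_expr_tpm` in parent 2 (category **B** is the mirror image);
#' * category **C** genes have low expression in both parents and a
#'   `boost_factor`-fold boosted rate in the heterokaryon;
#' * all other genes have equal parental rates, and the heterokaryon rate
#'   defaults to the parental mean (the additive null for complementation).
#'
#' @param genes A tibble from [simulate_genes()].
#' @param params A [simulation_params()] object (the same one used for the
#'   genes, so that seeds and tag length agree).
#' @return A list of class `synthetic_triad` with elements `libraries` (a
#'   named list `p1`/`p2`/`h` of `tag`/`count` tibbles), `truth` (per-gene
#'   tibble of planted rates, true TPM, category labels, measurability and
#'   allele divergence) and `params`.
#' @export
#' @examples
#' p <- simulation_params(n_genes = 50, library_size = 5000,
#'                        singleton_noise = 50, seed = 4)
#' triad <- simulate_triad(simulate_genes(p), p)
#' names(triad$libraries)
simulate_triad <- function(genes, params = simulation_params()) {
  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    abort("`genes` must be a non-empty tibble from simulate_genes()")
  }
  if (!inherits(params, "simulation_params")) {
    abort("`params` must be created with simulation_params()")
  }
  n <- nrow(genes)
  L <- params$tag_length
  derived_seed <- (params$seed + 1017881L) %% 2147483647L
  with_seed(derived_seed, {
    ## --- alleles -----------------------------------------------------------
    allele_p2 <- lapply(genes$sequence, mutate_sequence, rate = params$snp_rate)
    n_snps <- vapply(allele_p2, `[[`, integer(1), "n_snps")
    allele_p2 <- vapply(allele_p2, `[[`, character(1), "sequence")

    tag_p1 <- vapply(genes$sequence, emission_tag, character(1),
                     tag_length = L, USE.NAMES = FALSE)
    tag_p2 <- vapply(allele_p2, emission_tag, character(1),
                     tag_length = L, USE.NAMES = FALSE)

    ## --- planted per-strain rates (TPM-scale intents) ----------------------
    meanlog <- log(1e6 / n) - 1.5^2 / 2
    base <- stats::rlnorm(n, meanlog, 1.5)
    n_a <- round(params$frac_silent_p1 * n)
    n_b <- round(params$frac_silent_p2 * n)
    n_c <- round(params$frac_boost * n)
    planted <- sample.int(n, n_a + n_b + n_c)
    idx_a <- planted[seq_len(n_a)]
    idx_b <- planted[n_a + seq_len(n_b)]
    idx_c <- planted[n_a + n_b + seq_len(n_c)]

    rate_p1 <- rate_p2 <- base
    rate_p1[idx_a] <- 0
    rate_p2[idx_a] <- params$silent_expr_tpm
    rate_p2[idx_b] <- 0
    rate_p1[idx_b] <- params$silent_expr_tpm
    low <- runif(n_c, 0.5, 10)
    rate_p1[idx_c] <- low
    rate_p2[idx_c] <- runif(n_c, 0.5, 10)
    rate_h <- (rate_p1 + rate_p2) / 2
    rate_h[idx_c] <- rate_h[idx_c] * params$boost_factor

    category <- rep("none", n)
    category[idx_a] <- "A"
    category[idx_b] <- "B"
    category[idx_c] <- "C"

    ## --- counts and libraries ----------------------------------------------
    draw_counts <- function(rate) {
      mu <- rate / sum(rate) * params$library_size
      if (params$dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / params$dispersion)
      } else {
        rpois(n, mu)
      }
    }
    counts_p1 <- draw_counts(rate_p1)
    counts_p2 <- draw_counts(rate_p2)
    counts_h <- draw_counts(rate_h)
    # heterokaryon: each tag copy comes from one of the two alleles
    h_from_p1 <- rbinom(n, counts_h, 0.5)

    emitted_p1 <- tibble(tag = tag_p1, count = counts_p1)
    emitted_p2 <- tibble(tag = tag_p2, count = counts_p2)
    emitted_h <- tibble(
      tag = c(tag_p1, tag_p2),
      count = c(h_from_p1, counts_h - h_from_p1)
    )

    build_library <- function(emitted) {
      emitted <- emitted[!is.na(emitted$tag) & emitted$count > 0, ]
      lib <- corrupt_and_tally(emitted$tag, emitted$count, params)
      add_singleton_noise(lib, params)
    }
    libraries <- list(
      p1 = build_library(emitted_p1),
      p2 = build_library(emitted_p2),
      h = build_library(emitted_h)
    )

    truth <- tibble(
      gene_id = genes$gene_id,
      category = category,
      rate_p1 = rate_p1, rate_p2 = rate_p2, rate_h = rate_h,
      tpm_p1 = rate_p1 / sum(rate_p1) * 1e6,
      tpm_p2 = rate_p2 / sum(rate_p2) * 1e6,
      tpm_h = rate_h / sum(rate_h) * 1e6,
      measurable_p1 = !is.na(tag_p1),
      measurable_p2 = !is.na(tag_p2),
      n_snps = n_snps,
      tag_p1 = tag_p1,
      tag_p2 = tag_p2,
      tag_divergent = !is.na(tag_p1) & !is.na(tag_p2) & tag_p1 != tag_p2
    )
    structure(list(libraries = libraries, truth = truth, params = params),
              class = "synthetic_triad")
  })
}

# Expand (tag, count) rows to individual copies, apply base-call errors,
# N-replacement and adaptor substitution per copy, and tally back to a
# tag -> count tibble. Only copies actually hit by a noise process allocate
# new strings, so this stays cheap at millions of copies.
corrupt_and_tally <- function(tags, counts, params) {
  if (length(tags) == 0L) {
    return(tibble(tag = character(), count = integer()))
  }
  copies <- rep(tags, counts)
  m <- length(copies)
  L <- params$tag_length
  if (params$base_error_rate > 0) {
    k <- rbinom(m, L, params$base_error_rate)
    hit <- which(k > 0L)
    if (length(hit)) copies[hit] <- mutate_copies(copies[hit], k[hit], L)
  }
  if (params$n_rate > 0) {
    hit <- which(runif(m) < params$n_rate)
    if (length(hit)) {
      pos <- sample.int(L, length(hit), replace = TRUE)
      x <- copies[hit]
      substr(x, pos, pos) <- "N"
      copies[hit] <- x
    }
  }
  if (params$adaptor_rate > 0) {
    hit <- which(runif(m) < params$adaptor_rate)
    if (length(hit)) {
      copies[hit] <- sample(params$adaptor_sequences, length(hit), replace = TRUE)
    }
  }
  tally_tags(copies)
}

# Apply k[i] random substitutions to copy i (k >= 1 for every element).
# The k == 1 case dominates at realistic error rates and is fully
# vectorised; multi-error copies are handled one substitution at a time.
mutate_copies <- function(copies, k, L) {
  one <- which(k == 1L)
  if (length(one)) {
    copies[one] <- substitute_base(copies[one], L)
  }
  multi <- which(k > 1L)
  for (i in multi) {
    pos <- sample.int(L, k[i])
    for (p in pos) {
      orig <- substr(copies[i], p, p)
      substr(copies[i], p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
    }
  }
  copies
}

# Replace one uniformly chosen base of each sequence with a uniformly
# chosen *different* base (vectorised).
substitute_base <- function(seqs, L) {
  n <- length(seqs)
  pos <- sample.int(L, n, replace = TRUE)
  orig <- substr(seqs, pos, pos)
  slot <- sample.int(3L, n, replace = TRUE)
  idx <- match(orig, DNA_BASES)
  sub <- DNA_BASES[((idx %% 4L) + slot - 1L) %% 4L + 1L]
  substr(seqs, pos, pos) <- sub
  seqs
}

tally_tags <- function(copies) {
  tab <- table(copies)
  tibble(tag = names(tab), count = as.integer(tab)) %>%
    arrange(.data$tag)
}

# Append `singleton_noise` distinct junk tags with copy number exactly 1,
# guaranteed not to collide with any tag already in the library.
add_singleton_noise <- function(lib, params) {
  k <- params$singleton_noise
  if (k == 0L) return(lib)
  noise <- character(0)
  while (length(noise) < k) {
    cand <- unique(random_dna(rep(params$tag_length, k - length(noise))))
    cand <- setdiff(cand, c(lib$tag, noise))
    noise <- c(noise, cand)
  }
  bind_rows(lib, tibble(tag = noise, count = 1L)) %>%
    arrange(.data$tag)
}

#' @export
print.synthetic_triad <- function(x, ...) {
  tot <- vapply(x$libraries, function(l) sum(l$count), numeric(1))
  cat("<synthetic_triad>\n")
  cat(sprintf("  %d genes; libraries (total tags): p1 %d, p2 %d, h %d\n",
              nrow(x$truth), tot[["p1"]], tot[["p2"]], tot[["h"]]))
  cat(sprintf("  planted categories: A %d, B %d, C %d\n",
              sum(x$truth$category == "A"), sum(x$truth$category == "B"),
              sum(x$truth$category == "C")))
  invisible(x)
}
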