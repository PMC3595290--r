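test_that("simulate_genes respects size, determinism and the empty case", {
  expect_equal(nrow(simulate_genes(simulation_params(n_genes = 0, seed = 1))), 0)

  p <- simulation_params(n_genes = 500, seed = 1)
  g1 <- simulate_genes(p)
  g2 <- simulate_genes(p)
  expect_identical(g1, g2)
  expect_true(all(nchar(g1$sequence) >= 25))
  expect_equal(nrow(g1), 500)
})

test_that("anchored fraction of simulated genes yields virtual tags", {
  p <- simulation_params(n_genes = 200, catg_fraction = 1, seed = 7)
  genes <- simulate_genes(p)
  # direct scan, independent of the index code
  has_site <- vapply(genes$sequence, function(s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    hits[1] != -1L && any(hits + 20 <= nchar(s))
  }, logical(1), USE.NAMES = FALSE)
  expect_true(all(has_site))
  idx <- extract_virtual_tags(genes)
  expect_equal(length(unique(idx$tags$gene_id)), 200)

  # and with catg_fraction < 1, the scrubbed genes have no usable site
  p2 <- simulation_params(n_genes = 200, catg_fraction = 0.8, seed = 7)
  genes2 <- simulate_genes(p2)
  has_site2 <- vapply(genes2$sequence, function(s) {
    grepl("CATG", s, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(sum(!has_site2), 40)
})

test_that("simulate_triad is deterministic and conserves tag totals", {
  p <- simulation_params(n_genes = 100, library_size = 20000,
                         singleton_noise = 300, seed = 11)
  genes <- simulate_genes(p)
  t1 <- simulate_triad(genes, p)
  t2 <- simulate_triad(genes, p)
  expect_identical(t1$libraries, t2$libraries)
  expect_identical(t1$truth, t2$truth)

  # totals are near the nominal library size
  for (lib in t1$libraries) {
    expect_gt(sum(lib$count), 0.5 * p$library_size)
    expect_lt(sum(lib$count), 2 * p$library_size)
  }
})

test_that("noise-free triads contain only singleton-removable extras", {
  p <- simulation_params(n_genes = 80, library_size = 30000,
                         base_error_rate = 0, n_rate = 0, adaptor_rate = 0,
                         singleton_noise = 0, dispersion = 0, seed = 5)
  genes <- simulate_genes(p)
  tr <- simulate_triad(genes, p)
  for (lib in tr$libraries) {
    qc <- filter_tags(lib, adaptor_sequences = p$adaptor_sequences)
    acc <- qc$accounting
    expect_equal(acc$total[acc$row == "n_containing"], 0)
    expect_equal(acc$total[acc$row == "adaptor"], 0)
    # every tag is a genuine emission tag of some allele
    emitted <- unique(c(tr$truth$tag_p1, tr$truth$tag_p2))
    expect_true(all(lib$tag %in% emitted))
  }
})

test_that("per-gene emitted counts plus noise equal the library total", {
  # with all corruption off, per-gene emission can be reconstructed exactly
  p <- simulation_params(n_genes = 60, library_size = 15000,
                         base_error_rate = 0, n_rate = 0, adaptor_rate = 0,
                         snp_rate = 0, singleton_noise = 150, seed = 9)
  genes <- simulate_genes(p)
  tr <- simulate_triad(genes, p)
  lib <- tr$libraries$p1
  noise <- sum(!(lib$tag %in% tr$truth$tag_p1))
  expect_equal(noise, 150)
})

test_that("snp_rate controls allele divergence and parent-diagnostic tags", {
  p0 <- simulation_params(n_genes = 100, library_size = 5000,
                          snp_rate = 0, seed = 2)
  genes <- simulate_genes(p0)
  tr0 <- simulate_triad(genes, p0)
  expect_true(all(tr0$truth$n_snps == 0))
  expect_false(any(tr0$truth$tag_divergent))

  # a high in-window SNP rate must make some tags parent-diagnostic
  p1 <- simulation_params(n_genes = 100, library_size = 5000,
                          snp_rate = 0.02, seed = 2)
  tr1 <- simulate_triad(genes, p1)
  expect_gt(sum(tr1$truth$n_snps), 0)
  expect_gt(sum(tr1$truth$tag_divergent), 0)
})

test_that("planted categories obey their defining rate constraints", {
  p <- simulation_params(n_genes = 400, library_size = 50000, seed = 13)
  tr <- simulate_triad(simulate_genes(p), p)
  tt <- tr$truth
  a <- tt[tt$category == "A", ]
  expect_true(all(a$rate_p1 == 0 & a$rate_p2 > 0))
  b <- tt[tt$category == "B", ]
  expect_true(all(b$rate_p2 == 0 & b$rate_p1 > 0))
  cc <- tt[tt$category == "C", ]
  expect_true(all(cc$rate_p1 <= 10 & cc$rate_p2 <= 10))
  expect_true(all(cc$rate_h > pmax(cc$rate_p1, cc$rate_p2)))
})

test_that("empirical counts converge to planted rates at deep sampling", {
  # at 1e6 tags, genes at >= 100 TPM should be measured within 10%
  # relative error for at least 95% of such genes
  p <- simulation_params(n_genes = 300, library_size = 1e6,
                         base_error_rate = 0, n_rate = 0, adaptor_rate = 0,
                         singleton_noise = 0, dispersion = 0,
                         frac_silent_p1 = 0, frac_silent_p2 = 0,
                         frac_boost = 0, catg_fraction = 1, seed = 21)
  genes <- simulate_genes(p)
  tr <- simulate_triad(genes, p)
  lib <- tr$libraries$p1
  obs <- lib$count[match(tr$truth$tag_p1, lib$tag)]
  obs[is.na(obs)] <- 0
  expected <- tr$truth$tpm_p1 / 1e6 * sum(lib$count)
  hi <- tr$truth$tpm_p1 >= 100 & !is.na(tr$truth$tag_p1) &
    !duplicated(tr$truth$tag_p1)
  rel_err <- abs(obs[hi] - expected[hi]) / expected[hi]
  expect_gte(mean(rel_err < 0.10), 0.95)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(n_genes = -1), "n_genes")
  expect_error(simulation_params(base_error_rate = 1.5), "base_error_rate")
  expect_error(simulation_params(library_size = 0), "library_size")
  expect_error(simulation_params(frac_silent_p1 = 0.6, frac_silent_p2 = 0.6),
               "fractions")
  expect_error(simulate_triad(tibble::tibble(), simulation_params()),
               "non-empty")
})
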