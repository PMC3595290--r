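test_that("filter_tags attributes each removal class correctly on a toy library", {
  adaptors <- default_adaptors()
  raw <- tibble::tibble(
    tag = c(paste0("CATGN", strrep("A", 16)),       # N tags (3 distinct)
            paste0("CATGNN", strrep("A", 15)),
            paste0("NATGA", strrep("A", 16)),
            adaptors[1],                            # adaptor (1 distinct)
            paste0("CATG", strrep("T", 16),         # singletons (4)
                   c("A", "C", "G", "T")),
            paste0("CATG", strrep("G", 15),         # 10 good tags
                   c("AA", "AC", "AG", "AT", "CA",
                     "CC", "CG", "CT", "GA", "GC"))),
    count = c(2L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, rep(10L, 10))
  )
  res <- filter_tags(raw, adaptor_sequences = adaptors)
  acc <- res$accounting
  get <- function(r, col) acc[[col]][acc$row == r]
  expect_equal(get("raw", "distinct"), 18)
  expect_equal(get("raw", "total"), 111)
  expect_equal(get("n_containing", "distinct"), 3)
  expect_equal(get("n_containing", "total"), 5)
  expect_equal(get("adaptor", "distinct"), 1)
  expect_equal(get("adaptor", "total"), 2)
  expect_equal(get("singleton", "distinct"), 4)
  expect_equal(get("singleton", "total"), 4)
  expect_equal(get("clean", "distinct"), 10)
  expect_equal(get("clean", "total"), 100)
  expect_equal(nrow(res$clean), 10)
})

test_that("accounting identities hold on full-scale prescribed marginals", {
  # construct an actual library with the removal-class marginals of a real
  # ~6M-tag homokaryon library and check the ledger arithmetic end to end
  lib <- make_ledger_library(n_n = 4485, t_n = 7989,
                             n_ad = 185, t_ad = 202,
                             n_single = 38176,
                             n_clean = 106250, t_clean = 5950901,
                             seed = 3)
  res <- filter_tags(lib$raw, adaptor_sequences = lib$adaptors)
  acc <- res$accounting
  get <- function(r, col) acc[[col]][acc$row == r]
  expect_equal(get("raw", "distinct"), 149096)
  expect_equal(get("raw", "total"), 5997268)
  expect_equal(get("clean", "distinct"), 106250)
  expect_equal(get("clean", "total"), 5950901)
  expect_equal(get("copynum_ge_2", "distinct"), get("clean", "distinct"))
  expect_equal(get("copynum_ge_2", "total"), get("clean", "total"))
})

test_that("empty library yields an all-zero ledger", {
  res <- filter_tags(tibble::tibble(tag = character(), count = integer()))
  expect_true(all(res$accounting$distinct == 0))
  expect_true(all(res$accounting$total == 0))
  expect_equal(nrow(res$clean), 0)
})

test_that("threshold_table matches hand enumeration and boundaries", {
  lib <- tibble::tibble(tag = c("a", "b", "c"), count = c(2L, 6L, 101L))
  tt <- threshold_table(lib, thresholds = c(2, 5, 10, 20, 50, 100))
  expect_equal(tt$distinct, c(3, 2, 1, 1, 1, 1))
  expect_equal(tt$total, c(109, 107, 101, 101, 101, 101))

  empty <- threshold_table(tibble::tibble(tag = character(), count = integer()))
  expect_true(all(empty$distinct == 0) && all(empty$total == 0))

  all2 <- threshold_table(tibble::tibble(tag = letters[1:4], count = rep(2L, 4)))
  expect_equal(all2$distinct, c(4, 0, 0, 0, 0, 0))
  expect_equal(all2$total, c(8, 0, 0, 0, 0, 0))
})

test_that("QC conservation identities hold across random simulated libraries", {
  for (seed in c(1, 2, 3)) {
    p <- withr::with_seed(seed, simulation_params(
      n_genes = 80, library_size = 15000,
      base_error_rate = runif(1, 0, 0.01),
      n_rate = runif(1, 0, 0.01),
      adaptor_rate = runif(1, 0, 0.005),
      singleton_noise = sample(0:500, 1),
      seed = seed))
    tr <- simulate_triad(simulate_genes(p), p)
    for (lib in tr$libraries) {
      acc <- filter_tags(lib, adaptor_sequences = p$adaptor_sequences)$accounting
      get <- function(r, col) acc[[col]][acc$row == r]
      expect_equal(get("clean", "total"),
                   get("raw", "total") - get("n_containing", "total") -
                     get("adaptor", "total") - get("singleton", "total"))
      expect_equal(get("clean", "distinct"),
                   get("raw", "distinct") - get("n_containing", "distinct") -
                     get("adaptor", "distinct") - get("singleton", "distinct"))
      expect_equal(get("singleton", "distinct"), get("singleton", "total"))
      # threshold rows nonincreasing
      thr <- acc[grepl("^copynum", acc$row), ]
      expect_true(all(diff(thr$distinct) <= 0))
      expect_true(all(diff(thr$total) <= 0))
    }
  }
})

test_that("filtering is idempotent on a clean library", {
  p <- simulation_params(n_genes = 60, library_size = 10000, seed = 17)
  tr <- simulate_triad(simulate_genes(p), p)
  clean <- filter_tags(tr$libraries$p1,
                       adaptor_sequences = p$adaptor_sequences)$clean
  again <- filter_tags(clean, adaptor_sequences = p$adaptor_sequences)
  expect_identical(again$clean, clean)
  acc <- again$accounting
  expect_equal(sum(acc$total[acc$row %in% c("n_containing", "adaptor",
                                            "singleton")]), 0)
})

test_that("adaptor prefix mode matches tags starting with an adaptor", {
  ad <- "CATGAAA"
  raw <- tibble::tibble(tag = c(paste0(ad, strrep("G", 14)),
                                paste0("CATGCCC", strrep("G", 14))),
                        count = c(5L, 5L))
  exact <- filter_tags(raw, adaptor_sequences = ad)
  expect_equal(exact$accounting$distinct[exact$accounting$row == "adaptor"], 0)
  pref <- filter_tags(raw, adaptor_sequences = ad, adaptor_prefix = TRUE)
  expect_equal(pref$accounting$distinct[pref$accounting$row == "adaptor"], 1)
})
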