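test_that("class_totals sums an annotation by enzyme class", {
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:7),
    family = c("GH10", "GH43", "GH10", "GT2", "PL1", "CE4", "CE16")
  )
  ct <- class_totals(ann)
  expect_equal(ct$n[ct$class == "GH"], 3)
  expect_equal(ct$n[ct$class == "GT"], 1)
  expect_equal(ct$n[ct$class == "PL"], 1)
  expect_equal(ct$n[ct$class == "CE"], 2)
  expect_equal(attr(ct, "total"), 7)

  empty <- class_totals(tibble::tibble(gene_id = character(),
                                       family = character()))
  expect_true(all(empty$n == 0))
  expect_error(class_totals(tibble::tibble(gene_id = "x", family = "XYZ9")),
               "XYZ9")
})

test_that("the bundled fungal class counts reproduce the known summaries", {
  mat <- fungal_cazyme_counts()
  basidio <- unique(mat$genome[mat$lineage == "basidiomycete"])
  expect_length(basidio, 8)

  # the straw mushroom's repertoire: 191 + 44 + 19 + 31 = 285
  vv <- mat[mat$genome == "V_volvacea", ]
  expect_equal(sum(vv$count), 285)

  expect_equal(lineage_average(mat, basidio, "GH"), 161)
  expect_equal(lineage_average(mat, basidio, "GT"), 65)
  expect_equal(lineage_average(mat, basidio, "PL"), 8)
  expect_equal(lineage_average(mat, basidio, "CE"), 24)

  pl_max <- max_in_lineage(mat, basidio, "PL")
  expect_equal(pl_max$genomes, "V_volvacea")
  expect_equal(pl_max$count, 19)

  expect_equal(rank_by_total(mat, "V_volvacea"), 7)
  expect_equal(length(unique(mat$genome)), 15)
})

test_that("lineage_average rounds half away from zero and validates input", {
  mat <- tibble::tibble(
    genome = rep(c("a", "b"), each = 1),
    family = "GH5",
    count = c(3, 4)  # mean 3.5 -> 4 under half-away rounding
  )
  expect_equal(lineage_average(mat, c("a", "b"), "GH"), 4)
  expect_equal(lineage_average(mat, "a", "GH"), 3)  # single genome
  expect_error(lineage_average(mat, character(), "GH"), "non-empty")
  expect_error(lineage_average(mat, "zz", "GH"), "zz")
})

test_that("rank_by_total uses descending min-rank with ties", {
  mat <- tibble::tibble(
    genome = rep(c("a", "b", "c"), each = 1),
    family = "GH1",
    count = c(10, 10, 5)
  )
  expect_equal(rank_by_total(mat, "a"), 1)
  expect_equal(rank_by_total(mat, "b"), 1)
  expect_equal(rank_by_total(mat, "c"), 3)
  expect_error(rank_by_total(mat, "zz"), "unknown")
  single <- tibble::tibble(genome = "only", family = "GH1", count = 7)
  expect_equal(rank_by_total(single, "only"), 1)
})

test_that("max_in_lineage reports full tie sets and matches brute force", {
  tied <- tibble::tibble(genome = c("a", "b", "c"), family = "PL1",
                         count = c(4, 4, 4))
  res <- max_in_lineage(tied, c("a", "b", "c"), "PL")
  expect_setequal(res$genomes, c("a", "b", "c"))
  expect_equal(res$count, 4)

  withr::with_seed(19, {
    m <- tidyr::expand_grid(genome = paste0("g", 1:5),
                            family = c("GH1", "GH2", "PL1"))
    m$count <- sample(0:30, nrow(m), replace = TRUE)
    res2 <- max_in_lineage(m, paste0("g", 1:5), "GH")
    gh <- tapply(m$count[m$family != "PL1"], m$genome[m$family != "PL1"], sum)
    expect_equal(res2$count, unname(max(gh)))
    expect_setequal(res2$genomes, names(gh)[gh == max(gh)])
  })
})

test_that("bicluster merges identical genomes first and orders all labels", {
  mat <- tidyr::expand_grid(genome = c("a", "b", "c"),
                            family = paste0("GH", 1:4))
  base <- c(1, 5, 9, 2)
  mat$count <- c(base, base, base + 10)  # a and b identical
  bc <- bicluster(mat)
  expect_setequal(bc$col_order, c("a", "b", "c"))
  expect_setequal(bc$row_order, paste0("GH", 1:4))
  # the zero-distance pair merges first
  first <- bc$col_hclust$merge[1, ]
  expect_setequal(bc$col_hclust$labels[-first], c("a", "b"))
  expect_equal(bc$col_hclust$height[1], 0)
  # heights nondecreasing along merges
  expect_true(all(diff(bc$col_hclust$height) >= 0))
  expect_true(all(diff(bc$row_hclust$height) >= 0))
})

# reconstruct the member set created by each hclust merge step
hclust_member_sets <- function(hc) {
  sets <- list()
  for (i in seq_len(nrow(hc$merge))) {
    members <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[i, j]
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[i]] <- sort(members)
  }
  sets
}

test_that("bicluster agrees with a brute-force agglomeration oracle", {
  withr::with_seed(20, {
    for (linkage in c("average", "single")) {
      mat <- tidyr::expand_grid(genome = paste0("s", 1:4),
                                family = paste0("GH", 1:4))
      mat$count <- sample(0:25, 16, replace = TRUE)
      bc <- bicluster(mat, linkage = linkage)
      m <- t(bc$matrix)  # genomes as points
      o <- oracle_agglomerate(m, linkage)
      expect_equal(bc$col_hclust$height, o$heights, tolerance = 1e-12)
      # compare merged member sets at each step
      hc_sets <- hclust_member_sets(bc$col_hclust)
      expect_equal(hc_sets, o$merges)
    }
  })
})

test_that("degenerate bicluster inputs are handled", {
  const <- tidyr::expand_grid(genome = c("a", "b"), family = c("GH1", "GH2"))
  const$count <- 3
  expect_warning(bc <- bicluster(const), "arbitrary")
  expect_true(bc$constant)

  one_row <- tibble::tibble(genome = c("a", "b", "c"), family = "GH1",
                            count = c(1, 5, 20))
  bc1 <- bicluster(one_row)
  expect_null(bc1$row_hclust)
  expect_equal(bc1$row_order, "GH1")
  expect_equal(length(bc1$col_order), 3)
  expect_error(write_dendrogram_newick(bc1, "row", tempfile()), "single leaf")
})

test_that("dendrograms export as valid Newick and heatmap plots build", {
  withr::with_seed(21, {
    mat <- tidyr::expand_grid(genome = paste0("s", 1:5),
                              family = paste0("GH", 1:6))
    mat$count <- sample(0:40, 30, replace = TRUE)
    bc <- bicluster(mat)
    nwk <- tempfile(fileext = ".nwk")
    write_dendrogram_newick(bc, "col", nwk)
    tree <- ape::read.tree(nwk)
    expect_setequal(tree$tip.label, paste0("s", 1:5))
    expect_s3_class(autoplot(bc), "ggplot")
  })
})
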