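test_that("contact matrix counts window pairs and excludes the diagonal", {
  reg <- toy_regions(tss = c(6000, 18000, 30000, 42000))
  ## one contact joining windows of promoters 2 and 4
  cell <- toy_cell("c1", "t", toy_contacts("chrT", 17000, "chrT", 43000))
  m <- build_promoter_contact_matrix(cell, reg)
  expect_equal(m[2, 4], 1L)
  expect_equal(m[4, 2], 1L)
  expect_equal(sum(m), 2L)

  ## both ends inside one promoter's window -> all zero
  cell2 <- toy_cell("c2", "t", toy_contacts("chrT", 17000, "chrT", 18500))
  expect_equal(sum(build_promoter_contact_matrix(cell2, reg)), 0L)

  expect_error(build_promoter_contact_matrix(
    cell, rbind(reg, within(reg, chrom <- "chrX"))), "single chromosome")
})

test_that("contact matrix matches the brute-force membership oracle", {
  reg <- toy_regions(tss = c(6000, 14000, 22000, 30000))  # overlapping windows
  set.seed(7)
  pos <- sample(0:35000, 20, replace = TRUE)
  ct <- toy_contacts("chrT", pos[1:10], "chrT", pos[11:20])
  cell <- toy_cell("c", "t", ct)
  m <- build_promoter_contact_matrix(cell, reg)
  expect_equal(m, ref_contact_matrix(ct, reg), ignore_attr = TRUE)
  expect_true(isSymmetric(m))
  expect_equal(sum(diag(m)), 0L)
})

test_that("Hi-C similarity is cosine on binned contact pairs", {
  a <- toy_cell("a", "t", toy_contacts("chr1", c(100, 200e4, 350e4),
                                       "chr1", c(150e4, 220e4, 500e4)))
  expect_equal(hic_cell_similarity(a, a), 1.0)
  b <- toy_cell("b", "t", toy_contacts("chr2", 100, "chr2", 150e4))
  expect_equal(hic_cell_similarity(a, b), 0.0)

  ## hand-computed cosine: shared bin pair appears 2x in c, 1x in d, plus one
  ## unshared pair each
  cc <- toy_cell("c", "t", toy_contacts("chr1", c(10, 20, 999e4),
                                        "chr1", c(150e4, 150e4 + 5, 999e4 + 2)))
  d <- toy_cell("d", "t", toy_contacts("chr1", c(15, 500e4),
                                       "chr1", c(150e4 + 9, 600e4)))
  ## vectors over union bins: c = (2, 1, 0), d = (1, 0, 1)
  expect_equal(hic_cell_similarity(cc, d), 2 / sqrt(5 * 2))
  expect_error(hic_cell_similarity(a, toy_cell("e", "t",
    toy_contacts(character(), integer(), character(), integer()))),
    "no contacts")
})

test_that("neighbour selection is top-k by similarity with deterministic ties", {
  fx <- get_fixture()
  reg <- fx$genome_obj$regions_by_chrom
  target <- fx$cells[[1]]
  meta <- select_hic_neighbors(target, fx$cells, reg, k = 20,
                               bin_size = 1e4)
  ## brute-force argsort oracle
  others <- fx$cells[-1]
  sims <- vapply(others, function(cl)
    hic_cell_similarity(target, cl, 1e4), 0)
  ids <- vapply(others, `[[`, "", "cell_id")
  expected <- ids[order(-sims, ids)][1:20]
  expect_equal(meta$neighbor_ids, expected)
  expect_equal(meta$member_ids[1], target$cell_id)

  ## conservation: aggregated = sum of member matrices
  agg <- meta$aggregated[["chr1"]]
  expect_equal(agg, Reduce(`+`, meta$member_matrices[["chr1"]]))
  expect_equal(sum(agg), sum(vapply(meta$member_matrices[["chr1"]], sum, 0)))
  expect_true(isSymmetric(agg))
  expect_equal(sum(diag(agg)), 0)
})

test_that("type restriction excludes other types; pool of clones aggregates k+1 fold", {
  fx <- get_fixture()
  reg <- fx$genome_obj$regions_by_chrom
  target <- fx$cells[[1]]  # type1
  meta <- select_hic_neighbors(target, fx$cells, reg, k = 20,
                               restrict_to_type = TRUE, bin_size = 1e4)
  types <- stats::setNames(vapply(fx$cells, `[[`, "", "cell_type"),
                           vapply(fx$cells, `[[`, "", "cell_id"))
  expect_true(all(types[meta$neighbor_ids] == "type1"))

  ## pool made of k clones of the target
  clones <- lapply(1:20, function(i) {
    cl <- target; cl$cell_id <- sprintf("clone_%02d", i); cl
  })
  meta2 <- select_hic_neighbors(target, c(list(target), clones), reg, k = 20,
                                bin_size = 1e4)
  base <- build_promoter_contact_matrix(target, reg[["chr1"]])
  expect_equal(meta2$aggregated[["chr1"]], base * 21L,
               ignore_attr = TRUE)
  expect_error(select_hic_neighbors(target, clones[1:5], reg, k = 20,
                                    bin_size = 1e4), "only 5")
})

test_that("methylation pooling sums reads over members (ratio of sums)", {
  m1 <- toy_meth("chr1", c(100, 200), c("+", "+"), c(1, 2), c(2, 2))
  m2 <- toy_meth("chr1", c(100, 300), c("+", "-"), c(1, 0), c(2, 3))
  a <- toy_cell("a", "t", toy_contacts("chr1", 1, "chr1", 2), m1)
  b <- toy_cell("b", "t", toy_contacts("chr1", 1, "chr1", 2), m2)
  mm <- aggregate_methylation(a, list(a, b), k = 1)
  pooled <- mm$pooled
  ## shared site 100: (1+1)/(2+2) = 0.5
  expect_equal(pooled$level[pooled$pos == 100], 0.5)
  ## site 300 only in the neighbour is present with its values
  expect_equal(pooled$n_total[pooled$pos == 300], 3L)
  expect_equal(pooled$level[pooled$pos == 300], 0)
  ## site 200 only in the target
  expect_equal(pooled$level[pooled$pos == 200], 1)

  ## 5-cell hand-summation oracle on the fixture
  fx <- get_fixture()
  sub <- fx$cells[1:5]
  mm2 <- aggregate_methylation(sub[[1]], sub, k = 4)
  members <- sub  # target + all 4 others
  allm <- do.call(rbind, lapply(members, `[[`, "meth"))
  key <- paste(allm$chrom, allm$pos, allm$strand)
  for (s in sample(unique(key), 10)) {
    expect_equal(
      mm2$pooled$n_meth[paste(mm2$pooled$chrom, mm2$pooled$pos,
                              mm2$pooled$strand) == s],
      sum(allm$n_meth[key == s]))
  }
})

test_that("cells with no shared methylation sites get similarity zero", {
  m1 <- toy_meth("chr1", 100, "+", 1, 2)
  m2 <- toy_meth("chr2", 100, "+", 1, 2)
  a <- toy_cell("a", "t", toy_contacts("chr1", 1, "chr1", 2), m1)
  b <- toy_cell("b", "t", toy_contacts("chr1", 1, "chr1", 2), m2)
  expect_equal(meth_cell_similarity(a, b), 0)
  expect_equal(meth_cell_similarity(a, a), 1)
})
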