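test_that("RPKM follows count * 1e9 / (total * length)", {
  mat <- matrix(c(0L, 100L), ncol = 1, dimnames = list(c("G0", "G1"), "s"))
  ct <- count_table(mat, totals = 1e6, lengths = c(500, 2000))
  r <- compute_rpkm(ct)
  expect_equal(r["G0", "s"], 0)
  expect_equal(r["G1", "s"], 50)
  ct0 <- ct
  ct0$totals[] <- 0
  expect_error(compute_rpkm(ct0), "total")
})

test_that("RPKM is invariant to a common rescaling of counts and totals", {
  mat <- matrix(c(3L, 11L, 0L), ncol = 1, dimnames = list(paste0("G", 1:3), "s"))
  ct1 <- count_table(mat, totals = 1e5, lengths = c(100, 200, 300))
  ct2 <- count_table(mat * 2L, totals = 2e5, lengths = c(100, 200, 300))
  expect_equal(compute_rpkm(ct1), compute_rpkm(ct2))
})

test_that("input flooring uses the interpolated percentile", {
  expect_equal(as.numeric(floor_input(c(10, 10, 10))), c(10, 10, 10))

  v <- as.numeric(1:100)
  fl <- floor_input(v, 5)
  expect_equal(attr(fl, "floor"), 5.95)  # 1 + 0.05 * 99, linear interpolation
  expect_equal(as.numeric(fl), pmax(v, 5.95))

  # percentile 0: no flooring unless zeros are present
  expect_equal(as.numeric(floor_input(v, 0)), v)
  withz <- c(0, 2, 5)
  expect_equal(as.numeric(floor_input(withz, 0)), c(2, 2, 5))
  expect_error(floor_input(c(0, 0)), "all-zero")
})

test_that("input flooring is monotone and idempotent", {
  set.seed(11)
  for (i in 1:20) {
    v <- rexp(50)
    fl_full <- floor_input(v)
    fl <- as.numeric(fl_full)
    expect_true(all(fl >= v))
    # applying the same floor again is the identity
    expect_equal(pmax(fl, attr(fl_full, "floor")), fl)
    # raising one value never lowers its floored value
    j <- sample(50, 1)
    v2 <- v; v2[j] <- v2[j] + 1
    expect_gte(as.numeric(floor_input(v2))[j], fl[j])
  }
})

test_that("fold enrichment and its log2 follow the epsilon rule", {
  fe <- compute_fe(c(5, 40, 0), c(5, 5, 5))
  expect_equal(fe$fe, c(1, 8, 0))
  expect_equal(fe$log2_fe, c(0, 3, -10))
  expect_error(compute_fe(1:3, 1:2), "length")
  expect_error(compute_fe(1, 0), "floored")
})

test_that("chromosome-level FE is a ratio of per-chromosome densities", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  same <- c(chr1 = 100, chr2 = 100)
  r <- chromosome_fe(same, same, 1e6, 1e6, lens)
  expect_equal(r$fe, c(1, 1))
  doubled <- c(chr1 = 200, chr2 = 100)
  r2 <- chromosome_fe(doubled, same, 1e6, 1e6, lens)
  expect_equal(r2$fe, c(2, 1))
  expect_equal(r2$log2_fe, c(1, 0))
  expect_error(chromosome_fe(same, c(chr1 = 0, chr2 = 100), 1e6, 1e6, lens),
               "chr1")
})

test_that("per-chromosome medians use the mean-of-middle-two rule", {
  enr <- make_enrichment(setNames(c(2, 4, 6), paste0("G", 1:3)))
  expect_equal(median_promoter_fe_by_chrom(enr)$median_fe, 4)
  enr2 <- make_enrichment(setNames(c(2, 4, 6, 10), paste0("G", 1:4)))
  expect_equal(median_promoter_fe_by_chrom(enr2)$median_fe, 5)
  one <- make_enrichment(c(G1 = 7.5), chrom = "chr2")
  expect_equal(median_promoter_fe_by_chrom(one)$median_fe, 7.5)
  expect_warning(median_promoter_fe_by_chrom(one, chroms = c("chr2", "chr9")),
                 "chr9")
})

test_that("marked classification is inclusive at the threshold", {
  enr <- make_enrichment(c(G1 = 4.0, G2 = 3.999, G3 = 12))
  mm <- classify_marked(enr, threshold = 4)
  expect_equal(unname(mm$marked[, "lineA.ac"]), c(TRUE, FALSE, TRUE))
  expect_setequal(mm$universe, c("G1", "G3"))

  all_low <- classify_marked(make_enrichment(c(G1 = 1, G2 = 1)))
  expect_length(all_low$universe, 0)
})

test_that("three-way Venn partition enumerates regions and conserves the union", {
  fe <- function(ids, val = 10) setNames(rep(val, length(ids)), ids)
  lines <- c("L1", "L2", "L3")
  # disjoint sets of sizes 1, 2, 3
  enr <- rbind(
    make_enrichment(c(fe("A"), fe(c("B1", "B2"), 1), fe(c("C1", "C2", "C3"), 1)),
                    cell_line = "L1"),
    make_enrichment(c(fe("A", 1), fe(c("B1", "B2")), fe(c("C1", "C2", "C3"), 1)),
                    cell_line = "L2"),
    make_enrichment(c(fe("A", 1), fe(c("B1", "B2"), 1), fe(c("C1", "C2", "C3"))),
                    cell_line = "L3"))
  mm <- classify_marked(enr)
  v <- venn_partition(mm, "ac", lines)
  expect_equal(unname(v$counts[c("L1", "L2", "L3")]), c(1, 2, 3))
  expect_equal(sum(v$counts), v$union)
  expect_equal(v$union, 6)
  expect_true(all(v$counts[grepl("&", names(v$counts))] == 0))

  # identical marked sets land in the triple overlap
  enr_same <- do.call(rbind, lapply(lines, function(l)
    make_enrichment(fe(c("X", "Y")), cell_line = l)))
  v2 <- venn_partition(classify_marked(enr_same), "ac", lines)
  expect_equal(unname(v2$counts["L1&L2&L3"]), 2)
  expect_equal(v2$union, 2)

  # empty marked sets: all zeros
  enr_empty <- do.call(rbind, lapply(lines, function(l)
    make_enrichment(fe(c("X", "Y"), 1), cell_line = l)))
  v3 <- venn_partition(classify_marked(enr_empty), "ac", lines)
  expect_true(all(v3$counts == 0))
  expect_equal(v3$union, 0)

  expect_error(venn_partition(mm, "ac", lines[1:2]), "three")
})

test_that("permuting cell-line order permutes Venn labels consistently", {
  st <- tiny_study(tiny_config(n_genes = 200, marked_fraction = 0.4))
  mm <- classify_marked(st$enr)
  canonical <- function(v) {
    parts <- strsplit(names(v$counts), "&", fixed = TRUE)
    key <- vapply(parts, function(p) paste(sort(p), collapse = "&"),
                  character(1))
    setNames(as.integer(v$counts), key)[order(key)]
  }
  v1 <- venn_partition(mm, "me3", c("lineA", "lineB", "lineC"))
  v2 <- venn_partition(mm, "me3", c("lineC", "lineA", "lineB"))
  expect_equal(canonical(v1), canonical(v2))
  expect_equal(v1$union, v2$union)
})

test_that("top-fraction strata use ceiling and deterministic tie-breaks", {
  n <- 10964
  ids <- sprintf("P%05d", seq_len(n))
  enr <- make_enrichment(setNames(rep(5, n), ids))
  mm <- classify_marked(enr)
  expect_length(mm$universe, n)
  expect_equal(nrow(rank_top_fraction(enr, mm, "ac", 0.25)), 2741)
  expect_equal(nrow(rank_top_fraction(enr, mm, "ac", 0.02)), 220)
  expect_equal(nrow(rank_top_fraction(enr, mm, "ac", 1)), n)
  # all-tied FE: stratum is the lexicographically first gene ids
  top <- rank_top_fraction(enr, mm, "ac", 0.02)
  expect_equal(top$gene_id, ids[1:220])

  empty_mm <- classify_marked(make_enrichment(c(G1 = 1)))
  expect_error(rank_top_fraction(enr, empty_mm, "ac", 0.25), "universe")
})
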