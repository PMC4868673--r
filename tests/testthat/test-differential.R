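two_line_enrichment <- function(fe_a, fe_b, mark = "ac") {
  rbind(make_enrichment(fe_a, mark = mark, cell_line = "A"),
        make_enrichment(fe_b, mark = mark, cell_line = "B"))
}

test_that("differential marking thresholds the log2 FE difference", {
  fe_a <- c(G1 = 2, G2 = 2, G3 = 5)
  fe_b <- c(G1 = 16, G2 = 6, G3 = 5)
  d <- differential_fe(two_line_enrichment(fe_a, fe_b), "A", "B")
  expect_equal(d$delta, log2(fe_b) - log2(fe_a), ignore_attr = TRUE)
  expect_equal(d$differential, c(TRUE, FALSE, FALSE))
  expect_equal(d$gaining, c("B", NA, NA))

  # identical tables: nothing differential
  d0 <- differential_fe(two_line_enrichment(fe_a, fe_a), "A", "B")
  expect_true(all(d0$delta == 0))
  expect_false(any(d0$differential))

  # loss in B is a gain attributed to A
  d2 <- differential_fe(two_line_enrichment(fe_b, fe_a), "A", "B")
  expect_equal(d2$gaining, c("A", NA, NA))
})

test_that("mismatched promoter universes are rejected with the difference size", {
  enr <- rbind(make_enrichment(c(G1 = 2, G2 = 2), cell_line = "A"),
               make_enrichment(c(G1 = 2, G3 = 2, G4 = 2), cell_line = "B"))
  expect_error(differential_fe(enr, "A", "B"), "3")
})

test_that("mark categories separate single, joint and opposite gains", {
  mk_diff <- function(ac_a, ac_b, me3_a, me3_b) {
    enr <- rbind(make_enrichment(ac_a, "ac", "A"),
                 make_enrichment(ac_b, "ac", "B"),
                 make_enrichment(me3_a, "me3", "A"),
                 make_enrichment(me3_b, "me3", "B"))
    differential_fe(enr, "A", "B")
  }
  fe <- c(G1 = 2)
  cat_of <- function(d, line) {
    ct <- assign_mark_category(d)
    ct$category[ct$cell_line == line]
  }
  # ac gains 8-fold toward B, me3 flat
  d <- mk_diff(fe, fe * 8, fe, fe)
  expect_equal(cat_of(d, "B"), "ac_only")
  expect_equal(cat_of(d, "A"), "none")
  # both marks gain toward B
  d <- mk_diff(fe, fe * 8, fe, fe * 8)
  expect_equal(cat_of(d, "B"), "both")
  # opposite gains never merge into "both"
  d <- mk_diff(fe, fe * 8, fe * 8, fe)
  expect_equal(cat_of(d, "B"), "ac_only")
  expect_equal(cat_of(d, "A"), "me3_only")
  # neither mark differential
  d <- mk_diff(fe, fe * 2, fe, fe)
  expect_equal(cat_of(d, "B"), "none")
})

make_collection <- function(sets, universe_size) {
  structure(list(sets = sets,
                 descriptions = setNames(rep("d", length(sets)),
                                         names(sets)),
                 universe_size = universe_size),
            class = "gene_set_collection")
}

test_that("the binomial over-representation tail matches the brute-force oracle", {
  # set 100, universe 1000, query 50, intersection 10
  universe <- sprintf("U%04d", 1:1000)
  set_genes <- universe[1:100]
  query <- c(universe[1:10], universe[901:940])
  coll <- make_collection(list(S = set_genes), 1000)
  res <- binomial_overrep(query, coll, restrict_universe = FALSE)
  expect_equal(res$intersection, 10)
  expect_equal(res$query_size, 50)
  expect_equal(res$p_value, oracle_binom_tail(10, 50, 0.1),
               tolerance = 1e-14)

  # zero intersection: P(X >= 0) = 1
  res0 <- binomial_overrep(universe[901:910], coll,
                           restrict_universe = FALSE)
  expect_equal(res0$p_value, 1)
})

test_that("the binomial tail is monotone in k and in n", {
  p <- 0.07
  tails_k <- vapply(0:30, function(k)
    markscape:::binom_upper_tail(k, 30, p), numeric(1))
  expect_true(all(diff(tails_k) <= 1e-15))
  tails_n <- vapply(10:60, function(n)
    markscape:::binom_upper_tail(5, n, p), numeric(1))
  expect_true(all(diff(tails_n) >= -1e-15))
})

test_that("query genes outside the collection namespace are dropped", {
  coll <- make_collection(list(S = c("A", "B", "C")), 10)
  expect_message(res <- binomial_overrep(c("A", "B", "ZZZ"), coll),
                 "dropped")
  expect_equal(res$query_size, 2)
  expect_equal(res$intersection, 2)
  expect_error(suppressMessages(binomial_overrep("ZZZ", coll)), "namespace")
  expect_error(binomial_overrep(character(0), coll), "empty")
})

test_that("Bonferroni flagging divides alpha or honors an explicit threshold", {
  res <- data.frame(set = c("S1", "S2"), set_size = 10, query_size = 5,
                    intersection = c(3, 0), p_value = c(0.04, 1),
                    neg_log10_p = c(-log10(0.04), 0))
  r1 <- apply_bonferroni(res[1, ], alpha = 0.05, n_tests = 1)
  expect_equal(attr(r1, "threshold"), 0.05)
  expect_true(r1$significant)
  r2 <- apply_bonferroni(res, alpha = 0.05, n_tests = 4914)
  expect_equal(attr(r2, "threshold"), 0.05 / 4914)
  expect_false(any(r2$significant))
  r3 <- apply_bonferroni(res, threshold = 4.9e-9)
  expect_equal(attr(r3, "threshold"), 4.9e-9)
})

test_that("heat matrices keep significant sets ordered by peak signal", {
  mk_res <- function(p, sig) data.frame(
    set = paste0("S", seq_along(p)), set_size = 10, query_size = 5,
    intersection = 1, p_value = p, neg_log10_p = -log10(p),
    significant = sig)
  none <- build_heat_matrix(list(q1 = mk_res(c(0.5, 0.9), c(FALSE, FALSE))))
  expect_equal(nrow(none), 0)

  res1 <- mk_res(c(1e-10, 1e-3, 1e-6), c(TRUE, FALSE, TRUE))
  res2 <- mk_res(c(1e-2, 1e-12, 1e-4), c(FALSE, TRUE, FALSE))
  heat <- build_heat_matrix(list(q1 = res1, q2 = res2))
  expect_equal(rownames(heat), c("S2", "S1", "S3"))  # by descending max
  expect_equal(heat["S1", "q1"], 10)                 # p = 1e-10
  expect_equal(dim(attr(heat, "intersections")), dim(heat))
})

test_that("a planted differential set is detected and decoys are not", {
  res <- planted_run(seed = 7, n_genes = 1000, set_size = 100)
  expect_true(res$significant[res$set == "PLANTED"])
  expect_true(mean(res$significant[res$set != "PLANTED"]) <= 0.05)
})
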