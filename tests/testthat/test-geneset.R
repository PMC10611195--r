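gene_results_fixture <- function(ids, bmd, bmdl = bmd / 2, bmdu = bmd * 2,
                                 excluded = FALSE) {
  tibble::tibble(gene_id = ids, bmd = bmd, bmdl = bmdl, bmdu = bmdu,
                 excluded = excluded)
}

test_that("two-tailed Fisher p equals exhaustive enumeration and fisher.test", {
  cases <- list(
    c(5, 10, 20, 100),
    c(0, 10, 20, 100),
    c(3, 3, 5, 40),
    c(2, 30, 10, 60),
    c(7, 12, 15, 80)
  )
  for (cs in cases) {
    p <- fisher_exact_two_tailed(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, fisher_enum_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    tab <- matrix(c(cs[1], cs[2] - cs[1], cs[3] - cs[1],
                    cs[4] - cs[2] - cs[3] + cs[1]), 2, 2)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_two_tailed(5, 4, 10, 20), "inconsistent")
})

test_that("Fisher p matches enumeration across random tables up to N = 200", {
  set.seed(20)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    K <- sample.int(N, 1)
    k <- sample.int(N, 1)
    sup <- max(0, K + k - N):min(K, k)
    x <- sup[sample.int(length(sup), 1)]
    expect_equal(fisher_exact_two_tailed(x, K, k, N),
                 fisher_enum_oracle(x, K, k, N), tolerance = 1e-12)
  }
})

test_that("enrichment needs p < 0.05 AND at least three overlapping genes", {
  universe <- paste0("g", 1:1000)
  # overlap 2 out of a 2-gene set, all responsive genes inside: tiny p
  gene_results <- gene_results_fixture(paste0("g", 1:2), bmd = c(1, 2))
  sets <- list(tiny = c("g1", "g2"), all = universe)
  enr <- enrich_gene_sets(sets, gene_results, universe)
  tiny <- enr[enr$set_id == "tiny", ]
  expect_lt(tiny$p_value, 1e-4)
  expect_false(tiny$enriched)              # fails the >= 3 overlap rule
  whole <- enr[enr$set_id == "all", ]
  expect_equal(whole$p_value, 1)           # set = universe is uninformative
  expect_false(whole$enriched)
})

test_that("per-set medians use only non-excluded genes, order-independently", {
  ids <- paste0("g", 1:5)
  res <- gene_results_fixture(ids, bmd = c(1, 2, 3, 4, 100),
                              bmdl = c(.5, 1, 1.5, 2, 50),
                              bmdu = c(2, 4, 6, 8, 200),
                              excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  sets <- list(s1 = ids)
  universe <- c(ids, paste0("x", 1:20))
  enr1 <- enrich_gene_sets(sets, res, universe)
  expect_equal(enr1$overlap, 4)            # excluded gene does not count
  expect_equal(enr1$median_bmd, 2.5)
  expect_equal(enr1$median_bmdl, 1.25)
  expect_equal(enr1$median_bmdu, 5)

  set.seed(21)
  enr2 <- enrich_gene_sets(list(s1 = sample(rep(ids, 1))), res[sample(5), ],
                           universe)
  expect_equal(enr2$median_bmd, enr1$median_bmd)
  expect_equal(enr2$p_value, enr1$p_value)
})

test_that("TPOD comes from the most sensitive enriched set (Table-2 pattern)", {
  enr <- tibble::tibble(
    set_id = c("mammary_prolif", "other"),
    overlap = c(5, 5), set_size = c(10, 10), n_responsive = 40,
    n_universe = 1000, p_value = c(1e-4, 1e-4),
    enriched = c(TRUE, TRUE),
    median_bmd = c(0.018, 0.101), median_bmdl = c(0.009, 0.046),
    median_bmdu = c(0.429, 1.291)
  )
  tp <- derive_tpod(enr, chemical = "fenthion", assay = "mouse")
  expect_equal(tp$set_id, "mammary_prolif")
  expect_equal(tp$geneset_bmd, 0.018)
  expect_equal(tp$tpod, 0.009)
  expect_equal(tp$n_enriched_sets, 2L)
})

test_that("a single enriched set's median BMDL is the TPOD", {
  res <- gene_results_fixture(paste0("g", 1:3), bmd = c(1, 2, 4),
                              bmdl = c(0.5, 1, 2))
  enr <- enrich_gene_sets(list(s = paste0("g", 1:3)), res, paste0("g", 1:50))
  expect_true(enr$enriched)
  tp <- derive_tpod(enr)
  expect_equal(tp$tpod, 1)     # median of {0.5, 1, 2}
})

test_that("ties break by median BMDL, then p, then set id; empty is explicit", {
  base <- tibble::tibble(
    overlap = 5, set_size = 10, n_responsive = 40, n_universe = 1000,
    enriched = TRUE, median_bmdu = 10
  )
  enr <- dplyr::bind_cols(
    tibble::tibble(set_id = c("b", "a", "c"),
                   p_value = c(0.001, 0.001, 0.0001),
                   median_bmd = c(1, 1, 1),
                   median_bmdl = c(0.5, 0.5, 0.9)),
    base
  )
  tp <- derive_tpod(enr)
  expect_equal(tp$set_id, "a")   # lowest BMDL ties at 0.5 -> p ties -> id

  none <- derive_tpod(enr[integer(0), ], chemical = "x")
  expect_equal(none$n_enriched_sets, 0L)
  expect_true(is.na(none$tpod))
  expect_equal(none$chemical, "x")
})

test_that("accumulation table sorts by BMD with independent BMDL ranks", {
  enr <- tibble::tibble(
    set_id = c("s1", "s2", "s3"),
    overlap = 3, set_size = 5, n_responsive = 10, n_universe = 100,
    p_value = 0.01, enriched = TRUE,
    median_bmd = c(0.2, 0.1, 0.3),
    # BMDL order crosses the BMD order
    median_bmdl = c(0.01, 0.09, 0.05),
    median_bmdu = c(1, 1, 1)
  )
  acc <- accumulation_table(enr)
  expect_equal(acc$set_id, c("s2", "s1", "s3"))       # ascending median BMD
  expect_equal(acc$median_bmd, c(0.1, 0.2, 0.3))
  expect_equal(acc$rank_bmd, 1:3)
  expect_equal(acc$rank_bmdl[acc$set_id == "s1"], 1L)  # different order by BMDL
  expect_equal(acc$rank_bmdl[acc$set_id == "s2"], 3L)

  single <- accumulation_table(enr[1, ])
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank_bmd, 1L)
})

test_that("removing the winning set can only raise the gene-set BMD", {
  set.seed(22)
  for (i in 1:10) {
    n_sets <- 5
    enr <- tibble::tibble(
      set_id = paste0("s", 1:n_sets),
      overlap = 4, set_size = 8, n_responsive = 20, n_universe = 500,
      p_value = runif(n_sets, 0, 0.04), enriched = TRUE,
      median_bmd = runif(n_sets, 0.1, 5),
      median_bmdl = NA_real_, median_bmdu = NA_real_
    )
    enr$median_bmdl <- enr$median_bmd * runif(n_sets, 0.2, 0.9)
    enr$median_bmdu <- enr$median_bmd * runif(n_sets, 1.1, 3)
    tp <- derive_tpod(enr)
    tp2 <- derive_tpod(enr[enr$set_id != tp$set_id, ])
    expect_gte(tp2$geneset_bmd, tp$geneset_bmd)
  }
})

test_that("empty universe errors; sets outside the universe are skipped", {
  res <- gene_results_fixture("g1", bmd = 1)
  expect_error(enrich_gene_sets(list(s = "g1"), res, character(0)),
               "empty universe")
  enr <- enrich_gene_sets(list(s = "g1", ghost = c("z1", "z2")), res,
                          c("g1", paste0("g", 2:10)))
  expect_identical(attr(enr, "skipped_sets"), "ghost")
  expect_equal(nrow(enr), 1L)
})
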