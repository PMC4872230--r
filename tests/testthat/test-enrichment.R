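test_that("hypergeometric upper tail handles boundary cases", {
  expect_equal(hypergeom_upper_tail(N = 10, M = 4, n = 5, m = 0), 1.0)
  expect_equal(hypergeom_upper_tail(N = 7, M = 7, n = 7, m = 7), 1.0)
  expect_error(hypergeom_upper_tail(N = 5, M = 6, n = 2, m = 1), "invalid")
  expect_error(hypergeom_upper_tail(N = 5, M = 2, n = 2, m = 3), "invalid")
})

test_that("upper tail equals exhaustive draw enumeration", {
  expect_equal(hypergeom_upper_tail(N = 10, M = 4, n = 5, m = 3),
               oracle_hyper_upper(10, 4, 5, 3), tolerance = 1e-12)
  for (N in c(6, 9)) {
    for (M in 0:N) {
      for (n in 1:N) {
        for (m in seq_len(min(n, M))) {
          expect_equal(hypergeom_upper_tail(N, M, n, m),
                       oracle_hyper_upper(N, M, n, m),
                       tolerance = 1e-12,
                       label = sprintf("N=%d M=%d n=%d m=%d", N, M, n, m))
        }
      }
    }
  }
})

test_that("upper tail is symmetric in (M, n) and monotone in m", {
  set.seed(101)
  for (i in 1:30) {
    N <- sample(5:40, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    m <- if (min(n, M) > 0) sample(0:min(n, M), 1) else 0
    expect_equal(hypergeom_upper_tail(N, M, n, m),
                 hypergeom_upper_tail(N, n, M, m), tolerance = 1e-12)
    if (m < min(n, M)) {
      expect_gte(hypergeom_upper_tail(N, M, n, m),
                 hypergeom_upper_tail(N, M, n, m + 1))
    }
  }
})

test_that("enrichment applies Bonferroni over tested terms only", {
  # 20 terms, one strongly enriched; terms with m = 0 are not tested
  genes <- sprintf("g%02d", 1:40)
  map <- data.frame(gene = rep(genes, each = 1),
                    term = rep(sprintf("T%02d", 1:20), each = 2),
                    stringsAsFactors = FALSE)
  cand <- genes[1:2]  # both carry T01
  res <- enrich(map, cand, method = "bonferroni")
  expect_true(all(res$m >= 1))
  t01 <- res[res$term == "T01", ]
  expect_equal(t01$p_adjusted,
               min(1, t01$p_raw * nrow(res)), tolerance = 1e-12)
  expect_equal(t01$N, 40)
  expect_equal(t01$n, 2)
  expect_equal(t01$M, 2)
  expect_equal(t01$m, 2)
  # raw p of a tested term does not depend on m = 0 terms being present
  map2 <- rbind(map, data.frame(gene = "g40", term = "T99"))
  res2 <- enrich(map2, cand, method = "bonferroni")
  expect_equal(res2$p_raw[res2$term == "T01"], t01$p_raw)

  expect_error(enrich(map, c("g01", "nope")), "nope")
})

test_that("all-null p-values are never significant", {
  genes <- sprintf("g%02d", 1:10)
  map <- data.frame(gene = genes, term = "T01", stringsAsFactors = FALSE)
  res <- enrich(map, genes[1:3])  # p = 1 exactly (M = N)
  expect_equal(res$p_raw, 1)
  expect_false(any(res$significant & res$p_adjusted < 1))
})

test_that("BH significance set equals the step-up oracle", {
  set.seed(102)
  for (i in 1:30) {
    p <- runif(sample(5:30, 1))^sample(1:3, 1)
    sig_pkg <- stats::p.adjust(p, "BH") <= 0.05
    expect_equal(sig_pkg, oracle_bh_significant(p, 0.05),
                 label = paste("case", i))
  }
  # and through the enrich() surface
  genes <- sprintf("g%03d", 1:60)
  set.seed(103)
  map <- data.frame(
    gene = sample(genes, 300, TRUE),
    term = sample(sprintf("T%02d", 1:12), 300, TRUE))
  map <- unique(map)
  cand <- sample(genes, 15)
  cand <- intersect(cand, map$gene)
  res <- enrich(map, cand, method = "BH", alpha = 0.3)
  expect_equal(res$significant, oracle_bh_significant(res$p_raw, 0.3))
  expect_true(all(res$p_adjusted >= res$p_raw))
})

test_that("GO classification counts genes once per category", {
  map <- data.frame(gene = "g1", term = "T1", stringsAsFactors = FALSE)
  ont <- c(T1 = "BP")
  cc <- classify_go(map, ont)
  expect_equal(cc$n_genes[cc$category == "BP"], 1)
  expect_equal(cc$n_genes[cc$category == "CC"], 0)

  map <- data.frame(gene = c("g1", "g1"), term = c("T1", "T2"))
  ont <- c(T1 = "BP", T2 = "MF")
  cc <- classify_go(map, ont)
  expect_equal(cc$n_genes[cc$category %in% c("BP", "MF")], c(1, 1))

  set.seed(104)
  genes <- sprintf("g%02d", 1:20)
  terms <- sprintf("T%02d", 1:9)
  ont <- setNames(rep(c("BP", "CC", "MF"), 3), terms)
  map <- unique(data.frame(gene = sample(genes, 60, TRUE),
                           term = sample(terms, 60, TRUE)))
  cc <- classify_go(map, ont)
  for (cat in c("BP", "CC", "MF")) {
    want <- length(unique(map$gene[ont[map$term] == cat]))
    expect_equal(cc$n_genes[cc$category == cat], want, label = cat)
  }
})

test_that("validation rates follow the detected-over-tested convention", {
  expect_equal(validation_rate(3, 4), 75)
  expect_equal(validation_rate(18, 19), 94.7)
  expect_error(validation_rate(5, 4))
})
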