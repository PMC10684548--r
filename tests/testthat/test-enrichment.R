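test_that("odds ratio follows the printed formula with zero-cell handling", {
  expect_equal(odds_ratio(5, 5, 1, 9), 9)
  expect_equal(odds_ratio(3, 7, 3, 7), 1)
  expect_equal(odds_ratio(4, 6, 0, 10), Inf)
  expect_equal(odds_ratio(0, 6, 4, 10), 0)
  expect_true(is.nan(odds_ratio(0, 5, 0, 5)))
  # reciprocal symmetry on all-positive tables
  set.seed(41)
  for (rep in 1:20) {
    t <- sample(1:30, 4, replace = TRUE)
    expect_equal(odds_ratio(t[1], t[2], t[3], t[4]) *
                   odds_ratio(t[3], t[4], t[1], t[2]), 1, tolerance = 1e-12)
  }
})

test_that("one-tailed Fisher p has its closed-form extremes", {
  expect_equal(fisher_one_tailed(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_one_tailed(0, 10, 10, 0), 1)
})

test_that("Fisher p agrees with enumeration and with fisher.test", {
  set.seed(42)
  for (rep in 1:200) {
    t <- sample(0:12, 4, replace = TRUE)
    got <- fisher_one_tailed(t[1], t[2], t[3], t[4])
    expect_equal(got, oracle_fisher(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    if (sum(t) > 0) {
      ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                               alternative = "greater")
      expect_equal(got, ft$p.value, tolerance = 1e-8)
    }
  }
})

test_that("domain enrichment counts architectures, not rHMMs", {
  # topology T occurs in 8/10 mosaic and 1/20 non-mosaic architectures
  keys <- c(paste0("900.1.1|", sprintf("%d.1.1", 1:8)),       # mosaic with T
            paste0("901.1.1|", sprintf("%d.1.1", c(9, 10))),  # mosaic without
            paste0("900.1.1|", "902.1.1"),                    # non-mosaic with
            sprintf("%d.2.1|%d.3.1", 11:29, 11:29))           # non-mosaic without
  archs <- data.frame(rhmm_id = sprintf("r%02d", seq_along(keys)),
                      architecture_key = keys, stringsAsFactors = FALSE)
  tg <- strsplit(keys, "|", fixed = TRUE)
  archs$n_t_groups <- lengths(tg)
  archs$n_x_groups <- lengths(tg)
  calls <- data.frame(id_a = sprintf("r%02d", 1:10),
                      id_b = sprintf("r%02d", c(2:10, 1)),
                      basis = "ecod", p_id = NA_real_,
                      stringsAsFactors = FALSE)
  res <- domain_enrichment(archs, calls)
  row <- res[res$feature == "900.1.1", ]
  expect_equal(unname(unlist(row[, c("a", "b", "c", "d")])), c(8, 2, 1, 19))
  expect_equal(row$odds_ratio, (8 / 2) / (1 / 19))
  expect_equal(row$n_tests[1], length(unique(unlist(tg))))
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * res$n_tests))
  # a topology present in every architecture exercises the infinite branch
  keys2 <- c("1.1.1|2.1.1", "1.1.1|3.1.1")
  archs2 <- data.frame(rhmm_id = c("x1", "x2"), architecture_key = keys2,
                       n_t_groups = 2L, n_x_groups = 2L,
                       stringsAsFactors = FALSE)
  calls2 <- data.frame(id_a = "x1", id_b = "x2", basis = "ecod",
                       p_id = NA_real_, stringsAsFactors = FALSE)
  res2 <- domain_enrichment(archs2, calls2)
  expect_true(all(is.nan(res2$odds_ratio)))  # no non-mosaic units at all
})

test_that("independent tally reproduces the domain contingency tables", {
  set.seed(43)
  t_pool <- paste0(1:12, ".1.1")
  keys <- vapply(1:25, function(i)
    paste(sort(sample(t_pool, sample(1:3, 1))), collapse = "|"),
    character(1))
  keys <- unique(keys)
  archs <- data.frame(rhmm_id = sprintf("r%02d", seq_along(keys)),
                      architecture_key = keys, stringsAsFactors = FALSE)
  tg <- strsplit(keys, "|", fixed = TRUE)
  archs$n_t_groups <- lengths(tg)
  archs$n_x_groups <- lengths(tg)
  mosaic_ids <- archs$rhmm_id[seq_len(floor(length(keys) / 3))]
  calls <- data.frame(id_a = mosaic_ids, id_b = rev(mosaic_ids),
                      basis = "ecod", p_id = NA_real_,
                      stringsAsFactors = FALSE)
  res <- domain_enrichment(archs, calls)
  flag <- keys %in% archs$architecture_key[archs$rhmm_id %in% mosaic_ids]
  for (f in res$feature) {
    has <- vapply(tg, function(t) f %in% t, TRUE)
    expect_equal(unname(unlist(res[res$feature == f, c("a", "b", "c", "d")])),
                 c(sum(has & flag), sum(!has & flag),
                   sum(has & !flag), sum(!has & !flag)))
  }
})

test_that("class-family enrichment matches a hand-counted toy", {
  # 6 families, 3 classes; families 1-3 mosaic
  part <- data.frame(rhmm_id = sprintf("r%d", 1:12),
                     family_id = rep(1:6, each = 2), stringsAsFactors = FALSE)
  flags <- data.frame(family_id = 1:6,
                      ecod_mosaic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      sequence_mosaic = FALSE)
  ann <- data.frame(
    rhmm_id = sprintf("r%d", 1:12), status = "assigned",
    simplified_class = c("A", "A",   # fam 1 mosaic
                         "A", "B",   # fam 2 mosaic
                         "B", "B",   # fam 3 mosaic
                         "A", "A",   # fam 4
                         "C", "C",   # fam 5
                         "B", "C"),  # fam 6
    stringsAsFactors = FALSE)
  res <- class_family_enrichment(part, flags, ann, c("A", "B", "C"), "ecod")
  # class A: mosaic with = {1,2}, mosaic without = {3}; non-mosaic with {4},
  # without {5,6}
  expect_equal(unname(unlist(res[res$feature == "A", c("a", "b", "c", "d")])),
               c(2, 1, 1, 2))
  expect_equal(unname(unlist(res[res$feature == "C", c("a", "b", "c", "d")])),
               c(0, 3, 2, 1))
  expect_equal(res$odds_ratio[res$feature == "C"], 0)
  expect_equal(unique(res$n_tests), 3L)
})

test_that("mosaic class network applies the four-architecture-pair rule", {
  # classes P and Q linked through 4 distinct architecture pairs; Q-R only 3
  mk_arch <- function(i) sprintf("%d.1.1|%d00.1.1", i, i)
  rids <- sprintf("r%02d", 1:14)
  archs <- data.frame(rhmm_id = rids,
                      architecture_key = mk_arch(1:14),
                      n_t_groups = 2L, n_x_groups = 2L,
                      stringsAsFactors = FALSE)
  ann <- data.frame(rhmm_id = rids, status = "assigned",
                    simplified_class = c(rep("P", 4), rep("Q", 7),
                                         rep("R", 3)),
                    stringsAsFactors = FALSE)
  fm <- data.frame(phrog_class = "x", simplified_class = "P",
                   category = "c", phrog_total_seqs = 600L,
                   stringsAsFactors = FALSE)
  attr(fm, "generic_classes") <- character()
  calls <- data.frame(
    id_a = c(rids[1:4], rids[12:14]),
    id_b = c(rids[5:8], rids[9:11]),
    basis = "ecod",
    p_id = c(0.55, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  net <- mosaic_network(calls, archs, ann, fm, min_arch_pairs = 4)
  edges <- igraph::as_data_frame(net, "edges")
  expect_equal(nrow(edges), 1L)
  expect_setequal(unlist(edges[, c("from", "to")]), c("P", "Q"))
  expect_equal(edges$n_arch_pairs, 4L)
  expect_true(edges$contemporary)
  # without the contemporary-identity pair the flag is off
  calls$p_id[1] <- 0.49
  net2 <- mosaic_network(calls, archs, ann, fm, min_arch_pairs = 4)
  expect_false(igraph::as_data_frame(net2, "edges")$contemporary)
  # node size: distinct architectures per class
  expect_equal(igraph::V(net)$n_architectures[match("Q", igraph::V(net)$name)],
               7L)
})

test_that("recent network maps unannotated partners to an unknown node", {
  ann <- data.frame(rhmm_id = c("r1", "r2"), status = "assigned",
                    simplified_class = c("P", "Q"), stringsAsFactors = FALSE)
  fm <- data.frame(phrog_class = "x", simplified_class = "P", category = "c",
                   phrog_total_seqs = 600L, stringsAsFactors = FALSE)
  attr(fm, "generic_classes") <- character()
  calls <- data.frame(id_a = c("r1", "r1", "r2"),
                      id_b = c("r2", "r9", "r8"),
                      basis = "sequence",
                      p_id = c(0.75, 0.92, 0.69),
                      tier = recency_tier(c(0.75, 0.92, 0.69)),
                      stringsAsFactors = FALSE)
  net <- recent_network(calls, ann, fm, min_tier = "recent_high")
  edges <- igraph::as_data_frame(net, "edges")
  expect_equal(nrow(edges), 2L)  # r2-r8 is below the tier
  expect_true("unknown" %in% igraph::V(net)$name)
  expect_true(any(edges$from == "unknown" | edges$to == "unknown"))
  net_hi <- recent_network(calls, ann, fm, min_tier = "recent_very_high")
  expect_equal(nrow(igraph::as_data_frame(net_hi, "edges")), 1L)
})

test_that("networks ignore the order of the input calls", {
  set.seed(44)
  rids <- sprintf("r%02d", 1:10)
  archs <- data.frame(rhmm_id = rids,
                      architecture_key = sprintf("%d.1.1|%d00.1.1", 1:10, 1:10),
                      n_t_groups = 2L, n_x_groups = 2L, stringsAsFactors = FALSE)
  ann <- data.frame(rhmm_id = rids, status = "assigned",
                    simplified_class = rep(c("P", "Q"), 5),
                    stringsAsFactors = FALSE)
  fm <- data.frame(phrog_class = "x", simplified_class = "P", category = "c",
                   phrog_total_seqs = 600L, stringsAsFactors = FALSE)
  attr(fm, "generic_classes") <- character()
  calls <- data.frame(id_a = rids[1:5], id_b = rids[6:10], basis = "ecod",
                      p_id = runif(5), stringsAsFactors = FALSE)
  n1 <- mosaic_network(calls, archs, ann, fm, min_arch_pairs = 2)
  n2 <- mosaic_network(calls[sample(5), ], archs, ann, fm, min_arch_pairs = 2)
  e1 <- igraph::as_data_frame(n1, "edges")
  e2 <- igraph::as_data_frame(n2, "edges")
  expect_equal(e1[order(e1$from, e1$to), ], e2[order(e2$from, e2$to), ],
               ignore_attr = TRUE)
})

test_that("random mosaic labels keep the Fisher rejection rate near nominal", {
  set.seed(45)
  n_units <- 200; n_feat <- 300
  flag <- rep(c(TRUE, FALSE), n_units / 2)
  p <- numeric(n_feat)
  for (f in seq_len(n_feat)) {
    present <- runif(n_units) < 0.5
    fl <- sample(flag)
    p[f] <- fisher_one_tailed(sum(present & fl), sum(!present & fl),
                              sum(present & !fl), sum(!present & !fl))
  }
  rate <- mean(p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / n_feat)
  expect_lt(rate, 0.05 + bound)
  expect_gt(rate, 0.05 - bound - 0.02)  # discreteness keeps the test conservative
})
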