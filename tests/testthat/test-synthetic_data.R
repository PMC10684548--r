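test_that("the generator is deterministic given a seed", {
  b1 <- simulate_mosaic_data(simulation_config(seed = 5))
  b2 <- simulate_mosaic_data(simulation_config(seed = 5))
  expect_identical(b1, b2)
  b3 <- simulate_mosaic_data(simulation_config(seed = 6))
  expect_false(identical(b1$self_hits, b3$self_hits))
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_mosaic_data(simulation_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("noiseless output contains every true domain at full quality", {
  b <- simulate_mosaic_data(simulation_config(
    seed = 2, domain_dropout_rate = 0, probability_jitter_sd = 0))
  expect_true(all(b$ecod_hits$probability == 0.99))
  expect_true(all(b$ecod_hits$s_start == 1L &
                    b$ecod_hits$s_end == b$ecod_hits$s_len))
  n_true <- sum(lengths(b$truth$architectures))
  expect_equal(nrow(b$ecod_hits), n_true)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_rhmms = 20, n_families = 15,
                                 n_ecod_mosaic_pairs = 20),
               "infeasible")
  expect_error(simulation_config(domain_dropout_rate = 1.5), "dropout")
})

test_that("dropout removes domains at the configured binomial rate", {
  cfg <- simulation_config(seed = 3, n_rhmms = 600, n_families = 0,
                           n_ecod_mosaic_pairs = 0,
                           n_sequence_mosaic_pairs = 0,
                           domain_dropout_rate = 0.3)
  b <- simulate_mosaic_data(cfg)
  n_true <- sum(lengths(b$truth$architectures))
  expect_gt(n_true, 900)
  retained <- nrow(b$ecod_hits) / n_true
  ci <- 2.576 * sqrt(0.3 * 0.7 / n_true)
  expect_lt(abs(retained - 0.7), ci)
})

test_that("planted tables round-trip through the writers", {
  b <- simulate_mosaic_data(simulation_config(seed = 4, n_rhmms = 60,
                                              n_families = 4,
                                              n_ecod_mosaic_pairs = 4,
                                              n_sequence_mosaic_pairs = 4))
  dir <- withr::local_tempdir()
  write_simulation(b, dir)
  self <- read_hit_table(file.path(dir, "self_hits.tsv"), "native_tsv")
  expect_equal(self, b$self_hits)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md, b$metadata)
})

test_that("config files read back into equivalent configurations", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_rhmms: 80", "n_families: 5",
               "n_ecod_mosaic_pairs: 6", "n_sequence_mosaic_pairs: 6",
               "domain_dropout_rate: 0.2"), f)
  cfg <- read_simulation_config(f)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_rhmms, 80L)
  expect_equal(cfg$domain_dropout_rate, 0.2)
})

test_that("planted pairs satisfy their defining predicates by construction", {
  b <- simulate_mosaic_data(simulation_config(seed = 7))
  tr <- b$truth
  for (k in seq_len(nrow(tr$ecod_pairs)))
    expect_false(is.null(ecod_mosaic(
      tr$architectures[[tr$ecod_pairs$id_a[k]]],
      tr$architectures[[tr$ecod_pairs$id_b[k]]])))
  expect_true(all(tr$sequence_pairs$p_id >= 0.30))
  expect_equal(recency_tier(tr$sequence_pairs$p_id), tr$sequence_pairs$tier)
})

test_that("recovery scoring returns perfect values on matching calls", {
  b <- simulate_mosaic_data(simulation_config(seed = 8, n_rhmms = 60,
                                              n_families = 4,
                                              n_ecod_mosaic_pairs = 5,
                                              n_sequence_mosaic_pairs = 5))
  tr <- b$truth
  ecod_calls <- data.frame(id_a = tr$ecod_pairs$id_a,
                           id_b = tr$ecod_pairs$id_b, basis = "ecod",
                           stringsAsFactors = FALSE)
  seq_calls <- data.frame(id_a = tr$sequence_pairs$id_a,
                          id_b = tr$sequence_pairs$id_b, basis = "sequence",
                          stringsAsFactors = FALSE)
  part <- data.frame(rhmm_id = names(tr$families),
                     family_id = unname(tr$families),
                     stringsAsFactors = FALSE)
  sc <- score_recovery(ecod_calls, seq_calls, part, tr)
  expect_equal(sc$ecod$precision, 1)
  expect_equal(sc$sequence$recall, 1)
  expect_equal(sc$family_ari, 1)
  # a spurious call costs precision, not recall
  sc2 <- score_recovery(rbind(ecod_calls,
                              data.frame(id_a = "rhmm00001",
                                         id_b = "rhmm00059", basis = "ecod")),
                        seq_calls, part, tr)
  expect_lt(sc2$ecod$precision, 1)
  expect_equal(sc2$ecod$recall, 1)
})

test_that("partition ARI matches the hand-evaluated closed form", {
  # 4 nodes, planted {r1,r2}{r3,r4} vs recovered {r1,r3}{r2,r4}:
  # sum_ij C(n_ij,2)=0, sum_i C(a_i,2)=sum_j C(b_j,2)=2, E=2*2/C(4,2)=2/3,
  # max=2, so ARI = (0 - 2/3)/(2 - 2/3) = -1/2
  tr <- list(families = c(r1 = 1L, r2 = 1L, r3 = 2L, r4 = 2L),
             ecod_pairs = data.frame(id_a = character(), id_b = character()),
             sequence_pairs = data.frame(id_a = character(),
                                         id_b = character()))
  part <- data.frame(rhmm_id = c("r1", "r2", "r3", "r4"),
                     family_id = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  sc <- score_recovery(tr$ecod_pairs, tr$sequence_pairs, part, tr)
  expect_equal(sc$family_ari, -0.5)
  part$family_id <- c(1L, 1L, 2L, 2L)
  expect_equal(score_recovery(tr$ecod_pairs, tr$sequence_pairs, part,
                              tr)$family_ari, 1)
})

test_that("shuffled family labels score an ARI near zero", {
  b <- simulate_mosaic_data(simulation_config(seed = 10))
  tr <- b$truth
  aris <- replicate(20, {
    part <- data.frame(rhmm_id = names(tr$families),
                       family_id = sample(unname(tr$families)),
                       stringsAsFactors = FALSE)
    score_recovery(tr$ecod_pairs[0, ], tr$sequence_pairs[0, ],
                   part, tr)$family_ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("recovery recall does not increase with dropout", {
  recalls <- vapply(c(0, 0.3, 0.6), function(d) {
    cfg <- simulation_config(seed = 11, n_rhmms = 150, n_families = 0,
                             n_ecod_mosaic_pairs = 60,
                             n_sequence_mosaic_pairs = 0,
                             domain_dropout_rate = d)
    b <- simulate_mosaic_data(cfg)
    archs <- build_architectures(
      assign_domains(domain_hits_from_table(b$ecod_hits, b$ecod_map)),
      rhmm_ids = b$lengths$id)
    calls <- detect_ecod_mosaic(archs)
    part <- data.frame(rhmm_id = names(b$truth$families),
                       family_id = unname(b$truth$families),
                       stringsAsFactors = FALSE)
    score_recovery(calls, calls[0, ], part, b$truth)$ecod$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0.05))  # non-increasing up to noise
  expect_equal(recalls[1], 1)
})
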