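#' Configuration for the synthetic phage-proteome generator
#'
#' Describes a simulated set of representative profiles (rHMMs) with
#' planted ground truth: full-length homologous pairs grouped into protein
#' families, pairs with planted ECOD-based mosaicism (a shared private
#' T-group plus a unique-X domain on each side), pairs with planted
#' sequence-based mosaicism (a short, high-probability shared fragment),
#' and a background of rHMMs whose domains all come from a single X-group,
#' so that by construction no background pair can satisfy the ECOD
#' mosaicism predicate. Background X-groups are disjoint from the private
#' per-pair pool used by planted mosaic pairs.
#'
#' @param seed integer seed driving one explicit RNG stream.
#' @param n_rhmms total number of rHMMs.
#' @param n_families planted families of full-length homologs.
#' @param family_size_range inclusive range family sizes are drawn from.
#' @param n_ecod_mosaic_pairs,n_sequence_mosaic_pairs planted pair counts.
#' @param n_x_groups,h_per_x,t_per_h background ECOD universe dimensions.
#' @param architecture_size_distribution probabilities of 1..5 background
#'   domains per rHMM.
#' @param domain_dropout_rate probability that a true domain is missing
#'   from the ECOD hit table.
#' @param probability_jitter_sd Gaussian jitter subtracted from the 0.99
#'   base hit probability (clamped to keep qualifying hits qualifying).
#' @param sequence_tier_mix probabilities that a planted sequence-mosaic
#'   pair's fragment identity falls in the baseline / contemporary /
#'   recent-high / recent-very-high band (its planted "age").
#' @param class_labels simplified functional classes in play.
#' @param fraction_unknown fraction of rHMMs left without PHROG hits.
#' @param n_antidefence rHMMs additionally given a qualifying antidefence
#'   hit (overriding their class).
#' @param spurious_hit_rate expected number, per rHMM, of low-probability
#'   (non-qualifying) self-search hits to random partners; exercises the
#'   permissive-background filter.
#' @param n_genomes genomes the proteins are scattered over.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_rhmms = 200L,
                              n_families = 15L,
                              family_size_range = c(2L, 4L),
                              n_ecod_mosaic_pairs = 20L,
                              n_sequence_mosaic_pairs = 20L,
                              n_x_groups = 30L,
                              h_per_x = 2L,
                              t_per_h = 2L,
                              architecture_size_distribution =
                                c(0.45, 0.30, 0.15, 0.07, 0.03),
                              domain_dropout_rate = 0,
                              probability_jitter_sd = 0,
                              sequence_tier_mix = c(0.4, 0.3, 0.2, 0.1),
                              class_labels = c("tail fibre", "tail spike",
                                               "endolysin", "DNA polymerase",
                                               "terminase", "portal",
                                               "integrase", "exonuclease"),
                              fraction_unknown = 0.1,
                              n_antidefence = 2L,
                              spurious_hit_rate = 0,
                              n_genomes = 30L) {
  cfg <- list(seed = as.integer(seed), n_rhmms = as.integer(n_rhmms),
              n_families = as.integer(n_families),
              family_size_range = as.integer(family_size_range),
              n_ecod_mosaic_pairs = as.integer(n_ecod_mosaic_pairs),
              n_sequence_mosaic_pairs = as.integer(n_sequence_mosaic_pairs),
              n_x_groups = as.integer(n_x_groups),
              h_per_x = as.integer(h_per_x), t_per_h = as.integer(t_per_h),
              architecture_size_distribution = architecture_size_distribution,
              domain_dropout_rate = domain_dropout_rate,
              probability_jitter_sd = probability_jitter_sd,
              sequence_tier_mix = sequence_tier_mix,
              class_labels = class_labels,
              fraction_unknown = fraction_unknown,
              n_antidefence = as.integer(n_antidefence),
              spurious_hit_rate = spurious_hit_rate,
              n_genomes = as.integer(n_genomes))
  max_family <- cfg$n_families * max(cfg$family_size_range)
  need <- max_family + 2L * cfg$n_ecod_mosaic_pairs +
    2L * cfg$n_sequence_mosaic_pairs
  if (need > cfg$n_rhmms)
    stop("infeasible config: ", need, " rHMMs needed for planted structure ",
         "but n_rhmms = ", cfg$n_rhmms)
  if (cfg$domain_dropout_rate < 0 || cfg$domain_dropout_rate > 1)
    stop("domain_dropout_rate must be in [0,1]")
  if (abs(sum(cfg$architecture_size_distribution) - 1) > 1e-8)
    stop("architecture_size_distribution must sum to 1")
  if (abs(sum(cfg$sequence_tier_mix) - 1) > 1e-8)
    stop("sequence_tier_mix must sum to 1")
  class(cfg) <- "simulation_config"
  cfg
}

#' Read a simulation configuration from a YAML key-value file
#'
#' Scalar keys override the defaults of [simulation_config()].
#'
#' @param path YAML file.
#' @return `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

tier_bands <- list(baseline = c(0.30, 0.49), contemporary = c(0.50, 0.69),
                   recent_high = c(0.70, 0.89),
                   recent_very_high = c(0.90, 0.99))

#' Simulate a full input bundle with planted ground truth
#'
#' Deterministic given `config$seed`. Produces every table the pipeline
#' consumes (self/ECOD/PHROG/antidefence hit tables, ECOD id map, function
#' map, genome metadata) together with the `truth` record of what was
#' planted. Planted ECOD-mosaic pairs satisfy the three-part architecture
#' predicate on their true architectures, and planted sequence-mosaic
#' pairs satisfy all four fragment criteria on their true values, by
#' construction; unrelated pairs emit no qualifying hits.
#'
#' @param config a [simulation_config()].
#' @return list with `self_hits`, `ecod_hits`, `phrog_hits`,
#'   `antidefence_hits`, `ecod_map`, `function_map`, `metadata`, `lengths`
#'   and `truth` (list: `architectures`, `classes`, `families`,
#'   `ecod_pairs`, `sequence_pairs`, `groups`).
#' @export
simulate_mosaic_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_rhmms
  ids <- sprintf("rhmm%05d", seq_len(n))

  # ---- allocate roles -------------------------------------------------
  fam_sizes <- sample(seq(config$family_size_range[1L],
                          config$family_size_range[2L]),
                      config$n_families, replace = TRUE)
  cursor <- 0L
  take <- function(k) {
    out <- ids[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  fam_members <- lapply(fam_sizes, take)
  ecod_pairs <- lapply(seq_len(config$n_ecod_mosaic_pairs),
                       function(k) take(2L))
  seq_pairs <- lapply(seq_len(config$n_sequence_mosaic_pairs),
                      function(k) take(2L))
  background <- if (cursor < n) ids[(cursor + 1L):n] else character()

  # ---- ECOD universe and true architectures ---------------------------
  bg_t <- unlist(lapply(seq_len(config$n_x_groups), function(x)
    unlist(lapply(seq_len(config$h_per_x), function(h)
      paste(x, h, seq_len(config$t_per_h), sep = ".")))))
  bg_t_by_x <- split(bg_t, ecod_x_of(bg_t))

  true_arch <- stats::setNames(vector("list", n), ids)
  # background-style architecture: all domains from one X-group
  draw_background_arch <- function() {
    size <- sample(1:5, 1L, prob = config$architecture_size_distribution)
    x <- sample(names(bg_t_by_x), 1L)
    pool <- bg_t_by_x[[x]]
    sort(sample(pool, min(size, length(pool))))
  }
  for (id in c(unlist(fam_members), unlist(seq_pairs), background))
    true_arch[[id]] <- draw_background_arch()
  # family members share their family's architecture (full-length homologs)
  for (mem in fam_members)
    for (id in mem[-1L]) true_arch[[id]] <- true_arch[[mem[1L]]]
  # planted ECOD pairs: three private T-groups per pair, X-groups disjoint
  # from the background pool
  x_base <- 1000L
  for (k in seq_along(ecod_pairs)) {
    xs <- x_base + 3L * (k - 1L) + 0:2
    t_shared <- paste0(xs[1L], ".1.1")
    t_a <- paste0(xs[2L], ".1.1")
    t_b <- paste0(xs[3L], ".1.1")
    true_arch[[ecod_pairs[[k]][1L]]] <- sort(c(t_shared, t_a))
    true_arch[[ecod_pairs[[k]][2L]]] <- sort(c(t_shared, t_b))
  }

  domain_len <- 100L
  seq_len_of <- stats::setNames(
    pmax(300L, domain_len * vapply(true_arch, length, integer(1)) + 100L),
    ids)
  seq_len_of[unlist(seq_pairs)] <- pmax(seq_len_of[unlist(seq_pairs)], 400L)
  for (mem in fam_members)  # homologs share a length
    seq_len_of[mem] <- max(seq_len_of[mem])

  # ---- classes and function map --------------------------------------
  categories <- c("structural", "lysis", "DNA/RNA metabolism", "other")
  cat_of_class <- stats::setNames(
    categories[1L + (seq_along(config$class_labels) - 1L) %% length(categories)],
    config$class_labels)
  fmap <- data.frame(
    phrog_class = c(paste0(rep(config$class_labels, each = 2L), " phrog ",
                           rep(1:2, length(config$class_labels))),
                    "tail phrog 1", "structural phrog 1"),
    simplified_class = c(rep(config$class_labels, each = 2L),
                         "tail", "structural protein"),
    category = c(rep(unname(cat_of_class), each = 2L),
                 "structural", "structural"),
    phrog_total_seqs = 600L,
    stringsAsFactors = FALSE)
  attr(fmap, "generic_classes") <- c("tail", "structural protein")

  true_class <- stats::setNames(rep(NA_character_, n), ids)
  annotated <- stats::runif(n) >= config$fraction_unknown
  true_class[annotated] <- sample(config$class_labels, sum(annotated),
                                  replace = TRUE)
  for (mem in fam_members) {  # class is a family-level property
    cl <- true_class[mem[1L]]
    true_class[mem] <- cl
  }
  anti_ids <- character()
  if (config$n_antidefence > 0L) {
    cand <- ids[!is.na(true_class)]
    anti_ids <- sample(cand, min(config$n_antidefence, length(cand)))
  }

  # ---- hit tables -----------------------------------------------------
  jitter <- function(k) {
    if (config$probability_jitter_sd == 0) rep(0.99, k)
    else pmin(0.999, pmax(0.951,
      0.99 - abs(stats::rnorm(k, 0, config$probability_jitter_sd))))
  }

  # ECOD search: one hit per retained true domain, laid out sequentially
  ecod_rows <- list()
  for (id in ids) {
    ts <- true_arch[[id]]
    if (length(ts) == 0L) next
    kept <- stats::runif(length(ts)) >= config$domain_dropout_rate
    if (!any(kept)) next
    ki <- which(kept)
    ecod_rows[[id]] <- data.frame(
      query_id = id,
      subject_id = paste0("e", ts[ki]),
      probability = jitter(length(ki)),
      percent_identity = 0.25,
      q_start = (ki - 1L) * domain_len + 1L,
      q_end = ki * domain_len,
      s_start = 1L, s_end = domain_len,
      q_len = unname(seq_len_of[id]), s_len = domain_len,
      search_tag = "ecod", stringsAsFactors = FALSE)
  }
  ecod_hits <- if (length(ecod_rows)) do.call(rbind, ecod_rows)
  else empty_hit_table()
  rownames(ecod_hits) <- NULL
  all_t <- sort(unique(unlist(true_arch)))
  ecod_map <- data.frame(ecod_domain_id = paste0("e", all_t), t_id = all_t,
                         stringsAsFactors = FALSE)

  # self search: reciprocal full-length hits within families, reciprocal
  # fragment hits for sequence-mosaic pairs, optional spurious noise
  self_rows <- list()
  add_self <- function(qid, sid, qs, qe, ss, se, p, pid) {
    self_rows[[length(self_rows) + 1L]] <<- data.frame(
      query_id = qid, subject_id = sid, probability = p,
      percent_identity = pid, q_start = qs, q_end = qe,
      s_start = ss, s_end = se,
      q_len = unname(seq_len_of[qid]), s_len = unname(seq_len_of[sid]),
      search_tag = "self", stringsAsFactors = FALSE)
  }
  for (mem in fam_members) {
    prs <- utils::combn(mem, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      la <- seq_len_of[a]; lb <- seq_len_of[b]
      add_self(a, b, 1L, la, 1L, lb, 0.99, 0.6)
      add_self(b, a, 1L, lb, 1L, la, 0.99, 0.6)
    }
  }
  tiers <- names(tier_bands)
  seq_tier <- sample(tiers, length(seq_pairs), replace = TRUE,
                     prob = config$sequence_tier_mix)
  frag_len <- 120L
  seq_pid <- numeric(length(seq_pairs))
  for (k in seq_along(seq_pairs)) {
    band <- tier_bands[[seq_tier[k]]]
    pid <- stats::runif(1L, band[1L], band[2L])
    seq_pid[k] <- pid
    a <- seq_pairs[[k]][1L]; b <- seq_pairs[[k]][2L]
    off <- 50L
    add_self(a, b, 1L, frag_len, off, off + frag_len - 1L, 0.99, pid)
    add_self(b, a, off, off + frag_len - 1L, 1L, frag_len, 0.99, pid)
  }
  if (config$spurious_hit_rate > 0) {
    n_spur <- stats::rpois(1L, config$spurious_hit_rate * n)
    for (k in seq_len(n_spur)) {
      pr <- sample(ids, 2L)
      l1 <- seq_len_of[pr[1L]]; l2 <- seq_len_of[pr[2L]]
      add_self(pr[1L], pr[2L], 1L, min(60L, l1), 1L, min(60L, l2),
               stats::runif(1L, 0.5, 0.9), stats::runif(1L, 0.1, 0.25))
    }
  }
  self_hits <- if (length(self_rows)) do.call(rbind, self_rows)
  else empty_hit_table()
  rownames(self_hits) <- NULL

  # PHROG search: one qualifying full-coverage hit to a class profile
  phrog_len <- 250L
  ann_ids <- ids[!is.na(true_class)]
  phrog_of <- paste0(true_class[ann_ids], " phrog ",
                     sample(1:2, length(ann_ids), replace = TRUE))
  phrog_hits <- if (length(ann_ids)) data.frame(
    query_id = ann_ids, subject_id = phrog_of,
    probability = jitter(length(ann_ids)), percent_identity = 0.4,
    q_start = 1L, q_end = unname(seq_len_of[ann_ids]),
    s_start = 1L, s_end = phrog_len,
    q_len = unname(seq_len_of[ann_ids]), s_len = phrog_len,
    search_tag = "phrog", stringsAsFactors = FALSE)
  else empty_hit_table()

  antidefence_hits <- if (length(anti_ids)) data.frame(
    query_id = anti_ids,
    subject_id = paste0("antidefence ", seq_along(anti_ids)),
    probability = 0.99, percent_identity = 0.4,
    q_start = 1L, q_end = unname(seq_len_of[anti_ids]),
    s_start = 1L, s_end = phrog_len,
    q_len = unname(seq_len_of[anti_ids]), s_len = phrog_len,
    search_tag = "antidefence", stringsAsFactors = FALSE)
  else empty_hit_table()

  # ---- genome metadata ------------------------------------------------
  genomes <- sprintf("genome%03d", seq_len(config$n_genomes))
  host_pool <- c("Escherichia", "Klebsiella", "Pseudomonas", "Bacillus",
                 "Lactococcus", "Gordonia")
  fam_pool <- c("Autographiviridae", "Straboviridae", "Drexlerviridae",
                "Herelleviridae")
  genus_pool <- paste0("Genus", 1:8)
  g_host <- sample(c(host_pool, NA), config$n_genomes, replace = TRUE)
  g_fam <- sample(c(fam_pool, NA, NA), config$n_genomes, replace = TRUE)
  g_gen <- sample(c(genus_pool, NA), config$n_genomes, replace = TRUE)
  g_tp <- stats::runif(config$n_genomes)
  g_tp[g_tp >= 0.45 & g_tp < 0.65] <- NA  # some genomes unpredicted
  n_prot <- sample(1:3, n, replace = TRUE)
  prot_rhmm <- rep(ids, n_prot)
  prot_genome <- sample(genomes, length(prot_rhmm), replace = TRUE)
  gi <- match(prot_genome, genomes)
  metadata <- data.frame(
    genome_id = prot_genome,
    protein_id = sprintf("prot%06d", seq_along(prot_rhmm)),
    rhmm_id = prot_rhmm,
    host_genus = g_host[gi], ictv_family = g_fam[gi],
    ictv_genus = g_gen[gi], temperate_probability = g_tp[gi],
    stringsAsFactors = FALSE)

  # ---- truth ----------------------------------------------------------
  fam_id <- integer(0)
  planted_partition <- stats::setNames(rep(NA_integer_, n), ids)
  for (k in seq_along(fam_members)) planted_partition[fam_members[[k]]] <- k
  singles <- which(is.na(planted_partition))
  planted_partition[singles] <- length(fam_members) + seq_along(singles)

  expected_class <- true_class
  expected_class[anti_ids] <- paste0("antidefence ",
                                     seq_along(anti_ids))[match(anti_ids, anti_ids)]

  truth <- list(
    architectures = true_arch,
    classes = expected_class,
    phrog_class = true_class,
    families = planted_partition,
    ecod_pairs = data.frame(
      id_a = vapply(ecod_pairs, function(p) min(p), character(1)),
      id_b = vapply(ecod_pairs, function(p) max(p), character(1)),
      stringsAsFactors = FALSE),
    sequence_pairs = data.frame(
      id_a = vapply(seq_pairs, function(p) min(p), character(1)),
      id_b = vapply(seq_pairs, function(p) max(p), character(1)),
      p_id = seq_pid, tier = seq_tier, stringsAsFactors = FALSE)
  )

  list(self_hits = self_hits, ecod_hits = ecod_hits,
       phrog_hits = phrog_hits, antidefence_hits = antidefence_hits,
       ecod_map = ecod_map, function_map = fmap, metadata = metadata,
       lengths = data.frame(id = ids, length = unname(seq_len_of),
                            stringsAsFactors = FALSE),
       truth = truth, config = config)
}

#' Write a simulated bundle to a directory of TSV files
#'
#' @param bundle output of [simulate_mosaic_data()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  write_hit_table(bundle$self_hits, file.path(dir, "self_hits.tsv"))
  write_hit_table(bundle$ecod_hits, file.path(dir, "ecod_hits.tsv"))
  write_hit_table(bundle$phrog_hits, file.path(dir, "phrog_hits.tsv"))
  write_hit_table(bundle$antidefence_hits,
                  file.path(dir, "antidefence_hits.tsv"))
  w(bundle$ecod_map, "ecod_map.tsv")
  w(bundle$function_map, "function_map.tsv")
  w(bundle$metadata, "metadata.tsv")
  w(bundle$lengths, "lengths.tsv")
  invisible(dir)
}

#' Score recovery of planted structure
#'
#' Precision and recall are computed over unordered rHMM pairs for each
#' mosaicism basis; the family partition is compared to the planted one by
#' the adjusted Rand index.
#'
#' @param ecod_calls,sequence_calls call tables from the detectors.
#' @param partition family partition from [mcl()].
#' @param truth `truth` element of a simulated bundle.
#' @return list with `ecod` and `sequence` (each `precision`, `recall`,
#'   `tp`, `fp`, `fn`) and `family_ari`.
#' @export
score_recovery <- function(ecod_calls, sequence_calls, partition, truth) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  score_basis <- function(calls, planted) {
    got <- unique(pair_key(calls$id_a, calls$id_b))
    want <- unique(pair_key(planted$id_a, planted$id_b))
    tp <- sum(got %in% want)
    list(precision = if (length(got)) tp / length(got) else NA_real_,
         recall = if (length(want)) tp / length(want) else NA_real_,
         tp = tp, fp = length(got) - tp, fn = length(want) - tp)
  }
  m <- match(names(truth$families), partition$rhmm_id)
  ari <- mclust::adjustedRandIndex(unname(truth$families)[!is.na(m)],
                                   partition$family_id[m[!is.na(m)]])
  list(ecod = score_basis(ecod_calls, truth$ecod_pairs),
       sequence = score_basis(sequence_calls, truth$sequence_pairs),
       family_ari = ari)
}
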