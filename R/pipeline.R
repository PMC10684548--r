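#' Aggregate query-vs-database hits per (query, target) pair
#'
#' For searches against an annotation database (PHROG or antidefence
#' profiles) the two roles are not interchangeable, so hits are grouped by
#' (query rHMM, target profile) and summarised as the per-residue average
#' probability over the query region, the weighted mean identity, and the
#' pairwise coverage `min(qcov, scov)`.
#'
#' @param hits hit table (query = rHMM, subject = database profile).
#' @return data frame with `query_id`, `subject_id`, `p`, `p_id`, `qcov`,
#'   `scov`, `cov`.
#' @export
aggregate_query_subject <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      p = numeric(), p_id = numeric(), qcov = numeric(),
                      scov = numeric(), cov = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    qc <- residue_coverage(h$q_start, h$q_end, h$q_len[1L])
    sc <- residue_coverage(h$s_start, h$s_end, h$s_len[1L])
    data.frame(query_id = h$query_id[1L], subject_id = h$subject_id[1L],
               p = per_residue_probability(h$q_start, h$q_end,
                                           h$probability, h$q_len[1L]),
               p_id = direction_identity(h),
               qcov = qc$fraction, scov = sc$fraction,
               cov = min(qc$fraction, sc$fraction),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ECOD hit table -> per-hit domain records (rhmm_id, t_id, probability,
# scov, q_start, q_end) via the domain-id map
domain_hits_from_table <- function(ecod_hits, ecod_map) {
  t_of <- stats::setNames(ecod_map$t_id, ecod_map$ecod_domain_id)
  missing <- setdiff(unique(ecod_hits$subject_id), names(t_of))
  if (length(missing))
    stop("ECOD hit to a domain id absent from the map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  data.frame(
    rhmm_id = ecod_hits$query_id,
    t_id = unname(t_of[ecod_hits$subject_id]),
    probability = ecod_hits$probability,
    scov = (ecod_hits$s_end - ecod_hits$s_start + 1L) / ecod_hits$s_len,
    q_start = ecod_hits$q_start, q_end = ecod_hits$q_end,
    stringsAsFactors = FALSE)
}

#' Run the full domain-mosaicism analysis
#'
#' Orchestrates the pipeline end to end: pair aggregation of the
#' all-by-all self search at the permissive (p >= 0.5 hits) and strict
#' (p >= 0.95 hits) contexts, functional annotation, ECOD domain
#' architectures, both mosaicism detectors, Markov clustering into
#' families, domain and class enrichment, the mosaic class network, and
#' (when metadata are provided) per-genome mosaic fractions.
#'
#' @param self_hits directional all-by-all rHMM hit table (collected at
#'   the permissive probability floor of 0.5).
#' @param ecod_hits rHMM-vs-ECOD hit table.
#' @param phrog_hits rHMM-vs-PHROG hit table.
#' @param ecod_map ECOD domain-id map ([read_ecod_map()] schema).
#' @param function_map function map ([read_function_map()] schema).
#' @param antidefence_hits optional antidefence hit table.
#' @param metadata optional genome metadata ([read_metadata()] schema).
#' @param rhmm_ids universe of rHMM ids; defaults to every id seen in the
#'   inputs.
#' @param mcl_inflation inflation for the family clustering.
#' @return object of class `mosaic_analysis`: a list with `pairs_permissive`,
#'   `pairs_strict`, `annotations`, `eligible_classes`, `domain_hits`,
#'   `architectures`, `ecod_calls`, `sequence_calls`, `signals`,
#'   `partition`, `family_flags`, `domain_enrichment`,
#'   `class_enrichment_ecod`, `class_enrichment_either`, `network`,
#'   `genome_fractions`.
#' @export
mosaic_analysis <- function(self_hits, ecod_hits, phrog_hits, ecod_map,
                            function_map, antidefence_hits = NULL,
                            metadata = NULL, rhmm_ids = NULL,
                            mcl_inflation = 2) {
  rhmm_ids <- sort(unique(c(
    rhmm_ids, self_hits$query_id, self_hits$subject_id,
    ecod_hits$query_id, phrog_hits$query_id,
    if (!is.null(metadata)) metadata$rhmm_id[!is.na(metadata$rhmm_id)])))

  pairs_perm <- aggregate_hit_table(self_hits, min_hit_p = 0.5,
                                    threshold_context = "permissive_p50")
  pairs_strict <- aggregate_hit_table(self_hits, min_hit_p = 0.95,
                                      threshold_context = "strict_p95")

  phrog_pairs <- aggregate_query_subject(phrog_hits)
  names(phrog_pairs)[1:2] <- c("rhmm_id", "phrog_class")
  anti_pairs <- NULL
  if (!is.null(antidefence_hits) && nrow(antidefence_hits)) {
    anti_pairs <- aggregate_query_subject(antidefence_hits)
    names(anti_pairs)[1:2] <- c("rhmm_id", "antidefence_class")
  }
  annotations <- annotate_functions(phrog_pairs, function_map,
                                    antidefence_pairs = anti_pairs,
                                    rhmm_ids = rhmm_ids)
  eligible <- eligible_classes(annotations, function_map)

  domain_hits <- assign_domains(domain_hits_from_table(ecod_hits, ecod_map))
  architectures <- build_architectures(domain_hits, rhmm_ids = rhmm_ids)

  ecod_calls <- detect_ecod_mosaic(architectures, pairs = pairs_strict)
  sequence_calls <- detect_sequence_mosaic(pairs_perm, pairs_strict)
  all_calls <- rbind(ecod_calls[, c("id_a", "id_b", "basis")],
                     sequence_calls[, c("id_a", "id_b", "basis")])
  signals <- mosaic_signal(all_calls, rhmm_ids = rhmm_ids)

  graph <- build_family_graph(pairs_strict, nodes = rhmm_ids)
  partition <- mcl(graph, inflation = mcl_inflation)
  family_flags <- family_mosaic_status(partition, signals)

  dom_enr <- domain_enrichment(architectures, ecod_calls)
  cls_ecod <- class_family_enrichment(partition, family_flags, annotations,
                                      eligible, basis = "ecod")
  cls_either <- class_family_enrichment(partition, family_flags, annotations,
                                        eligible, basis = "either")
  network <- mosaic_network(ecod_calls, architectures, annotations,
                            function_map)
  genome_fractions <- if (!is.null(metadata))
    genome_mosaic_fraction(metadata, signals) else NULL

  structure(list(
    pairs_permissive = pairs_perm, pairs_strict = pairs_strict,
    annotations = annotations, eligible_classes = eligible,
    domain_hits = domain_hits, architectures = architectures,
    ecod_calls = ecod_calls, sequence_calls = sequence_calls,
    signals = signals, partition = partition, family_flags = family_flags,
    domain_enrichment = dom_enr, class_enrichment_ecod = cls_ecod,
    class_enrichment_either = cls_either, network = network,
    genome_fractions = genome_fractions), class = "mosaic_analysis")
}

#' @export
print.mosaic_analysis <- function(x, ...) {
  cat("Domain-mosaicism analysis\n")
  cat("  rHMMs:               ", nrow(x$signals), "\n")
  cat("  strict pair hits:    ", nrow(x$pairs_strict), "\n")
  cat("  families:            ", length(unique(x$partition$family_id)), "\n")
  cat("  ECOD mosaic pairs:   ", nrow(x$ecod_calls), "\n")
  cat("  sequence mosaic pairs:", nrow(x$sequence_calls), "\n")
  invisible(x)
}

#' @export
summary.mosaic_analysis <- function(object, ...) {
  sig <- object$signals
  tiers <- table(object$sequence_calls$tier)
  out <- list(
    n_rhmms = nrow(sig),
    n_families = length(unique(object$partition$family_id)),
    n_mosaic_rhmms = sum(sig$ecod | sig$sequence),
    n_ecod_calls = nrow(object$ecod_calls),
    n_sequence_calls = nrow(object$sequence_calls),
    sequence_tiers = tiers,
    n_enriched_domains = sum(object$domain_enrichment$p_bonferroni < 0.05),
    n_enriched_classes_either =
      sum(object$class_enrichment_either$p_bonferroni < 0.05))
  class(out) <- "summary.mosaic_analysis"
  out
}

#' @export
print.summary.mosaic_analysis <- function(x, ...) {
  cat("Domain-mosaicism analysis summary\n")
  cat("  rHMMs:", x$n_rhmms, " families:", x$n_families, "\n")
  cat("  rHMMs with any mosaic signal:", x$n_mosaic_rhmms, "\n")
  cat("  calls: ecod =", x$n_ecod_calls, ", sequence =",
      x$n_sequence_calls, "\n")
  if (length(x$sequence_tiers)) {
    cat("  sequence-call tiers:\n")
    print(x$sequence_tiers)
  }
  cat("  Bonferroni-significant domains:", x$n_enriched_domains, "\n")
  cat("  Bonferroni-significant classes (either basis):",
      x$n_enriched_classes_either, "\n")
  invisible(x)
}
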