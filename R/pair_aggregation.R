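#' Residue coverage of a set of alignment intervals
#'
#' Coverage is the total number of residues in the aligned regions divided
#' by the sequence length; overlapping intervals are counted once (interval
#' union).
#'
#' @param starts,ends 1-based inclusive interval bounds on one sequence.
#' @param seq_len full sequence length.
#' @return list with `fraction` (union size / `seq_len`) and `count`
#'   (union residue count).
#' @export
residue_coverage <- function(starts, ends, seq_len) {
  if (length(starts) == 0L) return(list(fraction = 0, count = 0L))
  if (any(starts < 1L | ends > seq_len | starts > ends))
    stop("alignment interval outside [1, ", seq_len, "]")
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  count <- 0L
  cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[i])
    } else {
      count <- count + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  count <- count + (cur_e - cur_s + 1L)
  list(fraction = count / seq_len, count = as.integer(count))
}

#' Per-residue pairwise probability
#'
#' The pairwise probability of a homologous region is the average of the
#' hit probabilities assigned to each residue in that region. Where hits
#' overlap, a residue carries the maximum probability among the hits
#' covering it; the mean is taken over covered residues only.
#'
#' @param starts,ends 1-based inclusive hit intervals on one sequence.
#' @param probs per-hit probabilities (fractions).
#' @param seq_len full sequence length.
#' @return mean probability over covered residues.
#' @export
per_residue_probability <- function(starts, ends, probs, seq_len) {
  if (length(starts) == 0L)
    stop("per-residue probability is undefined without hits")
  if (any(starts < 1L | ends > seq_len | starts > ends))
    stop("alignment interval outside [1, ", seq_len, "]")
  arr <- rep(NA_real_, seq_len)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    arr[idx] <- pmax(arr[idx], probs[i], na.rm = TRUE)
  }
  mean(arr[!is.na(arr)])
}

# alignment-length-weighted mean identity over the HSPs of one direction
direction_identity <- function(hits) {
  w <- hits$q_end - hits$q_start + 1L
  sum(hits$percent_identity * w) / sum(w)
}

#' Aggregate directional hits between two profiles into one pair record
#'
#' HMM-HMM alignments are non-commutative, so a pair of profiles is searched
#' in both directions (query-to-subject and subject-to-query) and may yield
#' several local hits (HSPs) per direction. This collapses them into one
#' symmetric comparison:
#'
#' * the pairwise probability `p` is, per direction, the per-residue average
#'   probability over that direction's hits, then conservatively the minimum
#'   over the non-empty directions;
#' * the pairwise identity `p_id` is, per direction, the
#'   alignment-length-weighted mean of the hit identities, then the minimum
#'   over the non-empty directions;
#' * coverages `qcov` (of `a`) and `scov` (of `b`) merge the aligned
#'   intervals from both directions, so coverage is symmetric in the
#'   direction order.
#'
#' @param hits_ab hits with `a` as query and `b` as subject (possibly
#'   zero rows).
#' @param hits_ba hits with `b` as query and `a` as subject.
#' @param id_a,id_b profile identifiers.
#' @param len_a,len_b full profile lengths.
#' @param threshold_context label recording which probability floor the hit
#'   set was collected at (`"permissive_p50"` or `"strict_p95"`).
#' @return one-row data frame with id_a, id_b (lexicographically ordered),
#'   p, p_id, qcov, scov, cov_min, cov_max, aligned_len_a, aligned_len_b,
#'   threshold_context.
#' @export
aggregate_pair <- function(hits_ab, hits_ba, id_a, id_b, len_a, len_b,
                           threshold_context = "strict_p95") {
  n_ab <- NROW(hits_ab); n_ba <- NROW(hits_ba)
  if (n_ab + n_ba == 0L)
    stop("cannot aggregate a pair with no hits in either direction")

  dir_p <- c(
    if (n_ab) per_residue_probability(hits_ab$q_start, hits_ab$q_end,
                                      hits_ab$probability, len_a),
    if (n_ba) per_residue_probability(hits_ba$q_start, hits_ba$q_end,
                                      hits_ba$probability, len_b)
  )
  dir_id <- c(if (n_ab) direction_identity(hits_ab),
              if (n_ba) direction_identity(hits_ba))

  # role-a intervals: query side of a->b plus subject side of b->a
  a_starts <- c(if (n_ab) hits_ab$q_start, if (n_ba) hits_ba$s_start)
  a_ends <- c(if (n_ab) hits_ab$q_end, if (n_ba) hits_ba$s_end)
  b_starts <- c(if (n_ab) hits_ab$s_start, if (n_ba) hits_ba$q_start)
  b_ends <- c(if (n_ab) hits_ab$s_end, if (n_ba) hits_ba$q_end)
  cov_a <- residue_coverage(a_starts, a_ends, len_a)
  cov_b <- residue_coverage(b_starts, b_ends, len_b)

  if (id_b < id_a) {
    tmp <- list(id_a, len_a, cov_a)
    id_a <- id_b; len_a <- len_b; cov_a <- cov_b
    id_b <- tmp[[1L]]; len_b <- tmp[[2L]]; cov_b <- tmp[[3L]]
  }
  data.frame(
    id_a = id_a, id_b = id_b,
    p = min(dir_p), p_id = min(dir_id),
    qcov = cov_a$fraction, scov = cov_b$fraction,
    cov_min = min(cov_a$fraction, cov_b$fraction),
    cov_max = max(cov_a$fraction, cov_b$fraction),
    aligned_len_a = cov_a$count, aligned_len_b = cov_b$count,
    threshold_context = threshold_context,
    stringsAsFactors = FALSE
  )
}

#' Aggregate a full directional hit table into pair comparisons
#'
#' Groups a self-search hit table by unordered profile pair and applies
#' [aggregate_pair()] to each group. Self-hits (query equal to subject) are
#' dropped. A probability floor may be applied to the individual hits before
#' aggregation, which is how the strict (p >= 0.95) context is derived from
#' a permissive search.
#'
#' @param hits hit data frame as from [read_hit_table()].
#' @param min_hit_p drop individual hits below this probability before
#'   aggregating.
#' @param threshold_context context label stored on every output row.
#' @return pair-comparison data frame, one row per unordered pair with at
#'   least one surviving hit.
#' @export
aggregate_hit_table <- function(hits, min_hit_p = 0,
                                threshold_context = "strict_p95") {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  hits <- hits[hits$probability >= min_hit_p, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_pair_table())
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    id_a <- min(h$query_id[1L], h$subject_id[1L])
    id_b <- max(h$query_id[1L], h$subject_id[1L])
    ab <- h[h$query_id == id_a, , drop = FALSE]
    ba <- h[h$query_id == id_b, , drop = FALSE]
    len_a <- if (nrow(ab)) ab$q_len[1L] else ba$s_len[1L]
    len_b <- if (nrow(ba)) ba$q_len[1L] else ab$s_len[1L]
    aggregate_pair(ab, ba, id_a, id_b, len_a, len_b, threshold_context)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_pair_table <- function() {
  data.frame(id_a = character(), id_b = character(), p = numeric(),
             p_id = numeric(), qcov = numeric(), scov = numeric(),
             cov_min = numeric(), cov_max = numeric(),
             aligned_len_a = integer(), aligned_len_b = integer(),
             threshold_context = character(), stringsAsFactors = FALSE)
}

#' Filter pair comparisons by probability and coverage
#'
#' @param pairs pair-comparison data frame.
#' @param min_p minimum pairwise probability (inclusive).
#' @param min_cov_mode which coverage the test uses: `"min"` for
#'   `cov_min = min(qcov, scov)`, `"max"` for `cov_max`, `"none"` to skip
#'   the coverage test.
#' @param min_cov minimum coverage (inclusive).
#' @return the surviving rows.
#' @export
filter_pairs <- function(pairs, min_p = 0.95,
                         min_cov_mode = c("min", "max", "none"),
                         min_cov = 0.8) {
  min_cov_mode <- match.arg(min_cov_mode)
  keep <- pairs$p >= min_p
  if (min_cov_mode == "min") keep <- keep & pairs$cov_min >= min_cov
  if (min_cov_mode == "max") keep <- keep & pairs$cov_max >= min_cov
  pairs[keep, , drop = FALSE]
}
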