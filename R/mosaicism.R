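#' ECOD-based mosaicism predicate for one architecture pair
#'
#' A pair of rHMMs exhibits domain (ECOD-based) mosaicism when (1) each
#' side has at least two domains belonging to different X-groups, (2) the
#' two share at least one domain of the same T-group, and (3) each side
#' additionally carries at least one domain from an X-group absent on the
#' other side. Self-pairs and identical architectures can never qualify.
#'
#' @param arch_a,arch_b architectures as returned by [architecture()], or
#'   character vectors of T-group ids.
#' @return `NULL` if the pair is not mosaic, otherwise a list with
#'   `shared_t_groups`, `unique_x_a`, `unique_x_b`.
#' @export
ecod_mosaic <- function(arch_a, arch_b) {
  ta <- if (is.list(arch_a)) arch_a$t_groups else unique(arch_a)
  tb <- if (is.list(arch_b)) arch_b$t_groups else unique(arch_b)
  if (length(ta) == 0L || length(tb) == 0L) return(NULL)
  xa <- unique(ecod_x_of(ta)); xb <- unique(ecod_x_of(tb))
  if (length(xa) < 2L || length(xb) < 2L) return(NULL)
  shared_t <- intersect(ta, tb)
  if (length(shared_t) == 0L) return(NULL)
  ua <- setdiff(xa, xb); ub <- setdiff(xb, xa)
  if (length(ua) == 0L || length(ub) == 0L) return(NULL)
  list(shared_t_groups = sort(shared_t), unique_x_a = sort(ua),
       unique_x_b = sort(ub))
}

#' Detect all ECOD-based mosaic rHMM pairs
#'
#' Evaluates the [ecod_mosaic()] predicate over every candidate pair, using
#' an inverted T-group index so only pairs that share at least one T-group
#' are examined. A fragment identity for each called pair is looked up in
#' the strict-context self-search pair table when available, and a recency
#' tier is derived from it.
#'
#' @param architectures data frame from [build_architectures()].
#' @param pairs optional strict-context pair table (for fragment `p_id`).
#' @return data frame of calls with columns `id_a`, `id_b`, `basis`
#'   (`"ecod"`), `shared_t_groups`, `unique_x_a`, `unique_x_b`, `p_id`,
#'   `tier`.
#' @export
detect_ecod_mosaic <- function(architectures, pairs = NULL) {
  multi <- architectures[architectures$n_x_groups >= 2L, , drop = FALSE]
  tg <- arch_t_groups(multi$architecture_key)
  idx <- split(rep(seq_len(nrow(multi)), lengths(tg)), unlist(tg))
  cand <- unique(do.call(rbind, lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)
    t(utils::combn(sort(i), 2L))
  })))
  out <- list()
  if (!is.null(cand) && nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      call <- ecod_mosaic(tg[[i]], tg[[j]])
      if (is.null(call)) next
      ids <- sort(c(multi$rhmm_id[i], multi$rhmm_id[j]))
      out[[length(out) + 1L]] <- data.frame(
        id_a = ids[1L], id_b = ids[2L], basis = "ecod",
        shared_t_groups = paste(call$shared_t_groups, collapse = "|"),
        unique_x_a = paste(call$unique_x_a, collapse = "|"),
        unique_x_b = paste(call$unique_x_b, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      basis = character(), shared_t_groups = character(),
                      unique_x_a = character(), unique_x_b = character(),
                      p_id = numeric(), tier = character(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  calls <- unique(calls)
  calls$p_id <- NA_real_
  if (!is.null(pairs) && nrow(pairs)) {
    key <- paste(pairs$id_a, pairs$id_b, sep = "\r")
    m <- match(paste(calls$id_a, calls$id_b, sep = "\r"), key)
    calls$p_id <- pairs$p_id[m]
  }
  calls$tier <- recency_tier(calls$p_id)
  rownames(calls) <- NULL
  calls
}

#' Sequence-based mosaicism predicate for one rHMM pair
#'
#' A pair is sequence-mosaic when a shared fragment, detected among the
#' high-probability (p >= 0.95) hits, (2) has probability >= `min_p`,
#' (3) identity >= `min_p_id` and (4) length >= `min_len` residues, while
#' (1) the pair aligns over at most half of both sequences in the
#' permissive background (all hits at p >= 0.5):
#' `max(qcov, scov) <= max_cov` on the permissive-context comparison.
#'
#' @param pc_permissive one-row pair comparison at the permissive context
#'   (coverage computed from all p >= 0.5 hits); mandatory.
#' @param pc_strict one-row pair comparison aggregated from the p >= 0.95
#'   hits only (the fragment), or `NULL` when no such hits exist.
#' @param max_cov,min_p,min_p_id,min_len the four thresholds (inclusive).
#' @return `NULL` if not mosaic, else a list with the fragment statistics
#'   `p`, `p_id`, `length_a`, `length_b` and the `tier`.
#' @export
sequence_mosaic <- function(pc_permissive, pc_strict, max_cov = 0.5,
                            min_p = 0.95, min_p_id = 0.30, min_len = 50) {
  if (is.null(pc_permissive) || NROW(pc_permissive) == 0L)
    stop("permissive-context comparison is required as the homology background")
  if (is.null(pc_strict) || NROW(pc_strict) == 0L) return(NULL)
  if (max(pc_permissive$qcov, pc_permissive$scov) > max_cov) return(NULL)
  if (pc_strict$p < min_p) return(NULL)
  if (pc_strict$p_id < min_p_id) return(NULL)
  if (min(pc_strict$aligned_len_a, pc_strict$aligned_len_b) < min_len)
    return(NULL)
  list(p = pc_strict$p, p_id = pc_strict$p_id,
       length_a = pc_strict$aligned_len_a,
       length_b = pc_strict$aligned_len_b,
       tier = recency_tier(pc_strict$p_id))
}

#' Detect all sequence-based mosaic rHMM pairs
#'
#' @param pairs_permissive pair table at the permissive context
#'   (`threshold_context = "permissive_p50"`).
#' @param pairs_strict pair table recomputed from the p >= 0.95 hits.
#' @param max_cov,min_p,min_p_id,min_len thresholds, see
#'   [sequence_mosaic()].
#' @return data frame of calls with `id_a`, `id_b`, `basis` (`"sequence"`),
#'   fragment `p`, `p_id`, `length_a`, `length_b` and `tier`.
#' @export
detect_sequence_mosaic <- function(pairs_permissive, pairs_strict,
                                   max_cov = 0.5, min_p = 0.95,
                                   min_p_id = 0.30, min_len = 50) {
  if (nrow(pairs_strict) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      basis = character(), p = numeric(), p_id = numeric(),
                      length_a = integer(), length_b = integer(),
                      tier = character(), stringsAsFactors = FALSE))
  perm_key <- paste(pairs_permissive$id_a, pairs_permissive$id_b, sep = "\r")
  m <- match(paste(pairs_strict$id_a, pairs_strict$id_b, sep = "\r"), perm_key)
  if (anyNA(m))
    stop("strict-context pair missing from the permissive background: ",
         pairs_strict$id_a[which(is.na(m))[1L]], " vs ",
         pairs_strict$id_b[which(is.na(m))[1L]])
  perm <- pairs_permissive[m, , drop = FALSE]
  keep <- pmax(perm$qcov, perm$scov) <= max_cov &
    pairs_strict$p >= min_p &
    pairs_strict$p_id >= min_p_id &
    pmin(pairs_strict$aligned_len_a, pairs_strict$aligned_len_b) >= min_len
  calls <- pairs_strict[keep, c("id_a", "id_b", "p", "p_id",
                                "aligned_len_a", "aligned_len_b")]
  names(calls)[5:6] <- c("length_a", "length_b")
  calls$basis <- "sequence"
  calls$tier <- recency_tier(calls$p_id)
  calls <- calls[, c("id_a", "id_b", "basis", "p", "p_id", "length_a",
                     "length_b", "tier")]
  rownames(calls) <- NULL
  calls
}

#' Recency tier of a mosaic fragment
#'
#' Tiers by the fragment's amino-acid identity: contemporary at >= 50%,
#' recently emerged at high confidence >= 70% and very high confidence
#' >= 90%; anything below 50% (or unknown) is baseline.
#'
#' @param p_id fragment identity as a fraction (vectorised; `NA` allowed).
#' @return character vector with values `baseline`, `contemporary`,
#'   `recent_high`, `recent_very_high`.
#' @export
recency_tier <- function(p_id) {
  out <- rep("baseline", length(p_id))
  out[!is.na(p_id) & p_id >= 0.5] <- "contemporary"
  out[!is.na(p_id) & p_id >= 0.7] <- "recent_high"
  out[!is.na(p_id) & p_id >= 0.9] <- "recent_very_high"
  out
}

tier_rank <- function(tier) {
  match(tier, c("baseline", "contemporary", "recent_high", "recent_very_high"))
}

#' Per-rHMM mosaic signal
#'
#' An rHMM carries the signal of a given basis of mosaicism when it appears
#' in at least one mosaic pair called under that basis.
#'
#' @param calls data frame of calls (ECOD-basis, sequence-basis, or both
#'   row-bound; must have `id_a`, `id_b`, `basis`).
#' @param rhmm_ids optional universe of rHMM ids to report (others get
#'   all-`FALSE` rows).
#' @return data frame with `rhmm_id`, logical `ecod` and `sequence`.
#' @export
mosaic_signal <- function(calls, rhmm_ids = NULL) {
  ids <- sort(unique(c(rhmm_ids, calls$id_a, calls$id_b)))
  ecod_ids <- unique(c(calls$id_a[calls$basis == "ecod"],
                       calls$id_b[calls$basis == "ecod"]))
  seq_ids <- unique(c(calls$id_a[calls$basis == "sequence"],
                      calls$id_b[calls$basis == "sequence"]))
  data.frame(rhmm_id = ids,
             ecod = ids %in% ecod_ids,
             sequence = ids %in% seq_ids,
             stringsAsFactors = FALSE)
}
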