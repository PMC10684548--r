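#' Assign simplified functional classes to rHMMs
#'
#' Each representative profile (rHMM) is annotated from its pair-aggregated
#' hits against the PHROG profile database: a hit qualifies at probability
#' >= `min_p` and pairwise coverage `min(qcov, scov)` >= `min_cov`. The
#' simplified classes of the qualifying hits are collected and
#'
#' * exactly one non-generic class (generic classes such as `tail` and
#'   `structural protein` are tolerated alongside it) gives status
#'   `assigned`;
#' * more than one non-generic class gives `ambiguous_discarded`;
#' * only generic classes give `assigned` to the (single) generic class,
#'   or `ambiguous_discarded` if several distinct generic classes qualify;
#' * no qualifying hit gives `unknown`.
#'
#' An rHMM with both qualifying PHROG evidence and a qualifying hit to a
#' specific antidefence profile is overridden to that antidefence class.
#'
#' @param phrog_pairs data frame of pair-aggregated PHROG hits with columns
#'   `rhmm_id`, `phrog_class`, `p`, `cov` (pairwise coverage
#'   `min(qcov, scov)`).
#' @param fmap function map from [read_function_map()].
#' @param antidefence_pairs optional data frame with columns `rhmm_id`,
#'   `antidefence_class`, `p`, `cov`.
#' @param rhmm_ids optional universe of rHMM ids, so rHMMs with no hits
#'   appear with status `unknown`.
#' @param min_p,min_cov qualification thresholds (inclusive).
#' @return data frame with columns `rhmm_id`, `status`, `simplified_class`,
#'   `category`, `antidefence_class`.
#' @export
annotate_functions <- function(phrog_pairs, fmap, antidefence_pairs = NULL,
                               rhmm_ids = NULL, min_p = 0.95, min_cov = 0.8) {
  generic <- attr(fmap, "generic_classes")
  if (is.null(generic)) generic <- c("tail", "structural protein")
  unknown_phrog <- setdiff(unique(phrog_pairs$phrog_class), fmap$phrog_class)
  if (length(unknown_phrog))
    stop("hit references PHROG class missing from function map: ",
         paste(unknown_phrog, collapse = ", "))
  class_of <- stats::setNames(fmap$simplified_class, fmap$phrog_class)
  cat_of <- stats::setNames(fmap$category, fmap$phrog_class)

  q <- phrog_pairs[phrog_pairs$p >= min_p & phrog_pairs$cov >= min_cov, ,
                   drop = FALSE]
  q$simplified_class <- unname(class_of[q$phrog_class])
  q$category <- unname(cat_of[q$phrog_class])

  ad <- if (!is.null(antidefence_pairs)) {
    antidefence_pairs[antidefence_pairs$p >= min_p &
                        antidefence_pairs$cov >= min_cov, , drop = FALSE]
  } else {
    data.frame(rhmm_id = character(), antidefence_class = character(),
               stringsAsFactors = FALSE)
  }

  ids <- unique(c(rhmm_ids, phrog_pairs$rhmm_id))
  ids <- sort(ids)
  res <- lapply(ids, function(id) {
    cls <- unique(q$simplified_class[q$rhmm_id == id])
    specific <- setdiff(cls, generic)
    if (length(cls) == 0L) {
      status <- "unknown"; assigned <- NA_character_
    } else if (length(specific) > 1L || (length(specific) == 0L && length(cls) > 1L)) {
      status <- "ambiguous_discarded"; assigned <- NA_character_
    } else {
      status <- "assigned"
      assigned <- if (length(specific) == 1L) specific else cls
    }
    ad_cls <- unique(ad$antidefence_class[ad$rhmm_id == id])
    anti <- NA_character_
    if (status == "assigned" && length(ad_cls) == 1L) {
      anti <- ad_cls
    }
    category <- if (!is.na(assigned))
      unique(q$category[q$rhmm_id == id & q$simplified_class == assigned])[1L]
    else NA_character_
    data.frame(rhmm_id = id, status = status,
               simplified_class = assigned, category = category,
               antidefence_class = anti, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Functional classes eligible for class-level statistics
#'
#' A simplified class enters class-level analyses only if (1) its PHROG
#' classes total at least `min_phrog_seqs` sequences and (2) it was
#' assigned to at least `min_rhmms` rHMMs. Generic classes are excluded.
#'
#' @param annotations output of [annotate_functions()].
#' @param fmap function map from [read_function_map()].
#' @param min_phrog_seqs,min_rhmms inclusive lower bounds.
#' @return character vector of eligible class names.
#' @export
eligible_classes <- function(annotations, fmap, min_phrog_seqs = 500,
                             min_rhmms = 20) {
  generic <- attr(fmap, "generic_classes")
  seqs <- tapply(fmap$phrog_total_seqs, fmap$simplified_class, sum)
  assigned <- annotations[annotations$status == "assigned" &
                            !is.na(annotations$simplified_class), ]
  counts <- table(assigned$simplified_class)
  cls <- names(counts)[counts >= min_rhmms]
  cls <- cls[!is.na(seqs[cls]) & seqs[cls] >= min_phrog_seqs]
  sort(setdiff(cls, generic))
}

#' Retain qualifying ECOD domain hits
#'
#' A domain is considered present in an rHMM when the profile-profile hit to
#' the ECOD domain reaches probability >= `min_p` and subject coverage
#' (coverage of the ECOD domain profile) >= `min_scov`.
#'
#' @param ecod_hits data frame with columns `rhmm_id`, `t_id`,
#'   `probability`, `scov`, `q_start`, `q_end`.
#' @param min_p,min_scov inclusive thresholds.
#' @return the qualifying rows sorted by `rhmm_id` then `q_start`.
#' @export
assign_domains <- function(ecod_hits, min_p = 0.95, min_scov = 0.7) {
  keep <- ecod_hits$probability >= min_p & ecod_hits$scov >= min_scov
  out <- ecod_hits[keep, , drop = FALSE]
  out <- out[order(out$rhmm_id, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain architecture of one rHMM
#'
#' The architecture is the set of distinct ECOD T-groups detected in the
#' rHMM; multiplicity and layout order do not contribute to its identity.
#' The canonical key is the sorted T-group ids joined by `|`.
#'
#' @param domain_hits qualifying domain hits of one rHMM (may be empty).
#' @return list with `t_groups`, derived `x_groups`, the display `layout`
#'   (hits ordered by `q_start`) and `architecture_key`.
#' @export
architecture <- function(domain_hits) {
  t_groups <- sort(unique(domain_hits$t_id))
  list(
    t_groups = t_groups,
    x_groups = sort(unique(ecod_x_of(t_groups))),
    layout = domain_hits[order(domain_hits$q_start), , drop = FALSE],
    architecture_key = paste(t_groups, collapse = "|")
  )
}

#' Domain architectures for all rHMMs
#'
#' @param domain_hits qualifying domain hits from [assign_domains()].
#' @param rhmm_ids optional universe; rHMMs with no qualifying hit get an
#'   empty architecture key.
#' @return data frame with `rhmm_id`, `architecture_key`, `n_t_groups`,
#'   `n_x_groups`.
#' @export
build_architectures <- function(domain_hits, rhmm_ids = NULL) {
  ids <- sort(unique(c(rhmm_ids, domain_hits$rhmm_id)))
  split_hits <- split(domain_hits$t_id, domain_hits$rhmm_id)
  keys <- vapply(ids, function(id) {
    t <- sort(unique(split_hits[[id]]))
    paste(t, collapse = "|")
  }, character(1))
  n_t <- vapply(strsplit(keys, "|", fixed = TRUE),
                function(x) length(x[nzchar(x)]), integer(1))
  n_x <- vapply(strsplit(keys, "|", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    length(unique(ecod_x_of(x)))
  }, integer(1))
  data.frame(rhmm_id = ids, architecture_key = unname(keys),
             n_t_groups = n_t, n_x_groups = n_x, stringsAsFactors = FALSE)
}

arch_t_groups <- function(architecture_key) {
  x <- strsplit(architecture_key, "|", fixed = TRUE)
  lapply(x, function(t) t[nzchar(t)])
}

#' Class-by-domain presence matrix
#'
#' Counts, for every (functional class, domain) cell, the number of rHMMs
#' of the class in which the domain was detected. Cells below `min_rhmms`
#' are zeroed; optionally only domains present (after zeroing) in at least
#' `min_classes` classes are kept; generic classes are excluded.
#'
#' @param domain_hits qualifying domain hits from [assign_domains()].
#' @param annotations output of [annotate_functions()].
#' @param fmap function map (for the generic-class set).
#' @param level count domains at the homology (`"H"`) or topology (`"T"`)
#'   level.
#' @param min_rhmms inclusive per-cell floor.
#' @param min_classes keep only domains present in at least this many
#'   classes; `NULL` keeps all.
#' @return integer matrix, classes in rows, domains in columns.
#' @export
class_domain_presence <- function(domain_hits, annotations, fmap,
                                  level = c("H", "T"), min_rhmms = 5,
                                  min_classes = 3) {
  level <- match.arg(level)
  generic <- attr(fmap, "generic_classes")
  ann <- annotations[annotations$status == "assigned" &
                       !is.na(annotations$simplified_class) &
                       !(annotations$simplified_class %in% generic), ]
  dh <- domain_hits[domain_hits$rhmm_id %in% ann$rhmm_id, , drop = FALSE]
  if (nrow(dh) == 0L) return(matrix(0L, 0L, 0L))
  dh$domain <- if (level == "H") ecod_h_of(dh$t_id) else dh$t_id
  cls <- stats::setNames(ann$simplified_class, ann$rhmm_id)
  dh$class <- unname(cls[dh$rhmm_id])
  dh <- unique(dh[, c("rhmm_id", "class", "domain")])
  m <- table(dh$class, dh$domain)
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  m[m < min_rhmms] <- 0L
  if (!is.null(min_classes)) {
    keep <- colSums(m > 0L) >= min_classes
    m <- m[, keep, drop = FALSE]
  }
  m
}
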