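#' Odds ratio of a 2x2 contingency table
#'
#' For counts `a` (feature present, case), `b` (absent, case), `c`
#' (present, control), `d` (absent, control) the odds ratio is
#' `(a/b) / (c/d)`. Zero cells are reported without continuity
#' correction: a zero numerator gives 0, a zero in the denominator odds
#' gives `Inf`, and a table where both odds are degenerate gives `NaN`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return numeric odds ratio (possibly 0, `Inf` or `NaN`), vectorised.
#' @export
odds_ratio <- function(a, b, c, d) {
  num <- a * d
  den <- b * c
  out <- num / den
  out[num == 0 & den == 0] <- NaN
  out
}

#' One-tailed Fisher exact test for over-representation
#'
#' The p-value for the alternative "the feature is over-represented in the
#' cases" is the upper hypergeometric tail with all margins fixed:
#' `P(X >= a)` where `X` counts feature-positive cases.
#'
#' @param a,b,c,d cell counts as in [odds_ratio()] (vectorised).
#' @return p-value(s) in (0, 1\].
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

bonferroni <- function(p, n_tests) pmin(1, p * n_tests)

fisher_enrichment_table <- function(feature, a, b, c, d) {
  or <- odds_ratio(a, b, c, d)
  p <- fisher_one_tailed(a, b, c, d)
  n_tests <- length(feature)
  data.frame(feature = feature, a = a, b = b, c = c, d = d,
             odds_ratio = or, p_raw = p,
             p_bonferroni = bonferroni(p, n_tests),
             n_tests = rep(n_tests, length.out = length(feature)),
             stringsAsFactors = FALSE)
}

#' Domain over-representation in mosaic architectures
#'
#' The units are the unique domain architectures (not rHMMs), each
#' classified mosaic or non-mosaic; an architecture is mosaic when any
#' rHMM pair bearing it participates in an ECOD-basis mosaic call. For
#' every domain occurring in at least one architecture the 2x2 table is
#' (mosaic with domain `m_t`, mosaic without `m_nt`, non-mosaic with
#' `n_t`, non-mosaic without `n_nt`), tested one-tailed with Bonferroni
#' correction over the domains tested.
#'
#' @param architectures data frame from [build_architectures()]; rows with
#'   an empty key (no domain detected) are excluded.
#' @param calls ECOD-basis mosaic calls from [detect_ecod_mosaic()];
#'   optionally pre-filtered (e.g. to contemporary-tier calls).
#' @param level test at the topology (`"T"`) or homology (`"H"`) level.
#' @return enrichment data frame (feature, a, b, c, d, odds_ratio, p_raw,
#'   p_bonferroni, n_tests), sorted by raw p.
#' @export
domain_enrichment <- function(architectures, calls, level = c("T", "H")) {
  level <- match.arg(level)
  arch <- architectures[nzchar(architectures$architecture_key), , drop = FALSE]
  mosaic_rhmms <- unique(c(calls$id_a, calls$id_b))
  mosaic_key <- unique(arch$architecture_key[arch$rhmm_id %in% mosaic_rhmms])
  keys <- unique(arch$architecture_key)
  tg <- arch_t_groups(keys)
  if (level == "H") tg <- lapply(tg, function(t) unique(ecod_h_of(t)))
  flag <- keys %in% mosaic_key
  feats <- sort(unique(unlist(tg)))
  n_mosaic <- sum(flag); n_non <- sum(!flag)
  has <- vapply(feats, function(f)
    c(sum(vapply(tg[flag], function(t) f %in% t, TRUE)),
      sum(vapply(tg[!flag], function(t) f %in% t, TRUE))),
    numeric(2))
  a <- has[1L, ]; c_ <- has[2L, ]
  res <- fisher_enrichment_table(feats, a, n_mosaic - a, c_, n_non - c_)
  res[order(res$p_raw, res$feature), ]
}

#' Functional-class over-representation in mosaic families
#'
#' The units are the rHMM families; a family is mosaic when it contains any
#' rHMM with the chosen mosaic signal. For each eligible class the table is
#' (mosaic families containing the class, mosaic families containing none
#' of it but at least one rHMM of another eligible class, and the two
#' analogous non-mosaic counts), tested one-tailed with Bonferroni over the
#' classes tested.
#'
#' @param partition family partition from [mcl()].
#' @param family_flags data frame from [family_mosaic_status()].
#' @param annotations output of [annotate_functions()].
#' @param classes eligible classes from [eligible_classes()].
#' @param basis `"ecod"` for the ECOD-basis flag, `"either"` for ECOD or
#'   sequence.
#' @return enrichment data frame as in [domain_enrichment()].
#' @export
class_family_enrichment <- function(partition, family_flags, annotations,
                                    classes,
                                    basis = c("ecod", "either")) {
  basis <- match.arg(basis)
  mosaic_f <- if (basis == "ecod") family_flags$family_id[family_flags$ecod_mosaic]
  else family_flags$family_id[family_flags$ecod_mosaic |
                                family_flags$sequence_mosaic]
  ann <- annotations[annotations$status == "assigned" &
                       annotations$simplified_class %in% classes, ]
  fam <- stats::setNames(partition$family_id, partition$rhmm_id)
  ann$family_id <- unname(fam[ann$rhmm_id])
  classes_by_family <- lapply(split(ann$simplified_class, ann$family_id), unique)
  fams <- as.integer(names(classes_by_family))
  is_mosaic <- fams %in% mosaic_f
  cells <- vapply(classes, function(cl) {
    with_cl <- vapply(classes_by_family, function(x) cl %in% x, TRUE)
    c(a = sum(with_cl & is_mosaic),
      b = sum(!with_cl & is_mosaic),
      c = sum(with_cl & !is_mosaic),
      d = sum(!with_cl & !is_mosaic))
  }, numeric(4))
  res <- fisher_enrichment_table(classes, cells[1L, ], cells[2L, ],
                                 cells[3L, ], cells[4L, ])
  res[order(res$p_raw, res$feature), ]
}

#' Mosaic functional-class network
#'
#' Nodes are functional classes; a class pair (including self-pairs, i.e.
#' within-class mosaicism, rendered as self-loops) is linked when mosaicism
#' was found between at least `min_arch_pairs` distinct unordered pairs of
#' domain architectures, each supported by at least one ECOD-basis call.
#' An edge is flagged contemporary when at least one supporting rHMM pair
#' shares a fragment of identity >= 0.5. Node size is the number of
#' distinct domain architectures in the class; generic classes and
#' unannotated rHMMs are excluded.
#'
#' @param calls ECOD-basis calls from [detect_ecod_mosaic()].
#' @param architectures data frame from [build_architectures()].
#' @param annotations output of [annotate_functions()].
#' @param fmap function map (for the generic-class set).
#' @param min_arch_pairs inclusive edge threshold.
#' @return `igraph` graph with vertex attribute `n_architectures` and edge
#'   attributes `n_arch_pairs`, `contemporary`.
#' @export
mosaic_network <- function(calls, architectures, annotations, fmap,
                           min_arch_pairs = 4) {
  generic <- attr(fmap, "generic_classes")
  ann <- annotations[annotations$status == "assigned" &
                       !is.na(annotations$simplified_class) &
                       !(annotations$simplified_class %in% generic), ]
  cls <- stats::setNames(ann$simplified_class, ann$rhmm_id)
  key <- stats::setNames(architectures$architecture_key,
                         architectures$rhmm_id)
  ca <- unname(cls[calls$id_a]); cb <- unname(cls[calls$id_b])
  ka <- unname(key[calls$id_a]); kb <- unname(key[calls$id_b])
  ok <- !is.na(ca) & !is.na(cb)
  df <- data.frame(
    class_a = pmin(ca[ok], cb[ok]), class_b = pmax(ca[ok], cb[ok]),
    arch_pair = paste(pmin(ka[ok], kb[ok]), pmax(ka[ok], kb[ok]), sep = "\r"),
    contemporary = !is.na(calls$p_id[ok]) & calls$p_id[ok] >= 0.5,
    stringsAsFactors = FALSE)
  ckey <- paste(df$class_a, df$class_b, sep = "\r")
  n_pairs <- vapply(split(df$arch_pair, ckey),
                    function(x) length(unique(x)), integer(1))
  contemp <- vapply(split(df$contemporary, ckey), any, TRUE)
  keep <- n_pairs >= min_arch_pairs
  edge_cls <- do.call(rbind, strsplit(names(n_pairs)[keep], "\r", fixed = TRUE))
  n_arch <- vapply(split(key[ann$rhmm_id], ann$simplified_class),
                   function(x) length(unique(x[nzchar(x)])), integer(1))
  vertices <- data.frame(name = sort(unique(ann$simplified_class)),
                         stringsAsFactors = FALSE)
  vertices$n_architectures <- as.integer(n_arch[vertices$name])
  edges <- if (is.null(edge_cls)) {
    data.frame(from = character(), to = character())
  } else {
    data.frame(from = edge_cls[, 1L], to = edge_cls[, 2L],
               n_arch_pairs = unname(n_pairs[keep]),
               contemporary = unname(contemp[keep]),
               stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Network of recently emerged sequence mosaicism
#'
#' As [mosaic_network()], but built from sequence-basis calls at or above a
#' recency tier, with edges supported by individual rHMM pairs and
#' unannotated rHMMs mapped to an explicit `"unknown"` node.
#'
#' @param calls sequence-basis calls from [detect_sequence_mosaic()].
#' @param annotations output of [annotate_functions()].
#' @param fmap function map (for the generic-class set).
#' @param min_tier minimum tier (`"recent_high"` or `"recent_very_high"`).
#' @return `igraph` graph with edge attribute `n_pairs`.
#' @export
recent_network <- function(calls, annotations, fmap,
                           min_tier = c("recent_high", "recent_very_high")) {
  min_tier <- match.arg(min_tier)
  generic <- attr(fmap, "generic_classes")
  calls <- calls[tier_rank(calls$tier) >= tier_rank(min_tier), , drop = FALSE]
  ann <- annotations[annotations$status == "assigned" &
                       !is.na(annotations$simplified_class) &
                       !(annotations$simplified_class %in% generic), ]
  cls <- stats::setNames(ann$simplified_class, ann$rhmm_id)
  ca <- unname(cls[calls$id_a]); cb <- unname(cls[calls$id_b])
  ca[is.na(ca)] <- "unknown"; cb[is.na(cb)] <- "unknown"
  ckey <- paste(pmin(ca, cb), pmax(ca, cb), sep = "\r")
  n_pairs <- table(ckey)
  edge_cls <- do.call(rbind, strsplit(names(n_pairs), "\r", fixed = TRUE))
  vertices <- data.frame(
    name = sort(unique(c(ann$simplified_class, "unknown", ca, cb))),
    stringsAsFactors = FALSE)
  edges <- if (is.null(edge_cls)) {
    data.frame(from = character(), to = character())
  } else {
    data.frame(from = edge_cls[, 1L], to = edge_cls[, 2L],
               n_pairs = as.integer(n_pairs), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
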