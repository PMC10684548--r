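#' Classify phage lifestyle from temperate probability
#'
#' Genomes with a temperate probability of at least 0.90 are temperate,
#' those at or below 0.10 virulent; everything in between (or missing) is
#' unclassified.
#'
#' @param temperate_probability fraction(s) in \[0,1\], `NA` allowed.
#' @return character vector: `temperate`, `virulent` or `unclassified`.
#' @export
classify_lifestyle <- function(temperate_probability) {
  out <- rep("unclassified", length(temperate_probability))
  out[!is.na(temperate_probability) & temperate_probability >= 0.9] <- "temperate"
  out[!is.na(temperate_probability) & temperate_probability <= 0.1] <- "virulent"
  out
}

axis_values <- function(metadata, axis) {
  switch(axis,
         host_genus = metadata$host_genus,
         ictv_family = metadata$ictv_family,
         ictv_genus = metadata$ictv_genus,
         lifestyle = {
           v <- classify_lifestyle(metadata$temperate_probability)
           v[v == "unclassified"] <- NA_character_
           v
         },
         stop("unknown axis: ", axis))
}

#' Assign an rHMM to a taxonomic or ecological group
#'
#' The proteins of an rHMM each inherit a group value from their genome
#' (host genus, ICTV family/genus, or lifestyle). Unknown values are
#' ignored; if all remaining members agree the rHMM is allocated to that
#' group, if they disagree it is `conserved_across_groups`, and with no
#' classified member it is `unassigned`.
#'
#' @param rhmm_ids rHMM ids to assign (default: all in `metadata`).
#' @param metadata data frame from [read_metadata()].
#' @param axis one of `host_genus`, `ictv_family`, `ictv_genus`,
#'   `lifestyle`.
#' @return data frame with `rhmm_id`, `axis`, `value`.
#' @export
assign_groups <- function(metadata, axis, rhmm_ids = NULL) {
  md <- metadata[!is.na(metadata$rhmm_id), , drop = FALSE]
  vals <- axis_values(md, axis)
  by_rhmm <- split(vals, md$rhmm_id)
  ids <- sort(unique(c(rhmm_ids, names(by_rhmm))))
  value <- vapply(ids, function(id) {
    v <- unique(by_rhmm[[id]])
    v <- v[!is.na(v)]
    if (length(v) == 0L) "unassigned"
    else if (length(v) == 1L) v
    else "conserved_across_groups"
  }, character(1))
  data.frame(rhmm_id = ids, axis = axis, value = unname(value),
             stringsAsFactors = FALSE)
}

#' Per-genome proportion of proteins with a mosaic signal
#'
#' The numerator counts proteins whose rHMM carries an ECOD-based or
#' sequence-based mosaic signal; the denominator counts proteins mapped to
#' any rHMM. A genome with no rHMM-mapped protein gets `NA`.
#'
#' @param metadata data frame from [read_metadata()].
#' @param signals data frame from [mosaic_signal()].
#' @return data frame with `genome_id`, `n_proteins`, `n_mosaic`,
#'   `fraction`.
#' @export
genome_mosaic_fraction <- function(metadata, signals) {
  sig <- signals$rhmm_id[signals$ecod | signals$sequence]
  md <- metadata
  mapped <- !is.na(md$rhmm_id)
  genomes <- sort(unique(md$genome_id))
  n_prot <- vapply(genomes, function(g)
    sum(mapped & md$genome_id == g), integer(1))
  n_mos <- vapply(genomes, function(g)
    sum(mapped & md$genome_id == g & md$rhmm_id %in% sig), integer(1))
  data.frame(genome_id = genomes, n_proteins = unname(n_prot),
             n_mosaic = unname(n_mos),
             fraction = ifelse(n_prot > 0, n_mos / n_prot, NA_real_),
             stringsAsFactors = FALSE)
}

#' Cross-boundary classification of mosaic pairs
#'
#' Labels each mosaic call by whether the two rHMMs belong to the same
#' group on the chosen axis (`same_group`), to different concrete groups
#' (`cross_group`), or involve an rHMM conserved across groups
#' (`involves_conserved`) or without any classified member
#' (`involves_unassigned`). Calls are stratified into a recent stratum
#' (fragment identity >= `tier_split`) and an older stratum.
#'
#' @param calls mosaic calls with `id_a`, `id_b` and `p_id`.
#' @param groups group assignments from [assign_groups()].
#' @param tier_split identity split between the strata.
#' @return `calls` with added columns `boundary` and `stratum`
#'   (`recent` / `older`; `NA` identity falls in the older stratum).
#' @export
cross_boundary <- function(calls, groups, tier_split = 0.7) {
  val <- stats::setNames(groups$value, groups$rhmm_id)
  ga <- unname(val[calls$id_a]); gb <- unname(val[calls$id_b])
  ga[is.na(ga)] <- "unassigned"; gb[is.na(gb)] <- "unassigned"
  boundary <- ifelse(
    ga == "conserved_across_groups" | gb == "conserved_across_groups",
    "involves_conserved",
    ifelse(ga == "unassigned" | gb == "unassigned", "involves_unassigned",
           ifelse(ga == gb, "same_group", "cross_group")))
  calls$boundary <- boundary
  calls$stratum <- ifelse(!is.na(calls$p_id) & calls$p_id >= tier_split,
                          "recent", "older")
  calls
}
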