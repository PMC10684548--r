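#' Read a profile-profile hit table
#'
#' Parses tab-delimited hit tables from HMM-HMM homology searches into a
#' validated data frame of directional local hits. Two dialects are
#' supported:
#'
#' * `"blasttab_plus_prob"`: the hhsuite blast-tab style layout with columns
#'   query, subject, pid, aln_len, qstart, qend, sstart, send, evalue, prob.
#'   Full sequence lengths are not part of this layout and must be supplied
#'   through `lengths`, a data frame with columns `id` and `length`.
#' * `"native_tsv"`: the package's own layout with a header line and columns
#'   query_id, subject_id, probability, percent_identity, q_start, q_end,
#'   s_start, s_end, q_len, s_len, search_tag.
#'
#' Probabilities and identities are stored as fractions in \[0,1\]. hhsuite
#' prints both as percentages, so the blast-tab dialect defaults to
#' `prob_scale = "percent"`; the native dialect stores fractions.
#' Coordinates are 1-based inclusive residue positions and are never
#' converted elsewhere in the package.
#'
#' @param path path to a tab-delimited file; lines starting with `#` are
#'   ignored.
#' @param dialect input layout, see above.
#' @param lengths data frame with columns `id`, `length` giving full
#'   sequence lengths (required for `"blasttab_plus_prob"`).
#' @param prob_scale are probability and identity given as 0-100 percentages
#'   or 0-1 fractions?
#' @param search_tag tag recorded for every hit of a blast-tab table
#'   (`"self"`, `"ecod"`, `"phrog"` or `"antidefence"`).
#' @return data frame with columns query_id, subject_id, probability,
#'   percent_identity, q_start, q_end, s_start, s_end, q_len, s_len,
#'   search_tag; row order of the input is preserved.
#' @export
read_hit_table <- function(path,
                           dialect = c("native_tsv", "blasttab_plus_prob"),
                           lengths = NULL,
                           prob_scale = c("default", "percent", "fraction"),
                           search_tag = "self") {
  dialect <- match.arg(dialect)
  prob_scale <- match.arg(prob_scale)
  if (prob_scale == "default")
    prob_scale <- if (dialect == "blasttab_plus_prob") "percent" else "fraction"

  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  line_no <- which(keep)
  raw <- raw[keep]

  if (dialect == "native_tsv") {
    if (length(raw) == 0L) return(empty_hit_table())
    header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("query_id", "subject_id", "probability", "percent_identity",
              "q_start", "q_end", "s_start", "s_end", "q_len", "s_len",
              "search_tag")
    if (!all(need %in% header))
      stop("native_tsv hit table is missing columns: ",
           paste(setdiff(need, header), collapse = ", "))
    if (length(raw) == 1L) return(empty_hit_table())
    rows <- strsplit(raw[-1L], "\t", fixed = TRUE)
    nf <- vapply(rows, length, integer(1))
    if (any(nf != length(header)))
      stop("malformed row at line ", line_no[-1L][which(nf != length(header))[1L]])
    m <- do.call(rbind, rows)
    colnames(m) <- header
    hits <- data.frame(
      query_id = m[, "query_id"],
      subject_id = m[, "subject_id"],
      probability = as.numeric(m[, "probability"]),
      percent_identity = as.numeric(m[, "percent_identity"]),
      q_start = as.integer(m[, "q_start"]),
      q_end = as.integer(m[, "q_end"]),
      s_start = as.integer(m[, "s_start"]),
      s_end = as.integer(m[, "s_end"]),
      q_len = as.integer(m[, "q_len"]),
      s_len = as.integer(m[, "s_len"]),
      search_tag = m[, "search_tag"],
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(lengths))
      stop("dialect 'blasttab_plus_prob' requires a `lengths` table (id, length)")
    if (length(raw) == 0L) return(empty_hit_table())
    rows <- strsplit(raw, "\t", fixed = TRUE)
    nf <- vapply(rows, length, integer(1))
    if (any(nf != 10L))
      stop("malformed row at line ", line_no[which(nf != 10L)[1L]],
           ": expected 10 tab-separated fields")
    m <- do.call(rbind, rows)
    len_of <- stats::setNames(as.integer(lengths$length), lengths$id)
    q <- m[, 1L]; s <- m[, 2L]
    missing_len <- setdiff(unique(c(q, s)), names(len_of))
    if (length(missing_len))
      stop("no sequence length for: ", paste(missing_len, collapse = ", "))
    hits <- data.frame(
      query_id = q,
      subject_id = s,
      probability = as.numeric(m[, 10L]),
      percent_identity = as.numeric(m[, 3L]),
      q_start = as.integer(m[, 5L]),
      q_end = as.integer(m[, 6L]),
      s_start = as.integer(m[, 7L]),
      s_end = as.integer(m[, 8L]),
      q_len = unname(len_of[q]),
      s_len = unname(len_of[s]),
      search_tag = search_tag,
      stringsAsFactors = FALSE
    )
  }

  if (prob_scale == "percent") {
    hits$probability <- hits$probability / 100
    hits$percent_identity <- hits$percent_identity / 100
  }
  validate_hits(hits)
  hits
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             probability = numeric(), percent_identity = numeric(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             q_len = integer(), s_len = integer(),
             search_tag = character(), stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  bad_coord <- hits$q_start < 1L | hits$q_start > hits$q_end |
    hits$q_end > hits$q_len |
    hits$s_start < 1L | hits$s_start > hits$s_end | hits$s_end > hits$s_len
  if (any(bad_coord, na.rm = TRUE) || anyNA(bad_coord)) {
    i <- which(bad_coord | is.na(bad_coord))[1L]
    stop("coordinates out of range for hit ", hits$query_id[i], " vs ",
         hits$subject_id[i])
  }
  bad_frac <- hits$probability < 0 | hits$probability > 1 |
    hits$percent_identity < 0 | hits$percent_identity > 1
  if (any(bad_frac, na.rm = TRUE) || anyNA(bad_frac)) {
    i <- which(bad_frac | is.na(bad_frac))[1L]
    stop("probability/identity outside [0,1] for hit ", hits$query_id[i],
         " vs ", hits$subject_id[i])
  }
  invisible(hits)
}

#' Write a hit table in the native dialect
#'
#' Inverse of [read_hit_table()] for the `"native_tsv"` dialect:
#' `read_hit_table(write_hit_table(h, f))` is the identity on the record
#' list.
#'
#' @param hits hit data frame as returned by [read_hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse ECOD hierarchy identifiers
#'
#' ECOD identifiers are dot-separated integer paths through the hierarchy of
#' possible homology (X), homology (H) and topology (T) levels, e.g.
#' `"219.1.1"`; a fourth (family, F) level may be present and is retained.
#'
#' @param text character vector of identifiers with 3 or 4 levels.
#' @return data frame with columns `x_id` (integer), `h_id` (`"X.H"`),
#'   `t_id` (`"X.H.T"`) and `f_id` (`"X.H.T.F"` or `NA`).
#' @examples
#' parse_ecod_id("219.1.1")
#' @export
parse_ecod_id <- function(text) {
  parts <- strsplit(text, ".", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3L | n > 4L))
    stop("ECOD id must have 3 or 4 dot-separated levels: ",
         text[which(n < 3L | n > 4L)[1L]])
  flat <- unlist(parts)
  if (anyNA(suppressWarnings(as.integer(flat))) || any(!grepl("^[0-9]+$", flat)))
    stop("non-integer component in ECOD id: ",
         text[which(vapply(parts, function(p) any(!grepl("^[0-9]+$", p)), TRUE))[1L]])
  data.frame(
    x_id = vapply(parts, function(p) as.integer(p[1L]), integer(1)),
    h_id = vapply(parts, function(p) paste(p[1:2], collapse = "."), character(1)),
    t_id = vapply(parts, function(p) paste(p[1:3], collapse = "."), character(1)),
    f_id = vapply(parts, function(p)
      if (length(p) == 4L) paste(p, collapse = ".") else NA_character_,
      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Format an ECOD identifier record back to text
#'
#' @param ecod data frame as returned by [parse_ecod_id()].
#' @return character vector; the F-level is emitted when present.
#' @export
format_ecod_id <- function(ecod) {
  ifelse(is.na(ecod$f_id), ecod$t_id, ecod$f_id)
}

# X-group (integer) of a T-group string "X.H.T"
ecod_x_of <- function(t_id) as.integer(sub("\\..*$", "", t_id))

# H-group "X.H" of a T-group string
ecod_h_of <- function(t_id) sub("^([0-9]+\\.[0-9]+)\\..*$", "\\1", t_id)

#' Read the PHROG-to-simplified-class function map
#'
#' The map collapses fine-grained PHROG annotation classes into simplified
#' functional classes (e.g. *RusA-like Holliday junction resolvase* into
#' *Holliday junction resolvase*) and carries each PHROG class's total
#' sequence count, used for class eligibility. Generic classes (by default
#' `tail` and `structural protein`) are tolerated alongside a specific class
#' during annotation and excluded from class-level statistics.
#'
#' @param path tab-delimited file with header columns `phrog_class`,
#'   `simplified_class`, `category`, `phrog_total_seqs`.
#' @param generic_classes simplified classes treated as generic.
#' @return data frame with those columns and a `generic_classes` attribute.
#' @export
read_function_map <- function(path,
                              generic_classes = c("tail", "structural protein")) {
  fmap <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("phrog_class", "simplified_class", "category", "phrog_total_seqs")
  if (!all(need %in% names(fmap)))
    stop("function map is missing columns: ",
         paste(setdiff(need, names(fmap)), collapse = ", "))
  if (nrow(fmap) == 0L)
    stop("function map is empty: pipeline cannot annotate")
  dup <- split(fmap$simplified_class, fmap$phrog_class)
  conflict <- names(dup)[vapply(dup, function(x) length(unique(x)) > 1L, TRUE)]
  if (length(conflict))
    stop("conflicting simplified class for PHROG class: ",
         paste(conflict, collapse = ", "))
  fmap <- fmap[!duplicated(fmap$phrog_class), need]
  attr(fmap, "generic_classes") <- generic_classes
  fmap
}

#' Read genome/protein/rHMM metadata
#'
#' One row per protein: its genome, its representative-profile (rHMM)
#' membership, and the genome's host genus, ICTV family/genus and predicted
#' temperate probability. Empty strings and `NA` mark unknown values.
#'
#' @param path tab-delimited file with header columns `genome_id`,
#'   `protein_id`, `rhmm_id`, `host_genus`, `ictv_family`, `ictv_genus`,
#'   `temperate_probability`.
#' @return data frame with those columns; unknowns as `NA`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("genome_id", "protein_id", "rhmm_id", "host_genus",
            "ictv_family", "ictv_genus", "temperate_probability")
  if (!all(need %in% names(md)))
    stop("metadata is missing columns: ",
         paste(setdiff(need, names(md)), collapse = ", "))
  n_rhmm <- tapply(md$rhmm_id, md$protein_id,
                   function(x) length(unique(x[!is.na(x)])))
  if (any(n_rhmm > 1L))
    stop("protein mapped to more than one rHMM: ",
         paste(names(n_rhmm)[n_rhmm > 1L], collapse = ", "))
  bad_tp <- !is.na(md$temperate_probability) &
    (md$temperate_probability < 0 | md$temperate_probability > 1)
  if (any(bad_tp))
    stop("temperate_probability outside [0,1] for genome ",
         md$genome_id[which(bad_tp)[1L]])
  md[, need]
}

#' Write genome/protein/rHMM metadata
#' @param metadata data frame as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an ECOD domain-id map (domain id to X.H.T lineage)
#'
#' @param path tab-delimited file with header columns `ecod_domain_id`,
#'   `t_id` and optionally name columns.
#' @return data frame with `ecod_domain_id`, `t_id`, `h_id`, `x_id` and any
#'   name columns present.
#' @export
read_ecod_map <- function(path) {
  em <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("ecod_domain_id", "t_id") %in% names(em)))
    stop("ECOD map needs columns ecod_domain_id, t_id")
  parsed <- parse_ecod_id(em$t_id)
  em$h_id <- parsed$h_id
  em$x_id <- parsed$x_id
  em
}
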