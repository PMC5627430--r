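# Metabolic-enzyme conservation analysis over pairwise protein-alignment
# hit tables (12-column tabular format, as produced by blastp -outfmt 6).

#' Parse a tabular alignment hit file
#'
#' Reads 12-column tabular alignment output (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`).  A header
#' line starting with `qseqid` or `#` is skipped.  The subject strain is
#' taken from the `sseqid` prefix before the first `|` (the convention
#' written by [make_hit_table()]) unless `strain` is given.
#'
#' @param path Path to the hit file (UTF-8, tab-separated).
#' @param query_lengths Named numeric vector, query id -> protein length
#'   in amino acids; must cover every query in the file.
#' @param strain Optional strain token overriding the `sseqid` prefix.
#' @return Data frame with one row per hit: `query_id`, `subject_id`,
#'   `subject_strain`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `e_value`, `bit_score`, `query_length`.
#' @export
parse_hits <- function(path, query_lengths, strain = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  skip <- grepl("^#", lines) | grepl("^qseqid\\b", lines)
  body <- lines[!skip]
  if (!length(body))
    return(data.frame(query_id = character(), subject_id = character(),
                      subject_strain = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), mismatches = integer(),
                      gap_opens = integer(), e_value = numeric(),
                      bit_score = numeric(), query_length = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(body, "\t", fixed = TRUE)
  lineno <- which(!skip)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 12L)
      stop("hit file '", path, "', line ", lineno[i], ": expected 12 ",
           "tab-separated columns, found ", length(f))
    num <- suppressWarnings(as.numeric(f[c(3, 4, 5, 6, 11, 12)]))
    if (anyNA(num))
      stop("hit file '", path, "', line ", lineno[i],
           ": non-numeric value in numeric column")
    if (num[5] < 0)
      stop("hit file '", path, "', line ", lineno[i], ": negative e-value")
    if (num[2] <= 0)
      stop("hit file '", path, "', line ", lineno[i],
           ": non-positive alignment length")
    st <- if (!is.null(strain)) strain
          else if (grepl("|", f[2], fixed = TRUE))
            sub("\\|.*$", "", f[2]) else "unknown"
    rows[[i]] <- data.frame(
      query_id = f[1], subject_id = f[2], subject_strain = st,
      percent_identity = num[1], alignment_length = as.integer(num[2]),
      mismatches = as.integer(num[3]), gap_opens = as.integer(num[4]),
      e_value = num[5], bit_score = num[6], query_length = NA_real_,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  miss <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(miss))
    stop("query id(s) absent from query_lengths: ",
         paste(utils::head(miss, 5), collapse = ", "))
  hits$query_length <- as.numeric(query_lengths[hits$query_id])
  hits
}

#' Best hit per query against one strain
#'
#' Selects, for each query with at least one hit against the strain, the
#' top hit by lowest e-value; ties are broken by highest bit score, then
#' lexicographically smallest subject id.
#'
#' @param hits Hit data frame from [parse_hits()].
#' @param strain Strain token; `NULL` uses all hits (single-strain table).
#' @return One-row-per-query data frame of best hits.
#' @export
best_hit_per_query <- function(hits, strain = NULL) {
  if (!is.null(strain)) hits <- hits[hits$subject_strain == strain, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Call conservation of queries against one strain
#'
#' A query is conserved in the strain iff its best hit has percent
#' identity at or above `min_identity`, aligned length at or above
#' `min_coverage` of the query protein length, and e-value strictly below
#' `max_e` (identity and coverage thresholds are inclusive; the e-value
#' comparison is strict).  Queries with no hit are called not conserved.
#'
#' @param best Best-hit data frame from [best_hit_per_query()] (one
#'   strain).
#' @param query_lengths Named numeric vector covering every query to be
#'   called (queries absent from `best` get a not-conserved call).
#' @param min_identity Percent identity threshold (default 40).
#' @param min_coverage Fraction of query length that must be aligned
#'   (default 0.5).
#' @param max_e E-value ceiling, strict (default 1e-5).
#' @return Data frame of class `conservation_calls`: `query_id`,
#'   `subject_strain`, `conserved`, plus the best-hit columns (NA when
#'   the query had no hit).
#' @export
call_conservation <- function(best, query_lengths, min_identity = 40,
                              min_coverage = 0.5, max_e = 1e-5) {
  stopifnot(min_identity > 0, min_coverage > 0, max_e > 0)
  strain <- if (nrow(best)) unique(best$subject_strain) else "unknown"
  if (length(strain) > 1L)
    stop("best-hit table mixes strains: ", paste(strain, collapse = ", "),
         "; call per strain")
  queries <- names(query_lengths)
  idx <- match(queries, best$query_id)
  pid <- best$percent_identity[idx]
  alen <- best$alignment_length[idx]
  ev <- best$e_value[idx]
  qlen <- as.numeric(query_lengths)
  conserved <- !is.na(idx) &
    pid >= min_identity &
    alen >= min_coverage * qlen &
    ev < max_e
  out <- data.frame(query_id = queries, subject_strain = strain,
                    conserved = conserved,
                    percent_identity = pid, alignment_length = alen,
                    e_value = ev,
                    bit_score = best$bit_score[idx],
                    subject_id = best$subject_id[idx],
                    query_length = qlen,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("conservation_calls", class(out))
  out
}

#' Aggregate conservation calls per strain and per subsystem
#'
#' @param calls Conservation calls, possibly row-bound over several
#'   strains.
#' @param subsystem_map Named character vector, query id -> subsystem;
#'   must cover every query in `calls` (excluded subsystems are assumed
#'   to be filtered out upstream).
#' @return A `conservation_summary`: `per_strain_fraction` (named numeric
#'   in \[0,1\]), `per_subsystem` (long data frame `strain`, `subsystem`,
#'   `n_queries`, `fraction`), the wide `matrix` (strain x subsystem) and
#'   `n_queries`.  The per-strain fraction equals the query-count-weighted
#'   mean of that strain's subsystem fractions.
#' @export
summarize_conservation <- function(calls, subsystem_map) {
  miss <- setdiff(unique(calls$query_id), names(subsystem_map))
  if (length(miss))
    stop("query id(s) missing from subsystem_map: ",
         paste(utils::head(miss, 5), collapse = ", "))
  calls$subsystem <- as.character(subsystem_map[calls$query_id])
  agg <- stats::aggregate(conserved ~ subject_strain + subsystem,
                          data = calls,
                          FUN = function(x) c(n = length(x), f = mean(x)))
  long <- data.frame(strain = agg$subject_strain, subsystem = agg$subsystem,
                     n_queries = agg$conserved[, "n"],
                     fraction = agg$conserved[, "f"],
                     stringsAsFactors = FALSE)
  long <- long[order(long$strain, long$subsystem), , drop = FALSE]
  rownames(long) <- NULL
  per_strain <- tapply(calls$conserved, calls$subject_strain, mean)
  strains <- sort(unique(long$strain))
  subs <- sort(unique(long$subsystem))
  M <- matrix(NA_real_, length(strains), length(subs),
              dimnames = list(strains, subs))
  M[cbind(long$strain, long$subsystem)] <- long$fraction
  structure(list(per_strain_fraction = per_strain[strains],
                 per_subsystem = long, matrix = M,
                 n_queries = length(unique(calls$query_id))),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("Conservation summary over", x$n_queries, "queries and",
      length(x$per_strain_fraction), "strain(s)\n")
  print(round(x$per_strain_fraction, 4))
  invisible(x)
}

#' @export
plot.conservation_summary <- function(x, ...) {
  M <- x$matrix
  op <- graphics::par(mar = c(7, 6, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M), zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(M)), colnames(M), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(M)), rownames(M), las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Classify non-homologous queries
#'
#' Partitions the queries of one strain's conservation calls into four
#' mutually exclusive, exhaustive classes: `homolog` (conserved);
#' `isozyme_rescued` (not conserved, but some reaction it catalyzes has
#' another conserved enzyme in the strain); `annotation_similar` (not
#' conserved, no isozyme rescue, but flagged as having similar annotation
#' by external curation); `absent` (everything else).
#'
#' @param calls `conservation_calls` for a single strain.
#' @param reaction_enzyme_map List, reaction id -> character vector of
#'   query (enzyme) ids catalyzing it.
#' @param annotation_similarity Named logical vector, query id ->
#'   externally curated annotation-similarity flag; missing queries
#'   default to `FALSE`.
#' @return List with `counts` (named integer vector over the four
#'   classes, summing to the number of queries) and `calls` (the input
#'   with a `class` column).
#' @export
classify_nonhomologs <- function(calls, reaction_enzyme_map,
                                 annotation_similarity = logical()) {
  if (length(unique(calls$subject_strain)) > 1L)
    stop("classify_nonhomologs expects calls for a single strain")
  conserved <- stats::setNames(calls$conserved, calls$query_id)
  # enzyme -> reactions catalyzed
  enz2rxn <- list()
  for (rid in names(reaction_enzyme_map))
    for (q in reaction_enzyme_map[[rid]])
      enz2rxn[[q]] <- c(enz2rxn[[q]], rid)
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    q <- calls$query_id[i]
    if (isTRUE(conserved[[q]])) { cls[i] <- "homolog"; next }
    rescued <- FALSE
    for (rid in enz2rxn[[q]]) {
      others <- setdiff(reaction_enzyme_map[[rid]], q)
      if (any(vapply(others, function(o)
        o %in% names(conserved) && isTRUE(conserved[[o]]), logical(1)))) {
        rescued <- TRUE; break
      }
    }
    if (rescued) cls[i] <- "isozyme_rescued"
    else if (q %in% names(annotation_similarity) &&
             isTRUE(annotation_similarity[[q]]))
      cls[i] <- "annotation_similar"
    else cls[i] <- "absent"
  }
  calls$class <- cls
  counts <- vapply(c("homolog", "isozyme_rescued", "annotation_similar",
                     "absent"),
                   function(k) sum(cls == k), integer(1))
  list(counts = counts, calls = calls)
}
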