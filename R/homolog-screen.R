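#' Read a BLAST-style tabular homolog hit table
#'
#' Accepts either the package's minimal dialect (tab-separated columns
#' query_id, subject_id, bit_score, e_value, query_coverage, and optionally
#' subject_taxon) or standard 12-column tabular BLAST output (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' optionally followed by a 13th qlen column from which query coverage is
#' computed. Rows with E-value above `evalue_max` are dropped at ingestion;
#' malformed rows are skipped and counted in a message.
#'
#' @param path path to a tab-separated hit table (no header for the
#'   12-column BLAST dialect; a header naming the minimal-dialect columns is
#'   accepted and detected automatically).
#' @param evalue_max ingestion E-value ceiling (default 1e-05).
#' @return data frame of hits (query_id, subject_id, bit_score, e_value,
#'   query_coverage, subject_taxon).
#' @export
parse_hit_table <- function(path, evalue_max = 1e-05) {
  if (!file.exists(path)) stop(sprintf("cannot read hit table '%s'", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("hit table is empty", call. = FALSE)
  has_header <- grepl("query_id", first, fixed = TRUE)
  raw <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("hit table has no data rows", call. = FALSE)

  if (ncol(raw) >= 12L && !has_header) {
    qlen <- if (ncol(raw) >= 13L) suppressWarnings(as.numeric(raw[[13]])) else NA
    hits <- data.frame(query_id = as.character(raw[[1]]),
                       subject_id = as.character(raw[[2]]),
                       bit_score = suppressWarnings(as.numeric(raw[[12]])),
                       e_value = suppressWarnings(as.numeric(raw[[11]])),
                       query_coverage =
                         (abs(suppressWarnings(as.numeric(raw[[8]])) -
                              suppressWarnings(as.numeric(raw[[7]]))) + 1) / qlen,
                       subject_taxon = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    need <- c("query_id", "subject_id", "bit_score", "e_value", "query_coverage")
    if (!has_header) {
      if (ncol(raw) < 5L)
        stop("hit table must have >= 12 BLAST columns or the 5-column minimal dialect",
             call. = FALSE)
      names(raw)[1:5] <- need
      if (ncol(raw) >= 6L) names(raw)[6] <- "subject_taxon"
    }
    if (!all(need %in% names(raw)))
      stop("hit table header lacks required minimal-dialect columns", call. = FALSE)
    hits <- raw[, intersect(c(need, "subject_taxon"), names(raw)), drop = FALSE]
    if (!"subject_taxon" %in% names(hits)) hits$subject_taxon <- NA_character_
    for (col in c("bit_score", "e_value", "query_coverage"))
      hits[[col]] <- suppressWarnings(as.numeric(hits[[col]]))
  }

  bad <- !complete.cases(hits[, c("query_id", "subject_id", "bit_score",
                                  "e_value")]) |
    hits$bit_score <= 0 | hits$e_value < 0
  if (any(bad))
    message(sprintf("parse_hit_table: skipped %d malformed row(s)", sum(bad)))
  hits <- hits[!bad, , drop = FALSE]
  hits <- hits[hits$e_value <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("no parsable hits survive the E-value threshold", call. = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Retain top-scoring homolog hits for one query
#'
#' Implements the screening retention rule: self-hits are removed first,
#' then (under the default `"ratio"` rule) all hits whose bit score is at
#' least 80% of the best remaining bit score are retained -- the "top 20%
#' relative to the best bit score" reading, with ties at exactly 0.8 x best
#' kept. The alternative `"count"` rule instead keeps the top 20% of hits
#' by rank (at least one). A query with exactly one surviving hit is a
#' singleton (no tree can be built from it); one with none has status
#' `no_hit`.
#'
#' @param hits data frame of hits for a single query (as from
#'   [parse_hit_table()]).
#' @param query_id the query gene id (used to drop self-hits by exact id
#'   match, or via `id_map`).
#' @param rule `"ratio"` (default) or `"count"`.
#' @param ratio retention fraction of the best bit score under the ratio
#'   rule.
#' @param top_frac fraction of ranked hits kept under the count rule.
#' @param id_map optional named character vector mapping database subject
#'   ids to query ids, for catalogs whose ids differ from the query set.
#' @return list of class `screen_result`: `query_id`, `retained` (data
#'   frame), `status` in screened/singleton/no_hit.
#' @export
select_top_hits <- function(hits, query_id, rule = c("ratio", "count"),
                            ratio = 0.8, top_frac = 0.2, id_map = NULL) {
  rule <- match.arg(rule)
  if (nrow(hits) > 0 && !all(hits$query_id == query_id))
    stop("hits must all belong to `query_id`", call. = FALSE)
  subj <- hits$subject_id
  if (!is.null(id_map)) {
    mapped <- id_map[subj]
    subj <- ifelse(is.na(mapped), subj, mapped)
  }
  hits <- hits[subj != query_id, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(structure(list(query_id = query_id,
                          retained = hits, status = "no_hit"),
                     class = "screen_result"))
  if (rule == "ratio") {
    keep <- hits$bit_score >= ratio * max(hits$bit_score)
  } else {
    n_keep <- max(1L, ceiling(top_frac * nrow(hits)))
    ord <- order(-hits$bit_score, hits$subject_id)
    keep <- seq_len(nrow(hits)) %in% ord[seq_len(n_keep)]
  }
  retained <- hits[keep, , drop = FALSE]
  retained <- retained[order(-retained$bit_score, retained$subject_id), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  status <- if (nrow(retained) == 1L) "singleton" else "screened"
  structure(list(query_id = query_id, retained = retained, status = status),
            class = "screen_result")
}

#' Screen every query in a hit table
#'
#' Applies [select_top_hits()] per query and returns one row per query with
#' its status and a summary coverage (median query coverage of the retained
#' hits, used downstream as the gene's alignment coverage).
#'
#' @inheritParams select_top_hits
#' @param hits full hit table.
#' @param queries optional character vector of query ids to force into the
#'   output (queries with no rows at all are reported as `no_hit`).
#' @return data frame with columns query_id, status, n_retained,
#'   query_coverage; the per-query retained hits are attached as the
#'   `retained` attribute (named list).
#' @export
screen_hits <- function(hits, queries = NULL, rule = c("ratio", "count"),
                        ratio = 0.8, top_frac = 0.2, id_map = NULL) {
  rule <- match.arg(rule)
  queries <- queries %||% sort(unique(hits$query_id))
  res <- lapply(queries, function(q) {
    select_top_hits(hits[hits$query_id == q, , drop = FALSE], q,
                    rule = rule, ratio = ratio, top_frac = top_frac,
                    id_map = id_map)
  })
  out <- data.frame(
    query_id = queries,
    status = vapply(res, `[[`, "", "status"),
    n_retained = vapply(res, function(r) nrow(r$retained), 0L),
    query_coverage = vapply(res, function(r)
      if (nrow(r$retained)) median(r$retained$query_coverage) else NA_real_,
      0),
    stringsAsFactors = FALSE)
  attr(out, "retained") <- setNames(lapply(res, `[[`, "retained"), queries)
  out
}
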