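# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# top-hit retention by literal filtering
brute_top_hits <- function(hits, query_id, ratio = 0.8) {
  hits <- hits[hits$subject_id != query_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(list(retained = hits, status = "no_hit"))
  best <- max(hits$bit_score)
  retained <- hits[hits$bit_score >= ratio * best, , drop = FALSE]
  status <- if (nrow(retained) == 1L) "singleton" else "screened"
  list(retained = retained, status = status)
}

# exact hypergeometric upper tail by term enumeration
hyper_tail_enum <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# exhaustive cluster scan: every run, exact tail, greedy by p
brute_cluster_scan <- function(x, alpha = 0.001, max_span = 50L, min_k = 2L) {
  N <- length(x)
  K <- sum(x)
  cand <- NULL
  for (i in seq_len(N)) for (j in i:min(N, i + max_span - 1L)) {
    n <- j - i + 1L
    k <- sum(x[i:j])
    if (k < min_k) next
    p <- hyper_tail_enum(k, K, N, n)
    if (p < alpha)
      cand <- rbind(cand, data.frame(first = i, last = j, k = k, n = n,
                                     p = p))
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(cand$p, cand$first, cand$last), , drop = FALSE]
  taken <- rep(FALSE, N)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- cand$first[r]:cand$last[r]
    if (!any(taken[span])) { keep[r] <- TRUE; taken[span] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive 3-segment SSE change-point fit for short window vectors
brute_changepoint3 <- function(g, min_segment) {
  W <- length(g)
  sse <- function(v) sum((v - mean(v))^2)
  best <- NULL
  best_sse <- Inf
  for (i in min_segment:(W - 2 * min_segment))
    for (j in (i + min_segment):(W - min_segment)) {
      s <- sse(g[1:i]) + sse(g[(i + 1):j]) + sse(g[(j + 1):W])
      if (s < best_sse) { best_sse <- s; best <- c(i, j) }
    }
  list(cuts = best, sse = best_sse)
}

# GC fraction recomputed by naive character counting
naive_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

random_dna_test <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small hit table in the package's minimal dialect
make_hits <- function(query, subjects, bits,
                      evalue = 1e-10, coverage = 1, taxon = NA_character_) {
  data.frame(query_id = query, subject_id = subjects, bit_score = bits,
             e_value = evalue, query_coverage = coverage,
             subject_taxon = taxon, stringsAsFactors = FALSE)
}
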