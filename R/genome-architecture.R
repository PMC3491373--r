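#' Windowed GC profile of one sequence
#'
#' Tiles the sequence with non-overlapping windows (the final window may be
#' shorter) and reports per-window GC as (G+C)/(A+C+G+T); ambiguity codes
#' are excluded from both numerator and denominator.
#'
#' @param sequence a character string or `Biostrings::DNAString`.
#' @param window window size in bp (default 500); a window larger than the
#'   sequence yields a single window.
#' @param chrom optional chromosome id carried into the output.
#' @return data frame with columns chrom, window_start, window_length, gc.
#' @export
gc_windows <- function(sequence, window = 500L, chrom = NA_character_) {
  s <- if (inherits(sequence, "DNAString")) sequence
       else Biostrings::DNAString(as.character(sequence))
  len <- length(s)
  stopifnot(len > 0, window >= 1)
  starts <- seq.int(1L, len, by = as.integer(window))
  widths <- pmin(as.integer(window), len - starts + 1L)
  v <- Biostrings::Views(s, start = starts, width = widths)
  af <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  denom <- rowSums(af)
  gc <- ifelse(denom > 0, (af[, "C"] + af[, "G"]) / denom, NA_real_)
  data.frame(chrom = chrom, window_start = starts, window_length = widths,
             gc = gc, stringsAsFactors = FALSE)
}

#' GC profile over a whole genome
#'
#' @param sequences named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @inheritParams gc_windows
#' @return row-bound [gc_windows()] output for every chromosome.
#' @export
gc_profile <- function(sequences, window = 500L) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- sprintf("seq%d", seq_along(sequences))
  out <- lapply(seq_along(sequences), function(i)
    gc_windows(sequences[[i]], window = window, chrom = nm[i]))
  do.call(rbind, out)
}

#' Detect low-GC outlier chromosomes
#'
#' A chromosome is an outlier when its (length-weighted) mean GC falls more
#' than `delta` below the trimmed mean of all chromosome GC means -- the
#' trimming keeps a handful of true outliers from dragging the genome
#' reference down.
#'
#' @param profile a [gc_profile()] data frame.
#' @param delta absolute GC shortfall that flags an outlier (default 0.04,
#'   separating ~42% outliers from a ~48% genome).
#' @param trim fraction trimmed from each end when averaging chromosome
#'   means (default 0.2).
#' @return data frame of outliers (chrom, size_bp, mean_gc), sorted by size
#'   descending; zero rows when none qualify.
#' @export
detect_outlier_chromosomes <- function(profile, delta = 0.04, trim = 0.2) {
  chrs <- unique(profile$chrom)
  stopifnot(length(chrs) >= 3)
  by_chr <- data.frame(
    chrom = chrs,
    size_bp = vapply(chrs, function(ch)
      sum(profile$window_length[profile$chrom == ch]), 0),
    mean_gc = vapply(chrs, function(ch) {
      sub <- profile[profile$chrom == ch & !is.na(profile$gc), , drop = FALSE]
      sum(sub$gc * sub$window_length) / sum(sub$window_length)
    }, 0),
    stringsAsFactors = FALSE)
  ref <- mean(by_chr$mean_gc, trim = trim)
  out <- by_chr[by_chr$mean_gc < ref - delta, , drop = FALSE]
  out <- out[order(-out$size_bp, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

segment_sse <- function(cs, cs2, a, b) {
  # sum of squared deviations of g[a..b] around its mean, from cumsums
  n <- b - a + 1
  s <- cs[b + 1] - cs[a]
  (cs2[b + 1] - cs2[a]) - s * s / n
}

#' Delineate the low-GC core of a big outlier chromosome
#'
#' Fits a three-segment high-low-high step model to the chromosome's
#' windowed GC by exhaustive change-point search minimizing total
#' within-segment variance, each segment at least `min_segment` windows.
#' The middle (low-GC) segment is the BOC1 region. When the best
#' three-segment fit does not reduce the single-segment sum of squares by
#' at least `min_improve` (relative), or the middle segment is not the
#' lowest-GC one, the chromosome is uniformly atypical and is returned
#' whole with kind `SOC`. Chromosomes shorter than `3 * min_segment`
#' windows are also returned whole.
#'
#' @param profile [gc_windows()] rows of a single chromosome, in order.
#' @param min_segment minimum segment length in windows (default 50).
#' @param min_improve minimum relative SSE reduction of the 3-segment model
#'   over the 1-segment model (default 0.3).
#' @return one-row data frame: chrom, start, end (bp), kind ("BOC1" or
#'   "SOC"), mean_gc of the returned region, first_window, last_window.
#' @export
delineate_boc1 <- function(profile, min_segment = 50L, min_improve = 0.3) {
  stopifnot(length(unique(profile$chrom)) == 1)
  g <- profile$gc
  W <- length(g)
  whole <- function() {
    data.frame(chrom = profile$chrom[1], start = profile$window_start[1],
               end = profile$window_start[W] + profile$window_length[W] - 1L,
               kind = "SOC", mean_gc = sum(g * profile$window_length,
                                           na.rm = TRUE) /
                 sum(profile$window_length[!is.na(g)]),
               first_window = 1L, last_window = W, stringsAsFactors = FALSE)
  }
  if (W < 3L * min_segment) return(whole())
  gg <- g
  gg[is.na(gg)] <- mean(g, na.rm = TRUE)
  cs <- c(0, cumsum(gg))
  cs2 <- c(0, cumsum(gg^2))
  sse1 <- segment_sse(cs, cs2, 1L, W)

  # change points i (end of left flank) and j (end of middle segment)
  best <- c(NA_integer_, NA_integer_)
  best_sse <- Inf
  i_range <- min_segment:(W - 2L * min_segment)
  left <- vapply(i_range, function(i) segment_sse(cs, cs2, 1L, i), 0)
  for (ii in seq_along(i_range)) {
    i <- i_range[ii]
    j_range <- (i + min_segment):(W - min_segment)
    mid <- vapply(j_range, function(j) segment_sse(cs, cs2, i + 1L, j), 0)
    right <- vapply(j_range, function(j) segment_sse(cs, cs2, j + 1L, W), 0)
    tot <- left[ii] + mid + right
    k <- which.min(tot)
    if (tot[k] < best_sse) {
      best_sse <- tot[k]
      best <- c(i, j_range[k])
    }
  }
  i <- best[1]; j <- best[2]
  mean_seg <- function(a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
  improved <- sse1 > 0 && (sse1 - best_sse) / sse1 >= min_improve
  mid_lowest <- mean_seg(i + 1L, j) < mean_seg(1L, i) &&
    mean_seg(i + 1L, j) < mean_seg(j + 1L, W)
  if (!improved || !mid_lowest) return(whole())
  data.frame(chrom = profile$chrom[1],
             start = profile$window_start[i + 1L],
             end = profile$window_start[j] + profile$window_length[j] - 1L,
             kind = "BOC1", mean_gc = mean_seg(i + 1L, j),
             first_window = i + 1L, last_window = j,
             stringsAsFactors = FALSE)
}

#' Assign uniquely mapped ESTs to genes
#'
#' Non-unique alignments are discarded. Stranded alignments are assigned
#' only to same-strand overlapping genes; strandless alignments overlapping
#' more than one gene go to the gene with the larger overlap, with exact
#' ties discarded (counted in the `n_discarded` attribute). Coordinates are
#' 1-based inclusive.
#'
#' @param ests data frame with columns chrom, start, end, and optionally
#'   strand ("+", "-", or NA/"*" for strandless) and unique (logical,
#'   default TRUE).
#' @param genes gene-record data frame (gene_id, chrom, start, end, strand).
#' @return named integer vector of EST counts per gene (every gene present,
#'   zero-filled), with attribute `n_discarded`.
#' @export
assign_ests <- function(ests, genes) {
  if (is.null(ests$strand)) ests$strand <- NA_character_
  if (is.null(ests$unique)) ests$unique <- TRUE
  ests <- ests[ests$unique, , drop = FALSE]
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  n_disc <- 0L
  if (nrow(ests)) {
    gr_e <- GenomicRanges::GRanges(ests$chrom,
                                   IRanges::IRanges(ests$start, ests$end))
    gr_g <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gr_e, gr_g, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    width_ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_e)[qh], IRanges::ranges(gr_g)[sh]))
    for (e in unique(qh)) {
      idx <- which(qh == e)
      cand <- sh[idx]
      w <- width_ov[idx]
      es <- ests$strand[e]
      if (!is.na(es) && es %in% c("+", "-")) {
        same <- genes$strand[cand] == es
        cand <- cand[same]; w <- w[same]
      }
      if (length(cand) == 0L) next
      if (length(cand) > 1L) {
        mx <- w == max(w)
        if (sum(mx) > 1L) { n_disc <- n_disc + 1L; next }
        cand <- cand[mx]
      }
      counts[cand] <- counts[cand] + 1L
    }
  }
  attr(counts, "n_discarded") <- n_disc
  counts
}

#' Expression and intron-content gene categories
#'
#' Adds the four boolean categories used by the physical-cluster scan:
#' expressed (EST count > 0), highly expressed (EST count > 2), has an
#' intron (intron count > 0), intron-rich (intron count > 2).
#'
#' @param genes gene-record data frame with est_count and intron_count.
#' @return `genes` with logical columns expressed, highly_expressed,
#'   has_intron, intron_rich.
#' @export
categorize_genes <- function(genes) {
  genes$expressed <- genes$est_count > 0
  genes$highly_expressed <- genes$est_count > 2
  genes$has_intron <- genes$intron_count > 0
  genes$intron_rich <- genes$intron_count > 2
  genes
}

#' Hypergeometric scan for physical clusters of category genes
#'
#' On one chromosome's genes in positional order, evaluates every
#' contiguous run of up to `max_span` genes containing at least `min_k`
#' category members: the run's p-value is the exact hypergeometric
#' upper-tail probability of drawing that many category genes in a sample
#' of the run's size from the chromosome total. Significant runs
#' (p < `alpha`) are reported greedily by ascending p-value as maximal
#' non-overlapping clusters.
#'
#' @param genes data frame of one chromosome's genes with a logical column
#'   named by `category`, sorted by start (re-sorted defensively).
#' @param category name of the logical category column.
#' @param alpha significance threshold on the raw hypergeometric tail
#'   (default 0.001).
#' @param max_span maximum cluster size in genes (default 50).
#' @param min_k minimum category genes inside a cluster (default 2).
#' @return data frame with columns chrom, first_gene_index,
#'   last_gene_index, category, k, n, p_value (zero rows when nothing is
#'   significant).
#' @export
cluster_scan <- function(genes, category, alpha = 0.001, max_span = 50L,
                         min_k = 2L) {
  stopifnot(category %in% names(genes),
            length(unique(genes$chrom)) <= 1)
  empty <- data.frame(chrom = character(0), first_gene_index = integer(0),
                      last_gene_index = integer(0), category = character(0),
                      k = integer(0), n = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  x <- as.logical(genes[[category]])
  N <- length(x)
  K <- sum(x)
  if (K < min_k || N < 2L) return(empty)
  cx <- c(0L, cumsum(x))
  cand <- NULL
  for (i in seq_len(N)) {
    j_max <- min(N, i + max_span - 1L)
    if (j_max < i) next
    j <- i:j_max
    n <- j - i + 1L
    k <- cx[j + 1L] - cx[i]
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ok <- k >= min_k & p < alpha
    if (any(ok))
      cand <- rbind(cand, data.frame(first_gene_index = i,
                                     last_gene_index = j[ok],
                                     k = k[ok], n = n[ok], p_value = p[ok]))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$p_value, cand$first_gene_index,
                     cand$last_gene_index), , drop = FALSE]
  taken <- rep(FALSE, N)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- cand$first_gene_index[r]:cand$last_gene_index[r]
    if (!any(taken[span])) {
      keep[r] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$category <- category
  out$chrom <- if (nrow(genes)) genes$chrom[1] else NA_character_
  rownames(out) <- NULL
  out[, c("chrom", "first_gene_index", "last_gene_index", "category",
          "k", "n", "p_value")]
}

#' Scan every chromosome and category
#'
#' @param genes categorized gene table (see [categorize_genes()]).
#' @param categories category column names to scan.
#' @inheritParams cluster_scan
#' @return row-bound [cluster_scan()] results over chromosomes x categories.
#' @export
cluster_scan_genome <- function(genes,
                                categories = c("expressed", "highly_expressed",
                                               "has_intron", "intron_rich"),
                                alpha = 0.001, max_span = 50L, min_k = 2L) {
  res <- list()
  for (chr in unique(genes$chrom)) {
    sub <- genes[genes$chrom == chr, , drop = FALSE]
    for (cat in categories)
      res[[length(res) + 1L]] <- cluster_scan(sub, cat, alpha = alpha,
                                              max_span = max_span,
                                              min_k = min_k)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summary statistics for a chromosomal region
#'
#' Produces the descriptive row used to characterize outlier regions: size,
#' mean GC, gene count, gene density (bp per gene, floored), mean introns
#' per gene, EST-supported gene fraction, and the identified-function
#' percentage when a `function_known` column is present. Percentages are
#' rounded to integers.
#'
#' @param genes gene records inside the region.
#' @param span_bp region size in bp.
#' @param mean_gc optional mean GC of the region.
#' @return one-row data frame.
#' @export
region_summary <- function(genes, span_bp, mean_gc = NA_real_) {
  n <- nrow(genes)
  data.frame(
    size_bp = span_bp,
    mean_gc = mean_gc,
    gene_count = n,
    density_bp_per_gene = if (n > 0) floor(span_bp / n) else NA_real_,
    mean_introns_per_gene = if (n > 0) sum(genes$intron_count) / n else NA_real_,
    est_supported_pct = if (n > 0) round(100 * mean(genes$est_count > 0))
                        else NA_real_,
    identified_function_pct = if (n > 0 && !is.null(genes$function_known))
      round(100 * mean(genes$function_known)) else NA_real_,
    stringsAsFactors = FALSE)
}
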