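test_that("windowed GC handles whole, partial, and degenerate windows", {
  p1 <- gc_windows(strrep("ATGC", 125))            # exactly one 500-bp window
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$gc, 0.5)

  expect_equal(gc_windows(strrep("A", 500))$gc, 0)

  p3 <- gc_windows(paste0(strrep("GC", 250), strrep("AT", 125)))
  expect_equal(p3$window_length, c(500L, 250L))
  expect_equal(p3$gc, c(1, 0))

  # window larger than the sequence: one (short) window
  p4 <- gc_windows("ACGT", window = 500)
  expect_equal(nrow(p4), 1L)
  expect_equal(p4$window_length, 4L)

  # ambiguity codes excluded from numerator and denominator
  p5 <- gc_windows("GGNNAA", window = 6)
  expect_equal(p5$gc, 0.5)
})

test_that("window GC times window length conserves total G+C", {
  set.seed(1)
  seq <- random_dna_test(3120, 0.37)
  p <- gc_windows(seq, window = 500)
  total_gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C"))
  expect_equal(sum(p$gc * p$window_length), total_gc)
})

test_that("outlier chromosomes are the ones below the trimmed mean minus delta", {
  set.seed(3)
  mk <- function(gc, n = 40) data.frame(window_start = seq(1, by = 500,
                                                           length.out = n),
                                        window_length = 500, gc = gc)
  prof <- do.call(rbind, c(
    lapply(1:17, function(i) cbind(chrom = sprintf("n%02d", i),
                                   mk(rnorm(40, 0.48, 0.01)))),
    list(cbind(chrom = "big", mk(rnorm(60, 0.42, 0.01), n = 60)),
         cbind(chrom = "small", mk(rnorm(40, 0.42, 0.01))))))
  out <- detect_outlier_chromosomes(prof)
  expect_equal(out$chrom, c("big", "small"))   # sorted by size descending

  # uniform genome: nothing flagged; larger delta: threshold monotonicity
  prof_u <- prof
  prof_u$gc <- 0.48
  expect_equal(nrow(detect_outlier_chromosomes(prof_u)), 0L)
  expect_equal(nrow(detect_outlier_chromosomes(prof, delta = 0.10)), 0L)
})

test_that("the high-low-high change-point recovers planted BOC1 boundaries", {
  mkprof <- function(g) data.frame(chrom = "c1",
                                   window_start = seq(1, by = 500,
                                                      length.out = length(g)),
                                   window_length = 500, gc = g)
  g <- c(rep(0.60, 200), rep(0.42, 600), rep(0.60, 200))
  r <- delineate_boc1(mkprof(g), min_segment = 50)
  expect_equal(r$kind, "BOC1")
  expect_lte(abs(r$first_window - 201), 5)
  expect_lte(abs(r$last_window - 800), 5)

  # noisy version, and agreement with the exhaustive small-case oracle
  set.seed(8)
  g2 <- c(rnorm(30, 0.55, 0.02), rnorm(45, 0.40, 0.02), rnorm(25, 0.55, 0.02))
  r2 <- delineate_boc1(mkprof(g2), min_segment = 10)
  o <- brute_changepoint3(g2, 10)
  expect_equal(r2$first_window, o$cuts[1] + 1L)
  expect_equal(r2$last_window, o$cuts[2])

  # uniform GC: falls back to the whole chromosome
  set.seed(9)
  g3 <- rnorm(300, 0.48, 0.02)
  r3 <- delineate_boc1(mkprof(g3), min_segment = 50)
  expect_equal(r3$kind, "SOC")
  expect_equal(r3$first_window, 1L)
  expect_equal(r3$last_window, 300L)

  # chromosome shorter than three minimum segments: returned whole
  r4 <- delineate_boc1(mkprof(rep(0.42, 60)), min_segment = 50)
  expect_equal(r4$kind, "SOC")
})

test_that("EST assignment follows uniqueness, strand, and overlap rules", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(1, 200), end = c(240, 400),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  # overlaps g1 by 100 bp (141..240) and g2 by 41 bp (200..240)
  ests <- data.frame(chrom = "c1", start = 141, end = 240,
                     strand = NA_character_, unique = TRUE)
  cnt <- assign_ests(ests, genes)
  expect_equal(as.vector(cnt), c(1L, 0L))

  # non-unique alignments are discarded
  cnt2 <- assign_ests(transform(ests, unique = FALSE), genes)
  expect_equal(sum(cnt2), 0L)

  # exact tie (80 bp overlap with each gene) without strand: discarded
  tie <- data.frame(chrom = "c1", start = 161, end = 279,
                    strand = NA_character_, unique = TRUE)
  cnt3 <- assign_ests(tie, genes)
  expect_equal(sum(cnt3), 0L)
  expect_equal(attr(cnt3, "n_discarded"), 1L)

  # stranded EST only goes to a same-strand gene
  minus <- data.frame(chrom = "c1", start = 150, end = 260, strand = "-",
                      unique = TRUE)
  cnt4 <- assign_ests(minus, genes)
  expect_equal(as.vector(cnt4), c(0L, 1L))
})

test_that("gene categories use the strict >0 and >2 thresholds", {
  g <- categorize_genes(data.frame(est_count = c(3, 2, 0, 0),
                                   intron_count = c(0, 0, 3, 1)))
  expect_equal(g$expressed, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(g$highly_expressed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(g$has_intron, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(g$intron_rich, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("cluster significance is the exact hypergeometric tail", {
  mk <- function(flags) data.frame(chrom = "c1",
                                   start = seq_along(flags) * 1000,
                                   cat = flags, stringsAsFactors = FALSE)
  # N=10, K=4, a run of 4/4: p = 1/C(10,4) ~ 0.00476 > 0.001 -> no cluster
  g1 <- mk(c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(nrow(cluster_scan(g1, "cat")), 0L)
  expect_equal(hyper_tail_enum(4, 4, 10, 4), 1 / choose(10, 4))

  # N=20, K=5, a run of 5/5: p = 1/C(20,5) ~ 6.45e-5 < 0.001 -> one cluster
  g2 <- mk(c(rep(TRUE, 5), rep(FALSE, 15)))
  r2 <- cluster_scan(g2, "cat")
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$p_value, 1 / choose(20, 5))
  expect_equal(c(r2$first_gene_index, r2$last_gene_index, r2$k, r2$n),
               c(1L, 5L, 5L, 5L))

  # no category genes at all: empty
  expect_equal(nrow(cluster_scan(mk(rep(FALSE, 10)), "cat")), 0L)
})

test_that("greedy scan matches exhaustive enumeration on random chromosomes", {
  set.seed(101)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    x <- runif(N) < runif(1, 0.1, 0.5)
    genes <- data.frame(chrom = "c1", start = seq_len(N) * 500, cat = x)
    r <- cluster_scan(genes, "cat")
    o <- brute_cluster_scan(x)
    if (is.null(o)) {
      expect_equal(nrow(r), 0L)
    } else {
      expect_equal(nrow(r), nrow(o))
      expect_equal(r$first_gene_index, o$first)
      expect_equal(r$last_gene_index, o$last)
      expect_equal(r$p_value, o$p)
    }
  }
})

test_that("region summaries reproduce density and percentage arithmetic", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:72),
                      intron_count = 0L,
                      est_count = rep(c(1L, 0L), c(36, 36)),
                      function_known = rep(c(TRUE, FALSE), c(34, 38)))
  s <- region_summary(genes, span_bp = 146238)
  expect_equal(s$density_bp_per_gene, 2031)
  expect_equal(s$identified_function_pct, 47)
  expect_equal(s$est_supported_pct, 50)

  # whole-genome density is exact
  g2 <- data.frame(gene_id = c("a", "b"), intron_count = c(1L, 2L),
                   est_count = c(0L, 5L))
  s2 <- region_summary(g2, span_bp = 5000)
  expect_equal(s2$density_bp_per_gene, 2500)
  expect_equal(s2$mean_introns_per_gene, 1.5)
})
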