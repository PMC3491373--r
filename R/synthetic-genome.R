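#' Simulation configuration for a Mamiellales-like synthetic genome
#'
#' Builds and validates the parameter set for [simulate_genome()]. Defaults
#' emulate a Bathycoccus-like nuclear genome: 19 chromosomes at 48% GC with
#' two low-GC (42%) outliers -- a "big" outlier chromosome whose atypical
#' features are confined to a contiguous sub-region (BOC1) flanked by
#' baseline-GC extremities, and a "small" outlier chromosome (SOC) that is
#' low-GC over its whole length and carries species-specific genes without
#' family membership. BOC1 genes carry many small (40-65 bp) AT-rich introns
#' (1.54/gene on average) and are more often EST-supported than the rest of
#' the genome; a configurable fraction of genes genome-wide is planted as
#' horizontally transferred from a non-green donor group.
#'
#' @param n_chromosomes number of chromosomes (>= 3).
#' @param genes_per_chromosome genes on each ordinary chromosome; the SOC
#'   carries half as many, making it the smallest chromosome.
#' @param baseline_gc,outlier_gc GC fractions of ordinary regions and of the
#'   low-GC outlier regions; `outlier_gc < baseline_gc` is required.
#' @param boc1_span fraction of the big outlier chromosome's genes inside
#'   the BOC1 sub-region (strictly between 0 and 1).
#' @param boc1_intron_rate,background_intron_rate mean introns per gene
#'   (Poisson) inside and outside BOC1.
#' @param intron_length_range integer vector `c(min, max)` of intron lengths
#'   in bp.
#' @param hgt_fraction probability that a gene is planted as an HGT event.
#' @param taxon_groups ordered character vector of top-level taxon groups;
#'   must contain `green_group`. Donors are drawn from the non-green
#'   cellular groups.
#' @param green_group label of the green-lineage group.
#' @param est_mean_boc1,est_mean_background negative-binomial mean EST count
#'   for BOC1 genes and for all other genes.
#' @param est_dispersion negative-binomial size parameter (1 = geometric).
#' @param boc_chromosome,soc_chromosome indices of the big and small outlier
#'   chromosomes; they must differ.
#' @param seed integer seed; equal seeds give byte-identical bundles.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 19L,
                       genes_per_chromosome = 55L,
                       baseline_gc = 0.48,
                       outlier_gc = 0.42,
                       boc1_span = 0.8,
                       boc1_intron_rate = 1.54,
                       background_intron_rate = 0.15,
                       intron_length_range = c(40L, 65L),
                       hgt_fraction = 0.06,
                       taxon_groups = c("Viridiplantae", "Metazoa",
                                        "Stramenopiles", "Fungi",
                                        "other-Eukaryota", "Bacteria",
                                        "Archaea", "Viruses"),
                       green_group = "Viridiplantae",
                       est_mean_boc1 = 3,
                       est_mean_background = 0.9,
                       est_dispersion = 1,
                       boc_chromosome = NULL,
                       soc_chromosome = NULL,
                       seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 3L)
  genes_per_chromosome <- check_count(genes_per_chromosome,
                                      "genes_per_chromosome", min = 4L)
  check_fraction(baseline_gc, "baseline_gc")
  check_fraction(outlier_gc, "outlier_gc")
  if (outlier_gc >= baseline_gc)
    abort_invalid("outlier_gc", "must be below baseline_gc")
  check_fraction(boc1_span, "boc1_span")
  if (boc1_intron_rate < 0)
    abort_invalid("boc1_intron_rate", "must be >= 0")
  if (background_intron_rate < 0)
    abort_invalid("background_intron_rate", "must be >= 0")
  if (length(intron_length_range) != 2L ||
      intron_length_range[1] > intron_length_range[2] ||
      intron_length_range[1] < 1)
    abort_invalid("intron_length_range", "must be c(min, max) with 1 <= min <= max")
  check_fraction(hgt_fraction, "hgt_fraction", lo = 0, hi = 1,
                 lo_open = FALSE, hi_open = TRUE)
  if (!green_group %in% taxon_groups)
    abort_invalid("taxon_groups", sprintf("must include the green-lineage group '%s'",
                                          green_group))
  if (est_mean_boc1 < 0 || est_mean_background < 0)
    abort_invalid("est_mean_boc1/est_mean_background", "must be nonnegative")
  boc_chromosome <- boc_chromosome %||% min(14L, n_chromosomes - 1L)
  soc_chromosome <- soc_chromosome %||% n_chromosomes
  boc_chromosome <- check_count(boc_chromosome, "boc_chromosome")
  soc_chromosome <- check_count(soc_chromosome, "soc_chromosome")
  if (boc_chromosome > n_chromosomes || soc_chromosome > n_chromosomes ||
      boc_chromosome == soc_chromosome)
    abort_invalid("boc_chromosome/soc_chromosome",
                  "must be distinct chromosome indices")
  cfg <- list(n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              baseline_gc = baseline_gc, outlier_gc = outlier_gc,
              boc1_span = boc1_span,
              boc1_intron_rate = boc1_intron_rate,
              background_intron_rate = background_intron_rate,
              intron_length_range = as.integer(intron_length_range),
              hgt_fraction = hgt_fraction,
              taxon_groups = taxon_groups, green_group = green_group,
              est_mean_boc1 = est_mean_boc1,
              est_mean_background = est_mean_background,
              est_dispersion = est_dispersion,
              boc_chromosome = boc_chromosome,
              soc_chromosome = soc_chromosome,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a ground-truthed synthetic genome bundle
#'
#' Emits chromosome sequences, gene annotations with intron and EST counts,
#' and a truth table flagging planted HGT genes and outlier-region
#' membership. Sequences are i.i.d. nucleotide draws at the region's GC
#' level: the SOC chromosome is low-GC throughout; the big outlier
#' chromosome is low-GC only inside the BOC1 sub-region; BOC1 introns are
#' AT-rich (GC 0.25). Intron counts are Poisson per gene with region rates;
#' EST counts are negative-binomial with region means. SOC genes carry no
#' gene-family membership (species-specific).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `scan_bundle` with elements `sequences` (named
#'   character vector), `genes` (data frame of gene records), `exons`
#'   (per-gene exon intervals), `truth` (truth table), `boc1_region`
#'   (chromosome/start/end of the planted BOC1 segment), and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  sequences <- setNames(character(cfg$n_chromosomes), chroms)
  genes_l <- vector("list", cfg$n_chromosomes)
  exons_l <- vector("list", cfg$n_chromosomes)
  boc1_region <- NULL
  gene_no <- 0L

  donor_pool <- setdiff(cfg$taxon_groups, c(cfg$green_group, "Viruses"))

  for (ci in seq_len(cfg$n_chromosomes)) {
    is_boc <- ci == cfg$boc_chromosome
    is_soc <- ci == cfg$soc_chromosome
    ngene <- if (is_soc) max(4L, as.integer(round(cfg$genes_per_chromosome / 2)))
             else cfg$genes_per_chromosome

    # middle block of gene indices forms BOC1
    boc1_idx <- integer(0)
    if (is_boc) {
      m <- max(2L, as.integer(round(cfg$boc1_span * ngene)))
      m <- min(m, ngene - 2L)              # keep flanks nonempty
      lo <- as.integer(floor((ngene - m) / 2)) + 1L
      boc1_idx <- lo:(lo + m - 1L)
    }

    seq_parts <- character(0)
    cursor <- 0L
    g_rows <- vector("list", ngene)
    e_rows <- vector("list", ngene)
    gene_region_gc <- function(in_low) if (in_low) cfg$outlier_gc else cfg$baseline_gc

    boc1_bp <- c(NA_integer_, NA_integer_)

    for (gi in seq_len(ngene)) {
      gene_no <- gene_no + 1L
      in_boc1 <- gi %in% boc1_idx
      low_gc <- is_soc || in_boc1
      gapi <- sample(200:500, 1L)
      rate <- if (in_boc1) cfg$boc1_intron_rate else cfg$background_intron_rate
      n_int <- rpois(1L, rate)
      int_len <- if (n_int > 0)
        sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], n_int,
               replace = TRUE) else integer(0)
      cds_len <- sample(600:1200, 1L)
      # split CDS uniformly into n_int + 1 exon pieces
      if (n_int > 0) {
        cuts <- sort(sample(seq_len(cds_len - 1L), n_int))
        exon_len <- diff(c(0L, cuts, cds_len))
      } else exon_len <- cds_len

      region_gc <- gene_region_gc(low_gc)
      seq_parts <- c(seq_parts, random_dna(gapi, region_gc))
      g_start <- cursor + gapi + 1L
      pos <- g_start
      ex <- matrix(NA_integer_, nrow = length(exon_len), ncol = 2)
      for (k in seq_along(exon_len)) {
        seq_parts <- c(seq_parts, random_dna(exon_len[k], region_gc))
        ex[k, ] <- c(pos, pos + exon_len[k] - 1L)
        pos <- pos + exon_len[k]
        if (k <= n_int) {
          intron_gc <- if (in_boc1) 0.25 else region_gc
          seq_parts <- c(seq_parts, random_dna(int_len[k], intron_gc))
          pos <- pos + int_len[k]
        }
      }
      g_end <- pos - 1L
      cursor <- g_end

      if (in_boc1) {
        if (is.na(boc1_bp[1])) boc1_bp[1] <- g_start - as.integer(gapi / 2)
        boc1_bp[2] <- g_end + 100L
      }

      gid <- sprintf("g%05d", gene_no)
      est_mu <- if (in_boc1) cfg$est_mean_boc1 else cfg$est_mean_background
      est <- rnbinom(1L, mu = est_mu, size = cfg$est_dispersion)
      is_hgt <- runif(1L) < cfg$hgt_fraction
      donor <- if (is_hgt) sample(donor_pool, 1L) else NA_character_
      p_fun <- if (is_soc) 0.47 else if (in_boc1) 0.71 else 0.44
      has_fun <- runif(1L) < p_fun
      g_rows[[gi]] <- data.frame(
        gene_id = gid, chrom = chroms[ci], start = g_start, end = g_end,
        strand = sample(c("+", "-"), 1L), intron_count = n_int,
        est_count = est, family_id = NA_character_,
        in_boc1 = in_boc1, in_soc = is_soc,
        function_known = has_fun,
        is_hgt = is_hgt, donor_group = donor,
        stringsAsFactors = FALSE)
      e_rows[[gi]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                 start = ex[, 1], end = ex[, 2],
                                 stringsAsFactors = FALSE)
    }
    # terminal intergenic stretch
    tail_gap <- sample(200:500, 1L)
    seq_parts <- c(seq_parts, random_dna(tail_gap, gene_region_gc(is_soc)))
    sequences[ci] <- paste(seq_parts, collapse = "")
    genes_l[[ci]] <- do.call(rbind, g_rows)
    exons_l[[ci]] <- do.call(rbind, e_rows)
    if (is_boc)
      boc1_region <- data.frame(chrom = chroms[ci],
                                start = max(1L, boc1_bp[1]),
                                end = min(nchar(sequences[ci]), boc1_bp[2]))
  }

  genes <- do.call(rbind, genes_l)
  rownames(genes) <- NULL
  exons <- do.call(rbind, exons_l)
  rownames(exons) <- NULL

  # gene families: ~60% of non-SOC genes grouped into families of 2-5;
  # SOC genes stay species-specific (no membership)
  eligible <- which(!genes$in_soc)
  n_fam_genes <- as.integer(round(0.6 * length(eligible)))
  pool <- sample(eligible, n_fam_genes)
  fam_no <- 0L
  while (length(pool) >= 2L) {
    sz <- min(sample(2:5, 1L), length(pool))
    if (sz < 2L) break
    fam_no <- fam_no + 1L
    take <- pool[seq_len(sz)]
    genes$family_id[take] <- sprintf("FAM%04d", fam_no)
    pool <- pool[-seq_len(sz)]
  }

  # functional category / GO labels for annotated genes
  cats <- c("chromatin_assembly", "protein_transport", "signal_transduction",
            "metabolism", "photosynthesis", "gene_expression",
            "glycosyltransferase", "methyltransferase", "zinc_ion_binding",
            "unknown_domain")
  genes$category <- ifelse(genes$function_known, sample(cats, nrow(genes),
                                                        replace = TRUE),
                           NA_character_)
  genes$go_term <- ifelse(genes$function_known,
                          sprintf("GO:%07d", match(genes$category, cats)),
                          NA_character_)

  truth <- data.frame(gene_id = genes$gene_id, is_hgt = genes$is_hgt,
                      donor_group = genes$donor_group,
                      in_boc1 = genes$in_boc1, in_soc = genes$in_soc,
                      stringsAsFactors = FALSE)
  genes$is_hgt <- NULL
  genes$donor_group <- NULL

  bundle <- list(sequences = sequences, genes = genes, exons = exons,
                 truth = truth, boc1_region = boc1_region, config = cfg)
  class(bundle) <- "scan_bundle"
  bundle
}

#' @export
print.scan_bundle <- function(x, ...) {
  cat(sprintf("synthetic genome bundle: %d chromosomes, %d genes (%d planted HGT)\n",
              length(x$sequences), nrow(x$genes), sum(x$truth$is_hgt)))
  cat(sprintf("  total size %.2f Mb; BOC1 = %s:%d-%d; SOC = chr%02d\n",
              sum(nchar(x$sequences)) / 1e6,
              x$boc1_region$chrom, x$boc1_region$start, x$boc1_region$end,
              x$config$soc_chromosome))
  invisible(x)
}
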