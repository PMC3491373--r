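#' Pan- and core-genome family curves
#'
#' Walks the species in the given order and counts, at each step, the
#' families present in at least one (pan) and in all (core) of the species
#' seen so far. Pan is nondecreasing and core nonincreasing in the step;
#' the final pan count does not depend on the order.
#'
#' @param families data frame with columns family_id, species, gene_id.
#' @param species_order character vector; every label must occur in the
#'   table's species column.
#' @return data frame with columns step, species, pan, core.
#' @export
pan_core_curves <- function(families, species_order) {
  stopifnot(length(species_order) >= 2)
  unknown <- setdiff(species_order, unique(families$species))
  if (length(unknown))
    stop(sprintf("unknown species label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sets <- lapply(species_order, function(sp)
    unique(families$family_id[families$species == sp]))
  pan <- core <- integer(length(species_order))
  acc_pan <- character(0)
  acc_core <- NULL
  for (i in seq_along(sets)) {
    acc_pan <- union(acc_pan, sets[[i]])
    acc_core <- if (is.null(acc_core)) sets[[i]] else intersect(acc_core, sets[[i]])
    pan[i] <- length(acc_pan)
    core[i] <- length(acc_core)
  }
  data.frame(step = seq_along(species_order), species = species_order,
             pan = pan, core = core, stringsAsFactors = FALSE)
}

#' Mean gene-family size within a clade
#'
#' Over the core families of a clade (those present in every clade
#' species, or an explicit family set), returns the arithmetic mean of the
#' per-species copy numbers.
#'
#' @param families data frame with columns family_id, species, gene_id.
#' @param clade_species species labels forming the clade.
#' @param core_families optional explicit family ids; default is the
#'   clade's core set.
#' @return mean genes per family per species, or `NA` when the core set is
#'   empty.
#' @export
mean_family_size <- function(families, clade_species, core_families = NULL) {
  sub <- families[families$species %in% clade_species, , drop = FALSE]
  if (is.null(core_families)) {
    per_sp <- lapply(clade_species, function(sp)
      unique(sub$family_id[sub$species == sp]))
    core_families <- Reduce(intersect, per_sp)
  }
  if (length(core_families) == 0L) return(NA_real_)
  sub <- sub[sub$family_id %in% core_families, , drop = FALSE]
  copies <- table(factor(sub$family_id, levels = core_families),
                  factor(sub$species, levels = clade_species))
  mean(as.numeric(copies))
}

#' Detect expanded gene families in a focal species
#'
#' A family is flagged as expanded when its copy number in the focal
#' species reaches `min_copies` and is at least `ratio` times the maximum
#' copy number observed in any other species (zero counts in the others are
#' treated as 0.5 so that species-specific families can be flagged).
#'
#' @param copies numeric matrix, families x species, with column names.
#' @param focal focal species column name.
#' @param min_copies minimum focal copy number (default 5).
#' @param ratio minimum focal / max-other copy ratio (default 2.5).
#' @return data frame with family_id, focal_copies, max_other, expanded.
#' @export
detect_expansions <- function(copies, focal, min_copies = 5, ratio = 2.5) {
  stopifnot(is.matrix(copies), focal %in% colnames(copies),
            all(copies >= 0), all(copies == round(copies)))
  others <- copies[, setdiff(colnames(copies), focal), drop = FALSE]
  max_other <- if (ncol(others)) apply(others, 1, max) else rep(0, nrow(copies))
  denom <- ifelse(max_other == 0, 0.5, max_other)
  f <- copies[, focal]
  data.frame(family_id = rownames(copies) %||% as.character(seq_len(nrow(copies))),
             focal_copies = unname(f), max_other = unname(max_other),
             expanded = unname(f >= min_copies & f >= ratio * denom),
             stringsAsFactors = FALSE)
}

#' GO / functional-term enrichment by exact hypergeometric test
#'
#' For every term with at least one selected gene, computes the upper-tail
#' hypergeometric probability of observing at least the selected count
#' given the background, applies a Bonferroni correction over the tested
#' terms, and reports the fold enrichment (k/n)/(K/N).
#'
#' @param selected character vector of selected gene ids (a subset of the
#'   background).
#' @param background character vector of background gene ids.
#' @param term_map data frame with columns gene_id and term.
#' @param alpha Bonferroni-corrected significance threshold (default 0.05).
#' @return data frame: term, k, n, K, N, p_raw, p_bonferroni, fold,
#'   significant; sorted by p_raw. Zero rows for an empty selection.
#' @export
go_enrichment <- function(selected, background, term_map, alpha = 0.05) {
  stopifnot(all(selected %in% background))
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), fold = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(selected) == 0L) return(empty)
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(selected))
  sel_terms <- unique(tm$term[tm$gene_id %in% selected])
  if (length(sel_terms) == 0L) return(empty)
  rows <- lapply(sel_terms, function(t) {
    genes_t <- unique(tm$gene_id[tm$term == t])
    K <- length(genes_t)
    k <- length(intersect(genes_t, selected))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, n = n, K = K, N = N, p_raw = p,
               fold = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_raw, out$term),
             c("term", "k", "n", "K", "N", "p_raw", "p_bonferroni",
               "fold", "significant")]
  rownames(out) <- NULL
  out
}

#' Relative expression enrichment of functional categories in a region
#'
#' For each functional category, compares the expressed-gene fraction of
#' the region's category members against the region's overall
#' expressed-gene fraction; the region's overall expression excess over the
#' genome (the correction fold, e.g. ~1.6x for the big-outlier core) is
#' computed and reported alongside rather than inflating per-category
#' values.
#'
#' @param region_genes gene records inside the region (est_count plus a
#'   category column).
#' @param all_genes gene records of the whole genome.
#' @param category_col name of the category label column (default
#'   "category"); genes with `NA` belong to no category.
#' @return list with `table` (category, n_genes, frac_expressed,
#'   enrichment) and `correction_fold`.
#' @export
relative_expression_enrichment <- function(region_genes, all_genes,
                                           category_col = "category") {
  stopifnot(all(region_genes$gene_id %in% all_genes$gene_id))
  frac_expr <- function(g) if (nrow(g)) mean(g$est_count > 0) else NA_real_
  f_region <- frac_expr(region_genes)
  f_all <- frac_expr(all_genes)
  cats <- sort(unique(region_genes[[category_col]]))
  cats <- cats[!is.na(cats)]
  tab <- do.call(rbind, lapply(cats, function(cc) {
    sub <- region_genes[!is.na(region_genes[[category_col]]) &
                          region_genes[[category_col]] == cc, , drop = FALSE]
    data.frame(category = cc, n_genes = nrow(sub),
               frac_expressed = frac_expr(sub),
               enrichment = frac_expr(sub) / f_region,
               stringsAsFactors = FALSE)
  }))
  list(table = tab %||% data.frame(category = character(0),
                                   n_genes = integer(0),
                                   frac_expressed = numeric(0),
                                   enrichment = numeric(0)),
       region_frac_expressed = f_region,
       genome_frac_expressed = f_all,
       correction_fold = f_region / f_all)
}

#' Per-chromosome distribution of HGT genes
#'
#' Computes, per chromosome, the fraction of genes called HGT and its fold
#' over the genome-wide HGT fraction; when a BOC1 region is supplied, that
#' sub-region is reported as an extra bin (the big-outlier core and the
#' small outlier typically carry ~1.5-1.6x the genome-wide rate).
#'
#' @param calls origin-call data frame (gene_id, klass).
#' @param genes gene records (gene_id, chrom, start, end).
#' @param boc1_region optional one-row data frame (chrom, start, end).
#' @param classes klass values counted as HGT.
#' @return data frame: bin, n_genes, n_hgt, fraction, fold (fold is `NA`
#'   when there are no HGT calls at all).
#' @export
hgt_distribution <- function(calls, genes, boc1_region = NULL,
                             classes = c("hgt_eukaryote", "hgt_prokaryote")) {
  stopifnot(all(calls$gene_id %in% genes$gene_id))
  hgt_ids <- calls$gene_id[calls$klass %in% classes]
  overall <- length(hgt_ids) / nrow(genes)
  bins <- lapply(unique(genes$chrom), function(ch) {
    sub <- genes[genes$chrom == ch, , drop = FALSE]
    nh <- sum(sub$gene_id %in% hgt_ids)
    data.frame(bin = ch, n_genes = nrow(sub), n_hgt = nh,
               fraction = nh / nrow(sub), stringsAsFactors = FALSE)
  })
  if (!is.null(boc1_region)) {
    sub <- genes[genes$chrom == boc1_region$chrom &
                   genes$start >= boc1_region$start &
                   genes$end <= boc1_region$end, , drop = FALSE]
    nh <- sum(sub$gene_id %in% hgt_ids)
    bins[[length(bins) + 1L]] <-
      data.frame(bin = "BOC1", n_genes = nrow(sub), n_hgt = nh,
                 fraction = if (nrow(sub)) nh / nrow(sub) else NA_real_,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, bins)
  out$fold <- if (overall > 0) out$fraction / overall else NA_real_
  rownames(out) <- NULL
  out
}
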