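#' Simulate bootstrap-annotated gene trees with planted transfer events
#'
#' For every gene in a truth table, builds (by construction, not inference) a
#' small gene tree in which the query leaf's sister clade consists of
#' green-lineage homologs for vertically inherited genes and of homologs
#' from the planted donor group for HGT genes. The most patristically
#' distant leaf is always a non-sister outgroup clade, so rooting the tree
#' on that leaf recovers the intended sister clade. Internal-edge supports
#' are drawn from `support_fun`.
#'
#' @param truth truth table from [simulate_genome()] (columns `gene_id`,
#'   `is_hgt`, `donor_group`).
#' @param taxon_groups character vector of available taxon groups.
#' @param green_group label of the green-lineage group.
#' @param seed integer seed.
#' @param support_fun function of one integer `n` returning `n` support
#'   values in \[0, 100\]; default plants fully supported edges.
#' @return list of class `sim_trees` with `trees` (named list of `phylo`),
#'   `taxonomy` (data frame leaf_id/group), and `expected` (data frame of
#'   the origin class each planted tree should yield).
#' @export
simulate_hgt_trees <- function(truth,
                               taxon_groups = c("Viridiplantae", "Metazoa",
                                                "Stramenopiles", "Fungi",
                                                "other-Eukaryota", "Bacteria",
                                                "Archaea", "Viruses"),
                               green_group = "Viridiplantae",
                               seed = 1L,
                               support_fun = function(n) rep(100, n)) {
  stopifnot(is.data.frame(truth),
            all(c("gene_id", "is_hgt", "donor_group") %in% names(truth)))
  if (anyDuplicated(truth$gene_id))
    stop("truth table lists a gene more than once", call. = FALSE)
  bad <- !is.na(truth$donor_group) & !truth$donor_group %in% taxon_groups
  if (any(bad))
    stop(sprintf("unknown donor_group label(s): %s",
                 paste(unique(truth$donor_group[bad]), collapse = ", ")),
         call. = FALSE)
  if (any(truth$is_hgt & is.na(truth$donor_group)))
    stop("HGT genes must carry a donor_group", call. = FALSE)
  prok <- c("Bacteria", "Archaea")
  nongreen <- setdiff(taxon_groups, c(green_group, "Viruses"))

  with_seed(seed, {
    n <- nrow(truth)
    trees <- vector("list", n)
    tax_l <- vector("list", n)
    klass <- character(n)
    for (i in seq_len(n)) {
      gid <- truth$gene_id[i]
      if (truth$is_hgt[i]) {
        sis_grp <- truth$donor_group[i]
        out_grp <- green_group
        klass[i] <- if (sis_grp %in% prok) "hgt_prokaryote" else "hgt_eukaryote"
      } else {
        sis_grp <- green_group
        out_grp <- sample(nongreen, 1L)
        klass[i] <- "viridiplantae"
      }
      leaf <- function(grp, k) sprintf("%s_%s_x%d", make.names(grp), gid, k)
      s1 <- leaf(sis_grp, 1L); s2 <- leaf(sis_grp, 2L)
      o1 <- leaf(out_grp, 3L); o2 <- leaf(out_grp, 4L)
      sup <- round(support_fun(3L))
      nwk <- sprintf(
        "((%s:0.05,(%s:0.02,%s:0.025)%d:0.03)%d:0.1,(%s:0.05,%s:0.06)%d:0.6);",
        gid, s1, s2, sup[1], sup[2], o1, o2, sup[3])
      trees[[i]] <- ape::read.tree(text = nwk)
      tax_l[[i]] <- data.frame(leaf_id = c(s1, s2, o1, o2),
                               group = c(sis_grp, sis_grp, out_grp, out_grp),
                               stringsAsFactors = FALSE)
    }
    names(trees) <- truth$gene_id
    expected <- data.frame(gene_id = truth$gene_id, klass = klass,
                           donor_group = truth$donor_group,
                           stringsAsFactors = FALSE)
    out <- list(trees = trees, taxonomy = do.call(rbind, tax_l),
                expected = expected, green_group = green_group)
    class(out) <- "sim_trees"
    out
  })
}

#' Simulate a BLAST-tabular homolog hit table from gene trees
#'
#' Emulates the similarity-search step the screening stage consumes: per
#' query, every other leaf becomes one hit whose bit score decreases
#' monotonically with its patristic distance from the query leaf, a
#' self-hit row carries the maximum score, and E-values are kept below the
#' ingestion threshold.
#'
#' @param sim a `sim_trees` object (or a named list of `phylo` trees plus a
#'   `taxonomy` data frame).
#' @param seed integer seed.
#' @param coverage either a single query-coverage fraction in (0, 1\]
#'   applied to every hit, or a function of one integer returning that many
#'   coverages.
#' @return data frame with columns query_id, subject_id, bit_score,
#'   e_value, query_coverage, subject_taxon.
#' @export
simulate_hit_table <- function(sim, seed = 1L, coverage = 1) {
  trees <- if (inherits(sim, "sim_trees")) sim$trees else sim$trees
  taxonomy <- sim$taxonomy
  tax <- setNames(taxonomy$group, taxonomy$leaf_id)
  cov_fun <- if (is.function(coverage)) coverage else function(n) rep(coverage, n)
  with_seed(seed, {
    rows <- vector("list", length(trees))
    for (i in seq_along(trees)) {
      gid <- names(trees)[i]
      tr <- trees[[i]]
      if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
      d <- ape::cophenetic.phylo(tr)[gid, ]
      d <- d[names(d) != gid]
      bit <- 400 * exp(-d)
      covs <- cov_fun(length(d) + 1L)
      covs <- pmin(pmax(covs, 1e-6), 1)
      rows[[i]] <- data.frame(
        query_id = gid,
        subject_id = c(gid, names(d)),
        bit_score = round(c(500, bit), 3),
        e_value = signif(10^(-c(500, bit) / 20), 3),
        query_coverage = covs,
        subject_taxon = c("self", unname(tax[names(d)])),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
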