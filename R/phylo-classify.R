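#' Read a bootstrap-annotated gene tree with its taxonomy
#'
#' Parses a Newick tree whose internal node labels are bootstrap support
#' values (missing labels default to 0), checks that the query leaf is
#' present exactly once, and attaches a taxonomy (leaf id to top-level
#' taxon group) covering every non-query leaf.
#'
#' @param newick a Newick string or a path to a Newick file.
#' @param taxonomy either a named character vector (leaf id -> group) or a
#'   data frame with columns `leaf_id` and `group`.
#' @param query_id the query leaf label.
#' @return list of class `support_tree`: `tree` (ape `phylo` with numeric
#'   `node.label`), `taxonomy`, `query_id`.
#' @export
read_support_tree <- function(newick, taxonomy, query_id) {
  tree <- if (length(newick) == 1L && !grepl("(", newick, fixed = TRUE) &&
              file.exists(newick)) ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (is.data.frame(taxonomy))
    taxonomy <- setNames(taxonomy$group, taxonomy$leaf_id)
  nq <- sum(tree$tip.label == query_id)
  if (nq == 0L)
    stop(sprintf("query leaf '%s' absent from tree", query_id), call. = FALSE)
  if (nq > 1L)
    stop(sprintf("query leaf '%s' appears %d times", query_id, nq),
         call. = FALSE)
  others <- setdiff(tree$tip.label, query_id)
  missing <- others[!others %in% names(taxonomy)]
  if (length(missing))
    stop(sprintf("leaf/leaves without taxonomy: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  sup[is.na(sup)] <- 0
  tree$node.label <- sup
  structure(list(tree = tree, taxonomy = taxonomy[others],
                 query_id = query_id),
            class = "support_tree")
}

#' Nearest-neighbor clade of the query leaf
#'
#' Roots the tree on the leaf most patristically distant from the query
#' (outgroup-by-distance; `rooting = "midpoint"` is available as an
#' alternative) and returns the query's sister subtree under that rooting,
#' together with the bootstrap support of the edge subtending query +
#' sister. Trees without branch lengths are treated as having unit-length
#' edges. On a two-leaf tree the single other leaf is the neighbor and the
#' support is `NA`; if the query hangs off an unresolved root
#' multifurcation, all remaining leaves form the neighbor set with support
#' 0.
#'
#' @param st a `support_tree` from [read_support_tree()].
#' @param rooting `"distance"` (default; root on the leaf farthest from the
#'   query) or `"midpoint"`.
#' @return list with `leaves` (character vector of sister-clade leaf ids)
#'   and `support` (numeric in \[0, 100\] or `NA`).
#' @export
nearest_neighbor_clade <- function(st, rooting = c("distance", "midpoint")) {
  rooting <- match.arg(rooting)
  tree <- st$tree
  q <- st$query_id
  if (ape::Ntip(tree) < 2L) stop("tree has fewer than 2 leaves", call. = FALSE)
  if (ape::Ntip(tree) == 2L)
    return(list(leaves = setdiff(tree$tip.label, q), support = NA_real_))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))

  if (rooting == "distance") {
    d <- ape::cophenetic.phylo(tree)[q, ]
    d <- d[names(d) != q]
    out_leaf <- names(d)[which.max(d)]          # first index on ties
    rooted <- ape::root(tree, outgroup = out_leaf, resolve.root = TRUE,
                        edgelabel = TRUE)
  } else {
    rooted <- phytools_free_midpoint(tree)
  }
  qi <- match(q, rooted$tip.label)
  parent <- rooted$edge[rooted$edge[, 2] == qi, 1]
  # unresolved sister (query hangs off a multifurcation): every other leaf
  # is equally near, support 0
  if (sum(rooted$edge[, 1] == parent) > 2L)
    return(list(leaves = setdiff(rooted$tip.label, q), support = 0))
  sub_tips <- ape::extract.clade(rooted, parent)$tip.label
  leaves <- setdiff(sub_tips, q)
  root_node <- ape::Ntip(rooted) + 1L
  lab <- rooted$node.label
  sup <- if (parent == root_node) 0
         else suppressWarnings(as.numeric(lab[parent - ape::Ntip(rooted)]))
  if (is.na(sup)) sup <- 0
  list(leaves = leaves, support = sup)
}

# midpoint rooting without adding a hard dependency at this call site
phytools_free_midpoint <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  # root on the endpoint of the longest path farther from the tree "center"
  ape::root(tree, outgroup = rownames(d)[ij[1]], resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Taxonomic origin call for a nearest-neighbor leaf set
#'
#' Maps each neighbor leaf to its top-level taxon group and applies the
#' origin rules: all green-lineage neighbors give `viridiplantae`; all
#' neighbors from one non-green eukaryote group give `hgt_eukaryote` (with
#' that group as `donor_detail`); all Bacteria or all Archaea give
#' `hgt_prokaryote`; neighbors spanning two or more non-green groups, or
#' mixing green with non-green, form a multi-kingdom punctuate pattern and
#' are excluded from HGT calls (`multi_kingdom`). An all-virus neighbor set
#' is likewise treated as `multi_kingdom` (excluded) rather than as a
#' cellular donor.
#'
#' @param nn_leaves character vector of neighbor leaf ids (nonempty).
#' @param taxonomy named character vector, leaf id -> group.
#' @param coverage query alignment coverage fraction for the gene.
#' @param gene_id gene identifier carried into the call.
#' @param nn_support bootstrap support of the neighbor clade.
#' @param green_group label of the green-lineage group.
#' @return one-row data frame (an origin call): gene_id, klass, nn_group,
#'   nn_support, donor_detail, query_coverage, reliable (initialized FALSE;
#'   see [reliability_filter()]).
#' @export
classify_origin <- function(nn_leaves, taxonomy, coverage = NA_real_,
                            gene_id = NA_character_, nn_support = NA_real_,
                            green_group = "Viridiplantae") {
  if (length(nn_leaves) == 0L)
    stop("nearest-neighbor leaf set is empty", call. = FALSE)
  groups <- taxonomy[nn_leaves]
  if (anyNA(groups))
    stop(sprintf("unknown taxon group for leaf/leaves: %s",
                 paste(nn_leaves[is.na(groups)], collapse = ", ")),
         call. = FALSE)
  prok <- c("Bacteria", "Archaea")
  ug <- unique(unname(groups))
  klass <- if (all(ug == green_group)) {
    "viridiplantae"
  } else if (length(ug) == 1L && ug %in% prok) {
    "hgt_prokaryote"
  } else if (length(ug) == 1L && ug != "Viruses") {
    "hgt_eukaryote"
  } else {
    "multi_kingdom"
  }
  donor <- if (klass %in% c("hgt_eukaryote", "hgt_prokaryote")) ug
           else NA_character_
  data.frame(gene_id = gene_id, klass = klass,
             nn_group = if (length(ug) == 1L) ug else "mixed",
             nn_support = nn_support, donor_detail = donor,
             query_coverage = coverage, reliable = FALSE,
             stringsAsFactors = FALSE)
}

#' Flag reliable HGT calls
#'
#' A call is reliable when it is an HGT class (eukaryotic or prokaryotic
#' donor), its neighbor-clade bootstrap support exceeds
#' `support_threshold` (strictly), and its query alignment coverage is at
#' least `coverage_threshold`.
#'
#' @param calls data frame of origin calls.
#' @param support_threshold bootstrap support bound, default 90 (strict >).
#' @param coverage_threshold coverage bound, default 0.5 (inclusive >=).
#' @return `calls` with the `reliable` column set.
#' @export
reliability_filter <- function(calls, support_threshold = 90,
                               coverage_threshold = 0.5) {
  calls$reliable <- calls$klass %in% c("hgt_eukaryote", "hgt_prokaryote") &
    !is.na(calls$nn_support) & calls$nn_support > support_threshold &
    !is.na(calls$query_coverage) & calls$query_coverage >= coverage_threshold
  calls
}

#' Classify a set of gene trees
#'
#' Runs the full per-gene chain -- neighbor clade, origin class,
#' reliability flag -- over a collection of trees, pulling each gene's
#' alignment coverage from a screening result when given and passing
#' singleton / no-hit genes through with their status as the class.
#' Per-gene failures (query leaf missing, unknown taxonomy) are logged and
#' the gene is skipped.
#'
#' @param trees named list of `phylo` objects (names are gene ids, each
#'   tree contains its gene id as the query leaf), or a `sim_trees` object.
#' @param taxonomy data frame (`leaf_id`, `group`) or named vector.
#' @param screen optional data frame from [screen_hits()]; its
#'   singleton/no_hit rows are emitted as calls without a tree and its
#'   `query_coverage` feeds the reliability filter.
#' @param support_threshold,coverage_threshold see [reliability_filter()].
#' @param rooting see [nearest_neighbor_clade()].
#' @param green_group label of the green-lineage group.
#' @return data frame of origin calls, one row per gene.
#' @export
classify_trees <- function(trees, taxonomy, screen = NULL,
                           support_threshold = 90, coverage_threshold = 0.5,
                           rooting = "distance",
                           green_group = "Viridiplantae") {
  if (inherits(trees, "sim_trees")) {
    taxonomy <- trees$taxonomy
    trees <- trees$trees
  }
  if (is.data.frame(taxonomy))
    taxonomy <- setNames(taxonomy$group, taxonomy$leaf_id)
  cov <- if (!is.null(screen))
    setNames(screen$query_coverage, screen$query_id) else NULL
  status <- if (!is.null(screen))
    setNames(screen$status, screen$query_id) else NULL

  calls <- vector("list", length(trees))
  skipped <- character(0)
  for (i in seq_along(trees)) {
    gid <- names(trees)[i]
    st_status <- if (!is.null(status) && gid %in% names(status))
      status[[gid]] else "screened"
    if (st_status %in% c("singleton", "no_hit")) {
      calls[[i]] <- data.frame(gene_id = gid, klass = st_status,
                               nn_group = NA_character_,
                               nn_support = NA_real_,
                               donor_detail = NA_character_,
                               query_coverage = unname(cov[gid]),
                               reliable = FALSE, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      st <- structure(list(tree = trees[[i]],
                           taxonomy = taxonomy,
                           query_id = gid), class = "support_tree")
      if (!gid %in% st$tree$tip.label)
        stop(sprintf("query leaf '%s' absent", gid), call. = FALSE)
      nn <- nearest_neighbor_clade(st, rooting = rooting)
      cv <- if (!is.null(cov) && gid %in% names(cov)) unname(cov[gid]) else 1
      classify_origin(nn$leaves, taxonomy, coverage = cv, gene_id = gid,
                      nn_support = nn$support, green_group = green_group)
    }, error = function(e) {
      message(sprintf("classify_trees: skipping %s (%s)", gid,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, gid) else calls[[i]] <- res
  }
  # genes with screen status but no tree (no_hit / singleton without Newick)
  if (!is.null(screen)) {
    extra <- setdiff(screen$query_id[screen$status != "screened"],
                     names(trees))
    if (length(extra))
      calls <- c(calls, lapply(extra, function(g)
        data.frame(gene_id = g, klass = unname(status[g]),
                   nn_group = NA_character_, nn_support = NA_real_,
                   donor_detail = NA_character_,
                   query_coverage = unname(cov[g]), reliable = FALSE,
                   stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  rownames(out) <- NULL
  reliability_filter(out, support_threshold, coverage_threshold)
}

#' Summarize origin calls
#'
#' Tabulates calls per class and, within the HGT classes, per donor group,
#' with percentages.
#'
#' @param calls data frame of origin calls.
#' @return list with `classes` (klass, n, pct) and `donors` (donor_detail,
#'   n, pct among HGT calls; empty when there are none).
#' @export
summarize_origins <- function(calls) {
  stopifnot(nrow(calls) > 0)
  tab <- as.data.frame(table(klass = calls$klass), stringsAsFactors = FALSE)
  names(tab) <- c("klass", "n")
  tab$pct <- 100 * tab$n / sum(tab$n)
  hgt <- calls[calls$klass %in% c("hgt_eukaryote", "hgt_prokaryote"), ]
  donors <- if (nrow(hgt)) {
    dt <- as.data.frame(table(donor = hgt$donor_detail),
                        stringsAsFactors = FALSE)
    names(dt) <- c("donor_group", "n")
    dt$pct <- 100 * dt$n / sum(dt$n)
    dt
  } else data.frame(donor_group = character(0), n = integer(0),
                    pct = numeric(0))
  list(classes = tab, donors = donors)
}
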