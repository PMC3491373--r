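#' Write a synthetic bundle to disk
#'
#' Emits the bundle in standard plain-text formats: chromosome FASTA,
#' GFF3 gene/exon annotation (1-based inclusive coordinates, with
#' intron/EST counts and region tags as attributes), per-gene EST-count
#' TSV, and the truth-table TSV.
#'
#' @param bundle a `scan_bundle` from [simulate_genome()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             est = file.path(dir, "est_counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$sequences), paths["fasta"])
  write_genes_gff3(bundle$genes, bundle$exons, paths["gff"])
  write.table(bundle$genes[, c("gene_id", "est_count")], paths["est"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

write_genes_gff3 <- function(genes, exons, path) {
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id,
    intron_count = genes$intron_count, est_count = genes$est_count,
    family_id = ifelse(is.na(genes$family_id), "none", genes$family_id),
    region = ifelse(genes$in_boc1, "BOC1",
                    ifelse(genes$in_soc, "SOC", "normal")),
    function_known = ifelse(genes$function_known, "yes", "no"))
  strand <- setNames(genes$strand, genes$gene_id)
  gr_e <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    strand = unname(strand[exons$gene_id]),
    type = "exon", Parent = exons$gene_id)
  rtracklayer::export.gff3(c(gr_g, gr_e), path)
  invisible(path)
}

#' Read a gene annotation written by [write_bundle()]
#'
#' @param path GFF3 path.
#' @return data frame of gene records (the exon rows define introns; the
#'   per-gene intron count is also carried as an attribute).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gene <- gr[gr$type == "gene"]
  out <- data.frame(gene_id = gene$ID,
                    chrom = as.character(GenomicRanges::seqnames(gene)),
                    start = GenomicRanges::start(gene),
                    end = GenomicRanges::end(gene),
                    strand = as.character(GenomicRanges::strand(gene)),
                    intron_count = as.integer(gene$intron_count),
                    est_count = as.integer(gene$est_count),
                    family_id = as.character(gene$family_id),
                    stringsAsFactors = FALSE)
  out$family_id[out$family_id == "none"] <- NA_character_
  out$in_boc1 <- gene$region == "BOC1"
  out$in_soc <- gene$region == "SOC"
  out$function_known <- gene$function_known == "yes"
  out
}

#' Write gene trees and their taxonomy map
#'
#' One Newick file per gene (supports as internal node labels) plus a
#' two-column taxonomy TSV.
#'
#' @param sim a `sim_trees` object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_trees <- function(sim, dir) {
  dir.create(file.path(dir, "trees"), showWarnings = FALSE, recursive = TRUE)
  for (g in names(sim$trees))
    ape::write.tree(sim$trees[[g]], file.path(dir, "trees",
                                              paste0(g, ".nwk")))
  write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a directory of per-gene Newick trees
#'
#' @param dir directory containing `<gene_id>.nwk` files.
#' @return named list of `phylo` trees.
#' @export
read_trees <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nwk$", full.names = TRUE))
  trees <- lapply(files, ape::read.tree)
  names(trees) <- sub("\\.nwk$", "", basename(files))
  trees
}

#' Read chromosome sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
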