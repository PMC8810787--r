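#' Read extant gene orders
#'
#' Loads one or more genomes as ordered, stranded gene lists. Gene order
#' (0-based rank along each chromosome) is the primary coordinate axis of
#' the whole pipeline; physical coordinates are used only to assign ranks.
#'
#' @param path path to a tab-delimited file. For `format = "bed_like"` the
#'   file must have a header with columns `genome`, `chromosome`, `start`,
#'   `end`, `strand`, `gene_id` (`#` comment lines are ignored). For
#'   `format = "gff3"` a standard GFF3 file is read via rtracklayer and
#'   `gene`-type features are used.
#' @param format input dialect.
#' @param genome genome identifier, required for GFF3 input (a GFF3 file
#'   describes a single genome).
#' @return a `gene_orders` data.frame with columns `genome`, `chromosome`,
#'   `gene_id`, `rank`, `strand` (and `start`, `end` when present). Ranks
#'   are densified to `0..n-1` per chromosome, assigned by ascending start
#'   coordinate with ties broken by lexicographic `gene_id`.
#' @export
read_gene_orders <- function(path, format = c("bed_like", "gff3"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed_like") {
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("genome", "chromosome", "start", "end", "strand", "gene_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 input requires the rtracklayer package")
    if (is.null(genome)) stop("'genome' is required for GFF3 input")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    df <- data.frame(
      genome = genome,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = as.character(gr$ID),
      stringsAsFactors = FALSE
    )
  }
  df$gene_id <- as.character(df$gene_id)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup)[seq_len(min(5, length(unique(dup))))],
                                      collapse = ", "))
  df$strand <- normalize_strand(df$strand)
  as_gene_orders(df)
}

normalize_strand <- function(s) {
  s <- as.character(s)
  s[s == "−"] <- "-"  # unicode minus
  bad <- setdiff(unique(s), c("+", "-"))
  if (length(bad)) stop("unknown strand symbol: ", paste(bad, collapse = ", "))
  s
}

#' Construct a `gene_orders` object from a data.frame
#'
#' Assigns dense 0-based ranks per chromosome. If a `start` column is
#' present, genes are ordered by ascending start (ties by `gene_id`);
#' otherwise an existing `rank` column is used and re-densified.
#'
#' @param df data.frame with at least `genome`, `chromosome`, `gene_id`,
#'   `strand` and one of `start` / `rank`.
#' @return `gene_orders` data.frame sorted by genome, chromosome, rank.
#' @export
as_gene_orders <- function(df) {
  stopifnot(all(c("genome", "chromosome", "gene_id", "strand") %in% names(df)))
  df$genome <- as.character(df$genome)
  df$chromosome <- as.character(df$chromosome)
  df$gene_id <- as.character(df$gene_id)
  df$strand <- normalize_strand(df$strand)
  if (!is.null(df$start)) {
    o <- order(df$genome, df$chromosome, df$start, df$gene_id)
  } else if (!is.null(df$rank)) {
    o <- order(df$genome, df$chromosome, df$rank, df$gene_id)
  } else {
    stop("need a 'start' or 'rank' column to order genes")
  }
  df <- df[o, , drop = FALSE]
  key <- paste(df$genome, df$chromosome, sep = "\r")
  df$rank <- as.integer(stats::ave(seq_len(nrow(df)), key, FUN = seq_along)) - 1L
  rownames(df) <- NULL
  class(df) <- c("gene_orders", "data.frame")
  validate_gene_orders(df)
  df
}

validate_gene_orders <- function(x) {
  key <- paste(x$genome, x$chromosome, sep = "\r")
  ok <- tapply(x$rank, key, function(r) identical(sort(r), seq_along(r) - 1L))
  if (!all(unlist(ok))) stop("ranks are not dense 0..n-1 on every chromosome")
  invisible(x)
}

#' Write gene orders to a bed-like TSV
#' @param x `gene_orders` object.
#' @param path output path.
#' @export
write_gene_orders <- function(x, path) {
  if (is.null(x$start)) {
    # synthesize physical coordinates from ranks so the file round-trips
    x$start <- x$rank * 1000L
    x$end <- x$start + 500L
  }
  cols <- c("genome", "chromosome", "start", "end", "strand", "gene_id")
  utils::write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read syntenic homolog pairs
#'
#' Reads a SynMap-style homolog table. Pairs missing both Ks and similarity
#' are dropped (with a message); symmetric duplicates keep the first
#' occurrence.
#'
#' @param path TSV with header `gene_a`, `gene_b`, `ks`, `similarity`,
#'   `pair_class` (`ks`/`similarity` may be `NA`).
#' @param genomes optional `gene_orders` used to validate gene ids.
#' @param unknown_gene what to do with pairs referencing genes absent from
#'   `genomes`: drop with a warning (default) or raise an error.
#' @return `homolog_pairs` data.frame.
#' @export
read_homolog_pairs <- function(path, genomes = NULL,
                               unknown_gene = c("warn", "error")) {
  unknown_gene <- match.arg(unknown_gene)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "ks", "similarity", "pair_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  as_homolog_pairs(df, genomes = genomes, unknown_gene = unknown_gene)
}

#' @rdname read_homolog_pairs
#' @param df data.frame with the homolog-pair columns.
#' @export
as_homolog_pairs <- function(df, genomes = NULL, unknown_gene = c("warn", "error")) {
  unknown_gene <- match.arg(unknown_gene)
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$ks <- suppressWarnings(as.numeric(df$ks))
  df$similarity <- suppressWarnings(as.numeric(df$similarity))
  if (is.null(df$pair_class)) df$pair_class <- "unknown"
  df$pair_class <- as.character(df$pair_class)
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sum(self), " self-pairs dropped")
    df <- df[!self, , drop = FALSE]
  }
  both_na <- is.na(df$ks) & is.na(df$similarity)
  if (any(both_na)) {
    message(sum(both_na), " pairs dropped: both ks and similarity missing")
    df <- df[!both_na, , drop = FALSE]
  }
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b), paste(df$gene_b, df$gene_a))
  df <- df[!duplicated(key), , drop = FALSE]
  if (!is.null(genomes)) {
    known <- unique(genomes$gene_id)
    bad <- !(df$gene_a %in% known & df$gene_b %in% known)
    if (any(bad)) {
      if (unknown_gene == "error")
        stop(sum(bad), " pairs reference genes absent from the loaded genomes")
      warning(sum(bad), " pairs dropped: gene id absent from loaded genomes")
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("homolog_pairs", "data.frame")
  df
}

#' Write homolog pairs to TSV
#' @param x `homolog_pairs` object.
#' @param path output path.
#' @export
write_homolog_pairs <- function(x, path) {
  cols <- c("gene_a", "gene_b", "ks", "similarity", "pair_class")
  utils::write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted binary species tree
#'
#' Parses a newick tree. If the root is a trifurcation and `outgroup` is
#' given, the tree is rooted on the outgroup first. Any remaining
#' non-binary node is a hard error. Internal nodes without labels receive
#' labels `node<k>`.
#'
#' @param path newick file.
#' @param outgroup optional leaf label used to root a trifurcating tree.
#' @return an [ape::read.tree] `phylo` object, strictly binary.
#' @export
read_species_tree <- function(path, outgroup = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  check_species_tree(tr, outgroup)
}

#' @rdname read_species_tree
#' @param tr a `phylo` object.
#' @export
check_species_tree <- function(tr, outgroup = NULL) {
  rooted_binary <- function(x) ape::is.binary(x) && ape::is.rooted(x)
  if (!is.null(outgroup) && !rooted_binary(tr)) {
    if (!outgroup %in% tr$tip.label) stop("unknown outgroup: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in species tree")
  if (!rooted_binary(tr)) {
    deg <- tabulate(tr$edge[, 1], nbins = max(tr$edge))
    bad <- which(deg > 2)
    stop("species tree is not binary at node(s): ",
         paste(node_label(tr, bad), collapse = ", "))
  }
  nt <- length(tr$tip.label)
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  empty <- !nzchar(tr$node.label)
  tr$node.label[empty] <- paste0("node", which(empty) + nt)
  tr
}

node_label <- function(tr, node) {
  nt <- length(tr$tip.label)
  ifelse(node <= nt, tr$tip.label[node],
         if (is.null(tr$node.label)) as.character(node)
         else ifelse(nzchar(tr$node.label[node - nt]),
                     tr$node.label[node - nt], as.character(node)))
}

#' Write / read an ancestral genome table
#'
#' The ancestor TSV has one row per protogene in ancestral order:
#' `protochromosome_id`, `position`, `family_id`, `contig_id`,
#' `adjacency_support`.
#'
#' @param ancestor `ancestor_genome` data.frame.
#' @param path file path.
#' @export
write_ancestor <- function(ancestor, path) {
  cols <- c("protochromosome_id", "position", "family_id", "contig_id",
            "adjacency_support")
  utils::write.table(as.data.frame(ancestor)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ancestor
#' @export
read_ancestor <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$family_id <- as.character(df$family_id)
  df$contig_id <- as.character(df$contig_id)
  class(df) <- c("ancestor_genome", "data.frame")
  df
}

#' Write / read a chromosome painting as BED
#'
#' Half-open, 0-based gene-rank intervals with a protochromosome label in
#' the fourth column (`unpainted` for unlabeled segments).
#'
#' @param painting `painting` data.frame (columns `chromosome`, `start`,
#'   `end`, `label`).
#' @param path file path.
#' @export
write_painting <- function(painting, path) {
  df <- as.data.frame(painting)[c("chromosome", "start", "end", "label")]
  df$label[is.na(df$label)] <- "unpainted"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_painting
#' @export
read_painting <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chromosome", "start", "end", "label"))
  df$label[df$label == "unpainted"] <- NA_character_
  class(df) <- c("painting", "data.frame")
  df
}
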