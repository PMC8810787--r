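#' Syntenic-depth profile of a target genome
#'
#' Syntenic depth is the number of times a genomic region of the target is
#' syntenic to regions of another genome; its modal value reflects that
#' genome's number of subgenomes (level of ploidy) relative to the target.
#' Target chromosomes are tiled into bins of `bin` gene ranks and the depth
#' of a bin is the number of synteny blocks overlapping it; the mode is
#' taken over covered bins (depth > 0) per query genome.
#'
#' @param blocks data.frame of synteny blocks with columns `query_genome`,
#'   `query_chromosome`, `query_start`, `query_end`, `target_genome`,
#'   `target_chromosome`, `target_start`, `target_end`, `block_id`
#'   (half-open gene-rank intervals).
#' @param target genome id whose chromosomes are tiled (blocks with a
#'   different `target_genome` are ignored).
#' @param bin bin width in gene ranks (default 50); must be >= 1.
#' @param chrom_lengths optional named vector of target chromosome lengths
#'   in gene ranks; defaults to the maximal block end per chromosome.
#' @return `depth_profile`: list with `modal_depth` (named by query genome),
#'   `histogram` (depth frequency table per query genome over covered bins)
#'   and `bins` (long data.frame chromosome/bin_start/query_genome/depth).
#' @export
syntenic_depth <- function(blocks, target, bin = 50L, chrom_lengths = NULL) {
  if (bin < 1L) stop("bin width must be >= 1")
  b <- blocks[blocks$target_genome == target, , drop = FALSE]
  queries <- sort(unique(b$query_genome))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(b$target_end, b$target_chromosome, max)
  }
  bins <- list()
  for (chr in names(chrom_lengths)) {
    starts <- seq(0L, max(0L, chrom_lengths[[chr]] - 1L), by = bin)
    for (q in queries) {
      bb <- b[b$target_chromosome == chr & b$query_genome == q, , drop = FALSE]
      depth <- vapply(starts, function(s)
        sum(bb$target_start < s + bin & bb$target_end > s), 0L)
      bins[[length(bins) + 1L]] <- data.frame(
        chromosome = chr, bin_start = starts, query_genome = q,
        depth = depth, stringsAsFactors = FALSE)
    }
  }
  bins <- if (length(bins)) do.call(rbind, bins) else
    data.frame(chromosome = character(), bin_start = integer(),
               query_genome = character(), depth = integer())
  modal <- vapply(queries, function(q) {
    d <- bins$depth[bins$query_genome == q & bins$depth > 0L]
    if (!length(d)) return(0L)
    tb <- table(d)
    as.integer(names(tb)[order(-tb, as.integer(names(tb)))][1L])
  }, 0L)
  if (!length(queries)) modal <- stats::setNames(integer(0), character(0))
  hists <- lapply(stats::setNames(queries, queries), function(q)
    table(bins$depth[bins$query_genome == q & bins$depth > 0L]))
  structure(list(modal_depth = modal, histogram = hists, bins = bins,
                 target = target, bin = bin),
            class = "depth_profile")
}

#' Reciprocal syntenic-depth ratio between two genomes
#'
#' Assembles the "a:b" ploidy-ratio string: the modal depth of `genome_a`
#' blocks over `genome_b` bins (how many `genome_a` subgenomes cover each
#' `genome_b` region) versus the reciprocal. A 1x genome against a
#' genome with three subgenomes reads "1:3" seen from the polyploid side.
#'
#' @param blocks synteny blocks containing both orientations (or a
#'   symmetric set; see [make_synteny_blocks()]).
#' @param genome_a,genome_b genome ids.
#' @param bin bin width in gene ranks.
#' @return list with `ratio` (string "a:b"), `depth_a` (modal depth of a on
#'   b's bins) and `depth_b`.
#' @export
depth_ratio <- function(blocks, genome_a, genome_b, bin = 50L) {
  on_b <- syntenic_depth(blocks, target = genome_b, bin = bin)
  on_a <- syntenic_depth(blocks, target = genome_a, bin = bin)
  da <- if (genome_a %in% names(on_b$modal_depth))
    on_b$modal_depth[[genome_a]] else 0L
  db <- if (genome_b %in% names(on_a$modal_depth))
    on_a$modal_depth[[genome_b]] else 0L
  list(ratio = paste0(da, ":", db), depth_a = da, depth_b = db)
}

#' Build synteny blocks from ortholog anchors
#'
#' Chains ortholog pairs between two genomes into maximal co-linear runs:
#' anchors sharing a (query chromosome, target chromosome) combination are
#' sorted along the query and split wherever the gene-rank gap on either
#' side exceeds `max_gap`; runs with at least `min_anchors` anchors become
#' blocks, emitted in both orientations so depth can be profiled on either
#' genome.
#'
#' @param orders `gene_orders` containing both genomes.
#' @param pairs `homolog_pairs`; only rows with `pair_class == "ortholog"`
#'   linking the two genomes are used.
#' @param genome_a,genome_b genome ids.
#' @param max_gap maximal rank gap within a block (default 15).
#' @param min_anchors minimal anchors per block (default 5).
#' @return data.frame of blocks in the [syntenic_depth()] layout.
#' @export
make_synteny_blocks <- function(orders, pairs, genome_a, genome_b,
                                max_gap = 15L, min_anchors = 5L) {
  gmap <- stats::setNames(orders$genome, orders$gene_id)
  cmap <- stats::setNames(orders$chromosome, orders$gene_id)
  rmap <- stats::setNames(orders$rank, orders$gene_id)
  p <- pairs[pairs$pair_class == "ortholog", , drop = FALSE]
  ga <- gmap[p$gene_a]; gb <- gmap[p$gene_b]
  known <- !is.na(ga) & !is.na(gb)
  sel_ab <- known & ga == genome_a & gb == genome_b
  sel_ba <- known & ga == genome_b & gb == genome_a
  anchors <- rbind(
    data.frame(qg = p$gene_a[sel_ab], tg = p$gene_b[sel_ab],
               stringsAsFactors = FALSE),
    data.frame(qg = p$gene_b[sel_ba], tg = p$gene_a[sel_ba],
               stringsAsFactors = FALSE))
  if (!nrow(anchors)) {
    return(empty_blocks())
  }
  a <- data.frame(q_chr = cmap[anchors$qg], q_rank = rmap[anchors$qg],
                  t_chr = cmap[anchors$tg], t_rank = rmap[anchors$tg],
                  stringsAsFactors = FALSE)
  a <- a[order(a$q_chr, a$t_chr, a$q_rank, a$t_rank), ]
  grp <- paste(a$q_chr, a$t_chr, sep = "\r")
  out <- list()
  bid <- 0L
  for (g in unique(grp)) {
    s <- a[grp == g, , drop = FALSE]
    brk <- c(TRUE, diff(s$q_rank) > max_gap | abs(diff(s$t_rank)) > max_gap)
    run <- cumsum(brk)
    for (r in unique(run)) {
      ss <- s[run == r, , drop = FALSE]
      if (nrow(ss) < min_anchors) next
      bid <- bid + 1L
      out[[bid]] <- data.frame(
        query_genome = genome_a, query_chromosome = ss$q_chr[1L],
        query_start = min(ss$q_rank), query_end = max(ss$q_rank) + 1L,
        target_genome = genome_b, target_chromosome = ss$t_chr[1L],
        target_start = min(ss$t_rank), target_end = max(ss$t_rank) + 1L,
        block_id = sprintf("B%05d", bid), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_blocks())
  blocks <- do.call(rbind, out)
  # emit both orientations so either genome can be the depth target
  swapped <- blocks
  names(swapped) <- names(blocks)[c(5:8, 1:4, 9)]
  swapped <- swapped[names(blocks)]
  swapped$block_id <- paste0(blocks$block_id, "r")
  res <- rbind(blocks, swapped)
  rownames(res) <- NULL
  res
}

empty_blocks <- function() {
  data.frame(query_genome = character(), query_chromosome = character(),
             query_start = integer(), query_end = integer(),
             target_genome = character(), target_chromosome = character(),
             target_start = integer(), target_end = integer(),
             block_id = character(), stringsAsFactors = FALSE)
}
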