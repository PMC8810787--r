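#' Map ancestral contigs onto modern chromosomes
#'
#' Builds the contig-by-chromosome occurrence matrix: entry (contig, modern
#' chromosome) counts how many of the contig's protogene families have at
#' least one member gene on that chromosome. Row-wise proportions are kept
#' alongside the raw counts so that long and short contigs can be compared
#' by distribution rather than size.
#'
#' @param contigs `ancestral_contigs`.
#' @param genomes `gene_orders`.
#' @param families `gene_families`.
#' @return `occurrence_matrix`: list with `counts` and `proportions`
#'   (matrices, rows = contigs sorted by id, columns = `genome:chromosome`).
#' @export
map_contigs <- function(contigs, genomes, families) {
  cids <- sort(unique(contigs$contig_id))
  cols <- sort(unique(paste(genomes$genome, genomes$chromosome, sep = ":")))
  counts <- matrix(0L, nrow = length(cids), ncol = length(cols),
                   dimnames = list(cids, cols))
  if (nrow(contigs)) {
    fmap <- family_map(families, drop_oversize = FALSE)
    fam <- unname(fmap[genomes$gene_id])
    gcol <- paste(genomes$genome, genomes$chromosome, sep = ":")
    pres <- unique(data.frame(family_id = fam, col = gcol,
                              stringsAsFactors = FALSE)[!is.na(fam), ])
    m <- merge(contigs[c("contig_id", "family_id")], pres, by = "family_id")
    if (nrow(m)) {
      tb <- table(m$contig_id, m$col)
      counts[rownames(tb), colnames(tb)] <- as.integer(tb)
    }
  }
  zero <- rowSums(counts) == 0L
  if (any(zero))
    message(sum(zero), " contig(s) with zero occurrences retained as zero rows")
  props <- counts / pmax(rowSums(counts), 1L)
  structure(list(counts = counts, proportions = props),
            class = "occurrence_matrix")
}

#' Cluster contigs into protochromosomes
#'
#' Complete-linkage agglomerative clustering of the contigs' co-occurrence
#' on modern chromosomes: pairwise similarity is the Pearson correlation of
#' the row-proportion vectors, distance is 1 - correlation, and the
#' dendrogram is cut into exactly `k` clusters. Contigs with all-zero rows
#' cannot be placed and are assigned to an `NA` ("unplaced") bucket.
#'
#' @param occ `occurrence_matrix` from [map_contigs()].
#' @param k number of protochromosomes (default 7, the ancestral eudicot
#'   karyotype). `k` is a user parameter, never auto-selected.
#' @return `proto_assignment` data.frame: `contig_id`,
#'   `protochromosome_id` (integer 1..k, `NA` for unplaced), plus the
#'   `hclust` object in attribute `linkage`.
#' @export
cluster_contigs <- function(occ, k = 7L) {
  counts <- occ$counts
  nz <- rownames(counts)[rowSums(counts) > 0L]
  if (k < 1L || k > length(nz))
    stop("k must be between 1 and the number of contigs with nonzero rows (",
         length(nz), ")")
  nz <- sort(nz)
  p <- occ$proportions[nz, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(p)))
  # constant rows have undefined correlation: identical rows are perfectly
  # similar, anything else maximally distant
  if (anyNA(cc)) {
    for (i in which(apply(p, 1, stats::sd) == 0)) {
      same <- apply(p, 1, function(r) isTRUE(all.equal(r, p[i, ])))
      cc[i, ] <- ifelse(same, 1, -1)
      cc[, i] <- cc[i, ]
    }
  }
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, k = k)
  # deterministic protochromosome numbering: by first contig id in cluster
  first <- tapply(names(cl), cl, min)
  relab <- stats::setNames(rank(first), names(first))
  proto <- as.integer(relab[as.character(cl)])
  res <- data.frame(contig_id = rownames(counts),
                    protochromosome_id = proto[match(rownames(counts), nz)],
                    stringsAsFactors = FALSE)
  res <- res[order(res$contig_id), ]
  rownames(res) <- NULL
  structure(res, class = c("proto_assignment", "data.frame"), linkage = hc)
}

#' Order contigs within protochromosomes against a reference genome
#'
#' For each protochromosome, the best-matching reference chromosome is the
#' one carrying the most member genes of the protochromosome's families;
#' member contigs are then ordered by the median reference rank of their
#' families' gene copies on that chromosome (ties by contig id). Contigs
#' with no gene on the best-matching chromosome are placed last.
#'
#' @param assignment `proto_assignment` from [cluster_contigs()].
#' @param contigs `ancestral_contigs`.
#' @param genomes `gene_orders`.
#' @param families `gene_families`.
#' @param reference_genome genome id used for ordering.
#' @return `ancestor_genome` data.frame: `protochromosome_id`, `position`,
#'   `family_id`, `contig_id`, `adjacency_support` (the matched weight of
#'   the join to the next protogene within the same contig).
#' @export
order_within <- function(assignment, contigs, genomes, families,
                         reference_genome) {
  ref <- genomes[genomes$genome == reference_genome, , drop = FALSE]
  if (!nrow(ref)) stop("reference genome not loaded: ", reference_genome)
  fmap <- family_map(families, drop_oversize = FALSE)
  ref_fam <- unname(fmap[ref$gene_id])
  placed <- assignment[!is.na(assignment$protochromosome_id), , drop = FALSE]
  out <- list()
  for (pc in sort(unique(placed$protochromosome_id))) {
    cids <- placed$contig_id[placed$protochromosome_id == pc]
    fams_pc <- contigs$family_id[contigs$contig_id %in% cids]
    hits <- ref$chromosome[!is.na(ref_fam) & ref_fam %in% fams_pc]
    if (!length(hits)) {
      best_chr <- NA_character_
    } else {
      tb <- table(hits)
      best_chr <- names(tb)[order(-tb, names(tb))][1L]
    }
    med <- vapply(cids, function(cid) {
      cf <- contigs$family_id[contigs$contig_id == cid]
      r <- ref$rank[ref$chromosome %in% best_chr & !is.na(ref_fam) &
                      ref_fam %in% cf]
      if (!length(r)) Inf else stats::median(r)
    }, 0)
    if (any(!is.finite(med)))
      message(sum(!is.finite(med)), " contig(s) without reference hits placed ",
              "last on protochromosome ", pc)
    cids <- cids[order(med, cids)]
    rows <- do.call(rbind, lapply(cids, function(cid) {
      ii <- which(contigs$contig_id == cid)
      data.frame(protochromosome_id = pc,
                 family_id = contigs$family_id[ii],
                 contig_id = cid,
                 adjacency_support = contigs$join_weight[ii],
                 stringsAsFactors = FALSE)
    }))
    rows$position <- seq_len(nrow(rows)) - 1L
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  res <- res[c("protochromosome_id", "position", "family_id", "contig_id",
               "adjacency_support")]
  rownames(res) <- NULL
  class(res) <- c("ancestor_genome", "data.frame")
  res
}

#' Assemble protochromosomes from contigs
#'
#' Convenience wrapper: [map_contigs()] + [cluster_contigs()] +
#' [order_within()].
#'
#' @inheritParams order_within
#' @inheritParams cluster_contigs
#' @return `ancestor_genome` (see [order_within()]), with the
#'   `proto_assignment` in attribute `assignment`.
#' @export
assemble_protochromosomes <- function(contigs, genomes, families, k = 7L,
                                      reference_genome) {
  occ <- map_contigs(contigs, genomes, families)
  assignment <- cluster_contigs(occ, k = k)
  anc <- order_within(assignment, contigs, genomes, families, reference_genome)
  attr(anc, "assignment") <- assignment
  anc
}
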