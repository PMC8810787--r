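#' Build disjoint gene families from homolog pairs
#'
#' Families are the connected components of the homology graph: a gene that
#' is homologous (orthologous or paralogous) to any member of a family
#' belongs to that family. Families whose copy number in any single genome
#' exceeds `max_copies_per_genome` are flagged oversize and excluded from
#' ancestral inference (they are retained for reporting).
#'
#' @param pairs `homolog_pairs` data.frame.
#' @param genomes `gene_orders` for the genomes the pairs refer to; needed
#'   for per-genome copy counts. Genes absent from `genomes` do not count
#'   toward any genome.
#' @param max_copies_per_genome copy-number ceiling per genome (default 5,
#'   enough for lineages with two rounds of whole-genome duplication).
#' @return a `gene_families` object: list with `membership` (data.frame
#'   `gene_id`, `family_id`), `families` (data.frame `family_id`, `n_genes`,
#'   `oversize`) and the ceiling used. Family ids are the lexicographically
#'   smallest member gene id, so they are deterministic.
#' @export
build_families <- function(pairs, genomes = NULL, max_copies_per_genome = 5L) {
  if (nrow(pairs) == 0L) {
    return(structure(list(
      membership = data.frame(gene_id = character(), family_id = character(),
                              stringsAsFactors = FALSE),
      families = data.frame(family_id = character(), n_genes = integer(),
                            oversize = logical(), stringsAsFactors = FALSE),
      max_copies_per_genome = max_copies_per_genome
    ), class = "gene_families"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$gene_a, to = pairs$gene_b,
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  memb <- igraph::components(g)$membership
  genes <- names(memb)
  fam_min <- tapply(genes, memb, min)
  family_id <- unname(fam_min[as.character(memb)])
  membership <- data.frame(gene_id = genes, family_id = family_id,
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$family_id, membership$gene_id), ]
  rownames(membership) <- NULL

  fam_sizes <- table(membership$family_id)
  oversize <- rep(FALSE, length(fam_sizes))
  names(oversize) <- names(fam_sizes)
  if (!is.null(genomes)) {
    gmap <- stats::setNames(genomes$genome, genomes$gene_id)
    known <- membership$gene_id %in% names(gmap)
    if (any(known)) {
      cc <- table(membership$family_id[known], gmap[membership$gene_id[known]])
      over_fams <- rownames(cc)[apply(cc, 1, max) > max_copies_per_genome]
      oversize[over_fams] <- TRUE
    }
  }
  families <- data.frame(family_id = names(fam_sizes),
                         n_genes = as.integer(fam_sizes),
                         oversize = unname(oversize),
                         stringsAsFactors = FALSE)
  families <- families[order(families$family_id), ]
  rownames(families) <- NULL
  structure(list(membership = membership, families = families,
                 max_copies_per_genome = max_copies_per_genome),
            class = "gene_families")
}

#' @export
print.gene_families <- function(x, ...) {
  cat("gene_families:", nrow(x$families), "families,",
      nrow(x$membership), "genes,",
      sum(x$families$oversize), "oversize\n")
  invisible(x)
}

#' Gene-to-family lookup vector
#'
#' @param families `gene_families` object.
#' @param drop_oversize if `TRUE` (default) members of oversize families map
#'   to `NA`, excluding them from ancestral inference.
#' @return named character vector gene_id -> family_id.
#' @export
family_map <- function(families, drop_oversize = TRUE) {
  m <- stats::setNames(families$membership$family_id,
                       families$membership$gene_id)
  if (drop_oversize && any(families$families$oversize)) {
    bad <- families$families$family_id[families$families$oversize]
    m[m %in% bad] <- NA_character_
  }
  m
}

#' Extract window-based generalized adjacencies from a genome
#'
#' For every pair of genes on the same chromosome at gene-rank distance at
#' most `w - 1`, emits one adjacency joining the two *facing* ends: the end
#' of the left gene pointing right and the end of the right gene pointing
#' left, resolved by strand (side 0 = 5'-most, 1 = 3'-most in each gene's
#' own reading orientation). These are the ends that would fuse if the
#' intervening genes were lost, which makes the adjacency robust to
#' post-polyploid fractionation and to inversions with breakpoints inside
#' the window. With `w = 2` this reduces to the classical immediate-neighbor
#' adjacency set.
#'
#' Pairs whose genes lack a family assignment or belong to an oversize
#' family are skipped. Same-family (tandem) pairs break matching semantics
#' and are excluded unless `include_tandem = TRUE`, in which case they are
#' emitted flagged `tandem = TRUE` for reporting only (downstream candidate
#' collection still ignores them).
#'
#' @param genomes `gene_orders` (one or more genomes).
#' @param families `gene_families` from [build_families()].
#' @param w window size in consecutive genes (default 7); must be >= 2.
#' @param include_tandem emit same-family pairs flagged as tandem.
#' @return data.frame with columns `genome`, `chromosome`, `gene_a`,
#'   `gene_b`, `family_a`, `family_b`, `side_a`, `side_b`, `distance`,
#'   `tandem`; one row per unordered gene pair.
#' @export
extract_generalized_adjacencies <- function(genomes, families, w = 7L,
                                            include_tandem = FALSE) {
  if (w < 2L) stop("window size w must be >= 2")
  fmap <- family_map(families)
  g <- genomes[order(genomes$genome, genomes$chromosome, genomes$rank), ]
  fam <- unname(fmap[g$gene_id])
  key <- paste(g$genome, g$chromosome, sep = "\r")
  idx <- split(seq_len(nrow(g)), key)
  out <- vector("list", length(idx) * (w - 1L))
  k <- 0L
  for (ii in idx) {
    n <- length(ii)
    for (d in seq_len(w - 1L)) {
      if (n <= d) break
      i <- ii[seq_len(n - d)]
      j <- ii[seq_len(n - d) + d]
      keep <- !is.na(fam[i]) & !is.na(fam[j])
      if (!include_tandem) keep <- keep & fam[i] != fam[j]
      keep <- keep & (fam[i] != fam[j] | g$gene_id[i] != g$gene_id[j])
      if (!any(keep)) next
      i <- i[keep]; j <- j[keep]
      k <- k + 1L
      out[[k]] <- data.frame(
        genome = g$genome[i],
        chromosome = g$chromosome[i],
        gene_a = g$gene_id[i],
        gene_b = g$gene_id[j],
        family_a = fam[i],
        family_b = fam[j],
        side_a = ifelse(g$strand[i] == "+", 1L, 0L),
        side_b = ifelse(g$strand[j] == "+", 0L, 1L),
        distance = d,
        tandem = fam[i] == fam[j],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else data.frame(
    genome = character(), chromosome = character(), gene_a = character(),
    gene_b = character(), family_a = character(), family_b = character(),
    side_a = integer(), side_b = integer(), distance = integer(),
    tandem = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("observed_adjacencies", "data.frame")
  res
}
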