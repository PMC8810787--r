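#' Run the full reconstruction pipeline
#'
#' Orchestrates the stages -- families, adjacencies, ancestor
#' reconstruction (per ancestor node), protochromosome assembly, painting,
#' choppiness, syntenic depth and the topology scan -- into one reproducible
#' run. Every stage reads and writes plain files under `out_dir`, a
#' manifest records the package version, the fully resolved configuration
#' and input checksums, and re-running on identical inputs reproduces
#' identical outputs (no stage uses the RNG).
#'
#' @param config a named list:
#' \describe{
#'   \item{gene_orders}{path to a bed-like gene-order TSV (or a
#'     `gene_orders` object).}
#'   \item{homolog_pairs}{path to a homolog-pair TSV (or object).}
#'   \item{tree}{path to a newick species tree (or `phylo`).}
#'   \item{ancestors}{character vector of internal node labels to
#'     reconstruct.}
#'   \item{paint_genomes}{genomes to paint (default: all leaves).}
#'   \item{reference_genome}{reference for contig ordering (default: first
#'     painted genome).}
#'   \item{w}{adjacency window, default 7.}
#'   \item{max_copies_per_genome}{family copy ceiling, default 5.}
#'   \item{k}{protochromosome count, default 7.}
#'   \item{min_segment, smooth_window}{painting parameters (5, 1).}
#'   \item{depth_bin}{syntenic-depth bin width, default 50.}
#'   \item{treescan_axis}{"ks" or "similarity", default "ks".}
#'   \item{out_dir}{output directory.}
#' }
#' @return (invisibly) the output directory; side effect: stage outputs and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(w = 7L, max_copies_per_genome = 5L, k = 7L,
                   min_segment = 5L, smooth_window = 1L, depth_bin = 50L,
                   treescan_axis = "ks", paint_genomes = NULL,
                   reference_genome = NULL, ancestors = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  checksums <- list()
  load_input <- function(x, reader, what) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("missing ", what, " input: ", x)
      checksums[[what]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }

  orders <- stage("load", load_input(config$gene_orders, read_gene_orders,
                                     "gene_orders"))
  pairs <- load_input(config$homolog_pairs,
                      function(p) read_homolog_pairs(p, genomes = orders),
                      "homolog_pairs")
  tree <- tryCatch(
    load_input(config$tree, read_species_tree, "tree"),
    error = function(e)
      stop("stage 'reconstruct' failed: ", conditionMessage(e), call. = FALSE))
  if (is.null(config$ancestors))
    stop("stage 'reconstruct' failed: no ancestor nodes given")
  if (is.null(config$paint_genomes))
    config$paint_genomes <- sort(unique(orders$genome))
  if (is.null(config$reference_genome))
    config$reference_genome <- config$paint_genomes[1L]

  out <- function(...) file.path(config$out_dir, ...)
  stages_run <- character(0)

  families <- stage("families", build_families(
    pairs, genomes = orders,
    max_copies_per_genome = config$max_copies_per_genome))
  utils::write.table(families$membership, out("families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stages_run <- c(stages_run, "families")

  adj <- stage("adjacencies", extract_generalized_adjacencies(
    orders, families, w = config$w))
  utils::write.table(adj, out("adjacencies.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stages_run <- c(stages_run, "adjacencies")

  ancestors <- list()
  for (anc in config$ancestors) {
    contigs <- stage(paste0("reconstruct:", anc), reconstruct_ancestor(
      orders, families, tree, anc, w = config$w, adjacencies = adj))
    ancestor <- stage(paste0("assemble:", anc), assemble_protochromosomes(
      contigs, orders, families, k = config$k,
      reference_genome = config$reference_genome))
    write_ancestor(ancestor, out(paste0("ancestor_", anc, ".tsv")))
    ancestors[[anc]] <- ancestor
  }
  stages_run <- c(stages_run, "reconstruct", "assemble")

  choppiness <- list()
  for (anc in names(ancestors)) {
    for (g in config$paint_genomes) {
      p <- stage(paste0("paint:", g, ":", anc), paint(
        orders, ancestors[[anc]], families, genome_id = g,
        min_segment = config$min_segment,
        smooth_window = config$smooth_window))
      write_painting(p, out(paste0("painting_", g, "_", anc, ".bed")))
      ex <- count_exchanges(p)
      choppiness[[length(choppiness) + 1L]] <- data.frame(
        genome = g, ancestor = anc, exchanges = ex$total,
        stringsAsFactors = FALSE)
    }
  }
  stages_run <- c(stages_run, "paint", "choppiness")
  utils::write.table(do.call(rbind, choppiness), out("choppiness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  depth_rows <- list()
  gset <- sort(unique(orders$genome))
  for (i in seq_along(gset)) for (j in seq_along(gset)) {
    if (i >= j) next
    blocks <- make_synteny_blocks(orders, pairs, gset[i], gset[j])
    if (!nrow(blocks)) next
    dr <- depth_ratio(blocks, gset[i], gset[j], bin = config$depth_bin)
    depth_rows[[length(depth_rows) + 1L]] <- data.frame(
      genome_a = gset[i], genome_b = gset[j], ratio = dr$ratio,
      depth_a = dr$depth_a, depth_b = dr$depth_b, stringsAsFactors = FALSE)
  }
  stage("depth", utils::write.table(do.call(rbind, depth_rows),
                                    out("syntenic_depth.tsv"), sep = "\t",
                                    quote = FALSE, row.names = FALSE))
  stages_run <- c(stages_run, "depth")

  verdicts <- stage("treescan", pipeline_treescan(
    orders, pairs, axis = config$treescan_axis))
  if (!is.null(verdicts))
    utils::write.table(verdicts, out("treescan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  stages_run <- c(stages_run, "treescan")

  manifest <- list(
    tool = "protochrom",
    version = as.character(utils::packageVersion("protochrom")),
    stages = stages_run,
    config = config[setdiff(names(config), c("gene_orders", "homolog_pairs",
                                             "tree"))],
    input_md5 = checksums
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}

# per-genome-pair ortholog peak sets feeding the topology scan; NULL when
# fewer than 3 genomes or insufficient pairs
pipeline_treescan <- function(orders, pairs, axis = "ks", min_values = 30L) {
  gmap <- stats::setNames(orders$genome, orders$gene_id)
  ga <- gmap[pairs$gene_a]
  gb <- gmap[pairs$gene_b]
  ok <- !is.na(ga) & !is.na(gb) & ga != gb & pairs$pair_class == "ortholog"
  val <- if (axis == "ks") pairs$ks else pairs$similarity
  ok <- ok & !is.na(val)
  key <- paste(pmin(ga[ok], gb[ok]), pmax(ga[ok], gb[ok]), sep = "|")
  leaves <- sort(unique(c(ga[ok], gb[ok])))
  if (length(leaves) < 3L || length(leaves) > 8L) return(NULL)
  need <- apply(utils::combn(leaves, 2L), 2L, paste, collapse = "|")
  vals <- split(val[ok], key)
  if (!all(need %in% names(vals)) ||
      any(vapply(vals[need], length, 0L) < min_values)) return(NULL)
  pair_peaks <- lapply(vals[need], estimate_peaks, axis = axis)
  trees_in_peaks(pair_peaks, axis = axis, leaves = leaves)
}
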