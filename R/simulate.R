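#' Configuration for the genome-evolution simulator
#'
#' Describes a study design: an ancestral karyotype, a species tree with
#' branch lengths in Ks units, and a per-branch event schedule. Branch
#' lengths double as divergence Ks (strict molecular clock, no rate
#' variation), so peak positions of simulated Ks distributions sit at known
#' node depths.
#'
#' @param tree rooted binary `phylo` with branch lengths and node labels
#'   (or a newick string).
#' @param events named list (by branch, keyed on the child node/tip label)
#'   of event schedules; each entry may set `wgd` (number of whole-genome
#'   doublings), `addition` (number of single-subgenome additions -- the
#'   second step of a two-step hexaploidy, where a third genome is donated
#'   to the initial tetraploid), `fractionation` (per-branch deletion
#'   probability for each duplicate-copy gene born of the branch's
#'   WGD/addition events; the resident copy is not at risk),
#'   `inversions`, `translocations` (reciprocal terminal-segment swaps),
#'   `fusions`, `fissions` (event counts). Unset fields default to 0.
#' @param n_chromosomes ancestral chromosome number (default 7).
#' @param genes_per_chromosome genes per ancestral chromosome (default 150).
#' @param ks_sigma standard deviation of the Gaussian Ks noise (default
#'   0.05), truncated at 0.
#' @param inv_len inversion length range in genes (default 2..15, uniform).
#' @param seed RNG seed (mandatory).
#' @return `evolution_config` list.
#' @export
new_evolution_config <- function(tree, events = list(), n_chromosomes = 7L,
                                 genes_per_chromosome = 150L,
                                 ks_sigma = 0.05, inv_len = c(2L, 15L),
                                 seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- check_species_tree(tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths (Ks units)")
  labels <- c(tree$tip.label, tree$node.label)
  for (nm in names(events)) {
    if (!nm %in% labels) stop("event schedule names unknown branch: ", nm)
    bad <- setdiff(names(events[[nm]]),
                   c("wgd", "addition", "fractionation", "inversions",
                     "translocations", "fusions", "fissions"))
    if (length(bad)) stop("unknown event field(s): ", paste(bad, collapse = ", "))
    p <- events[[nm]]$fractionation
    if (!is.null(p) && (p < 0 || p > 1)) stop("fractionation must be in [0,1]")
  }
  structure(list(tree = tree, events = events,
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 ks_sigma = ks_sigma, inv_len = as.integer(inv_len),
                 seed = as.integer(seed)),
            class = "evolution_config")
}

branch_events <- function(config, label) {
  e <- config$events[[label]]
  defaults <- list(wgd = 0L, addition = 0L, fractionation = 0,
                   inversions = 0L, translocations = 0L,
                   fusions = 0L, fissions = 0L)
  for (nm in names(e)) defaults[[nm]] <- e[[nm]]
  defaults
}

#' Eudicot-like preset study design
#'
#' A six-leaf clock tree shaped like (Ranunculales-like, (Proteales-like,
#' ((Buxus-like, Tetracentron-like), (coreA, coreB)))) carrying the
#' inferred early-eudicot event map: one WGD on the Buxus-like branch, two
#' successive WGDs on the Tetracentron-like branch, and a two-step
#' hexaploidy (WGD then donation of a third subgenome) on the core stem.
#' Light fractionation (0.1 per duplicated gene per branch below each
#' polyploidy) leaves modal copy numbers of 2 (Buxus-like), 4
#' (Tetracentron-like) and 3 (core leaves), matching the 2:3 / 4:3 / 4:2
#' reciprocal syntenic depths of the corresponding real genomes. Every
#' branch carries 2 inversions and 1 reciprocal translocation.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [new_evolution_config()]
#'   (`n_chromosomes`, `genes_per_chromosome`, `ks_sigma`, `inv_len`).
#' @return `evolution_config`.
#' @export
preset_eudicot <- function(seed, ...) {
  nwk <- paste0("(ran:1.4,(pro:1.15,((bux:0.6,tet:0.6)n4:0.3,",
                "(coreA:0.5,coreB:0.5)n5:0.4)n3:0.25)n2:0.25)n1;")
  base <- list(inversions = 2L, translocations = 1L)
  ev <- list(
    ran = base, pro = base, n2 = base, n3 = base, n4 = base,
    bux = c(base, list(wgd = 1L, fractionation = 0.1)),
    tet = c(base, list(wgd = 2L, fractionation = 0.1)),
    n5 = c(base, list(wgd = 1L, addition = 1L, fractionation = 0.1)),
    coreA = c(base, list(fractionation = 0.1)),
    coreB = c(base, list(fractionation = 0.1))
  )
  new_evolution_config(nwk, events = ev, seed = seed, ...)
}

# ---- internal genome state -------------------------------------------------
# genome: list of chromosomes; chromosome: list(genes = int ids, strand = +-1)
# registry (environment): parent, depth, event, family vectors indexed by id

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$parent <- integer(0)
  reg$depth <- numeric(0)
  reg$event <- character(0)
  reg$family <- integer(0)
  reg$dup <- logical(0)   # born as a duplicate copy on the current branch
  reg
}

new_genes <- function(reg, parents, event, depth, family = NULL,
                      dup = FALSE) {
  n <- length(parents)
  ids <- length(reg$parent) + seq_len(n)
  reg$parent <- c(reg$parent, parents)
  reg$depth <- c(reg$depth, rep(depth, n))
  reg$event <- c(reg$event, rep(event, n))
  reg$family <- c(reg$family, if (is.null(family)) reg$family[parents]
                  else family)
  reg$dup <- c(reg$dup, rep(dup, length.out = n))
  ids
}

# dup: "reset" (speciation: a fresh branch carries no at-risk copies),
# "inherit" (a relabeled duplicate stays at risk within its branch) or
# "set" (the new copies of a polyploidy event)
relabel_genome <- function(genome, reg, event, depth, dup = "reset") {
  lapply(genome, function(ch) {
    flag <- switch(dup, reset = FALSE, set = TRUE,
                   inherit = reg$dup[ch$genes])
    list(genes = new_genes(reg, ch$genes, event, depth, dup = flag),
         strand = ch$strand)
  })
}

apply_wgd <- function(genome, reg, depth, event = "wgd") {
  a <- relabel_genome(genome, reg, event, depth, dup = "inherit")
  b <- relabel_genome(genome, reg, event, depth, dup = "set")
  c(a, b)
}

apply_addition <- function(genome, reg, depth) {
  # donation of one extra subgenome (the second step of a two-step
  # hexaploidy): one chromosome copy per family is duplicated. All resident
  # genes are relabeled too so that ancestry paths stay genome-wide and
  # donated/resident copies diverge exactly at this event's depth.
  a <- relabel_genome(genome, reg, "addition", depth, dup = "inherit")
  covered <- integer(0)
  pick <- integer(0)
  for (ci in seq_along(genome)) {
    fams <- reg$family[genome[[ci]]$genes]
    if (!any(fams %in% covered)) {
      pick <- c(pick, ci)
      covered <- c(covered, fams)
    }
  }
  donated <- relabel_genome(genome[pick], reg, "addition", depth, dup = "set")
  c(a, donated)
}

apply_deletions <- function(genome, del_ids) {
  genome <- lapply(genome, function(ch) {
    keep <- !(ch$genes %in% del_ids)
    list(genes = ch$genes[keep], strand = ch$strand[keep])
  })
  genome[vapply(genome, function(ch) length(ch$genes) > 0L, TRUE)]
}

apply_inversion <- function(genome, chrom, start, len) {
  ch <- genome[[chrom]]
  idx <- start:(start + len - 1L)
  ch$genes[idx] <- rev(ch$genes[idx])
  ch$strand[idx] <- -rev(ch$strand[idx])
  genome[[chrom]] <- ch
  genome
}

apply_translocation <- function(genome, ca, cb, ba, bb) {
  A <- genome[[ca]]; B <- genome[[cb]]
  la <- length(A$genes); lb <- length(B$genes)
  newA <- list(genes = c(A$genes[seq_len(ba)], B$genes[(bb + 1L):lb]),
               strand = c(A$strand[seq_len(ba)], B$strand[(bb + 1L):lb]))
  newB <- list(genes = c(B$genes[seq_len(bb)], A$genes[(ba + 1L):la]),
               strand = c(B$strand[seq_len(bb)], A$strand[(ba + 1L):la]))
  genome[[ca]] <- newA
  genome[[cb]] <- newB
  genome
}

apply_fusion <- function(genome, ca, cb) {
  genome[[ca]] <- list(genes = c(genome[[ca]]$genes, genome[[cb]]$genes),
                       strand = c(genome[[ca]]$strand, genome[[cb]]$strand))
  genome[-cb]
}

apply_fission <- function(genome, chrom, pos) {
  ch <- genome[[chrom]]
  n <- length(ch$genes)
  left <- list(genes = ch$genes[seq_len(pos)], strand = ch$strand[seq_len(pos)])
  right <- list(genes = ch$genes[(pos + 1L):n], strand = ch$strand[(pos + 1L):n])
  genome[[chrom]] <- left
  c(genome, list(right))
}

gene_id_str <- function(i) sprintf("g%07d", i)
family_id_str <- function(i) sprintf("F%05d", i)

# ---- simulation ------------------------------------------------------------

#' Simulate genome evolution along a species tree
#'
#' Starting from an ancestral genome of `n_chromosomes` x
#' `genes_per_chromosome` unique single-copy genes, evolves a genome down
#' every branch of the species tree applying, in order: whole-genome
#' duplications / subgenome additions (all gene copies are relabeled at the
#' event so divergence bookkeeping stays exact), one round of fractionation
#' (each duplicate-copy gene created by the branch's polyploidies deleted
#' independently with the branch's probability), inversions, reciprocal
#' translocations, fusions
#' and fissions. Translocation breakpoints are rejection-sampled to fall
#' inside single-origin territory on both chromosomes and to join two
#' different ancestral origins, so every translocation creates exactly two
#' painted boundaries. Ortholog and paralog pairs are emitted with
#' clock-like Ks (sum of branch lengths through the divergence point, plus
#' truncated Gaussian noise) and similarity `100 * exp(-ks)`.
#'
#' @param config `evolution_config` from [new_evolution_config()] or
#'   [preset_eudicot()].
#' @return `genome_simulation`: list with `orders` (`gene_orders` over all
#'   leaves), `pairs` (`homolog_pairs`), `tree`, `config` and `truth`
#'   (node snapshots, true family map, family origins, event log, true
#'   divergence table).
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  set.seed(config$seed)
  sim_walk(config, replay_log = NULL)
}

#' Replay a recorded event log
#'
#' Re-applies the realized events of a previous simulation (same breakpoints,
#' same deletions) without touching the RNG; the leaf genomes must be
#' reproduced exactly.
#'
#' @param config the original `evolution_config`.
#' @param event_log the `truth$event_log` of a [simulate_evolution()] run.
#' @return `genome_simulation` (Ks noise is re-used from the log's pair
#'   table, so `orders` and `truth` match the original run).
#' @export
replay_events <- function(config, event_log) {
  sim_walk(config, replay_log = event_log)
}

sim_walk <- function(config, replay_log = NULL) {
  tree <- config$tree
  nt <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  reg <- new_registry()
  sampling <- is.null(replay_log)
  log <- if (sampling) list() else replay_log
  log_i <- 0L

  record <- function(entry) {
    if (sampling) log[[length(log) + 1L]] <<- entry
    entry
  }
  next_logged <- function() {
    log_i <<- log_i + 1L
    log[[log_i]]
  }

  # ancestral genome
  root_genome <- lapply(seq_len(config$n_chromosomes), function(i) {
    ids <- new_genes(reg, parents = rep(0L, config$genes_per_chromosome),
                     event = "root", depth = 0,
                     family = (i - 1L) * config$genes_per_chromosome +
                       seq_len(config$genes_per_chromosome))
    list(genes = ids, strand = rep(1L, config$genes_per_chromosome))
  })
  fam_origin <- rep(seq_len(config$n_chromosomes),
                    each = config$genes_per_chromosome)

  snapshots <- list()
  leaves <- list()
  root <- nt + 1L
  snapshots[[node_label(tree, root)]] <- root_genome

  origin_of <- function(ch, i) fam_origin[reg$family[ch$genes[i]]]

  run_branch <- function(genome, child) {
    lab <- node_label(tree, child)
    parent <- tree$edge[tree$edge[, 2] == child, 1]
    d0 <- depths[parent]
    d1 <- depths[child]
    ev <- branch_events(config, lab)
    genome <- relabel_genome(genome, reg, "speciation", d0)

    big <- c(rep("wgd", ev$wgd), rep("addition", ev$addition))
    for (i in seq_along(big)) {
      entry <- if (sampling) {
        record(list(type = big[i], branch = lab,
                    depth = d0 + (d1 - d0) * i / (length(big) + 1L)))
      } else next_logged()
      genome <- if (entry$type == "wgd") apply_wgd(genome, reg, entry$depth)
                else apply_addition(genome, reg, entry$depth)
    }

    if (ev$fractionation > 0) {
      if (sampling) {
        all_genes <- unlist(lapply(genome, `[[`, "genes"))
        eligible <- all_genes[reg$dup[all_genes]]
        del <- eligible[stats::runif(length(eligible)) < ev$fractionation]
        entry <- record(list(type = "fractionation", branch = lab,
                             p = ev$fractionation, deleted = del))
      } else entry <- next_logged()
      if (length(entry$deleted)) {
        lost <- setdiff(unique(reg$family[entry$deleted]),
                        unique(reg$family[unlist(lapply(
                          apply_deletions(genome, entry$deleted),
                          `[[`, "genes"))]))
        if (length(lost))
          message(length(lost), " family(ies) entirely lost on branch ", lab)
        genome <- apply_deletions(genome, entry$deleted)
      }
    }

    for (i in seq_len(ev$inversions)) {
      lens <- vapply(genome, function(ch) length(ch$genes), 0L)
      ok <- which(lens >= 2L)
      if (!length(ok)) break
      if (sampling) {
        chrom <- ok[sample.int(length(ok), 1L, prob = lens[ok])]
        L <- min(lens[chrom],
                 max(2L, sample(config$inv_len[1]:config$inv_len[2], 1L)))
        start <- sample.int(lens[chrom] - L + 1L, 1L)
        entry <- record(list(type = "inversion", branch = lab, chrom = chrom,
                             start = start, len = L))
      } else entry <- next_logged()
      genome <- apply_inversion(genome, entry$chrom, entry$start, entry$len)
    }

    for (i in seq_len(ev$translocations)) {
      lens <- vapply(genome, function(ch) length(ch$genes), 0L)
      ok <- which(lens >= 2L)
      if (length(ok) < 2L) break
      if (sampling) {
        pick <- NULL
        for (try in 1:200) {
          cs <- sample(ok, 2L)
          ca <- cs[1]; cb <- cs[2]
          ba <- sample.int(lens[ca] - 1L, 1L)
          bb <- sample.int(lens[cb] - 1L, 1L)
          A <- genome[[ca]]; B <- genome[[cb]]
          # breakpoints interior to one origin territory, joining two origins
          if (origin_of(A, ba) == origin_of(A, ba + 1L) &&
              origin_of(B, bb) == origin_of(B, bb + 1L) &&
              origin_of(A, ba) != origin_of(B, bb)) {
            pick <- list(ca = ca, cb = cb, ba = ba, bb = bb)
            break
          }
        }
        entry <- if (is.null(pick)) {
          record(list(type = "noop", branch = lab))
        } else {
          record(c(list(type = "translocation", branch = lab), pick))
        }
      } else entry <- next_logged()
      if (entry$type == "noop") next
      genome <- apply_translocation(genome, entry$ca, entry$cb,
                                    entry$ba, entry$bb)
    }

    for (i in seq_len(ev$fusions)) {
      if (length(genome) < 2L) break
      if (sampling) {
        cs <- sample.int(length(genome), 2L)
        entry <- record(list(type = "fusion", branch = lab,
                             ca = cs[1], cb = cs[2]))
      } else entry <- next_logged()
      genome <- apply_fusion(genome, entry$ca, entry$cb)
    }

    for (i in seq_len(ev$fissions)) {
      lens <- vapply(genome, function(ch) length(ch$genes), 0L)
      ok <- which(lens >= 2L)
      if (!length(ok)) break
      if (sampling) {
        chrom <- ok[sample.int(length(ok), 1L, prob = lens[ok])]
        pos <- sample.int(lens[chrom] - 1L, 1L)
        entry <- record(list(type = "fission", branch = lab,
                             chrom = chrom, pos = pos))
      } else entry <- next_logged()
      genome <- apply_fission(genome, entry$chrom, entry$pos)
    }

    if (child <= nt) {
      leaves[[lab]] <<- genome
    } else {
      snapshots[[lab]] <<- genome
      for (k in tree$edge[tree$edge[, 1] == child, 2]) run_branch(genome, k)
    }
  }

  for (k in tree$edge[tree$edge[, 1] == root, 2]) run_branch(root_genome, k)

  orders <- genome_to_orders(leaves)
  idx <- as.integer(sub("^g", "", orders$gene_id))
  fam_map <- stats::setNames(family_id_str(reg$family[idx]), orders$gene_id)

  pairs <- build_pairs(leaves, reg, depths, tree, config, sampling, log)
  log <- pairs$log
  node_orders <- lapply(names(snapshots), function(nm)
    genome_to_orders(stats::setNames(snapshots[nm], nm)))
  names(node_orders) <- names(snapshots)

  structure(list(
    orders = orders,
    pairs = pairs$pairs,
    tree = tree,
    config = config,
    truth = list(
      node_genomes = snapshots,
      node_orders = node_orders,
      family_map = fam_map,
      fam_origin = stats::setNames(sprintf("chr%02d", fam_origin),
                                   family_id_str(seq_along(fam_origin))),
      event_log = log,
      divergence = pairs$divergence,
      registry = reg,
      leaf_depths = stats::setNames(depths[seq_len(nt)], tree$tip.label)
    )
  ), class = "genome_simulation")
}

genome_to_orders <- function(genomes) {
  rows <- list()
  for (gname in names(genomes)) {
    chroms <- genomes[[gname]]
    for (ci in seq_along(chroms)) {
      ch <- chroms[[ci]]
      if (!length(ch$genes)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome = gname, chromosome = sprintf("chr%02d", ci),
        gene_id = gene_id_str(ch$genes), rank = seq_along(ch$genes) - 1L,
        strand = ifelse(ch$strand > 0L, "+", "-"), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("gene_orders", "data.frame")
  df
}

# all within-family gene pairs across (and within) leaf genomes, with true
# divergence from the gene genealogy
build_pairs <- function(leaves, reg, depths, tree, config, sampling, log) {
  nt <- length(tree$tip.label)
  leaf_depth <- stats::setNames(depths[seq_len(nt)], tree$tip.label)
  # ancestry paths root -> gene, one matrix per leaf (equal path lengths
  # within a leaf: every relabeling event is genome-wide)
  paths <- list()
  members <- list()
  for (lab in names(leaves)) {
    genes <- unlist(lapply(leaves[[lab]], `[[`, "genes"))
    p <- list(genes)
    cur <- genes
    repeat {
      cur <- reg$parent[cur]
      if (all(cur == 0L)) break
      p[[length(p) + 1L]] <- cur
    }
    paths[[lab]] <- do.call(cbind, rev(p))  # columns: root ... leaf
    members[[lab]] <- data.frame(idx = seq_along(genes), gene = genes,
                                 family = reg$family[genes])
  }
  combos <- utils::combn(names(leaves), 2L, simplify = FALSE)
  combos <- c(combos, lapply(names(leaves), function(l) c(l, l)))
  out <- list()
  for (cp in combos) {
    X <- cp[1]; Y <- cp[2]
    m <- merge(members[[X]], members[[Y]], by = "family",
               suffixes = c("_x", "_y"))
    if (X == Y) m <- m[m$idx_x < m$idx_y, , drop = FALSE]
    if (!nrow(m)) next
    PX <- paths[[X]]; PY <- paths[[Y]]
    L <- min(ncol(PX), ncol(PY))
    div <- rep(NA_integer_, nrow(m))
    alive <- rep(TRUE, nrow(m))
    for (j in seq_len(L)) {
      gx <- PX[m$idx_x, j]; gy <- PY[m$idx_y, j]
      hit <- alive & gx != gy
      div[hit] <- gx[hit]
      alive <- alive & !hit
    }
    stopifnot(!any(alive))  # distinct genes must diverge somewhere
    div_depth <- reg$depth[div]
    div_event <- reg$event[div]
    ks_true <- (leaf_depth[[X]] - div_depth) + (leaf_depth[[Y]] - div_depth)
    out[[length(out) + 1L]] <- data.frame(
      gene_a = gene_id_str(m$gene_x), gene_b = gene_id_str(m$gene_y),
      genome_a = X, genome_b = Y,
      ks_true = ks_true,
      pair_class = ifelse(div_event == "speciation", "ortholog", "paralog"),
      div_event = div_event, div_depth = div_depth,
      stringsAsFactors = FALSE)
  }
  divergence <- do.call(rbind, out)
  rownames(divergence) <- NULL
  if (sampling) {
    noise <- stats::rnorm(nrow(divergence), 0, config$ks_sigma)
    log[[length(log) + 1L]] <- list(type = "ks_noise", noise = noise)
  } else {
    noise <- log[[length(log)]]$noise
  }
  ks <- pmax(0, divergence$ks_true + noise)
  pairs <- data.frame(gene_a = divergence$gene_a, gene_b = divergence$gene_b,
                      ks = ks, similarity = 100 * exp(-ks),
                      pair_class = divergence$pair_class,
                      stringsAsFactors = FALSE)
  class(pairs) <- c("homolog_pairs", "data.frame")
  list(pairs = pairs, divergence = divergence, log = log)
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat("genome_simulation:", length(unique(x$orders$genome)), "leaves,",
      nrow(x$orders), "genes,", nrow(x$pairs), "homolog pairs\n")
  invisible(x)
}

# ---- ground-truth accessors ------------------------------------------------

#' True ancestral genome at an internal node
#'
#' Builds an `ancestor_genome` table from the simulator's snapshot at a
#' node: protochromosomes are the node's chromosomes, protogenes its gene
#' families in their true order.
#'
#' @param sim `genome_simulation`.
#' @param node internal node label.
#' @return `ancestor_genome` data.frame (with `adjacency_support` `NA`).
#' @export
true_ancestor <- function(sim, node) {
  g <- sim$truth$node_genomes[[node]]
  if (is.null(g)) stop("no snapshot for node: ", node)
  reg <- sim$truth$registry
  rows <- lapply(seq_along(g), function(ci) {
    fams <- family_id_str(reg$family[g[[ci]]$genes])
    data.frame(protochromosome_id = ci, position = seq_along(fams) - 1L,
               family_id = fams, contig_id = sprintf("chr%02d", ci),
               adjacency_support = NA_integer_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("ancestor_genome", "data.frame")
  res
}

#' True neighbor adjacencies at an internal node
#'
#' @param sim `genome_simulation`.
#' @param node internal node label.
#' @return character vector of unordered true-family pairs `"Fa|Fb"`.
#' @export
true_adjacencies <- function(sim, node) {
  g <- sim$truth$node_genomes[[node]]
  if (is.null(g)) stop("no snapshot for node: ", node)
  reg <- sim$truth$registry
  res <- character(0)
  for (ch in g) {
    fams <- family_id_str(reg$family[ch$genes])
    if (length(fams) < 2L) next
    a <- fams[-length(fams)]; b <- fams[-1L]
    keep <- a != b
    res <- c(res, paste(pmin(a, b), pmax(a, b), sep = "|")[keep])
  }
  sort(unique(res))
}

#' Ground-truth gene families as a `gene_families` object
#'
#' Packages the simulator's true gene-to-family map in the shape returned
#' by [build_families()], for painting or adjacency extraction against
#' ground truth.
#'
#' @param sim `genome_simulation`.
#' @return `gene_families` object (no family is oversize).
#' @export
true_families <- function(sim) {
  fm <- sim$truth$family_map
  membership <- data.frame(gene_id = names(fm), family_id = unname(fm),
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$family_id, membership$gene_id), ]
  rownames(membership) <- NULL
  sizes <- table(membership$family_id)
  structure(list(
    membership = membership,
    families = data.frame(family_id = names(sizes),
                          n_genes = as.integer(sizes),
                          oversize = FALSE, stringsAsFactors = FALSE),
    max_copies_per_genome = Inf
  ), class = "gene_families")
}

#' Translate inferred family pairs to true families
#'
#' Inferred family ids are gene ids (smallest member), so the simulator's
#' gene-to-family truth map translates them directly.
#'
#' @param pairs character vector `"f|g"` of inferred family pairs.
#' @param sim `genome_simulation`.
#' @return character vector of true-family pairs, sorted unique.
#' @export
as_true_pairs <- function(pairs, sim) {
  fm <- sim$truth$family_map
  sp <- strsplit(pairs, "|", fixed = TRUE)
  a <- fm[vapply(sp, `[`, "", 1L)]
  b <- fm[vapply(sp, `[`, "", 2L)]
  sort(unique(paste(pmin(a, b), pmax(a, b), sep = "|")))
}
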