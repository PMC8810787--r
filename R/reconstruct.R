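#' Partition the species tree at an ancestor node
#'
#' An internal, non-root ancestor node has three incident branches: one
#' incoming edge and two outgoing edges. They partition the leaves into the
#' two descendant clades and the outgroup-side remainder; an adjacency must
#' be observed in at least two of these three subtrees to count as evidence
#' for the ancestor.
#'
#' @param tree binary `phylo` with node labels (see [read_species_tree()]).
#' @param ancestor internal node label (or number). The root is refused
#'   unless `root_mode = TRUE`, in which case only the two child subtrees
#'   are returned and candidate weights are capped at 2.
#' @param root_mode allow the root with a two-subtree partition.
#' @return `subtree_partition`: list with `ancestor`, `node` (number) and
#'   `subtrees`, a list of 2-3 character vectors of leaf labels.
#' @export
partition_subtrees <- function(tree, ancestor, root_mode = FALSE) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  if (is.character(ancestor)) {
    nodenum <- match(ancestor, tree$node.label) + nt
    if (is.na(nodenum)) stop("unknown ancestor node label: ", ancestor)
  } else {
    nodenum <- as.integer(ancestor)
    if (nodenum <= nt || nodenum > nt + tree$Nnode)
      stop("ancestor must be an internal node")
  }
  if (nodenum == root && !root_mode)
    stop("the root has only two incident subtrees; rerun with root_mode = TRUE ",
         "for a two-subtree partition (candidate weights capped at 2)")
  kids <- tree$edge[tree$edge[, 1] == nodenum, 2]
  tip_set <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    todo <- node
    tips <- character()
    while (length(todo)) {
      ch <- tree$edge[tree$edge[, 1] %in% todo, 2]
      tips <- c(tips, tree$tip.label[ch[ch <= nt]])
      todo <- ch[ch > nt]
    }
    tips
  }
  s1 <- sort(tip_set(kids[1]))
  s2 <- sort(tip_set(kids[2]))
  subtrees <- list(s1, s2)
  if (nodenum != root) {
    s3 <- sort(setdiff(tree$tip.label, c(s1, s2)))
    if (!length(s3)) stop("ancestor has an empty outgroup-side subtree")
    subtrees <- list(s1, s2, s3)
  }
  structure(list(ancestor = node_label(tree, nodenum), node = nodenum,
                 subtrees = subtrees),
            class = "subtree_partition")
}

#' @export
print.subtree_partition <- function(x, ...) {
  cat("ancestor", x$ancestor, "with", length(x$subtrees), "subtrees:\n")
  for (s in x$subtrees) cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' Collect candidate ancestral adjacencies for an ancestor
#'
#' A family pair observed as a generalized adjacency anywhere in any genome
#' of two or three of the ancestor's incident subtrees becomes a candidate,
#' weighted 2 or 3 by the number of supporting subtrees. Adjacency identity
#' is the unordered family pair: reading direction is not used, because
#' inversions within a window preserve the adjacency but not the
#' orientation. A pair seen in a single subtree (however many genomes) is
#' not a candidate. The same family pair observed at several window
#' distances collapses to one candidate.
#'
#' @param adjacencies `observed_adjacencies` pooled over all genomes.
#' @param partition `subtree_partition` for the ancestor.
#' @return `candidate_adjacencies` data.frame: `family_a` < `family_b`,
#'   `weight` (2 or 3), `subtrees`, `genomes` (comma-separated support).
#' @export
collect_candidates <- function(adjacencies, partition) {
  adj <- adjacencies[!adjacencies$tandem, , drop = FALSE]
  ns <- length(partition$subtrees)
  g2s <- integer(0)
  for (i in seq_len(ns))
    g2s[partition$subtrees[[i]]] <- i
  sub <- g2s[adj$genome]
  keep <- !is.na(sub)
  adj <- adj[keep, , drop = FALSE]
  sub <- sub[keep]
  if (!nrow(adj)) {
    return(structure(data.frame(family_a = character(), family_b = character(),
                                side_a = integer(), side_b = integer(),
                                weight = integer(), distance = integer(),
                                subtrees = character(),
                                genomes = character(), stringsAsFactors = FALSE),
                     class = c("candidate_adjacencies", "data.frame"),
                     partition = partition))
  }
  swap <- adj$family_a > adj$family_b
  fa <- ifelse(swap, adj$family_b, adj$family_a)
  fb <- ifelse(swap, adj$family_a, adj$family_b)
  sa <- ifelse(swap, adj$side_b, adj$side_a)
  sb <- ifelse(swap, adj$side_a, adj$side_b)
  key <- paste(fa, fb, sep = "\r")
  usub <- !duplicated(paste(key, sub))
  subtree_count <- tapply(sub[usub], key[usub], function(s) sort(unique(s)))
  ugen <- !duplicated(paste(key, adj$genome))
  genome_sets <- tapply(adj$genome[ugen], key[ugen],
                        function(g) paste(sort(unique(g)), collapse = ","))
  # modal observed end pair per candidate (ties: smallest side combination);
  # reading direction is not trusted as adjacency identity, but the dominant
  # end pair anchors the matching edge
  combo <- paste(sa, sb)
  combo_n <- table(key, combo)
  modal_combo <- colnames(combo_n)[apply(combo_n, 1L, which.max)]
  names(modal_combo) <- rownames(combo_n)
  # consensus (modal) observed gene-rank distance per pair: true ancestral
  # neighbors sit at distance 1 in most genomes, whereas a within-window
  # skip pair shows its true larger distance wherever the intervening genes
  # survive (ties go to the smaller distance)
  d_modal <- tapply(adj$distance, key, function(d) {
    tb <- table(d)
    as.integer(names(tb)[order(-tb, as.integer(names(tb)))][1L])
  })
  weight <- lengths(subtree_count)
  keys <- names(weight)[weight >= 2L]
  keys <- sort(keys)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  sides <- strsplit(modal_combo[keys], " ", fixed = TRUE)
  res <- data.frame(
    family_a = vapply(parts, `[`, "", 1L),
    family_b = vapply(parts, `[`, "", 2L),
    side_a = as.integer(vapply(sides, `[`, "", 1L)),
    side_b = as.integer(vapply(sides, `[`, "", 2L)),
    weight = as.integer(weight[keys]),
    distance = as.integer(d_modal[keys]),
    subtrees = vapply(keys, function(k)
      paste(subtree_count[[k]], collapse = ","), ""),
    genomes = unname(unlist(genome_sets[keys])),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res, class = c("candidate_adjacencies", "data.frame"),
            partition = partition)
}

#' Families eligible as protogenes of an ancestor
#'
#' A family is placed in the ancestor only if it is present (has at least
#' one member gene) in at least two of the ancestor's incident subtrees --
#' the same two-subtree evidence rule that admits candidate adjacencies.
#'
#' @param genomes `gene_orders`.
#' @param families `gene_families`.
#' @param partition `subtree_partition`.
#' @return character vector of eligible family ids.
#' @export
eligible_families <- function(genomes, families, partition) {
  fmap <- family_map(families)
  fam <- unname(fmap[genomes$gene_id])
  ns <- length(partition$subtrees)
  g2s <- integer(0)
  for (i in seq_len(ns)) g2s[partition$subtrees[[i]]] <- i
  sub <- g2s[genomes$genome]
  ok <- !is.na(fam) & !is.na(sub)
  u <- !duplicated(paste(fam[ok], sub[ok]))
  n_sub <- table(fam[ok][u])
  sort(names(n_sub)[n_sub >= 2L])
}

#' Assemble ancestral contigs by maximum-weight matching of protogene ends
#'
#' Builds a graph on protogene ends (f.0, f.1 per family) and computes an
#' exact maximum-weight matching, so that every end is used by at most one
#' adjacency; the matched edges plus the intrinsic gene edges decompose
#' into simple paths (linear contigs) and, occasionally, cycles, which
#' [linearize()] opens afterwards.
#'
#' With `ports = "observed"` (default) each candidate contributes one edge
#' between its modal observed end pair. With `ports = "free"` orientation
#' is discarded entirely and each candidate contributes all four port edges
#' (f.0-g.0, f.0-g.1, f.1-g.0, f.1-g.1) at its weight; note that free ports
#' let the matcher pair families into weight-maximal 2-cycles instead of
#' chains (two port edges of the same pair outweigh any chain), so this
#' mode is exploratory only.
#'
#' @param candidates `candidate_adjacencies`.
#' @param eligible optional character vector of eligible family ids (see
#'   [eligible_families()]); families not incident to any matched adjacency
#'   become singleton contigs. Defaults to the families present in
#'   `candidates`.
#' @param ports `"observed"` or `"free"` (see above).
#' @return `ancestral_contigs` data.frame: `contig_id`, `position`,
#'   `family_id`, `join_weight` (weight of the join to the next protogene;
#'   on the last row of a circular contig it is the wrap-around join, `NA`
#'   for linear contigs). Attributes: `topology` data.frame and
#'   `total_weight`.
#' @export
mwm_assemble <- function(candidates, eligible = NULL,
                         ports = c("observed", "free")) {
  ports <- match.arg(ports)
  if (nrow(candidates)) {   # normalize pair order
    fa <- pmin(candidates$family_a, candidates$family_b)
    fb <- pmax(candidates$family_a, candidates$family_b)
    candidates$family_a <- fa
    candidates$family_b <- fb
  }
  fams <- sort(unique(c(candidates$family_a, candidates$family_b, eligible)))
  if (!length(fams)) stop("no candidate adjacencies and no eligible families")
  if (nrow(candidates)) {
    if (ports == "observed") {
      if (is.null(candidates$side_a) || anyNA(candidates$side_a))
        stop("candidates lack observed end sides; use ports = \"free\"")
      ed <- data.frame(u = paste0(candidates$family_a, "\r", candidates$side_a),
                       v = paste0(candidates$family_b, "\r", candidates$side_b),
                       w = candidates$weight,
                       fa = candidates$family_a, fb = candidates$family_b,
                       stringsAsFactors = FALSE)
    } else {
      ends <- expand.grid(sa = 0:1, sb = 0:1)
      ed <- do.call(rbind, lapply(seq_len(nrow(ends)), function(i) {
        data.frame(u = paste0(candidates$family_a, "\r", ends$sa[i]),
                   v = paste0(candidates$family_b, "\r", ends$sb[i]),
                   w = candidates$weight,
                   fa = candidates$family_a, fb = candidates$family_b,
                   stringsAsFactors = FALSE)
      }))
    }
    # matching weight: subtree support (2 or 3) is primary; among
    # equal-support candidates, those observed at smaller gene-rank distance
    # are preferred. The scaled integer weight keeps support dominant per
    # edge while the distance term resolves the otherwise massive ties that
    # window-based candidates create (every within-window pair of a
    # conserved region is a candidate).
    if (!is.null(candidates$distance) && !anyNA(candidates$distance)) {
      pen <- pmin(pmax(candidates$distance - 1L, 0L), 15L)
    } else {
      pen <- 0L
    }
    ed$w <- ed$w * 16L - rep(pen, length.out = nrow(ed))
    # deterministic edge order: weight desc, family pair, then port sides
    ed <- ed[order(-ed$w, ed$fa, ed$fb, ed$u, ed$v), , drop = FALSE]
    mate <- max_weight_matching(ed[c("u", "v", "w")])
  } else {
    mate <- stats::setNames(character(0), character(0))
  }
  wkey <- stats::setNames(candidates$weight,
                          paste(candidates$family_a, candidates$family_b,
                                sep = "\r"))
  pair_weight <- function(f, g) {
    unname(wkey[paste(pmin(f, g), pmax(f, g), sep = "\r")])
  }
  end_of <- function(f, s) paste0(f, "\r", s)
  fam_of <- function(e) sub("\r[01]$", "", e)
  side_of <- function(e) as.integer(sub("^.*\r", "", e))
  mate_of <- function(e) {
    if (e %in% names(mate)) mate[[e]] else NA_character_
  }

  visited <- stats::setNames(rep(FALSE, length(fams)), fams)
  contigs <- list()
  topo <- character()

  walk <- function(start_fam, start_side) {
    # enter start_fam at start_side, exit at the other side, follow matches
    seq_f <- start_fam
    joins <- integer(0)
    visited[start_fam] <<- TRUE
    cur <- end_of(start_fam, 1L - start_side)
    repeat {
      nxt <- mate_of(cur)
      if (is.na(nxt)) return(list(fams = seq_f, joins = joins, closed = FALSE))
      g <- fam_of(nxt)
      joins <- c(joins, pair_weight(fam_of(cur), g))
      if (g == start_fam && side_of(nxt) == start_side)
        return(list(fams = seq_f, joins = joins, closed = TRUE))
      seq_f <- c(seq_f, g)
      visited[g] <<- TRUE
      cur <- end_of(g, 1L - side_of(nxt))
    }
  }

  # pass 1: singletons and paths (started from an unmatched end); a family
  # with both ends matched may still sit mid-path, so cycles are what is
  # left unvisited afterwards
  for (f in fams) {
    if (visited[f]) next
    m0 <- mate_of(end_of(f, 0L))
    m1 <- mate_of(end_of(f, 1L))
    if (is.na(m0) && is.na(m1)) {
      visited[f] <- TRUE
      contigs[[length(contigs) + 1L]] <- list(fams = f, joins = integer(0))
      topo <- c(topo, "linear")
    } else if (is.na(m0) || is.na(m1)) {
      res <- walk(f, if (is.na(m0)) 0L else 1L)
      contigs[[length(contigs) + 1L]] <- res[c("fams", "joins")]
      topo <- c(topo, "linear")
    }
  }
  # pass 2: cycles (fams is sorted, so each cycle starts at its smallest
  # member family)
  for (f in fams) {
    if (visited[f]) next
    res <- walk(f, 0L)
    stopifnot(res$closed)
    contigs[[length(contigs) + 1L]] <- res[c("fams", "joins")]
    topo <- c(topo, "circular")
  }

  # canonical orientation of linear contigs: first family <= last family
  for (i in seq_along(contigs)) {
    cf <- contigs[[i]]$fams
    if (topo[i] == "linear" && length(cf) > 1L &&
        cf[1L] > cf[length(cf)]) {
      contigs[[i]]$fams <- rev(cf)
      contigs[[i]]$joins <- rev(contigs[[i]]$joins)
    }
  }
  ord <- order(vapply(contigs, function(cc) cc$fams[1L], ""))
  contigs <- contigs[ord]
  topo <- topo[ord]
  ids <- sprintf("C%04d", seq_along(contigs))
  rows <- lapply(seq_along(contigs), function(i) {
    cf <- contigs[[i]]$fams
    jw <- contigs[[i]]$joins
    join_weight <- if (topo[i] == "circular") jw else c(jw, NA_integer_)
    data.frame(contig_id = ids[i], position = seq_along(cf) - 1L,
               family_id = cf, join_weight = as.integer(join_weight),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  total_w <- sum(unlist(lapply(contigs, `[[`, "joins")))
  structure(out, class = c("ancestral_contigs", "data.frame"),
            topology = data.frame(contig_id = ids,
                                  length = vapply(contigs, function(cc)
                                    length(cc$fams), 0L),
                                  topology = topo, stringsAsFactors = FALSE),
            total_weight = total_w)
}

#' Linearize circular ancestral contigs
#'
#' Every circular contig is opened by deleting its lowest-weight join (ties
#' broken at the lexicographically smallest family pair), which costs the
#' least matched weight. The topology attribute records the event as
#' `circularized`.
#'
#' @param contigs `ancestral_contigs` from [mwm_assemble()].
#' @return `ancestral_contigs`, all linear.
#' @export
linearize <- function(contigs) {
  topo <- attr(contigs, "topology")
  total_w <- attr(contigs, "total_weight")
  circ <- topo$contig_id[topo$topology == "circular"]
  if (!length(circ)) return(contigs)
  pieces <- split(seq_len(nrow(contigs)), contigs$contig_id)
  for (cid in circ) {
    ii <- pieces[[cid]]
    fams <- contigs$family_id[ii]
    jw <- contigs$join_weight[ii]          # join i: fams[i] -- fams[i %% n + 1]
    n <- length(fams)
    nxt <- c(fams[-1L], fams[1L])
    pa <- pmin(fams, nxt)
    pb <- pmax(fams, nxt)
    o <- order(jw, pa, pb)
    br <- o[1L]                            # min weight, then smallest pair
    total_w <- total_w - jw[br]
    # new linear order starts after the broken join
    idx <- c(seq_len(n)[-seq_len(br)], seq_len(br))
    fams2 <- fams[idx]
    jw2 <- c(jw[idx][-n], NA_integer_)
    if (fams2[1L] > fams2[n]) {            # canonical orientation
      fams2 <- rev(fams2)
      jw2 <- c(rev(jw2[-n]), NA_integer_)
    }
    contigs$family_id[ii] <- fams2
    contigs$join_weight[ii] <- jw2
    topo$topology[topo$contig_id == cid] <- "circularized"
  }
  attr(contigs, "topology") <- topo
  attr(contigs, "total_weight") <- total_w
  contigs
}

#' Family-pair adjacency set realized by a contig set
#'
#' @param contigs `ancestral_contigs`.
#' @return character vector of unordered family pairs (`"f|g"`, f < g), one
#'   per join.
#' @export
contig_adjacencies <- function(contigs) {
  res <- character(0)
  for (ii in split(seq_len(nrow(contigs)), contigs$contig_id)) {
    fams <- contigs$family_id[ii]
    jw <- contigs$join_weight[ii]
    n <- length(fams)
    if (n < 2L) next
    a <- fams[-n]; b <- fams[-1L]
    if (!is.na(jw[n])) { a <- c(a, fams[n]); b <- c(b, fams[1L]) }  # cycle wrap
    res <- c(res, paste(pmin(a, b), pmax(a, b), sep = "|"))
  }
  sort(unique(res))
}

#' Reconstruct an ancestral genome end to end
#'
#' Convenience wrapper chaining [partition_subtrees()],
#' [extract_generalized_adjacencies()], [collect_candidates()],
#' [mwm_assemble()] and [linearize()] for one ancestor node.
#'
#' @param genomes `gene_orders` for all leaves.
#' @param families `gene_families`.
#' @param tree binary `phylo`.
#' @param ancestor internal node label.
#' @param w generalized-adjacency window (default 7).
#' @param adjacencies optional precomputed `observed_adjacencies` (saves
#'   recomputation when reconstructing several ancestors).
#' @return `ancestral_contigs` (linearized), with the candidate set in
#'   attribute `candidates`.
#' @export
reconstruct_ancestor <- function(genomes, families, tree, ancestor, w = 7L,
                                 adjacencies = NULL) {
  part <- partition_subtrees(tree, ancestor)
  if (is.null(adjacencies))
    adjacencies <- extract_generalized_adjacencies(genomes, families, w = w)
  cand <- collect_candidates(adjacencies, part)
  elig <- eligible_families(genomes, families, part)
  contigs <- linearize(mwm_assemble(cand, eligible = elig))
  attr(contigs, "candidates") <- cand
  attr(contigs, "ancestor") <- part$ancestor
  contigs
}
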