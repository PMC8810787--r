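#' Enumerate all rooted binary topologies on a leaf set
#'
#' There are (2n-3)!! rooted binary topologies on n labeled leaves; they
#' are generated by inserting each successive leaf on every edge (including
#' above the root) of every smaller topology. Enumeration is limited to 8
#' leaves.
#'
#' @param leaves character vector of leaf labels (2..8, unique).
#' @return list of topologies; each topology is a nested list of two
#'   children, leaves being character scalars. Names are canonical newick
#'   strings (children ordered by smallest leaf).
#' @export
enumerate_rooted_topologies <- function(leaves) {
  leaves <- as.character(leaves)
  if (anyDuplicated(leaves)) stop("leaf labels must be unique")
  n <- length(leaves)
  if (n < 2L) stop("need at least 2 leaves")
  if (n > 8L) stop("topology enumeration is limited to 8 leaves (", n, " given)")
  leaves <- sort(leaves)
  trees <- list(list(leaves[1L], leaves[2L]))
  for (k in seq_len(n)[-(1:2)]) {
    leaf <- leaves[k]
    trees <- unlist(lapply(trees, insert_leaf_everywhere, leaf = leaf),
                    recursive = FALSE)
  }
  names(trees) <- vapply(trees, topology_newick, "")
  trees[order(names(trees))]
}

# all ways to attach `leaf` on the edge above every node of `tree`,
# plus above the root
insert_leaf_everywhere <- function(tree, leaf) {
  res <- list(list(tree, leaf))  # new root above the old one
  if (!is.character(tree)) {
    for (i in 1:2) {
      for (sub in insert_leaf_everywhere(tree[[i]], leaf)) {
        t2 <- tree
        t2[[i]] <- sub
        res[[length(res) + 1L]] <- t2
      }
    }
  }
  res
}

#' Canonical newick string of a topology
#' @param tree nested-list topology.
#' @return newick string (no branch lengths), children sorted by smallest
#'   descendant leaf.
#' @export
topology_newick <- function(tree) {
  paste0(newick_rec(tree)$s, ";")
}

newick_rec <- function(tree) {
  if (is.character(tree)) return(list(s = tree, min = tree))
  a <- newick_rec(tree[[1L]])
  b <- newick_rec(tree[[2L]])
  if (b$min < a$min) { tmp <- a; a <- b; b <- tmp }
  list(s = paste0("(", a$s, ",", b$s, ")"), min = a$min)
}

# per-topology structure: for each internal node, the leaf pairs whose MRCA
# it is, and the ancestor relation between internal nodes
topology_nodes <- function(tree) {
  nodes <- list()
  rec <- function(t, ancestors) {
    if (is.character(t)) return(t)
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, ancestors = ancestors, pairs = NULL)
    la <- rec(t[[1L]], c(ancestors, id))
    lb <- rec(t[[2L]], c(ancestors, id))
    prs <- expand.grid(a = la, b = lb, stringsAsFactors = FALSE)
    nodes[[id]]$pairs <<- paste(pmin(prs$a, prs$b), pmax(prs$a, prs$b),
                                sep = "|")
    c(la, lb)
  }
  rec(tree, integer(0))
  nodes
}

#' 'Trees in the Peaks': filter rooted topologies by peak-order consistency
#'
#' Every rooted binary topology on the leaves is evaluated against the
#' primary peaks of the per-pair Ks (or similarity) distributions. Each
#' internal node receives the peaks of the leaf pairs whose most recent
#' common ancestor it is; the node value is the mass-weighted mean of those
#' modes and the node interval is their union span. A topology is
#' consistent iff (a) the peaks mapped to one node mutually overlap, and
#' (b) every ancestral node precedes or overlaps its descendants: greater
#' Ks (or lower similarity), or overlapping intervals.
#'
#' @param pair_peaks named list of `peak_set` objects, one per unordered
#'   leaf pair, names `"A|B"` with A < B.
#' @param axis `"ks"` or `"similarity"`.
#' @param leaves leaf labels; default inferred from `names(pair_peaks)`.
#' @param use_paralog_peaks if `TRUE`, `paralog_peaks` adds the constraint
#'   that each lineage's WGD peak must be younger than (or overlap) the
#'   divergence peaks of all nodes above that leaf.
#' @param paralog_peaks named list of `peak_set` per leaf (WGD signal).
#' @return `topology_verdicts` data.frame: `topology` (newick),
#'   `consistent`, `n_violations`, `violations` (semicolon-separated
#'   descriptions).
#' @export
trees_in_peaks <- function(pair_peaks, axis = c("ks", "similarity"),
                           leaves = NULL, use_paralog_peaks = FALSE,
                           paralog_peaks = NULL) {
  axis <- match.arg(axis)
  if (is.null(leaves))
    leaves <- sort(unique(unlist(strsplit(names(pair_peaks), "|", fixed = TRUE))))
  need <- apply(utils::combn(sort(leaves), 2L), 2L, paste, collapse = "|")
  missing_pairs <- setdiff(need, names(pair_peaks))
  if (length(missing_pairs))
    stop("missing peak set for pair(s): ", paste(missing_pairs, collapse = ", "))
  prim <- lapply(pair_peaks[need], primary_peak)
  # on the similarity axis larger values are younger; flip so that
  # "precedes" always means "larger value"
  flip <- if (axis == "similarity") -1 else 1
  pk <- do.call(rbind, prim)
  pk$pair <- need
  pk$mode <- flip * pk$mode
  lo <- flip * ifelse(rep(flip, nrow(pk)) < 0, pk$hi, pk$lo)
  hi <- flip * ifelse(rep(flip, nrow(pk)) < 0, pk$lo, pk$hi)
  pk$lo <- pmin(lo, hi); pk$hi <- pmax(lo, hi)
  rownames(pk) <- pk$pair

  topos <- enumerate_rooted_topologies(leaves)
  verdicts <- lapply(names(topos), function(nw) {
    nodes <- topology_nodes(topos[[nw]])
    viol <- character(0)
    vals <- vapply(nodes, function(nd) {
      p <- pk[nd$pairs, , drop = FALSE]
      stats::weighted.mean(p$mode, p$mass)
    }, 0)
    ivs <- lapply(nodes, function(nd) {
      p <- pk[nd$pairs, , drop = FALSE]
      c(min(p$lo), max(p$hi))
    })
    # (a) peaks mapped to one node must mutually overlap
    for (nd in nodes) {
      p <- pk[nd$pairs, , drop = FALSE]
      if (nrow(p) > 1L && max(p$lo) > min(p$hi) + 1e-12)
        viol <- c(viol, paste0("node{", paste(nd$pairs, collapse = ","),
                               "}: peaks do not mutually overlap"))
    }
    # (b) ancestor precedes or overlaps descendant
    for (nd in nodes) {
      for (anc in nd$ancestors) {
        overlap <- ivs[[anc]][1L] <= ivs[[nd$id]][2L] + 1e-12 &&
          ivs[[nd$id]][1L] <= ivs[[anc]][2L] + 1e-12
        if (vals[anc] < vals[nd$id] && !overlap)
          viol <- c(viol, paste0("node", anc, " < node", nd$id,
                                 ": ancestor younger than descendant"))
      }
    }
    if (use_paralog_peaks && !is.null(paralog_peaks)) {
      leaf_anc <- leaf_ancestor_nodes(topos[[nw]])
      for (lf in names(paralog_peaks)) {
        pp <- primary_peak(paralog_peaks[[lf]])
        pmode <- flip * pp$mode
        plo <- min(flip * pp$lo, flip * pp$hi)
        phi <- max(flip * pp$lo, flip * pp$hi)
        for (anc in leaf_anc[[lf]]) {
          overlap <- ivs[[anc]][1L] <= phi + 1e-12 && plo <= ivs[[anc]][2L] + 1e-12
          if (vals[anc] < pmode && !overlap)
            viol <- c(viol, paste0("wgd(", lf, ") older than node", anc))
        }
      }
    }
    data.frame(topology = nw, consistent = length(viol) == 0L,
               n_violations = length(viol),
               violations = paste(viol, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, verdicts)
  rownames(res) <- NULL
  class(res) <- c("topology_verdicts", "data.frame")
  res
}

leaf_ancestor_nodes <- function(tree) {
  out <- list()
  rec <- function(t, ancestors, counter) {
    if (is.character(t)) {
      out[[t]] <<- ancestors
      return(counter)
    }
    id <- counter + 1L
    counter <- id
    counter <- rec(t[[1L]], c(ancestors, id), counter)
    rec(t[[2L]], c(ancestors, id), counter)
  }
  rec(tree, integer(0), 0L)
  out
}
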