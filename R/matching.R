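#' Exact maximum-weight matching on a general graph
#'
#' Computes a maximum-weight matching (each vertex incident to at most one
#' matched edge, total edge weight maximal) on an arbitrary undirected graph
#' with positive integer weights, using a primal-dual blossom algorithm.
#' This is the engine behind [mwm_assemble()]: vertices are protogene ends
#' and edges are candidate ancestral adjacencies.
#'
#' The graph is split into connected components and each component is solved
#' by a dense \eqn{O(V^3)} blossom implementation in C++. The result is
#' deterministic for a fixed edge order; callers that need a canonical
#' result should sort edges beforehand.
#'
#' @param edges data.frame with columns `u`, `v` (vertex labels, character
#'   or coercible) and `w` (positive integer weights).
#' @return named character vector: for every vertex appearing in `edges`,
#'   its matched partner, or `NA` if unmatched.
#' @examples
#' m <- max_weight_matching(data.frame(u = c("a", "b"), v = c("b", "c"),
#'                                     w = c(3L, 2L)))
#' m[["a"]]  # "b": the heavier edge wins
#' @export
max_weight_matching <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("u", "v", "w") %in% names(edges)))
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  w <- as.integer(edges$w)
  if (any(is.na(w)) || any(w <= 0)) stop("edge weights must be positive integers")
  if (any(u == v)) stop("self-loops are not allowed in a matching problem")
  verts <- sort(unique(c(u, v)))
  mate <- stats::setNames(rep(NA_character_, length(verts)), verts)
  if (nrow(edges) == 0L) return(mate)

  gr <- igraph::graph_from_data_frame(
    data.frame(from = u, to = v, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
  comp <- igraph::components(gr)$membership[verts]
  ui <- match(u, verts)
  vi <- match(v, verts)
  for (cc in unique(comp)) {
    cv <- which(comp == cc)
    if (length(cv) < 2L) next
    sel <- comp[ui] == cc
    lu <- match(ui[sel], cv)
    lv <- match(vi[sel], cv)
    m <- .mwm_dense(length(cv), lu, lv, w[sel])
    matched <- which(m > 0L)
    mate[cv[matched]] <- verts[cv[m[matched]]]
  }
  mate
}

#' Reference maximum-weight matching by exhaustive dynamic programming
#'
#' Independent check for [max_weight_matching()]: computes the optimal
#' matching weight over all matchings by dynamic programming on vertex
#' subsets. Exponential in the number of vertices; intended for graphs with
#' at most ~20 vertices.
#'
#' @param edges data.frame with columns `u`, `v`, `w` as in
#'   [max_weight_matching()].
#' @return the maximum total matching weight (numeric scalar).
#' @export
mwm_reference_weight <- function(edges) {
  if (nrow(edges) == 0L) return(0)
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  w <- as.numeric(edges$w)
  verts <- sort(unique(c(u, v)))
  nv <- length(verts)
  if (nv > 22L) stop("reference oracle limited to 22 vertices")
  ui <- match(u, verts) - 1L
  vi <- match(v, verts) - 1L
  adj <- matrix(0, nv, nv)
  for (i in seq_along(ui)) {
    a <- ui[i] + 1L; b <- vi[i] + 1L
    adj[a, b] <- adj[b, a] <- max(adj[a, b], w[i])
  }
  f <- rep(NA_real_, bitwShiftL(1L, nv))
  f[1L] <- 0
  best <- function(mask) {
    if (!is.na(f[mask + 1L])) return(f[mask + 1L])
    # lowest vertex still present in mask
    i <- 0L
    while (!bitwAnd(mask, bitwShiftL(1L, i))) i <- i + 1L
    res <- best(bitwAnd(mask, bitwNot(bitwShiftL(1L, i))))  # leave i unmatched
    rest <- bitwAnd(mask, bitwNot(bitwShiftL(1L, i)))
    for (j in seq_len(nv) - 1L) {
      if (j != i && bitwAnd(rest, bitwShiftL(1L, j)) && adj[i + 1L, j + 1L] > 0) {
        cand <- adj[i + 1L, j + 1L] +
          best(bitwAnd(rest, bitwNot(bitwShiftL(1L, j))))
        if (cand > res) res <- cand
      }
    }
    f[mask + 1L] <<- res
    res
  }
  best(bitwShiftL(1L, nv) - 1L)
}

#' Total weight of a matching returned by [max_weight_matching()]
#' @param mate named mate vector.
#' @param edges the edge data.frame the matching was computed from.
#' @return numeric total weight.
#' @export
matching_weight <- function(mate, edges) {
  if (nrow(edges) == 0L) return(0)
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  key <- ifelse(u < v, paste(u, v), paste(v, u))
  wbest <- tapply(as.numeric(edges$w), key, max)
  used <- !is.na(mate) & names(mate) < mate
  if (!any(used)) return(0)
  sum(wbest[paste(names(mate)[used], mate[used])])
}
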