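#' Estimate peaks of a Ks or similarity distribution
#'
#' Gaussian kernel density estimation with peak calling: local maxima of
#' the density whose basin (between the surrounding minima) carries at
#' least `min_mass` of the total mass become peaks. Each peak gets a
#' half-height interval: the span, within its basin, where the density
#' stays above half the peak height. Peaks of Ks distributions mark
#' speciations (orthologs) and whole-genome duplications (paralogs); their
#' positions and intervals are the currency of the topology scan in
#' [trees_in_peaks()].
#'
#' @param values numeric vector (Ks or percent similarity); at least 30.
#' @param axis `"ks"` or `"similarity"` (recorded; larger Ks = older,
#'   larger similarity = younger).
#' @param bandwidth `"auto"` (Silverman's rule, [stats::bw.nrd0]) or a
#'   fixed numeric bandwidth for reproducibility.
#' @param min_mass minimal mass fraction for a peak (default 0.05).
#' @return `peak_set`: list with `axis`, `peaks` (data.frame `mode`, `lo`,
#'   `hi`, `mass`, sorted by mode), `n`, `bandwidth`.
#' @export
estimate_peaks <- function(values, axis = c("ks", "similarity"),
                           bandwidth = "auto", min_mass = 0.05) {
  axis <- match.arg(axis)
  values <- values[!is.na(values)]
  if (length(values) < 30L)
    stop("need at least 30 values; pool more homolog pairs")
  if (length(unique(values)) == 1L) {
    v <- values[1L]
    return(structure(list(axis = axis,
                          peaks = data.frame(mode = v, lo = v, hi = v, mass = 1),
                          n = length(values), bandwidth = 0),
                     class = "peak_set"))
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values) else bandwidth
  d <- stats::density(values, bw = bw, n = 2048L)
  x <- d$x; y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  maxima <- which(is_max)
  if (!length(maxima)) maxima <- which.max(y)
  # basin boundaries: minima between consecutive maxima, plus the ends
  bounds <- c(1L, vapply(seq_len(length(maxima) - 1L), function(i) {
    seg <- maxima[i]:maxima[i + 1L]
    seg[which.min(y[seg])]
  }, 0L), n)
  total <- sum(y)
  peaks <- lapply(seq_along(maxima), function(i) {
    lo_i <- bounds[i]; hi_i <- bounds[i + 1L]; m <- maxima[i]
    mass <- sum(y[lo_i:hi_i]) / total
    half <- y[m] / 2
    li <- m
    while (li > lo_i && y[li - 1L] >= half) li <- li - 1L
    ri <- m
    while (ri < hi_i && y[ri + 1L] >= half) ri <- ri + 1L
    data.frame(mode = x[m], lo = x[li], hi = x[ri], mass = mass)
  })
  peaks <- do.call(rbind, peaks)
  keep <- peaks$mass >= min_mass
  if (!any(keep)) keep <- which.max(peaks$mass)
  peaks <- peaks[keep, , drop = FALSE]
  peaks <- peaks[order(peaks$mode), ]
  rownames(peaks) <- NULL
  structure(list(axis = axis, peaks = peaks, n = length(values),
                 bandwidth = bw),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set (", x$axis, ", n = ", x$n, "):\n", sep = "")
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Primary peak of a peak set
#'
#' The highest-mass peak (ties: smallest mode). Used as the
#' speciation/divergence signal of a genome pair.
#'
#' @param ps `peak_set`.
#' @return one-row data.frame `mode`, `lo`, `hi`, `mass`.
#' @export
primary_peak <- function(ps) {
  p <- ps$peaks
  p[order(-p$mass, p$mode), ][1L, , drop = FALSE]
}
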