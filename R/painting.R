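#' Paint a modern genome by protochromosome of origin
#'
#' Each gene is labeled with the protochromosome carrying its family in the
#' ancestral genome (or left unpainted if the family is absent). Labels can
#' be smoothed by majority vote in a sliding window, and maximal painted
#' runs shorter than `min_segment` genes are absorbed into the flanking
#' majority label, which suppresses single-gene transposition noise while
#' keeping true translocations. Runs are emitted as half-open gene-rank
#' segments tiling each chromosome.
#'
#' @param genome `gene_orders` restricted to one genome (or pass `genome_id`).
#' @param ancestor `ancestor_genome` (columns `family_id`,
#'   `protochromosome_id`).
#' @param families `gene_families` mapping the genome's genes to families.
#' @param min_segment minimum painted run length in genes (default 5).
#' @param smooth_window sliding-window width for majority smoothing
#'   (default 1 = off).
#' @param genome_id optional genome to select out of `genome`.
#' @return `painting` data.frame: `chromosome`, `start`, `end`, `label`
#'   (`NA` = unpainted), segments tiling `0..n` per chromosome.
#' @export
paint <- function(genome, ancestor, families, min_segment = 5L,
                  smooth_window = 1L, genome_id = NULL) {
  if (!is.null(genome_id))
    genome <- genome[genome$genome == genome_id, , drop = FALSE]
  if (length(unique(genome$genome)) != 1L)
    stop("paint() expects a single genome; use genome_id to select one")
  fam2pc <- ancestor$protochromosome_id[!duplicated(ancestor$family_id)]
  names(fam2pc) <- ancestor$family_id[!duplicated(ancestor$family_id)]
  fmap <- family_map(families, drop_oversize = FALSE)
  g <- genome[order(genome$chromosome, genome$rank), ]
  fam <- unname(fmap[g$gene_id])
  lab <- rep(NA_character_, nrow(g))
  known <- !is.na(fam) & fam %in% names(fam2pc)
  lab[known] <- as.character(fam2pc[fam[known]])

  segs <- list()
  for (chr in unique(g$chromosome)) {
    l <- lab[g$chromosome == chr]
    if (smooth_window > 1L) l <- smooth_labels(l, smooth_window)
    l <- merge_short_runs(l, min_segment)
    r <- rle_runs(l)
    segs[[chr]] <- data.frame(chromosome = chr, start = r$start, end = r$end,
                              label = r$label, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, segs)
  rownames(res) <- NULL
  structure(res, class = c("painting", "data.frame"),
            genome = unique(g$genome),
            params = list(min_segment = min_segment,
                          smooth_window = smooth_window))
}

# majority vote in a centered window of painted labels; NA entries do not
# vote and are never overwritten
smooth_labels <- function(l, w) {
  n <- length(l)
  half <- (w - 1L) %/% 2L
  out <- l
  for (i in seq_len(n)) {
    if (is.na(l[i])) next
    win <- l[max(1L, i - half):min(n, i + half)]
    win <- win[!is.na(win)]
    tb <- table(win)
    best <- names(tb)[order(-tb, names(tb))][1L]
    if (tb[[best]] > length(win) / 2) out[i] <- best
  }
  out
}

# absorb painted runs shorter than min_segment into the flanking majority
# label (the longer painted flank; ties go left); unpainted runs are
# transparent and never merged. Iterates to a fixed point.
merge_short_runs <- function(l, min_segment) {
  if (min_segment <= 1L) return(l)
  repeat {
    r <- rle_runs(l)
    painted <- which(!is.na(r$label))
    short <- painted[r$end[painted] - r$start[painted] < min_segment]
    if (!length(short)) return(l)
    changed <- FALSE
    for (i in short) {
      left <- painted[painted < i]
      right <- painted[painted > i]
      lv <- if (length(left)) max(left) else NA_integer_
      rv <- if (length(right)) min(right) else NA_integer_
      pick <- NA_integer_
      if (!is.na(lv) && !is.na(rv)) {
        llen <- r$end[lv] - r$start[lv]
        rlen <- r$end[rv] - r$start[rv]
        pick <- if (rlen > llen) rv else lv
      } else if (!is.na(lv)) pick <- lv else if (!is.na(rv)) pick <- rv
      if (is.na(pick) || r$label[pick] == r$label[i]) next
      l[(r$start[i] + 1L):r$end[i]] <- r$label[pick]
      changed <- TRUE
      break  # recompute runs after each merge
    }
    if (!changed) return(l)
  }
}

rle_runs <- function(l) {
  n <- length(l)
  if (!n) return(list(start = integer(0), end = integer(0), label = character(0)))
  key <- ifelse(is.na(l), "\rNA", l)
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  label <- ifelse(r$values == "\rNA", NA_character_, r$values)
  list(start = start, end = as.integer(end), label = label)
}

#' Count inter-chromosomal exchanges ("choppiness") of a painting
#'
#' The exchange count is the number of boundaries between adjacent painted
#' segments with different protochromosome labels, summed over chromosomes.
#' Unpainted runs are transparent: a boundary across them counts once if
#' the flanking painted labels differ. Label changes at chromosome ends are
#' not boundaries, so the count is invariant to whole-chromosome reversal.
#'
#' @param painting `painting` data.frame.
#' @return `exchange_report`: list with `total` and `per_chromosome`
#'   data.frame.
#' @export
count_exchanges <- function(painting) {
  per <- vapply(split(painting, painting$chromosome), function(s) {
    s <- s[order(s$start), ]
    labs <- s$label[!is.na(s$label)]
    if (length(labs) < 2L) return(0L)
    sum(labs[-1L] != labs[-length(labs)])
  }, 0L)
  structure(list(total = sum(per),
                 per_chromosome = data.frame(chromosome = names(per),
                                             exchanges = unname(per),
                                             stringsAsFactors = FALSE),
                 genome = attr(painting, "genome")),
            class = "exchange_report")
}

#' @export
print.exchange_report <- function(x, ...) {
  cat("exchange_report", if (!is.null(x$genome)) paste0("(", x$genome, ")"),
      ": ", x$total, " inter-chromosomal exchanges\n", sep = "")
  invisible(x)
}
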