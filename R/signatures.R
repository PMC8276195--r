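# piRNA-specific sequence statistics: positional base composition over the
# first 15 nt, 1U/10A bias tests, the ping-pong 5' overlap signature,
# per-group length distributions and strand coverage.

#' Position frequency matrix over the first bases of a sequence set
#'
#' Sequences shorter than `positions` contribute to the positions they
#' cover. Frequencies are column-normalised; the matrix keeps the raw
#' counts and per-position totals as attributes so exact binomial tests can
#' be run downstream.
#'
#' @param sequences character vector of DNA sequences (T, not U).
#' @param positions number of 5' positions profiled (default 15).
#' @param pseudocount added to every cell before normalisation (default 0).
#' @return an object of class `pfm`: 4 x positions frequency matrix
#'   (rows A, C, G, T) with attributes `counts`, `n_at_position`,
#'   `n_sequences`.
#' @export
pfm <- function(sequences, positions = 15L, pseudocount = 0) {
  if (length(sequences) == 0) stop("empty sequence set")
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4, ncol = positions,
                   dimnames = list(bases, seq_len(positions)))
  maxp <- min(positions, max(nchar(sequences)))
  for (p in seq_len(maxp)) {
    covered <- substr(sequences, p, p)
    covered <- covered[covered != ""]
    tab <- table(factor(covered, levels = bases))
    counts[, p] <- as.numeric(tab)
  }
  n_at <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2,
                pmax(n_at + 4 * pseudocount, 1), "/")
  structure(freq, counts = counts, n_at_position = n_at,
            n_sequences = length(sequences), class = "pfm")
}

#' Information content of a position frequency matrix
#' @param x a `pfm`.
#' @return numeric vector of per-position information content in bits
#'   (0 to 2).
#' @export
pfm_information <- function(x) {
  stopifnot(inherits(x, "pfm"))
  f <- unclass(x)
  ent <- apply(f, 2, function(col) {
    col <- col[col > 0]
    -sum(col * log2(col))
  })
  2 - ent
}

#' Exact binomial test for a positional base bias
#'
#' Tests the observed fraction of `base` at `position` against a background
#' probability (default 0.25), using the sequences that actually cover the
#' position.
#'
#' @param x a `pfm`.
#' @param position 1-based position.
#' @param base one of A, C, G, T.
#' @param background null probability (default 0.25).
#' @return list with `fraction`, `n`, `p_value` (two-sided exact binomial).
#' @export
bias_test <- function(x, position, base, background = 0.25) {
  stopifnot(inherits(x, "pfm"))
  counts <- attr(x, "counts")
  if (position < 1 || position > ncol(counts)) {
    stop("position outside the profiled range")
  }
  n <- unname(attr(x, "n_at_position")[position])
  if (n == 0) stop("no sequence covers position ", position)
  k <- unname(counts[base, position])
  bt <- stats::binom.test(k, n, p = background)
  list(fraction = k / n, n = unname(n), p_value = bt$p.value)
}

#' Ping-pong 5' overlap signature
#'
#' For every opposite-strand read pair on the same chromosome, the overlap
#' is the distance from the plus read's 5' end to the minus read's 5' end
#' (its rightmost genomic coordinate) plus one; overlaps of 1--20 nt are
#' histogrammed, each pair weighted by the product of the reads' weights
#' (1/n_hits for multi-mapped reads). The signature statistic `z10` is the
#' z-score of the 10-nt bin against the other 19 bins — ping-pong amplified
#' piRNA pairs overlap by exactly 10 nt.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand` and
#'   optionally `weight` (default 1).
#' @param max_overlap largest overlap binned (default 20).
#' @return list with `overlap_counts` (named numeric, bins 1..max_overlap),
#'   `z10`, and `defined` (`FALSE` when no opposite-strand pairs exist or
#'   the off-bin spread is zero).
#' @export
pingpong <- function(alignments, max_overlap = 20L) {
  w <- if (is.null(alignments$weight)) rep(1, nrow(alignments)) else
    alignments$weight
  bins <- stats::setNames(numeric(max_overlap), seq_len(max_overlap))
  plus <- alignments$strand == "+"
  minus <- alignments$strand == "-"
  for (chr in unique(alignments$chrom)) {
    pc <- plus & alignments$chrom == chr
    mc <- minus & alignments$chrom == chr
    if (!any(pc) || !any(mc)) next
    # 5' end: start for plus reads, end for minus reads
    wp <- tapply(w[pc], alignments$start[pc], sum)
    wm <- tapply(w[mc], alignments$end[mc], sum)
    p5 <- as.integer(names(wp))
    m5_map <- stats::setNames(as.numeric(wm), names(wm))
    for (k in seq_len(max_overlap)) {
      partner <- as.character(p5 + k - 1L)
      hit <- partner %in% names(m5_map)
      if (any(hit)) {
        bins[k] <- bins[k] + sum(as.numeric(wp)[hit] * m5_map[partner[hit]])
      }
    }
  }
  others <- bins[-10L]
  defined <- sum(bins) > 0 && stats::sd(others) > 0
  z10 <- if (defined) (bins[[10]] - mean(others)) / stats::sd(others) else
    NA_real_
  list(overlap_counts = bins, z10 = z10, defined = defined)
}

#' Read-length distribution of expressed features per group and method
#'
#' @param feature_lengths named integer vector (feature id -> length in nt).
#' @param expressed named list: `expressed[[method]][[group]]` is a
#'   character vector of expressed feature ids.
#' @return long data.frame: `method`, `group`, `length`, `n_features`.
#' @export
length_distribution <- function(feature_lengths, expressed) {
  out <- list()
  for (m in names(expressed)) {
    for (g in names(expressed[[m]])) {
      ids <- intersect(expressed[[m]][[g]], names(feature_lengths))
      if (!length(ids)) next
      tab <- table(feature_lengths[ids])
      out[[length(out) + 1L]] <- data.frame(
        method = m, group = g, length = as.integer(names(tab)),
        n_features = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(method = character(), group = character(),
                      length = integer(), n_features = integer()))
  }
  do.call(rbind, out)
}

#' Per-base strand coverage over a genomic region
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand`,
#'   optional `weight`.
#' @param chrom,start,end region (1-based closed), within genome bounds.
#' @param chrom_length length of the chromosome, for bounds checking
#'   (optional).
#' @return list with `plus` and `minus`: numeric vectors of length
#'   `end - start + 1`.
#' @export
strand_coverage <- function(alignments, chrom, start, end,
                            chrom_length = NULL) {
  if (start < 1 || end < start ||
      (!is.null(chrom_length) && end > chrom_length)) {
    stop("region outside genome bounds")
  }
  len <- end - start + 1L
  w <- if (is.null(alignments$weight)) rep(1, nrow(alignments)) else
    alignments$weight
  cov_one <- function(strand) {
    sel <- alignments$chrom == chrom & alignments$strand == strand &
      alignments$end >= start & alignments$start <= end
    v <- numeric(len)
    if (any(sel)) {
      s <- pmax(alignments$start[sel], start) - start + 1L
      e <- pmin(alignments$end[sel], end) - start + 1L
      ww <- w[sel]
      for (i in seq_along(s)) v[s[i]:e[i]] <- v[s[i]:e[i]] + ww[i]
    }
    v
  }
  list(plus = cov_one("+"), minus = cov_one("-"))
}

#' Draw a simple information-content sequence logo
#'
#' Stacked-letter logo of a position frequency matrix scaled by information
#' content, using base graphics (T drawn, not U).
#'
#' @param x a `pfm`.
#' @param main plot title.
#' @return invisibly, the information content vector.
#' @export
plot_logo <- function(x, main = "sequence logo") {
  info <- pfm_information(x)
  f <- unclass(x)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  graphics::plot(NULL, xlim = c(0.5, ncol(f) + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", main = main)
  for (p in seq_len(ncol(f))) {
    y <- 0
    ord <- order(f[, p])
    for (b in rownames(f)[ord]) {
      h <- f[b, p] * info[p]
      if (h > 1e-3) {
        graphics::text(p, y + h / 2, b, col = cols[[b]],
                       cex = 0.6 + 1.6 * h, font = 2)
        y <- y + h
      }
    }
  }
  invisible(info)
}
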