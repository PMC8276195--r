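# Complementarity-based prediction of mRNA targets for differentially
# expressed piRNAs.

# classify one duplex alignment: piRNA p (5'->3') against a candidate site
# m (5'->3', antiparallel): p[i] pairs with m[L - i + 1]
duplex_profile <- function(p_chars, m_chars_rev) {
  wc <- (p_chars == "A" & m_chars_rev == "T") |
    (p_chars == "T" & m_chars_rev == "A") |
    (p_chars == "C" & m_chars_rev == "G") |
    (p_chars == "G" & m_chars_rev == "C")
  wobble <- (p_chars == "G" & m_chars_rev == "T") |
    (p_chars == "T" & m_chars_rev == "G")
  list(wc = wc, wobble = wobble & !wc)
}

#' Predict piRNA target sites by antisense complementarity
#'
#' Scans each transcript region for antiparallel duplexes with a piRNA:
#' positions 2--11 of the piRNA (the seed) must be perfectly Watson-Crick
#' complementary; outside the seed up to `max_wobbles` G:U wobbles and up to
#' `max_mismatches` mismatches are tolerated. The score is
#' `matched + 0.5 * wobbles`. The scoring scheme is versioned in the output
#' so hit lists remain comparable across runs.
#'
#' @param pirnas data.frame with `id`, `sequence` (mature piRNA, 5'->3'),
#'   or a named character vector; must be non-empty.
#' @param regions data.frame with `id` (transcript), `region` (5UTR, CDS or
#'   3UTR) and `sequence` (5'->3'), or a named character vector with
#'   `id|region` names.
#' @param seed_span integer range of perfectly pairing piRNA positions
#'   (default 2:11).
#' @param max_mismatches maximum non-pairing positions (default 4).
#' @param max_wobbles maximum G:U pairs outside the seed (default 4).
#' @return data.frame of hits sorted by decreasing score: `pirna_id`,
#'   `transcript_id`, `region`, `start` (1-based in the region), `matched`,
#'   `wobbles`, `mismatches`, `score`; attribute `scoring` names the
#'   scheme. A `region_tally` attribute counts hits per region class.
#' @export
predict_targets <- function(pirnas, regions, seed_span = 2:11,
                            max_mismatches = 4L, max_wobbles = 4L) {
  if (is.character(pirnas)) {
    pirnas <- data.frame(id = names(pirnas), sequence = unname(pirnas),
                         stringsAsFactors = FALSE)
  }
  if (is.character(regions)) {
    parts <- strsplit(names(regions), "|", fixed = TRUE)
    regions <- data.frame(
      id = vapply(parts, `[[`, character(1), 1L),
      region = vapply(parts, function(p) if (length(p) > 1) p[2] else "CDS",
                      character(1)),
      sequence = unname(regions), stringsAsFactors = FALSE)
  }
  if (nrow(pirnas) == 0) stop("empty piRNA set")
  hits <- list()
  for (pi in seq_len(nrow(pirnas))) {
    pseq <- chartr("U", "T", toupper(pirnas$sequence[pi]))
    L <- nchar(pseq)
    p_chars <- strsplit(pseq, "")[[1]]
    seed <- seed_span[seed_span <= L]
    for (ri in seq_len(nrow(regions))) {
      rseq <- chartr("U", "T", toupper(regions$sequence[ri]))
      rl <- nchar(rseq)
      if (rl < L) next
      r_chars <- strsplit(rseq, "")[[1]]
      for (s in seq_len(rl - L + 1L)) {
        # site m = region[s .. s+L-1]; antiparallel: p[i] pairs m[s+L-i]
        m_rev <- r_chars[(s + L - 1L):s]
        prof <- duplex_profile(p_chars, m_rev)
        if (!all(prof$wc[seed])) next
        wob <- sum(prof$wobble)
        mm <- L - sum(prof$wc) - wob
        if (mm > max_mismatches || wob > max_wobbles) next
        hits[[length(hits) + 1L]] <- data.frame(
          pirna_id = pirnas$id[pi], transcript_id = regions$id[ri],
          region = regions$region[ri], start = s,
          matched = sum(prof$wc), wobbles = wob, mismatches = mm,
          score = sum(prof$wc) + 0.5 * wob, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(pirna_id = character(), transcript_id = character(),
               region = character(), start = integer(), matched = integer(),
               wobbles = integer(), mismatches = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$pirna_id, out$transcript_id, out$start),
             , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scoring") <- "seed2-11_wc+0.5wobble_v1"
  attr(out, "region_tally") <- table(factor(out$region,
                                            levels = c("5UTR", "CDS",
                                                       "3UTR")))
  out
}
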