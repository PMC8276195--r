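# Shared fixtures (built once per test run) and independent oracles.

.cache <- new.env(parent = emptyenv())

default_fix <- function() {
  if (is.null(.cache$fix)) {
    .cache$fix <- make_genome_and_databases(fixture_spec())
  }
  .cache$fix
}

default_track <- function() {
  if (is.null(.cache$track)) {
    fix <- default_fix()
    .cache$track <- suppressMessages(
      forge(run_config(), fix$pirnabank, fix$rnacentral, fix$genome,
            fix$gene_gtf, fix$te_bed))
  }
  .cache$track
}

# pure-R sliding-window scan: every full-length ungapped placement of q on
# either strand with <= max_mismatch mismatches and enough matched bases
brute_scan <- function(q, genome, min_match, max_mismatch) {
  out <- list()
  qlen <- nchar(q)
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp(q)
      qc <- strsplit(qq, "")[[1]]
      L <- nchar(s)
      if (L < qlen) next
      for (p in seq_len(L - qlen + 1L)) {
        w <- strsplit(substr(s, p, p + qlen - 1L), "")[[1]]
        mm <- sum(w != qc | qc == "N")
        if (mm <= max_mismatch && qlen - mm >= min_match) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = p, end = p + qlen - 1L,
            strand = strand, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer())
}

# Biostrings-based sliding scan (independent C implementation), for larger
# genomes than the pure-R oracle can handle
biostrings_scan <- function(q, genome, min_match, max_mismatch) {
  out <- list()
  qlen <- nchar(q)
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp(q)
      m <- Biostrings::matchPattern(qq, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      starts <- Biostrings::start(m)
      mm <- vapply(seq_along(m), function(i) {
        Biostrings::neditAt(qq, subj, at = starts[i])
      }, integer(1))
      keep <- qlen - mm >= min_match
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = starts[keep],
        end = starts[keep] + qlen - 1L, strand = strand,
        mismatches = mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer())
}

hit_key <- function(df) {
  sort(paste(df$chrom, df$start, df$end, df$strand, df$mismatches))
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

rand_seq <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

quiet <- function(expr) suppressMessages(expr)
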