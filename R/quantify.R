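# Read pre-processing and the two quantification tracks: genomic
# (ungapped alignment + feature counting) and transcriptomic
# (equivalence-class EM with bootstrap uncertainty).

#' Trim a 3' adapter from reads
#'
#' Finds the leftmost occurrence of the adapter in each read (including a
#' prefix of the adapter reaching the read end) whose per-alignment error
#' rate is at most `max_error_rate`, with a minimum overlap of
#' `min_overlap` bases, and removes it together with everything after it.
#' Reads shorter than `min_read_len` after trimming are discarded.
#'
#' @param reads data.frame with `id`, `sequence`, `quality` (see
#'   [read_fastq()]).
#' @param adapter adapter sequence (non-empty).
#' @param max_error_rate maximum mismatch fraction over the overlapped bases
#'   (default 0.1).
#' @param min_read_len minimum insert length kept (default 15).
#' @param min_overlap minimum adapter overlap (default 3).
#' @return list with `reads` (trimmed data.frame plus a `trimmed_bases`
#'   column) and `stats` (named integer: `input`, `trimmed`, `discarded`,
#'   `kept`).
#' @export
trim_reads <- function(reads, adapter, max_error_rate = 0.1,
                       min_read_len = 15L, min_overlap = 3L) {
  stopifnot(nchar(adapter) > 0)
  adapter <- chartr("U", "T", toupper(adapter))
  cut <- .cpp_trim_adapter(reads$sequence, adapter, max_error_rate,
                           as.integer(min_overlap))
  out <- reads
  out$trimmed_bases <- nchar(reads$sequence) - cut
  out$sequence <- substr(reads$sequence, 1L, cut)
  out$quality <- substr(reads$quality, 1L, cut)
  keep <- nchar(out$sequence) >= min_read_len
  stats <- c(input = nrow(reads), trimmed = sum(out$trimmed_bases > 0),
             discarded = sum(!keep), kept = sum(keep))
  list(reads = out[keep, , drop = FALSE], stats = stats)
}

#' Align trimmed reads to the genome
#'
#' Ungapped, splice-free placements on both strands with at least
#' `min_match` matched bases and at most `max_mismatch` mismatches; reads
#' with more than `max_loci` placements are reported unaligned. Reads with
#' non-ACGTN characters are skipped with a message. Identical read sequences
#' are aligned once and the placements propagated.
#'
#' @param reads trimmed read data.frame (`id`, `sequence`, `quality`).
#' @param genome named character vector of chromosome sequences or a
#'   `genome_ref`.
#' @param min_match,max_mismatch,max_loci alignment contract (defaults
#'   14/1/100).
#' @return list with `hits` (data.frame: `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `n_hits`, `weight` = 1/n_hits, `sequence`),
#'   and `stats` (named integer: `input`, `unique`, `multi`, `unaligned`).
#' @export
align_reads <- function(reads, genome, min_match = 14L, max_mismatch = 1L,
                        max_loci = 100L) {
  seqs <- if (is.list(genome) && !is.null(genome$sequences)) {
    genome$sequences
  } else genome
  ok <- !grepl("[^ACGTN]", reads$sequence)
  if (any(!ok)) {
    message("align_reads: skipping ", sum(!ok), " read(s) with non-ACGTN ",
            "characters")
    reads <- reads[ok, , drop = FALSE]
  }
  uniq <- unique(reads$sequence)
  res <- .cpp_find_hits(uniq, unname(seqs), as.integer(min_match),
                        as.integer(max_mismatch), as.integer(max_loci), TRUE)
  n_loci <- ifelse(res$exceeds_max_loci, 0L, res$n_loci)
  per_read_idx <- match(reads$sequence, uniq)
  read_nhits <- n_loci[per_read_idx]
  # expand unique-sequence hits to reads, vectorised: hit rows are already
  # grouped by query in the C++ output
  ord <- order(res$query)
  q_sorted <- res$query[ord]
  per_q_n <- tabulate(q_sorted, nbins = length(uniq))
  q_first <- cumsum(c(1L, per_q_n[-length(per_q_n)]))
  keep_reads <- which(read_nhits > 0L)
  if (length(keep_reads)) {
    uidx <- per_read_idx[keep_reads]
    nvec <- per_q_n[uidx]
    rows <- ord[sequence(nvec, from = q_first[uidx])]
    hits <- data.frame(
      read_id = rep(reads$id[keep_reads], nvec),
      chrom = names(seqs)[res$subject[rows]],
      start = res$start[rows],
      end = res$start[rows] +
        rep(nchar(reads$sequence[keep_reads]), nvec) - 1L,
      strand = ifelse(res$strand_code[rows] == 1L, "-", "+"),
      mismatches = res$mismatches[rows],
      n_hits = rep(nvec, nvec),
      sequence = rep(reads$sequence[keep_reads], nvec),
      stringsAsFactors = FALSE
    )
  } else {
    hits <- data.frame(read_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), mismatches = integer(),
                       n_hits = integer(), sequence = character(),
                       stringsAsFactors = FALSE)
  }
  hits$weight <- 1 / hits$n_hits
  stats <- c(input = nrow(reads),
             unique = sum(read_nhits == 1L),
             multi = sum(read_nhits > 1L),
             unaligned = sum(read_nhits == 0L))
  list(hits = hits, stats = stats)
}

#' Count read placements over annotation features
#'
#' A placement is assigned to a feature when its interval overlaps the
#' feature by at least 1 bp on the same strand; a placement overlapping more
#' than one distinct feature (gene id) is ambiguous and dropped. Multi-locus
#' placements of the same feature count once per placement. Multi-placed
#' reads are handled per `mode`: `unique` drops them, `all` adds 1 per
#' assigned placement, `fractional` adds 1/n_hits per assigned placement.
#'
#' @param alignments `hits` data.frame from [align_reads()].
#' @param track an `annotation_track` or feature `GRanges` with `gene_id`.
#' @param mode `"fractional"` (default), `"all"` or `"unique"`.
#' @return list with `counts` (named numeric vector over all track features)
#'   and `stats` (`assigned`, `ambiguous`, `unassigned` placement tallies).
#' @export
count_features <- function(alignments, track,
                           mode = c("fractional", "all", "unique")) {
  mode <- match.arg(mode)
  features <- if (inherits(track, "annotation_track")) track$features else
    track
  feature_ids <- unique(features$gene_id)
  counts <- stats::setNames(numeric(length(feature_ids)), feature_ids)
  if (nrow(alignments) == 0) {
    return(list(counts = counts,
                stats = c(assigned = 0, ambiguous = 0, unassigned = 0)))
  }
  if (!all(alignments$chrom %in%
             GenomeInfoDb::seqlevels(features))) {
    extra <- setdiff(unique(alignments$chrom),
                     GenomeInfoDb::seqlevels(features))
    # placements on chromosomes absent from the annotation are unassignable
    # but not an error; a full namespace mismatch is
    if (all(!alignments$chrom %in% GenomeInfoDb::seqlevels(features))) {
      stop("alignment and annotation share no chromosome: ",
           paste(utils::head(extra, 3), collapse = ", "))
    }
  }
  gr <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(alignments$start,
                                                alignments$end),
                               strand = alignments$strand)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, features, ignore.strand = FALSE))
  q <- S4Vectors::queryHits(ov)
  fid <- features$gene_id[S4Vectors::subjectHits(ov)]
  # distinct features per placement
  key <- paste0(q, "\r", fid)
  dedup <- !duplicated(key)
  q <- q[dedup]; fid <- fid[dedup]
  nfeat <- tabulate(q, nbins = nrow(alignments))
  ambiguous <- nfeat > 1L
  unassigned <- nfeat == 0L
  keep <- !ambiguous[q]
  q <- q[keep]; fid <- fid[keep]
  w <- switch(mode,
              fractional = alignments$weight[q],
              all = rep(1, length(q)),
              unique = ifelse(alignments$n_hits[q] == 1L, 1, 0))
  add <- tapply(w, fid, sum)
  counts[names(add)] <- counts[names(add)] + as.numeric(add)
  list(counts = counts,
       stats = c(assigned = sum(nfeat == 1L), ambiguous = sum(ambiguous),
                 unassigned = sum(unassigned)))
}

#' Build a counts matrix for several samples
#'
#' Convenience wrapper running [trim_reads()], [align_reads()] and
#' [count_features()] per sample.
#'
#' @param fastqs named character vector of FASTQ paths (names = sample ids).
#' @param genome genome sequences.
#' @param track annotation track.
#' @param adapter adapter sequence, or `NULL` for pre-trimmed reads.
#' @param config a [run_config()].
#' @return list with `counts` (features x samples matrix), `stats`
#'   (per-sample data.frame), `alignments` (list of per-sample hit tables).
#' @export
quantify_genomic <- function(fastqs, genome, track, adapter = NULL,
                             config = run_config()) {
  qc <- config$quant
  cols <- list(); stats <- list(); alns <- list()
  for (s in names(fastqs)) {
    reads <- read_fastq(fastqs[[s]])
    tstats <- c(input = nrow(reads), trimmed = NA, discarded = NA,
                kept = nrow(reads))
    if (!is.null(adapter)) {
      tr <- trim_reads(reads, adapter, qc$adapter_max_error_rate,
                       qc$min_read_len, qc$adapter_min_overlap)
      reads <- tr$reads
      tstats <- tr$stats
    }
    al <- align_reads(reads, genome, qc$min_match, qc$max_mismatch,
                      qc$max_loci)
    ct <- count_features(al$hits, track, qc$count_mode)
    cols[[s]] <- ct$counts
    alns[[s]] <- al$hits
    stats[[s]] <- data.frame(sample = s, t(tstats), t(al$stats),
                             t(ct$stats), stringsAsFactors = FALSE)
    log_stage("quant_genomic", sample = s, kept = tstats[["kept"]],
              assigned = ct$stats[["assigned"]])
  }
  counts <- do.call(cbind, cols)
  list(counts = counts, stats = do.call(rbind, stats), alignments = alns)
}

# map read sequences onto transcripts (sense, ungapped, <=max_mismatch) and
# collapse into equivalence classes
build_equivalence_classes <- function(read_seqs, tx_ids, tx_seqs,
                                      min_match = 14L, max_mismatch = 1L) {
  uniq <- unique(read_seqs)
  res <- .cpp_find_hits(uniq, tx_seqs, as.integer(min_match),
                        as.integer(max_mismatch),
                        .Machine$integer.max, FALSE)
  tx_by_query <- lapply(split(res$subject, factor(res$query,
                                                  levels = seq_along(uniq))),
                        function(s) sort(unique(s)))
  read_class <- tx_by_query[match(read_seqs, uniq)]
  keys <- vapply(read_class, paste, character(1), collapse = ",")
  mapped <- lengths(read_class) > 0
  tab <- table(keys[mapped])
  class_tx <- lapply(strsplit(names(tab), ",", fixed = TRUE), as.integer)
  list(transcript_sets = class_tx, read_counts = as.integer(tab),
       n_mapped = sum(mapped), n_unmapped = sum(!mapped))
}

em_abundance <- function(class_tx, class_counts, n_tx, tol = 1e-8,
                         max_iter = 1000L) {
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(class_tx), lengths(class_tx)),
    j = unlist(class_tx), x = 1,
    dims = c(length(class_tx), n_tx))
  n <- class_counts
  total <- sum(n)
  p <- rep(1 / n_tx, n_tx)
  ll <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(M %*% p)
    ll <- sum(n * log(denom))
    ll_trace <- c(ll_trace, ll)
    p_new <- p * as.numeric(Matrix::crossprod(M, n / denom)) / total
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  list(counts = p * total, proportions = p, loglik = ll,
       ll_trace = ll_trace, iterations = length(ll_trace))
}

#' Transcript abundance by equivalence-class EM
#'
#' Reads are mapped to every transcript containing them as an ungapped
#' near-substring (at most `max_mismatch` mismatches, sense strand) and
#' collapsed into equivalence classes; expected counts per transcript are
#' estimated by EM from uniform initial abundances, and their uncertainty by
#' multinomial resampling of the class counts (`n_bootstraps` seeded
#' replicates).
#'
#' @param reads trimmed read data.frame (`id`, `sequence`) or character
#'   vector of read sequences.
#' @param transcripts data.frame with `id`, `sequence` (the forge FASTA), or
#'   a named character vector.
#' @param n_bootstraps number of bootstrap replicates (default 100).
#' @param seed RNG seed for the bootstrap.
#' @param em_tol convergence tolerance on the abundance-proportion change
#'   (default 1e-8).
#' @param em_max_iter iteration cap (default 1000).
#' @param min_match,max_mismatch mapping contract (defaults 14/1).
#' @return list with `counts` (named expected counts; sums to the number of
#'   mapped reads), `bootstrap_sd` (named; `NA` when `n_bootstraps` = 0),
#'   `loglik_trace`, `n_mapped`, `n_unmapped`, `classes`.
#' @export
quantify_transcripts <- function(reads, transcripts, n_bootstraps = 100L,
                                 seed = 1L, em_tol = 1e-8,
                                 em_max_iter = 1000L, min_match = 14L,
                                 max_mismatch = 1L) {
  read_seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (is.data.frame(transcripts)) {
    tx_ids <- transcripts$id
    tx_seqs <- transcripts$sequence
  } else {
    tx_ids <- names(transcripts)
    tx_seqs <- unname(transcripts)
  }
  if (length(tx_seqs) == 0) stop("empty transcript set")
  ec <- build_equivalence_classes(read_seqs, tx_ids, tx_seqs, min_match,
                                  max_mismatch)
  zero <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  if (length(ec$transcript_sets) == 0) {
    return(list(counts = zero, bootstrap_sd = zero + NA, loglik_trace = NULL,
                n_mapped = 0L, n_unmapped = ec$n_unmapped, classes = ec))
  }
  fit <- em_abundance(ec$transcript_sets, ec$read_counts, length(tx_ids),
                      em_tol, em_max_iter)
  counts <- stats::setNames(fit$counts, tx_ids)
  boot_sd <- zero + NA
  if (n_bootstraps > 0) {
    total <- sum(ec$read_counts)
    prob <- ec$read_counts / total
    boot <- matrix(0, nrow = n_bootstraps, ncol = length(tx_ids))
    set.seed(seed)
    for (b in seq_len(n_bootstraps)) {
      nb <- as.integer(stats::rmultinom(1, total, prob))
      keep <- nb > 0
      fb <- em_abundance(ec$transcript_sets[keep], nb[keep], length(tx_ids),
                         em_tol, em_max_iter)
      boot[b, ] <- fb$counts
    }
    boot_sd <- stats::setNames(apply(boot, 2, stats::sd), tx_ids)
  }
  list(counts = counts, bootstrap_sd = boot_sd,
       loglik_trace = fit$ll_trace, n_mapped = ec$n_mapped,
       n_unmapped = ec$n_unmapped, classes = ec)
}

#' Transcriptomic quantification of several samples
#'
#' @param fastqs named character vector of FASTQ paths.
#' @param transcripts transcript table or named character vector.
#' @param adapter adapter sequence or `NULL`.
#' @param config a [run_config()].
#' @return list with `counts` (matrix), `bootstrap_sd` (matrix), `stats`.
#' @export
quantify_tx_samples <- function(fastqs, transcripts, adapter = NULL,
                                config = run_config()) {
  qc <- config$quant
  cols <- list(); sds <- list(); stats <- list()
  for (s in names(fastqs)) {
    reads <- read_fastq(fastqs[[s]])
    if (!is.null(adapter)) {
      reads <- trim_reads(reads, adapter, qc$adapter_max_error_rate,
                          qc$min_read_len, qc$adapter_min_overlap)$reads
    }
    q <- quantify_transcripts(reads, transcripts, qc$n_bootstraps,
                              seed = config$seed + match(s, names(fastqs)),
                              em_tol = qc$em_tol,
                              em_max_iter = qc$em_max_iter,
                              min_match = qc$min_match,
                              max_mismatch = qc$max_mismatch)
    cols[[s]] <- q$counts
    sds[[s]] <- q$bootstrap_sd
    stats[[s]] <- data.frame(sample = s, mapped = q$n_mapped,
                             unmapped = q$n_unmapped,
                             stringsAsFactors = FALSE)
    log_stage("quant_tx", sample = s, mapped = q$n_mapped)
  }
  list(counts = do.call(cbind, cols), bootstrap_sd = do.call(cbind, sds),
       stats = do.call(rbind, stats))
}

#' Consensus of expressed features across the two quantification tracks
#'
#' A feature is "expressed" in a track when it passes the low-expression
#' filter ([filter_low()]) of that track's count matrix; the consensus is
#' the union or intersection of the two expressed sets.
#'
#' @param genomic_counts,tx_counts features x samples matrices over the same
#'   samples.
#' @param mode `"union"` or `"intersection"`.
#' @param cpm_threshold,min_samples filter parameters (see [filter_low()]).
#' @return list with `features` (character vector), `genomic`, `tx` (the two
#'   expressed sets), `sizes` (named integer).
#' @export
consensus_expressed <- function(genomic_counts, tx_counts,
                                mode = c("union", "intersection"),
                                cpm_threshold = 1, min_samples = 1L) {
  mode <- match.arg(mode)
  if (!setequal(colnames(genomic_counts), colnames(tx_counts))) {
    stop("the two count matrices cover different samples")
  }
  g <- rownames(filter_low(genomic_counts, cpm_threshold,
                           min_samples)$counts)
  t <- rownames(filter_low(tx_counts, cpm_threshold, min_samples)$counts)
  feats <- if (mode == "union") union(g, t) else intersect(g, t)
  log_stage("consensus", mode = mode, genomic = length(g), tx = length(t),
            consensus = length(feats))
  list(features = sort(feats), genomic = sort(g), tx = sort(t),
       sizes = c(genomic = length(g), tx = length(t),
                 consensus = length(feats)))
}
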