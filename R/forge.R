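# Annotation forging: merge a piRNA database with a general sncRNA database
# into one harmonised GTF/FASTA track with region, multimapping, embedded and
# transposable-element metadata.

#' Parse a database FASTA into a sequence-record table
#'
#' Headers may be plain ids or `id|biotype`; records without a biotype field
#' get `default_biotype`.
#'
#' @param fasta data.frame from [read_fasta()] or a path.
#' @param source_db provenance label, e.g. `"pirnabank"` or `"rnacentral"`.
#' @param default_biotype biotype for headers without a `|biotype` suffix.
#' @return record table: `primary_id`, `alias_ids`, `sequence`, `biotype`,
#'   `source_db`, `length`.
#' @export
db_records <- function(fasta, source_db, default_biotype = "piRNA") {
  if (is.character(fasta) && length(fasta) == 1) fasta <- read_fasta(fasta)
  parts <- strsplit(fasta$id, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  bio <- vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else default_biotype
  }, character(1))
  data.frame(primary_id = ids, alias_ids = ids, sequence = fasta$sequence,
             biotype = bio, source_db = source_db,
             length = nchar(fasta$sequence), stringsAsFactors = FALSE)
}

join_ids <- function(x) paste(sort(unique(x)), collapse = ";")

split_ids <- function(x) unlist(strsplit(x, ";", fixed = TRUE))

#' Collapse duplicated database sequences
#'
#' One output record per distinct sequence string; all ids sharing the
#' sequence become aliases, the first id in input order stays primary.
#' Idempotent.
#'
#' @param records a record table (see [db_records()]).
#' @return collapsed record table in order of first occurrence.
#' @export
collapse_sequences <- function(records) {
  if (nrow(records) == 0) return(records)
  first <- !duplicated(records$sequence)
  grp <- match(records$sequence, records$sequence[first])
  out <- records[first, , drop = FALSE]
  agg <- function(col) {
    v <- vapply(split(records[[col]], grp),
                function(x) join_ids(split_ids(x)), character(1))
    unname(v[as.character(seq_len(nrow(out)))])
  }
  out$alias_ids <- agg("alias_ids")
  out$biotype <- agg("biotype")
  out$source_db <- agg("source_db")
  rownames(out) <- NULL
  out
}

#' Realign sequences to a genome, ungapped
#'
#' Every full-length ungapped placement on either strand with at least
#' `min_match` matched bases and at most `max_mismatch` mismatches is
#' reported. Sequences with more than `max_loci` placements are treated as
#' unmapped (no hits, flagged), mirroring an aligner's
#' too-many-multimapping-loci behaviour.
#'
#' @param records record table (or character vector of sequences).
#' @param genome named character vector of chromosome sequences, or a
#'   `genome_ref`.
#' @param min_match minimum matched bases (sequence length minus mismatches).
#' @param max_mismatch mismatch budget.
#' @param max_loci multimapping cap.
#' @return list with `hits` (data.frame: `seq_id`, `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `matched_bases`), `n_loci` (named integer,
#'   placement count per sequence), `exceeds_max_loci` (named logical).
#' @export
realign_ungapped <- function(records, genome, min_match = 16L,
                             max_mismatch = 0L, max_loci = 100L) {
  if (is.character(records)) {
    records <- data.frame(primary_id = paste0("seq", seq_along(records)),
                          sequence = records, stringsAsFactors = FALSE)
  }
  seqs <- if (is.list(genome) && !is.null(genome$sequences)) {
    genome$sequences
  } else genome
  bad <- grepl("[^ACGTN]", records$sequence)
  if (any(bad)) {
    stop("sequence with non-ACGTN characters: ",
         records$primary_id[which(bad)[1]])
  }
  res <- .cpp_find_hits(records$sequence, unname(seqs),
                        as.integer(min_match), as.integer(max_mismatch),
                        as.integer(max_loci), TRUE)
  qlen <- nchar(records$sequence)[res$query]
  hits <- data.frame(
    seq_id = records$primary_id[res$query],
    chrom = names(seqs)[res$subject],
    start = res$start,
    end = res$start + qlen - 1L,
    strand = ifelse(res$strand_code == 1L, "-", "+"),
    mismatches = res$mismatches,
    matched_bases = qlen - res$mismatches,
    stringsAsFactors = FALSE
  )
  n_loci <- stats::setNames(res$n_loci, records$primary_id)
  exceeds <- stats::setNames(res$exceeds_max_loci, records$primary_id)
  list(hits = hits, n_loci = n_loci, exceeds_max_loci = exceeds)
}

#' Keep sequences shorter than a length bound
#' @param records record table.
#' @param max_len exclusive upper bound in nt (default 100).
#' @return filtered record table.
#' @export
length_filter <- function(records, max_len = 100L) {
  records[records$length < max_len, , drop = FALSE]
}

non_pirna_biotypes <- function(biotype) {
  setdiff(unique(split_ids(biotype)), "piRNA")
}

#' Re-classify piRNA-database biotypes from a general sncRNA database
#'
#' A piRNA-database record whose sequence exactly matches a record of the
#' general database carrying a non-piRNA biotype takes that biotype
#' (piRNA-sized fragments of rRNA/tRNA/snRNA/snoRNA/YRNA and miRNA
#' intermediates are frequent contaminants of piRNA databases). A sequence
#' matching two different non-piRNA biotypes is flagged ambiguous and left as
#' piRNA.
#'
#' @param pirnabank_records,rnacentral_records collapsed record tables.
#' @return list with `records` (re-classified piRNA-database table) and
#'   `log` (data.frame: `primary_id`, `old_biotype`, `new_biotype`,
#'   `matched_id`, `status` in reclassified/ambiguous).
#' @export
reclassify_biotypes <- function(pirnabank_records, rnacentral_records) {
  out <- pirnabank_records
  idx <- match(out$sequence, rnacentral_records$sequence)
  log_rows <- list()
  for (i in which(!is.na(idx))) {
    rc <- rnacentral_records[idx[i], ]
    others <- non_pirna_biotypes(rc$biotype)
    if (length(others) == 1L) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        primary_id = out$primary_id[i], old_biotype = out$biotype[i],
        new_biotype = others, matched_id = rc$primary_id,
        status = "reclassified", stringsAsFactors = FALSE)
      out$biotype[i] <- others
    } else if (length(others) > 1L) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        primary_id = out$primary_id[i], old_biotype = out$biotype[i],
        new_biotype = "piRNA", matched_id = rc$primary_id,
        status = "ambiguous", stringsAsFactors = FALSE)
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(primary_id = character(), old_biotype = character(),
               new_biotype = character(), matched_id = character(),
               status = character(), stringsAsFactors = FALSE)
  list(records = out, log = log_df)
}

#' Integrate the piRNA database into the general sncRNA database
#'
#' The merged set is all general-database records plus the piRNA-database
#' records shorter than `pirnabank_max_len` (mature piRNAs are 21--35 nt;
#' longer piRNA-database entries are dropped). Records with an identical
#' sequence in both sources become one feature carrying both provenance tags
#' and all alias ids, with the general-database id as primary.
#'
#' @param pirnabank_records,rnacentral_records collapsed, length-filtered,
#'   re-classified record tables.
#' @param pirnabank_max_len exclusive length bound for piRNA-database
#'   integration (default 69).
#' @return list with `records` (merged table) and `counts` (named integer:
#'   `common`, `rnacentral_only`, `pirnabank_only`).
#' @export
integrate_databases <- function(pirnabank_records, rnacentral_records,
                                pirnabank_max_len = 69L) {
  pb <- pirnabank_records[pirnabank_records$length < pirnabank_max_len, ,
                          drop = FALSE]
  idx <- match(pb$sequence, rnacentral_records$sequence)
  common_pb <- pb[!is.na(idx), , drop = FALSE]
  only_pb <- pb[is.na(idx), , drop = FALSE]
  out <- rnacentral_records
  if (nrow(common_pb)) {
    j <- idx[!is.na(idx)]
    out$alias_ids[j] <- mapply(function(a, b) join_ids(c(split_ids(a),
                                                         split_ids(b))),
                               out$alias_ids[j], common_pb$alias_ids)
    out$source_db[j] <- mapply(function(a, b) join_ids(c(split_ids(a),
                                                         split_ids(b))),
                               out$source_db[j], common_pb$source_db)
  }
  merged <- rbind(out, only_pb)
  dup <- duplicated(merged$primary_id)
  if (any(dup)) {
    id <- merged$primary_id[dup][1]
    seqs <- unique(merged$sequence[merged$primary_id == id])
    if (length(seqs) > 1) {
      stop("id '", id, "' maps to different sequences across databases; ",
           "remap ids upstream")
    }
    merged <- merged[!dup, , drop = FALSE]
  }
  rownames(merged) <- NULL
  counts <- c(common = nrow(common_pb),
              rnacentral_only = nrow(rnacentral_records) - nrow(common_pb),
              pirnabank_only = nrow(only_pb))
  list(records = merged, counts = counts)
}

default_standard_chroms <- function(chroms) {
  chroms[grepl("^(chr)?([0-9]{1,2}|X|Y|M|MT)$", chroms)]
}

#' Build a feature GRanges from records and their genomic hits
#' @param records merged record table.
#' @param hits hits data.frame from [realign_ungapped()].
#' @return `GRanges` with metadata `gene_id`, `gene_biotype`, `provenance`,
#'   `alias_ids`.
#' @export
features_from_hits <- function(records, hits) {
  hits <- hits[hits$seq_id %in% records$primary_id, , drop = FALSE]
  i <- match(hits$seq_id, records$primary_id)
  GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand,
    gene_id = hits$seq_id,
    gene_biotype = records$biotype[i],
    provenance = records$source_db[i],
    alias_ids = records$alias_ids[i]
  )
}

#' Remove or flag features overlapping protein-coding sequence
#'
#' In stringent mode every feature interval overlapping (by at least 1 bp,
#' strand-agnostic) a protein-coding gene's exon, or any CDS interval, is
#' removed; in lenient mode nothing is removed and overlapping intervals are
#' flagged in a `coding_overlap` metadata column.
#'
#' @param features feature `GRanges`.
#' @param gene_annotation `GRanges` with metadata `type` (gene/exon/CDS) and
#'   `gene_type`.
#' @param stringent logical (default `TRUE`).
#' @return filtered (stringent) or flagged (lenient) `GRanges`.
#' @export
exclude_coding_overlap <- function(features, gene_annotation,
                                   stringent = TRUE) {
  ga <- gene_annotation
  bad <- ga[as.character(ga$type) == "CDS" |
              (as.character(ga$type) == "exon" &
                 !is.na(ga$gene_type) & ga$gene_type == "protein_coding")]
  hit <- IRanges::overlapsAny(features, bad, ignore.strand = TRUE)
  if (stringent) {
    features[!hit]
  } else {
    features$coding_overlap <- hit
    features
  }
}

#' Report piRNAs embedded in other non-coding RNAs
#'
#' Each piRNA feature fully contained in a host sncRNA/lncRNA interval (same
#' strand by default) yields one metadata row; features are untouched.
#'
#' @param features feature `GRanges`.
#' @param host_annotation `GRanges` of host intervals with metadata
#'   `gene_id` and `gene_type`.
#' @param host_biotypes host biotypes considered (default the non-coding
#'   classes a small RNA can derive from).
#' @param same_strand require sense containment (default `TRUE`).
#' @return data.frame: `pirna_id`, `host_id`, `host_biotype`.
#' @export
annotate_embedded <- function(features, host_annotation,
                              host_biotypes = c("lncRNA", "miRNA", "rRNA",
                                                "tRNA", "snRNA", "snoRNA",
                                                "YRNA", "misc_RNA"),
                              same_strand = TRUE) {
  hosts <- host_annotation[!is.na(host_annotation$gene_type) &
                             host_annotation$gene_type %in% host_biotypes]
  if (!is.null(hosts$type)) {
    hosts <- hosts[as.character(hosts$type) %in% c("gene", "transcript")]
  }
  ov <- GenomicRanges::findOverlaps(features, hosts, type = "within",
                                    ignore.strand = !same_strand)
  data.frame(
    pirna_id = features$gene_id[S4Vectors::queryHits(ov)],
    host_id = hosts$gene_id[S4Vectors::subjectHits(ov)],
    host_biotype = hosts$gene_type[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
}

#' Classify genomic regions of origin (piRNA cluster vs genic)
#'
#' Feature intervals within `max_gap` of each other on the same chromosome
#' (strand-agnostic) are merged into regions by single linkage; a region
#' overlapping any gene interval is `genic`, otherwise `cluster`. Each
#' sequence is labelled by the union of labels of the regions containing its
#' hits (`cluster`, `genic` or `both`).
#'
#' @param features feature `GRanges`.
#' @param max_gap maximum merge gap in bp (default 1000).
#' @param gene_annotation `GRanges` with a `type` metadata column; rows with
#'   `type == "gene"` define gene intervals.
#' @return list with `regions` (`GRanges` with `region_id`, `label`) and
#'   `seq_labels` (data.frame: `seq_id`, `region_label`).
#' @export
find_genomic_regions <- function(features, max_gap = 1000L,
                                 gene_annotation = NULL) {
  regions <- GenomicRanges::reduce(features, ignore.strand = TRUE,
                                   min.gapwidth = max_gap + 1L)
  genic <- if (!is.null(gene_annotation) && length(gene_annotation)) {
    genes <- gene_annotation[as.character(gene_annotation$type) == "gene"]
    IRanges::overlapsAny(regions, genes, ignore.strand = TRUE)
  } else rep(FALSE, length(regions))
  regions$region_id <- paste0("region_", seq_along(regions))
  regions$label <- ifelse(genic, "genic", "cluster")
  ov <- GenomicRanges::findOverlaps(features, regions, ignore.strand = TRUE)
  lab <- split(regions$label[S4Vectors::subjectHits(ov)],
               features$gene_id[S4Vectors::queryHits(ov)])
  seq_labels <- data.frame(
    seq_id = names(lab),
    region_label = vapply(lab, function(l) {
      u <- unique(l)
      if (length(u) > 1) "both" else u
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(seq_labels) <- NULL
  seq_labels <- seq_labels[order(seq_labels$seq_id), , drop = FALSE]
  list(regions = regions, seq_labels = seq_labels)
}

#' Intersect features with transposable elements
#'
#' @param features feature `GRanges`.
#' @param te_track `GRanges` from [read_te_bed()].
#' @return data.frame with one row per (feature, overlapping TE) pair:
#'   `seq_id`, `chrom`, `feature_start`, `feature_end`, `te_name`,
#'   `te_class`, `te_family`, `te_gene`, `overlap_len`.
#' @export
intersect_te <- function(features, te_track) {
  ov <- GenomicRanges::findOverlaps(features, te_track, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- IRanges::pintersect(GenomicRanges::ranges(features)[q],
                               GenomicRanges::ranges(te_track)[s])
  data.frame(
    seq_id = features$gene_id[q],
    chrom = as.character(GenomicRanges::seqnames(features))[q],
    feature_start = GenomicRanges::start(features)[q],
    feature_end = GenomicRanges::end(features)[q],
    te_name = te_track$te_name[s],
    te_class = te_track$te_class[s],
    te_family = te_track$te_family[s],
    te_gene = te_track$te_gene[s],
    overlap_len = IRanges::width(inter),
    stringsAsFactors = FALSE
  )
}

#' Forge the harmonised annotation track
#'
#' Runs the full annotation-forging pipeline: collapse each database,
#' realign the sequences to the genome (ungapped, dropping
#' over-multimapped sequences), filter by length, re-classify piRNA-database
#' biotypes, integrate the two databases, keep standard chromosomes, exclude
#' (or flag) protein-coding overlaps, and derive embedded-piRNA, genomic
#' region and transposable-element metadata. When `out_dir` is given the
#' track is written as GTF + FASTA plus `Genomic_Region_info.tsv`,
#' `Multimapping_piRNA_info.tsv`, `Transposable_Elements_info.tsv`,
#' `reclassification_log.tsv` and a `forge_stats.tsv` with the record count
#' after every stage.
#'
#' @param config a [run_config()].
#' @param pirna_db,sncrna_db FASTA paths or record tables; `sncrna_db`
#'   headers carry `id|biotype`.
#' @param genome named character vector of chromosome sequences, a
#'   `genome_ref`, or a FASTA path.
#' @param gene_gtf gene-annotation `GRanges` or GTF path (GENCODE-style
#'   `type`/`gene_type` attributes).
#' @param te_bed TE `GRanges` or BED path (see [read_te_bed()]).
#' @param out_dir optional output directory.
#' @return an `annotation_track`: list with `features` (GRanges), `records`
#'   (sequence table for the surviving features), `region_info`,
#'   `multimap_info`, `embedded_info`, `te_info`, `reclass_log`, `stats`.
#' @export
forge <- function(config = run_config(), pirna_db, sncrna_db, genome,
                  gene_gtf, te_bed = NULL, out_dir = NULL) {
  fc <- config$forge
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- read_fasta(genome)
    genome <- stats::setNames(g$sequence, sub("\\s.*$", "", g$id))
  } else if (is.list(genome) && !is.null(genome$sequences)) {
    genome <- genome$sequences
  }
  if (is.character(gene_gtf)) gene_gtf <- read_gtf(gene_gtf)
  if (is.character(te_bed)) te_bed <- read_te_bed(te_bed)

  as_records <- function(x, source_db) {
    if (is.data.frame(x) && "primary_id" %in% names(x)) return(x)
    db_records(x, source_db, default_biotype = "piRNA")
  }
  pb <- as_records(pirna_db, "pirnabank")
  rc <- as_records(sncrna_db, "rnacentral")

  stats_rows <- list()
  add_stat <- function(stage, ...) {
    stats_rows[[length(stats_rows) + 1L]] <<- log_stage(stage, ...)
  }
  add_stat("input", pirnabank = nrow(pb), rnacentral = nrow(rc))

  pb <- collapse_sequences(pb)
  rc <- collapse_sequences(rc)
  add_stat("collapse", pirnabank = nrow(pb), rnacentral = nrow(rc))

  all_rec <- rbind(pb, rc)
  uniq <- all_rec[!duplicated(all_rec$sequence), , drop = FALSE]
  aln <- realign_ungapped(uniq, genome, fc$min_match, fc$max_mismatch,
                          fc$max_loci)
  seq_hits <- stats::setNames(aln$n_loci, uniq$sequence)
  seq_exceeds <- stats::setNames(aln$exceeds_max_loci, uniq$sequence)
  hit_by_seq <- split(aln$hits, uniq$sequence[match(aln$hits$seq_id,
                                                    uniq$primary_id)])
  mapped_ok <- function(recs) {
    recs[seq_hits[recs$sequence] > 0 & !seq_exceeds[recs$sequence], ,
         drop = FALSE]
  }
  n_exceed <- sum(seq_exceeds)
  pb <- mapped_ok(pb); rc <- mapped_ok(rc)
  add_stat("realign", pirnabank = nrow(pb), rnacentral = nrow(rc),
           dropped_max_loci = n_exceed)

  pb <- length_filter(pb, fc$max_seq_len)
  rc <- length_filter(rc, fc$max_seq_len)
  add_stat("length_filter", pirnabank = nrow(pb), rnacentral = nrow(rc))

  recl <- reclassify_biotypes(pb, rc)
  pb <- recl$records
  add_stat("reclassify", reclassified = sum(recl$log$status == "reclassified"),
           ambiguous = sum(recl$log$status == "ambiguous"))

  integ <- integrate_databases(pb, rc, fc$pirnabank_max_len)
  records <- integ$records
  add_stat("integrate", merged = nrow(records),
           common = integ$counts[["common"]],
           rnacentral_only = integ$counts[["rnacentral_only"]],
           pirnabank_only = integ$counts[["pirnabank_only"]])

  # remap hit ids onto the merged primary ids via the sequence
  hits <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    h <- hit_by_seq[[records$sequence[i]]]
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h$seq_id <- records$primary_id[i]
    h
  }))
  std <- fc$standard_chroms
  if (is.null(std)) std <- default_standard_chroms(names(genome))
  hits <- hits[hits$chrom %in% std, , drop = FALSE]
  records <- records[records$primary_id %in% hits$seq_id, , drop = FALSE]
  add_stat("standard_chromosomes", sequences = nrow(records),
           locations = nrow(hits))

  features <- features_from_hits(records, hits)
  features <- exclude_coding_overlap(features, gene_gtf,
                                     stringent = fc$stringent_coding_filter)
  records <- records[records$primary_id %in% features$gene_id, , drop = FALSE]
  add_stat("coding_filter", sequences = nrow(records),
           locations = length(features),
           mode = if (fc$stringent_coding_filter) "stringent" else "lenient")

  embedded <- annotate_embedded(features, gene_gtf,
                                same_strand = fc$embedded_same_strand)
  reg <- find_genomic_regions(features, fc$region_gap, gene_gtf)
  te_info <- if (!is.null(te_bed)) intersect_te(features, te_bed) else
    intersect_te(features, GenomicRanges::GRanges(
      te_name = character(), te_class = character(),
      te_family = character(), te_gene = character()))
  multimap <- data.frame(seq_id = records$primary_id,
                         n_loci = as.integer(table(
                           factor(features$gene_id,
                                  levels = records$primary_id))),
                         stringsAsFactors = FALSE)
  add_stat("metadata", embedded_pairs = nrow(embedded),
           regions = length(reg$regions), te_pairs = nrow(te_info))

  stats_df <- do.call(rbind, stats_rows)
  track <- structure(list(
    features = features, records = records,
    region_info = reg$seq_labels, regions = reg$regions,
    multimap_info = multimap, embedded_info = embedded, te_info = te_info,
    reclass_log = recl$log, stats = stats_df
  ), class = "annotation_track")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(track, file.path(out_dir, "annotation.gtf"))
    write_fasta(data.frame(id = records$primary_id,
                           sequence = records$sequence),
                file.path(out_dir, "annotation.fasta"))
    write_tsv_file(reg$seq_labels,
                   file.path(out_dir, "Genomic_Region_info.tsv"))
    write_tsv_file(multimap,
                   file.path(out_dir, "Multimapping_piRNA_info.tsv"))
    write_tsv_file(te_info,
                   file.path(out_dir, "Transposable_Elements_info.tsv"))
    write_tsv_file(recl$log, file.path(out_dir, "reclassification_log.tsv"))
    write_tsv_file(stats_df, file.path(out_dir, "forge_stats.tsv"))
  }
  track
}

#' @export
print.annotation_track <- function(x, ...) {
  cat("annotation_track:", nrow(x$records), "sequences,",
      length(x$features), "genomic locations\n")
  cat("biotypes:", paste(names(table(x$records$biotype)),
                         table(x$records$biotype), collapse = ", "), "\n")
  invisible(x)
}
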