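#' Read a FASTA file of database or genome sequences
#'
#' Sequences are uppercased and U is mapped to T, so RNA database dumps and
#' DNA references come out in one alphabet.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return a data.frame with columns `id` (full header line after `>`) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("FASTA parse error in '", path, "': empty file")
  if (any(Biostrings::width(set) == 0)) {
    bad <- which(Biostrings::width(set) == 0)[1]
    stop("FASTA parse error in '", path, "': blank sequence for record ",
         bad, " ('", names(set)[bad], "')")
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  data.frame(id = names(set), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @param width line wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a 4-line-record FASTQ file, plain or gzip.
#' @return a data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0) stop("FASTQ parse error in '", path, "': empty file")
  if (n %% 4L != 0L) {
    stop("FASTQ parse error in '", path, "': truncated record ",
         n %/% 4L + 1L)
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- toupper(lines[seq(2L, n, by = 4L)])
  quals <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(!startsWith(ids, "@"))
  if (length(bad_hdr)) {
    stop("FASTQ parse error in '", path, "': record ", bad_hdr[1],
         " does not start with '@'")
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "': sequence/quality length ",
         "mismatch at record ", bad[1])
  }
  data.frame(id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#' @param x data.frame with columns `id`, `sequence`, `quality`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(x)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(x)) {
    out <- rbind(paste0("@", x$id), x$sequence, "+", x$quality)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `sample`, `group`, optional `batch`, and
#' optional `fastq` (path to the sample's reads).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `sample`, `group`, `batch`, `fastq`.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(x))) {
    stop("sample sheet must have 'sample' and 'group' columns")
  }
  if (anyDuplicated(x$sample)) stop("duplicate sample ids in sample sheet")
  if (any(table(x$group) < 1)) stop("every group needs at least one sample")
  if (is.null(x$batch)) x$batch <- NA_character_
  if (is.null(x$fastq)) x$fastq <- NA_character_
  x[, c("sample", "group", "batch", "fastq")]
}

# deterministic TSV writers used for all tabular outputs
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a counts matrix to TSV (feature_id + one column per sample)
#' @param counts numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Read a counts matrix written by [write_counts()]
#' @param path path to the TSV.
#' @return numeric matrix with feature rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  m
}

gtf_quote_attr <- function(key, value) paste0(key, " \"", value, "\";")

#' Write an annotation track to GTF
#'
#' One line per genomic placement, 1-based closed coordinates, GTF2.2
#' attribute style. Multi-locus sequences share a `gene_id` across lines.
#' Lines are ordered by (chromosome, start, end, gene_id) so identical tracks
#' always serialise to identical bytes.
#'
#' @param track an `annotation_track` (see [forge()]) or a `GRanges` with
#'   metadata columns `gene_id`, `gene_biotype`, `provenance`, `alias_ids`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(track, path) {
  gr <- if (inherits(track, "annotation_track")) track$features else track
  stopifnot(methods::is(gr, "GRanges"))
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr))) {
    stop("refusing to write feature with end < start")
  }
  mc <- S4Vectors::mcols(gr)
  for (col in c("gene_id", "gene_biotype", "provenance", "alias_ids")) {
    if (is.null(mc[[col]])) stop("missing GTF attribute column: ", col)
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  o <- order(chrom, GenomicRanges::start(gr), GenomicRanges::end(gr),
             mc$gene_id)
  gr <- gr[o]; mc <- S4Vectors::mcols(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  attrs <- paste(
    gtf_quote_attr("gene_id", mc$gene_id),
    gtf_quote_attr("gene_biotype", mc$gene_biotype),
    gtf_quote_attr("provenance", mc$provenance),
    gtf_quote_attr("alias_ids", mc$alias_ids),
    sep = " "
  )
  lines <- paste(chrom, "sncforge", "exon",
                 GenomicRanges::start(gr), GenomicRanges::end(gr), ".",
                 as.character(GenomicRanges::strand(gr)), ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation GTF into a GRanges
#'
#' Accepts both tracks written by [write_gtf()] and external gene-annotation
#' GTFs (GENCODE-style, with `type`/`gene_type` columns).
#'
#' @param path path to a GTF file.
#' @return a `GRanges`; attributes become metadata columns.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr
}

#' Read a transposable-element BED file
#'
#' BED 0-based half-open intervals, converted to 1-based closed; three extra
#' columns after the standard six carry TE class, family and gene.
#'
#' @param path path to a BED file with columns chrom, start, end, name,
#'   score, strand, te_class, te_family, te_gene. Malformed rows are skipped
#'   with a message.
#' @return a `GRanges` with metadata columns `te_name`, `te_class`,
#'   `te_family`, `te_gene`.
#' @export
read_te_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 9 && !is.na(suppressWarnings(as.integer(p[2]))) &&
      !is.na(suppressWarnings(as.integer(p[3]))) &&
      as.integer(p[3]) > as.integer(p[2])
  }, logical(1))
  if (any(!ok)) {
    message("read_te_bed: skipping ", sum(!ok), " malformed row(s)")
    parts <- parts[ok]
  }
  if (!length(parts)) {
    return(GenomicRanges::GRanges(te_name = character(),
                                  te_class = character(),
                                  te_family = character(),
                                  te_gene = character()))
  }
  m <- do.call(rbind, parts)
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = as.integer(m[, 2]) + 1L,
                              end = as.integer(m[, 3])),
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
    te_name = m[, 4], te_class = m[, 7], te_family = m[, 8],
    te_gene = m[, 9]
  )
}

#' Write read placements as SAM text
#'
#' Emits a valid header (`@HD`, one `@SQ` per chromosome) and one alignment
#' line per placement; minus-strand placements set FLAG bit 16 and store the
#' reverse complement of the read, and every line carries an `NH` tag with
#' the read's placement count.
#'
#' @param alignments data.frame with columns `read_id`, `chrom`, `start`
#'   (1-based), `end`, `strand`, `sequence` (read as sequenced), `n_hits`;
#'   optional `quality`.
#' @param genome_ref named character vector of chromosome sequences (or a
#'   `genome_ref` object from the fixture generator).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome_ref, path) {
  seqs <- if (is.list(genome_ref) && !is.null(genome_ref$sequences)) {
    genome_ref$sequences
  } else genome_ref
  if (nrow(alignments) && !all(alignments$chrom %in% names(seqs))) {
    bad <- setdiff(unique(alignments$chrom), names(seqs))
    stop("alignment references unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  body <- character(0)
  if (nrow(alignments)) {
    minus <- alignments$strand == "-"
    seq_out <- alignments$sequence
    seq_out[minus] <- revcomp(seq_out[minus])
    qual <- if (!is.null(alignments$quality)) {
      q <- alignments$quality
      q[minus] <- vapply(q[minus], function(s) {
        paste(rev(strsplit(s, "")[[1]]), collapse = "")
      }, character(1))
      q
    } else strrep("I", nchar(seq_out))
    body <- paste(alignments$read_id,
                  ifelse(minus, 16L, 0L),
                  alignments$chrom,
                  alignments$start,
                  255L,
                  paste0(nchar(seq_out), "M"),
                  "*", 0L, 0L,
                  seq_out, qual,
                  paste0("NH:i:", alignments$n_hits),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x character vector of ACGTN strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
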