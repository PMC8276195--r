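# Seeded generators for every input the toolkit consumes, with planted
# ground truth: a toy genome, piRNA and sncRNA database dumps engineered to
# exercise every forging rule, gene/TE annotation, NB-expressed small
# RNA-seq reads with spike-in dilutions and periodate depletion, and
# ping-pong read placements.

#' Specification of the synthetic fixture set
#'
#' Default scale: 2 chromosomes of 500 kb (+ one non-standard scaffold),
#' roughly 300 planted sncRNA sequences, 6 samples in 2 groups of 3 with
#' 50,000 reads each; the full pipeline runs in about a minute per stage on
#' one CPU. Every planted category maps to one forging rule (length filters,
#' biotype conflicts, multimapping caps, coding overlap, embedded hosts,
#' cluster/genic regions, TE overlaps, spike-ins, periodate depletion).
#'
#' @param seed integer seed; all generators are pure functions of the spec.
#' @param ... named overrides merged recursively into the defaults.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 101L, ...) {
  spec <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2L, chrom_len = 500000L, scaffold_len = 20000L),
    features = list(
      n_common = 120L,          # piRNAs in both databases (<69 nt)
      n_cluster_members = 60L,  # of the common piRNAs, placed in clusters
      n_genic = 12L,            # of the common piRNAs, placed in introns
      n_rc_only = 40L,
      n_pb_only = 15L,
      n_pb_long = 8L,           # 70-98 nt piRNA-database entries (dropped)
      n_too_long = 5L,          # >=100 nt entries (length filter)
      other_biotypes = c(miRNA = 20L, tRNA = 10L, rRNA = 8L, snoRNA = 12L,
                         snRNA = 8L, YRNA = 4L),
      n_conflicts = 10L,        # piRNA-db sequences re-classified from the
                                # sncRNA db
      n_ambiguous = 1L,         # sequence with two non-piRNA biotypes
      n_multilocus = 12L,       # 2-5 exact copies each
      n_multilocus_both = 2L,   # multilocus with one copy inside a gene
      max_loci_copies = 120L,   # one sequence above the multimapping cap
      n_coding = 10L,           # piRNAs inside coding sequence
      n_embedded = 3L,          # sense containment in lncRNA hosts
      n_embedded_antisense = 1L,
      n_scaffold = 6L,          # features only on the non-standard scaffold
      pirna_len = 24:31,
      bias_1u = 0.9, bias_10a = 0.6
    ),
    clusters = list(n = 10L, members = 6L, within_gap = c(100L, 300L)),
    genes = list(n = 8L),
    te = list(n_overlapping = 8L, n_spanning = 1L, n_free = 5L,
              classes = c("LINE", "SINE", "LTR", "DNA")),
    spikeins = list(
      ids = c("SS_22", "SS_28", "mSS_22", "mSS_28"),
      lengths = c(22L, 28L, 22L, 28L),
      methylated = c(FALSE, FALSE, TRUE, TRUE),
      dilution_base = 50,       # expected dil_A count; dil_B/C are x10/x100
      flat_count = 300          # expected count outside dilution designs
    ),
    expression = list(n_per_group = 3L, reads_per_sample = 50000L,
                      dispersion = 0.2, n_up = 15L, n_down = 15L,
                      logfc = 2, n_background = 1000L),
    periodate = list(delta = 0.05, n_per_condition = 2L,
                     spike_count = 2000),
    sequencing = list(read_len = 50L,
                      adapter = "TGGAATTCTCGGGTGCCAAGG",
                      error_rate = 0.001)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(spec[[nm]]) && is.list(overrides[[nm]])) {
      spec[[nm]] <- utils::modifyList(spec[[nm]], overrides[[nm]])
    } else {
      spec[[nm]] <- overrides[[nm]]
    }
  }
  stopifnot(spec$periodate$delta > 0, spec$periodate$delta <= 1)
  structure(spec, class = "fixture_spec")
}

rand_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# piRNA-like sequences: 5' U (drawn as T) bias and position-10 A bias; the
# bias parameter is the realised base frequency at that position
rand_pirna <- function(n, lens, bias_1u = 0.9, bias_10a = 0.6) {
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
    s[1] <- if (stats::runif(1) < bias_1u) "T" else
      sample(c("A", "C", "G"), 1)
    if (lens[i] >= 10) {
      s[10] <- if (stats::runif(1) < bias_10a) "A" else
        sample(c("C", "G", "T"), 1)
    }
    out[i] <- paste(s, collapse = "")
  }
  out
}

#' Sequences with planted positional base biases
#'
#' @param n number of sequences.
#' @param len sequence length.
#' @param bias1_p probability of `T` at position 1 (default 0.9).
#' @param bias10_p probability of `A` at position 10 (default 0.6).
#' @param seed RNG seed.
#' @return character vector of sequences.
#' @export
simulate_biased_sequences <- function(n, len = 28L, bias1_p = 0.9,
                                      bias10_p = 0.6, seed = 1L) {
  set.seed(seed)
  rand_pirna(n, rep(len, n), bias1_p, bias10_p)
}

#' Build the toy genome, databases, gene/TE annotation and truth tables
#'
#' Plants every feature category of the spec at non-overlapping genomic
#' slots (inter-feature gaps larger than the region-merge window except
#' inside piRNA clusters), writes the feature sequences into the genome
#' (reverse-complemented for minus-strand plants), and derives the truth
#' tables that say exactly which sequence survives each forging stage and
#' with which metadata.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `pirnabank.fasta`, `rnacentral.fasta`, `genes.gtf`, `te.bed` and the
#'   truth tables as TSVs.
#' @return list of class `fixture_set` with `genome` (named character),
#'   `pirnabank`/`rnacentral` (record FASTAs as data.frames), `gene_gtf`
#'   (GRanges), `te_bed` (GRanges), `truth` (per-sequence table), `hits`
#'   (per-plant table), `embedded_truth`, `te_truth`, `spec`, and `paths`
#'   when written.
#' @export
make_genome_and_databases <- function(spec = fixture_spec(),
                                      out_dir = NULL) {
  set.seed(spec$seed)
  fs <- spec$features
  std_chroms <- paste0("chr", seq_len(spec$genome$n_chroms))
  chrom_names <- c(std_chroms, "scaffold_1")
  chrom_len <- stats::setNames(
    c(rep(spec$genome$chrom_len, length(std_chroms)),
      spec$genome$scaffold_len), chrom_names)
  genome <- vapply(chrom_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(genome) <- chrom_names

  cursors <- stats::setNames(rep(1L, length(chrom_names)), chrom_names)
  alloc <- function(width, gap = 2000L, chrom = NULL) {
    if (is.null(chrom)) chrom <- std_chroms[which.min(cursors[std_chroms])]
    start <- cursors[[chrom]] + gap
    if (start + width > chrom_len[[chrom]]) {
      stop("fixture layout overflow on ", chrom,
           ": features do not fit the genome")
    }
    cursors[[chrom]] <<- start + width
    list(chrom = chrom, start = start)
  }

  seqs <- list()   # one row per distinct sequence
  plants <- list() # one row per genomic plant
  rc_counter <- 0L; pb_counter <- 0L
  new_rc_id <- function() {
    rc_counter <<- rc_counter + 1L
    sprintf("URS%06d", rc_counter)
  }
  new_pb_ids <- function(n) {
    ids <- sprintf("hsa_piR_%06d", pb_counter + seq_len(n))
    pb_counter <<- pb_counter + n
    ids
  }
  add_seq <- function(key, sequence, category, in_rc, in_pb, rc_biotype,
                      methylated = FALSE, n_pb_dups = 1L) {
    seqs[[key]] <<- data.frame(
      key = key, sequence = sequence, category = category,
      length = nchar(sequence),
      rc_id = if (in_rc) new_rc_id() else NA_character_,
      pb_ids = if (in_pb) paste(new_pb_ids(n_pb_dups), collapse = ";") else
        NA_character_,
      rc_biotype = rc_biotype, methylated = methylated,
      stringsAsFactors = FALSE)
  }
  add_plant <- function(key, chrom, start, width, strand, context) {
    plants[[length(plants) + 1L]] <<- data.frame(
      key = key, chrom = chrom, start = start, end = start + width - 1L,
      strand = strand, context = context, stringsAsFactors = FALSE)
  }
  plant_single <- function(key, width, context = "single", gap = 2000L,
                           chrom = NULL, strand = NULL) {
    at <- alloc(width, gap, chrom)
    if (is.null(strand)) strand <- sample(c("+", "-"), 1)
    add_plant(key, at$chrom, at$start, width, strand, context)
  }
  pl <- function(n) sample(fs$pirna_len, n, replace = TRUE)

  # --- common piRNAs: clusters, genic (intron) and plain singles ---------
  n_common <- fs$n_common
  common_lens <- pl(n_common)
  common_seqs <- rand_pirna(n_common, common_lens, fs$bias_1u, fs$bias_10a)
  for (i in seq_len(n_common)) {
    add_seq(paste0("common_", i), common_seqs[i], "common", TRUE, TRUE,
            "piRNA", methylated = TRUE,
            n_pb_dups = sample(1:3, 1))
  }
  ci <- 0L
  for (cl in seq_len(spec$clusters$n)) {
    members <- spec$clusters$members
    gaps <- sample(seq(spec$clusters$within_gap[1],
                       spec$clusters$within_gap[2]), members, replace = TRUE)
    widths <- common_lens[ci + seq_len(members)]
    block_w <- sum(widths) + sum(gaps)
    at <- alloc(block_w, gap = 2000L)
    pos <- at$start
    for (m in seq_len(members)) {
      ci <- ci + 1L
      add_plant(paste0("common_", ci), at$chrom, pos, widths[m],
                sample(c("+", "-"), 1), "cluster")
      pos <- pos + widths[m] + gaps[m]
    }
  }
  genic_idx <- ci + seq_len(fs$n_genic)   # planted below, inside genes
  single_idx <- setdiff(seq_len(n_common), c(seq_len(ci), genic_idx))
  for (i in single_idx) plant_single(paste0("common_", i), common_lens[i])

  # --- database-specific piRNAs and filter-exercising records ------------
  simple_cat <- function(prefix, n, lens, category, in_rc, in_pb,
                         rc_biotype = "piRNA", context = "single",
                         chrom = NULL, methylated = TRUE) {
    sqs <- rand_pirna(n, lens, fs$bias_1u, fs$bias_10a)
    for (i in seq_len(n)) {
      key <- paste0(prefix, i)
      add_seq(key, sqs[i], category, in_rc, in_pb, rc_biotype, methylated)
      plant_single(key, lens[i], context, chrom = chrom)
    }
  }
  simple_cat("rconly_", fs$n_rc_only, pl(fs$n_rc_only), "rc_only",
             TRUE, FALSE)
  simple_cat("pbonly_", fs$n_pb_only, pl(fs$n_pb_only), "pb_only",
             FALSE, TRUE)
  simple_cat("pblong_", fs$n_pb_long,
             sample(70:98, fs$n_pb_long, replace = TRUE), "pb_long",
             FALSE, TRUE)
  simple_cat("toolong_", fs$n_too_long,
             sample(100:119, fs$n_too_long, replace = TRUE), "too_long",
             TRUE, FALSE)
  bt_lens <- list(miRNA = 20:23, tRNA = 70:85, rRNA = 80:95,
                  snoRNA = 60:70, snRNA = 60:80, YRNA = 80:95)
  for (bt in names(fs$other_biotypes)) {
    n <- fs$other_biotypes[[bt]]
    lens <- sample(bt_lens[[bt]], n, replace = TRUE)
    sqs <- rand_dna(n, max(lens))
    for (i in seq_len(n)) {
      key <- paste0(bt, "_", i)
      s <- substr(sqs[i], 1, lens[i])
      add_seq(key, s, "other_biotype", TRUE, FALSE, bt, methylated = FALSE)
      plant_single(key, lens[i])
    }
  }
  conflict_bts <- rep(c("snoRNA", "rRNA", "tRNA", "snRNA", "YRNA"),
                      length.out = fs$n_conflicts)
  for (i in seq_len(fs$n_conflicts)) {
    key <- paste0("conflict_", i)
    len <- sample(fs$pirna_len, 1)
    add_seq(key, rand_pirna(1, len, fs$bias_1u, fs$bias_10a), "conflict",
            TRUE, TRUE, conflict_bts[i], methylated = FALSE)
    plant_single(key, len)
  }
  for (i in seq_len(fs$n_ambiguous)) {
    key <- paste0("ambig_", i)
    len <- sample(fs$pirna_len, 1)
    add_seq(key, rand_pirna(1, len, fs$bias_1u, fs$bias_10a), "ambiguous",
            TRUE, TRUE, "rRNA;snoRNA", methylated = FALSE)
    plant_single(key, len)
  }

  # --- multilocus sequences ----------------------------------------------
  for (i in seq_len(fs$n_multilocus)) {
    key <- paste0("multi_", i)
    len <- sample(fs$pirna_len, 1)
    add_seq(key, rand_pirna(1, len, fs$bias_1u, fs$bias_10a),
            if (i <= fs$n_multilocus_both) "multilocus_both" else
              "multilocus", TRUE, FALSE, "piRNA", methylated = TRUE)
    copies <- if (i <= fs$n_multilocus_both) 1L else sample(2:5, 1)
    for (cp in seq_len(copies)) {
      plant_single(key, len, "multilocus")
    }
  }
  key <- "maxloci_1"
  len <- sample(fs$pirna_len, 1)
  add_seq(key, rand_pirna(1, len, fs$bias_1u, fs$bias_10a), "max_loci",
          TRUE, FALSE, "piRNA", methylated = TRUE)
  block <- alloc(fs$max_loci_copies * (len + 60L), gap = 2000L)
  for (cp in seq_len(fs$max_loci_copies)) {
    add_plant(key, block$chrom, block$start + (cp - 1L) * (len + 60L), len,
              "+", "max_loci")
  }

  # --- protein-coding genes: intron piRNAs (kept, genic) and CDS piRNAs --
  gene_rows <- list()
  gq <- 0L # genic plant queue position
  genic_keys <- c(paste0("common_", genic_idx),
                  paste0("multi_", seq_len(fs$n_multilocus_both)))
  cq <- 0L
  coding_lens <- pl(fs$n_coding)
  for (i in seq_len(fs$n_coding)) {
    add_seq(paste0("coding_", i),
            rand_pirna(1, coding_lens[i], fs$bias_1u, fs$bias_10a),
            "coding_overlap", TRUE, FALSE, "piRNA", methylated = TRUE)
  }
  for (g in seq_len(spec$genes$n)) {
    at <- alloc(6600L, gap = 2000L)
    gs <- at$start; chrom <- at$chrom
    gid <- paste0("gene_", g)
    strand <- sample(c("+", "-"), 1)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      chrom = chrom, type = c("gene", "exon", "CDS", "exon", "CDS"),
      start = c(gs, gs, gs + 20L, gs + 6000L, gs + 6050L),
      end = c(gs + 6599L, gs + 599L, gs + 579L, gs + 6599L, gs + 6399L),
      strand = strand, gene_id = gid, gene_type = "protein_coding",
      stringsAsFactors = FALSE)
    # two CDS-overlapping piRNAs per gene while the queue lasts
    for (slot in 0:1) {
      if (cq >= fs$n_coding) break
      cq <- cq + 1L
      add_plant(paste0("coding_", cq), chrom,
                gs + 40L + slot * 250L, coding_lens[cq],
                sample(c("+", "-"), 1), "cds")
    }
    # two intronic piRNAs per gene while the queue lasts
    for (slot in 0:1) {
      if (gq >= length(genic_keys)) break
      gq <- gq + 1L
      k <- genic_keys[gq]
      w <- seqs[[k]]$length
      add_plant(k, chrom, gs + 1200L + slot * 1800L, w,
                sample(c("+", "-"), 1), "gene_intron")
    }
  }

  # --- lncRNA hosts with embedded piRNAs ---------------------------------
  embedded_rows <- list()
  n_emb <- fs$n_embedded + fs$n_embedded_antisense
  for (i in seq_len(n_emb)) {
    at <- alloc(2000L, gap = 2000L)
    hid <- paste0("lnc_", i)
    hstrand <- sample(c("+", "-"), 1)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      chrom = at$chrom, type = "gene", start = at$start,
      end = at$start + 1999L, strand = hstrand, gene_id = hid,
      gene_type = "lncRNA", stringsAsFactors = FALSE)
    key <- paste0("embedded_", i)
    len <- sample(fs$pirna_len, 1)
    sense <- i <= fs$n_embedded
    add_seq(key, rand_pirna(1, len, fs$bias_1u, fs$bias_10a),
            if (sense) "embedded" else "embedded_antisense",
            TRUE, FALSE, "piRNA", methylated = TRUE)
    fstrand <- if (sense) hstrand else setdiff(c("+", "-"), hstrand)
    add_plant(key, at$chrom, at$start + 500L + 13L * i, len, fstrand,
              if (sense) "host_sense" else "host_antisense")
    if (sense) {
      embedded_rows[[length(embedded_rows) + 1L]] <- data.frame(
        key = key, host_id = hid, host_biotype = "lncRNA",
        stringsAsFactors = FALSE)
    }
  }

  # --- non-standard scaffold features ------------------------------------
  simple_cat("scafonly_", fs$n_scaffold, pl(fs$n_scaffold), "scaffold",
             TRUE, FALSE, context = "scaffold", chrom = "scaffold_1")

  # --- spike-ins ----------------------------------------------------------
  sp <- spec$spikeins
  for (i in seq_along(sp$ids)) {
    key <- sp$ids[i]
    add_seq(key, rand_pirna(1, sp$lengths[i], 1, 1), "spikein", TRUE,
            FALSE, "piRNA", methylated = sp$methylated[i])
    plant_single(key, sp$lengths[i], "spikein")
  }

  seqs <- do.call(rbind, seqs); rownames(seqs) <- NULL
  if (anyDuplicated(seqs$sequence)) {
    stop("fixture generated duplicate sequences; change the seed")
  }
  plants <- do.call(rbind, plants)

  # write plants into the genome (reverse complement for minus strand)
  for (i in seq_len(nrow(plants))) {
    s <- seqs$sequence[match(plants$key[i], seqs$key)]
    if (plants$strand[i] == "-") s <- revcomp(s)
    substr(genome[[plants$chrom[i]]], plants$start[i], plants$end[i]) <- s
  }

  # --- transposable elements ----------------------------------------------
  te <- spec$te
  te_rows <- list(); te_truth <- list()
  te_id <- 0L
  pickable <- seqs$key[seqs$category %in% c("rc_only", "pb_only")]
  overlap_keys <- pickable[seq_len(te$n_overlapping + te$n_spanning)]
  for (i in seq_along(overlap_keys)) {
    k <- overlap_keys[i]
    p <- plants[plants$key == k, ][1, ]
    if (i <= te$n_overlapping) {
      te_id <- te_id + 1L
      nm <- paste0("TE_", te_id)
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        chrom = p$chrom, start = p$start - 30L, end = p$end + 30L,
        name = nm, strand = "+",
        class = te$classes[1 + (i %% length(te$classes))],
        family = paste0("fam", i), gene = paste0("teg", i),
        stringsAsFactors = FALSE)
      te_truth[[length(te_truth) + 1L]] <- data.frame(
        key = k, te_name = nm, stringsAsFactors = FALSE)
    } else {
      # one feature spanning two adjacent TEs
      mid <- p$start + (p$end - p$start) %/% 2L
      for (half in 1:2) {
        te_id <- te_id + 1L
        nm <- paste0("TE_", te_id)
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          chrom = p$chrom,
          start = if (half == 1) p$start - 20L else mid + 1L,
          end = if (half == 1) mid else p$end + 20L,
          name = nm, strand = "+", class = te$classes[half],
          family = paste0("famspan", half), gene = "tegspan",
          stringsAsFactors = FALSE)
        te_truth[[length(te_truth) + 1L]] <- data.frame(
          key = k, te_name = nm, stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(te$n_free)) {
    at <- alloc(400L, gap = 2000L)
    te_id <- te_id + 1L
    te_rows[[length(te_rows) + 1L]] <- data.frame(
      chrom = at$chrom, start = at$start, end = at$start + 399L,
      name = paste0("TE_", te_id), strand = "+",
      class = te$classes[1 + (i %% length(te$classes))],
      family = paste0("famfree", i), gene = paste0("tegfree", i),
      stringsAsFactors = FALSE)
  }
  te_rows <- do.call(rbind, te_rows)
  te_truth <- if (length(te_truth)) do.call(rbind, te_truth) else
    data.frame(key = character(), te_name = character())

  gene_df <- do.call(rbind, gene_rows)

  # --- truth assembly ------------------------------------------------------
  drop_reason <- c(common = "none", rc_only = "none", pb_only = "none",
                   pb_long = "pirnabank_69", too_long = "length",
                   other_biotype = "none", conflict = "none",
                   ambiguous = "none", multilocus = "none",
                   multilocus_both = "none", max_loci = "max_loci",
                   coding_overlap = "coding", embedded = "none",
                   embedded_antisense = "none", scaffold = "nonstandard",
                   spikein = "none")
  truth <- seqs
  truth$drop_reason <- unname(drop_reason[truth$category])
  truth$kept_stringent <- truth$drop_reason == "none"
  truth$kept_lenient <- truth$drop_reason %in% c("none", "coding")
  # the ambiguous record keeps the joined biotype of its sncRNA-db entries;
  # conflicts take the single non-piRNA biotype
  truth$final_biotype <- ifelse(!is.na(truth$rc_id), truth$rc_biotype,
                                "piRNA")
  truth$primary_id <- ifelse(!is.na(truth$rc_id), truth$rc_id,
                             vapply(strsplit(truth$pb_ids, ";"), `[[`,
                                    character(1), 1L))
  ctx <- split(plants$context, plants$key)
  region_of <- function(key) {
    if (!key %in% names(ctx)) return(NA_character_)
    lab <- ifelse(ctx[[key]] %in% c("gene_intron", "cds", "host_sense",
                                    "host_antisense"), "genic", "cluster")
    u <- unique(lab)
    if (length(u) > 1) "both" else u
  }
  truth$region_label <- ifelse(
    truth$kept_stringent,
    vapply(truth$key, region_of, character(1)),
    NA_character_)
  truth$n_loci <- as.integer(table(factor(plants$key,
                                          levels = truth$key)))

  embedded_truth <- if (length(embedded_rows)) {
    df <- do.call(rbind, embedded_rows)
    df$pirna_id <- truth$primary_id[match(df$key, truth$key)]
    df
  } else data.frame(key = character(), host_id = character(),
                    host_biotype = character(), pirna_id = character())
  te_truth$seq_id <- truth$primary_id[match(te_truth$key, truth$key)]

  hits <- plants
  hits$seq_id <- truth$primary_id[match(hits$key, truth$key)]

  # --- database FASTA tables ----------------------------------------------
  pb_rows <- list()
  for (i in which(!is.na(seqs$pb_ids))) {
    for (id in split_ids(seqs$pb_ids[i])) {
      pb_rows[[length(pb_rows) + 1L]] <- data.frame(
        id = id, sequence = seqs$sequence[i], stringsAsFactors = FALSE)
    }
  }
  pb_fasta <- do.call(rbind, pb_rows)
  pb_fasta <- pb_fasta[sample(nrow(pb_fasta)), , drop = FALSE]
  rownames(pb_fasta) <- NULL
  rc_rows <- list()
  for (i in which(!is.na(seqs$rc_id))) {
    bts <- split_ids(seqs$rc_biotype[i])
    for (j in seq_along(bts)) {
      id <- if (j == 1) seqs$rc_id[i] else paste0(seqs$rc_id[i], "_alt", j)
      rc_rows[[length(rc_rows) + 1L]] <- data.frame(
        id = paste0(id, "|", bts[j]), sequence = seqs$sequence[i],
        stringsAsFactors = FALSE)
    }
  }
  rc_fasta <- do.call(rbind, rc_rows)

  gene_gtf <- GenomicRanges::GRanges(
    seqnames = gene_df$chrom,
    ranges = IRanges::IRanges(gene_df$start, gene_df$end),
    strand = gene_df$strand, type = gene_df$type,
    gene_id = gene_df$gene_id, gene_type = gene_df$gene_type)
  te_gr <- GenomicRanges::GRanges(
    seqnames = te_rows$chrom,
    ranges = IRanges::IRanges(te_rows$start, te_rows$end),
    strand = te_rows$strand, te_name = te_rows$name,
    te_class = te_rows$class, te_family = te_rows$family,
    te_gene = te_rows$gene)

  out <- structure(list(
    genome = genome, pirnabank = pb_fasta, rnacentral = rc_fasta,
    gene_gtf = gene_gtf, te_bed = te_gr, truth = truth, hits = hits,
    embedded_truth = embedded_truth, te_truth = te_truth,
    gene_table = gene_df, spec = spec), class = "fixture_set")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(data.frame(id = names(genome), sequence = unname(genome)),
                p("genome.fasta"))
    write_fasta(pb_fasta, p("pirnabank.fasta"))
    write_fasta(rc_fasta, p("rnacentral.fasta"))
    gtf_lines <- paste(gene_df$chrom, "fixture", gene_df$type,
                       gene_df$start, gene_df$end, ".", gene_df$strand, ".",
                       paste0(gtf_quote_attr("gene_id", gene_df$gene_id),
                              " ",
                              gtf_quote_attr("gene_type",
                                             gene_df$gene_type)),
                       sep = "\t")
    writeLines(gtf_lines, p("genes.gtf"))
    bed_lines <- paste(te_rows$chrom, te_rows$start - 1L, te_rows$end,
                       te_rows$name, 0L, te_rows$strand, te_rows$class,
                       te_rows$family, te_rows$gene, sep = "\t")
    writeLines(bed_lines, p("te.bed"))
    write_tsv_file(truth, p("truth_features.tsv"))
    write_tsv_file(hits, p("truth_hits.tsv"))
    write_tsv_file(embedded_truth, p("truth_embedded.tsv"))
    write_tsv_file(te_truth, p("truth_te.tsv"))
    out$paths <- list(genome = p("genome.fasta"),
                      pirnabank = p("pirnabank.fasta"),
                      rnacentral = p("rnacentral.fasta"),
                      genes = p("genes.gtf"), te = p("te.bed"))
  }
  out
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  for (i in which(n_err > 0)) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample(length(chars), n_err[i])
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate small RNA-seq libraries from the planted annotation
#'
#' Draws negative-binomial per-feature fragment counts (Poisson for
#' spike-ins), renders each fragment as insert + 3' adapter + random fill
#' truncated to the read length, applies per-base substitution errors, and
#' writes per-sample FASTQ plus the truth count matrix.
#'
#' Designs: `two_group` (2 groups x n_per_group samples with planted
#' up/down-regulated piRNAs), `dilution` (3 samples whose spike-in inputs
#' follow a 1:10:100 series), `periodate` (untreated vs treated pairs where
#' every non-methylated species — including the non-methylated spike-ins —
#' is depleted by the factor `delta`).
#'
#' @param fix a `fixture_set` from [make_genome_and_databases()].
#' @param design `"two_group"`, `"dilution"` or `"periodate"`.
#' @param out_dir optional directory for FASTQ files, sample sheet and
#'   truth counts.
#' @return list with `reads` (named list of read data.frames), `samples`
#'   (sample sheet), `truth_counts` (features x samples), `de_truth`
#'   (two_group only: data.frame of planted logFC), `paths` (when written).
#' @export
simulate_reads <- function(fix, design = c("two_group", "dilution",
                                           "periodate"),
                           out_dir = NULL) {
  design <- match.arg(design)
  spec <- fix$spec
  set.seed(spec$seed + switch(design, two_group = 1L, dilution = 2L,
                              periodate = 3L))
  ex <- spec$expression; sq <- spec$sequencing; sp <- spec$spikeins
  truth <- fix$truth
  kept <- truth[truth$kept_stringent & truth$category != "spikein", ,
                drop = FALSE]
  feat_ids <- kept$primary_id
  base_mu <- stats::rgamma(nrow(kept), shape = 1.2, rate = 1)
  base_mu <- pmax(base_mu, 0.05)
  budget <- ex$reads_per_sample - sum(sp$flat_count) * length(sp$ids) -
    ex$n_background
  base_mu <- base_mu / sum(base_mu) * budget

  de_truth <- NULL
  if (design == "two_group") {
    samples <- data.frame(
      sample = c(paste0("A_", seq_len(ex$n_per_group)),
                 paste0("B_", seq_len(ex$n_per_group))),
      group = rep(c("A", "B"), each = ex$n_per_group),
      batch = NA_character_, stringsAsFactors = FALSE)
    pirna_pool <- which(kept$final_biotype == "piRNA" &
                          kept$category %in% c("common", "rc_only",
                                               "pb_only"))
    de_idx <- sample(pirna_pool, ex$n_up + ex$n_down)
    lfc <- stats::setNames(rep(0, nrow(kept)), feat_ids)
    lfc[de_idx[seq_len(ex$n_up)]] <- ex$logfc
    lfc[de_idx[ex$n_up + seq_len(ex$n_down)]] <- -ex$logfc
    # give DE features enough baseline signal to be detectable
    base_mu[de_idx] <- pmax(base_mu[de_idx], 30)
    de_truth <- data.frame(feature_id = feat_ids, logfc = unname(lfc),
                           stringsAsFactors = FALSE)
    mu_mat <- base_mu * 2^outer(unname(lfc),
                                ifelse(samples$group == "B", 1, 0))
    spike_mu <- matrix(sp$flat_count, nrow = length(sp$ids),
                       ncol = nrow(samples))
  } else if (design == "dilution") {
    samples <- data.frame(sample = c("dil_A", "dil_B", "dil_C"),
                          group = c("dil_A", "dil_B", "dil_C"),
                          batch = NA_character_, stringsAsFactors = FALSE)
    mu_mat <- matrix(base_mu, nrow = nrow(kept), ncol = 3)
    spike_mu <- outer(rep(sp$dilution_base, length(sp$ids)),
                      c(1, 10, 100))
  } else {
    n <- spec$periodate$n_per_condition
    samples <- data.frame(
      sample = c(paste0("untreated_", seq_len(n)),
                 paste0("treated_", seq_len(n))),
      group = rep(c("untreated", "treated"), each = n),
      batch = NA_character_, stringsAsFactors = FALSE)
    delta <- spec$periodate$delta
    depletion <- ifelse(kept$methylated, 1, delta)
    mu_mat <- outer(base_mu, rep(1, 2 * n))
    mu_mat[, samples$group == "treated"] <-
      mu_mat[, samples$group == "treated"] * depletion
    sp_dep <- ifelse(sp$methylated, 1, delta)
    spike_mu <- matrix(spec$periodate$spike_count, nrow = length(sp$ids),
                       ncol = 2 * n)
    spike_mu[, samples$group == "treated"] <-
      spike_mu[, samples$group == "treated"] * sp_dep
  }

  spike_seqs <- truth$sequence[match(sp$ids, truth$key)]
  spike_ids <- truth$primary_id[match(sp$ids, truth$key)]
  all_ids <- c(feat_ids, spike_ids)
  truth_counts <- matrix(0, nrow = length(all_ids), ncol = nrow(samples),
                         dimnames = list(all_ids, samples$sample))
  reads_out <- list()
  adapter <- sq$adapter
  for (j in seq_len(nrow(samples))) {
    cnt <- stats::rnbinom(nrow(kept), mu = mu_mat[, j],
                          size = 1 / ex$dispersion)
    spk <- stats::rpois(length(sp$ids), spike_mu[, j])
    truth_counts[, j] <- c(cnt, spk)
    inserts <- c(rep(kept$sequence, cnt), rep(spike_seqs, spk))
    if (ex$n_background > 0) {
      std <- setdiff(names(fix$genome), "scaffold_1")
      bl <- sample(20:30, ex$n_background, replace = TRUE)
      bchr <- sample(std, ex$n_background, replace = TRUE)
      bst <- vapply(seq_len(ex$n_background), function(i) {
        sample.int(nchar(fix$genome[[bchr[i]]]) - bl[i], 1)
      }, integer(1))
      bg <- substring(fix$genome[bchr], bst, bst + bl - 1L)
      flip <- stats::runif(ex$n_background) < 0.5
      bg[flip] <- revcomp(bg[flip])
      inserts <- c(inserts, bg)
    }
    n_reads <- length(inserts)
    need <- pmax(sq$read_len - nchar(inserts) - nchar(adapter), 0L)
    fill_pool <- paste(sample(c("A", "C", "G", "T"), max(need) + 1L,
                              replace = TRUE), collapse = "")
    reads <- substr(paste0(inserts, adapter,
                           substring(fill_pool, 1L, need)),
                    1L, sq$read_len)
    reads <- mutate_reads(reads, sq$error_rate)
    ord <- sample(n_reads)
    df <- data.frame(
      id = paste0(samples$sample[j], "_r", seq_len(n_reads)),
      sequence = reads[ord],
      quality = strrep("I", nchar(reads[ord])),
      stringsAsFactors = FALSE)
    reads_out[[samples$sample[j]]] <- df
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- stats::setNames(
      file.path(out_dir, paste0(samples$sample, ".fastq")), samples$sample)
    for (s in samples$sample) write_fastq(reads_out[[s]], paths[[s]])
    samples$fastq <- unname(paths)
    write_tsv_file(samples, file.path(out_dir, "samples.tsv"))
    write_counts(truth_counts, file.path(out_dir, "truth_counts.tsv"))
  }
  list(reads = reads_out, samples = samples, truth_counts = truth_counts,
       de_truth = de_truth, paths = paths)
}

#' Simulate read placements with a planted ping-pong signal
#'
#' Generates opposite-strand read pairs whose 5' ends overlap by exactly
#' `overlap` nt, plus uniformly placed background reads on both strands.
#'
#' @param n_pairs number of signal pairs.
#' @param overlap planted 5' overlap in nt (default 10).
#' @param n_background number of background reads (default
#'   `n_pairs / 10`, a 10:1 signal-to-noise ratio).
#' @param chrom_len length of the single simulated chromosome.
#' @param read_len read length range.
#' @param seed RNG seed.
#' @return alignments data.frame (`chrom`, `start`, `end`, `strand`,
#'   `weight`) usable by [pingpong()].
#' @export
simulate_pingpong <- function(n_pairs = 200L, overlap = 10L,
                              n_background = max(1L, n_pairs %/% 10L),
                              chrom_len = 100000L, read_len = 26:30,
                              seed = 1L) {
  set.seed(seed)
  rows <- list()
  if (n_pairs > 0) {
    p5 <- sample.int(chrom_len - 200L, n_pairs) + 100L
    plen <- sample(read_len, n_pairs, replace = TRUE)
    mlen <- sample(read_len, n_pairs, replace = TRUE)
    m5 <- p5 + overlap - 1L
    rows[[1]] <- data.frame(chrom = "chr1", start = p5,
                            end = p5 + plen - 1L, strand = "+", weight = 1)
    rows[[2]] <- data.frame(chrom = "chr1", start = m5 - mlen + 1L,
                            end = m5, strand = "-", weight = 1)
  }
  if (n_background > 0) {
    bs <- sample.int(chrom_len - 200L, n_background) + 100L
    blen <- sample(read_len, n_background, replace = TRUE)
    rows[[3]] <- data.frame(chrom = "chr1", start = bs,
                            end = bs + blen - 1L,
                            strand = sample(c("+", "-"), n_background,
                                            replace = TRUE), weight = 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Generic two-group NB count generator used for DE calibration: feature
#' means are drawn log-normally, dispersion is shared, and `logfc` (one
#' value per feature, 0 for null features) shifts group B.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group.
#' @param logfc numeric vector of planted log2 fold changes (length
#'   `n_features`; recycled).
#' @param mean_log,sd_log log-normal parameters of the feature means.
#' @param dispersion NB dispersion (default 0.2).
#' @param seed RNG seed.
#' @return list with `counts` (matrix), `groups`, `logfc`.
#' @export
simulate_nb_counts <- function(n_features = 2000L, n_per_group = 3L,
                               logfc = 0, mean_log = log(100), sd_log = 1,
                               dispersion = 0.2, seed = 1L) {
  set.seed(seed)
  logfc <- rep_len(logfc, n_features)
  mu <- exp(stats::rnorm(n_features, mean_log, sd_log))
  groups <- rep(c("A", "B"), each = n_per_group)
  mu_mat <- mu * 2^outer(logfc, ifelse(groups == "B", 1, 0))
  counts <- matrix(
    stats::rnbinom(n_features * 2 * n_per_group, mu = mu_mat,
                   size = 1 / dispersion),
    nrow = n_features,
    dimnames = list(paste0("f", seq_len(n_features)),
                    paste0(groups, "_", rep(seq_len(n_per_group), 2))))
  list(counts = counts, groups = groups, logfc = logfc)
}

#' Construct a merged DE table with planted up/down/discordant calls
#'
#' Deterministic fixture for the up/down classifier: `n_up` features with
#' positive concordant logFC and significant adjusted p in both methods,
#' `n_down` negative, `n_null` non-significant, `n_discordant` significant
#' but sign-conflicting between the two methods.
#'
#' @param n_up,n_down,n_null,n_discordant row counts.
#' @param alpha significance level the planted p-values respect.
#' @param seed RNG seed.
#' @return list with `table` (merged-DE-format data.frame) and `truth`
#'   (planted class per feature).
#' @export
make_de_classification_fixture <- function(n_up = 44L, n_down = 4L,
                                           n_null = 100L,
                                           n_discordant = 3L,
                                           alpha = 0.05, seed = 1L) {
  set.seed(seed)
  n <- n_up + n_down + n_null + n_discordant
  cls <- c(rep("up", n_up), rep("down", n_down), rep("null", n_null),
           rep("discordant", n_discordant))
  fc_g <- ifelse(cls == "up", stats::runif(n, 1, 4),
                 ifelse(cls == "down", -stats::runif(n, 1, 4),
                        stats::runif(n, -0.5, 0.5)))
  fc_t <- fc_g + stats::rnorm(n, 0, 0.1)
  fc_t[cls == "discordant"] <- -fc_g[cls == "discordant"]
  fc_g[cls == "discordant"] <- abs(fc_g[cls == "discordant"])
  fc_t[cls == "discordant"] <- -abs(fc_t[cls == "discordant"])
  sig <- cls != "null"
  adj_g <- ifelse(sig, stats::runif(n, 0, alpha * 0.9),
                  stats::runif(n, alpha * 2, 1))
  adj_t <- ifelse(sig, stats::runif(n, 0, alpha * 0.9),
                  stats::runif(n, alpha * 2, 1))
  ord <- sample(n)
  tab <- data.frame(
    feature_id = paste0("pi_", seq_len(n)),
    logFC_genomic = fc_g, p_genomic = adj_g / 2, adj_p_genomic = adj_g,
    logFC_tx = fc_t, p_tx = adj_t / 2, adj_p_tx = adj_t,
    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  list(table = tab,
       truth = data.frame(feature_id = paste0("pi_", seq_len(n)),
                          class = cls, stringsAsFactors = FALSE)[ord, ])
}
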