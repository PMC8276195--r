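records_of <- function(seqs, ids = paste0("id", seq_along(seqs)),
                       biotype = "piRNA", db = "pirnabank") {
  data.frame(primary_id = ids, alias_ids = ids, sequence = seqs,
             biotype = rep_len(biotype, length(seqs)),
             source_db = rep_len(db, length(seqs)),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

test_that("collapse merges identical sequences and keeps aliases", {
  empty <- records_of(character(0), character(0))
  expect_equal(nrow(collapse_sequences(empty)), 0)
  r <- records_of(c("ACGTACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGTACGT"),
                  c("hsa_piR_1", "hsa_piR_2"))
  c1 <- collapse_sequences(r)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$primary_id, "hsa_piR_1")
  expect_equal(c1$alias_ids, "hsa_piR_1;hsa_piR_2")
})

test_that("collapse count equals the number of distinct sequences", {
  set.seed(42)
  pool <- rand_seq(400, 26)
  draw <- sample(pool, 1000, replace = TRUE)
  r <- records_of(draw, sprintf("id%04d", seq_along(draw)))
  collapsed <- collapse_sequences(r)
  expect_equal(nrow(collapsed), length(unique(draw)))
  expect_identical(collapse_sequences(collapsed), collapsed)
})

test_that("realign finds unique plus- and minus-strand placements", {
  set.seed(5)
  genome <- c(chr1 = rand_seq(1, 20000))
  q <- substr(genome[["chr1"]], 5001, 5030)
  r <- realign_ungapped(q, genome, 16, 0, 100)
  expect_equal(nrow(r$hits), 1)
  expect_equal(r$hits$start, 5001)
  expect_equal(r$hits$strand, "+")
  r2 <- realign_ungapped(revcomp(q), genome, 16, 0, 100)
  expect_equal(r2$hits$strand, "-")
  expect_equal(r2$hits$start, 5001)
  expect_error(realign_ungapped("ACGTXACGTACGTACGT", genome, 16, 0, 100),
               "non-ACGTN")
})

test_that("realign matches the brute-force scan on planted multi-locus", {
  set.seed(6)
  g <- rand_seq(1, 30000)
  piece <- rand_seq(1, 25)
  pos <- c(100, 4000, 7000, 12000, 19000, 23000, 28000)
  for (p in pos) substr(g, p, p + 24) <- piece
  genome <- c(chr1 = g)
  r <- realign_ungapped(piece, genome, 16, 0, 100)
  expect_equal(nrow(r$hits), 7)
  oracle <- brute_scan(piece, genome, 16, 0)
  expect_identical(hit_key(r$hits), hit_key(oracle))
})

test_that("realign agrees with the sliding-window oracle under mismatches", {
  set.seed(7)
  genome <- c(chrA = rand_seq(1, 8000), chrB = rand_seq(1, 6000))
  queries <- c(
    substr(genome[["chrA"]], 101, 128),
    revcomp(substr(genome[["chrB"]], 2001, 2024)),
    rand_seq(1, 22),                 # unplanted: expect whatever scan finds
    substr(genome[["chrA"]], 500, 515))
  mutated <- queries[1]
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mutated, 10, 10))[1]
  queries <- c(queries, mutated)
  for (q in queries) {
    r <- realign_ungapped(q, genome, 14, 1, 100)
    oracle <- brute_scan(q, genome, 14, 1)
    expect_identical(hit_key(r$hits), hit_key(oracle))
  }
})

test_that("sequences above the multimapping cap are dropped and flagged", {
  set.seed(8)
  g <- rand_seq(1, 60000)
  piece <- rand_seq(1, 24)
  for (p in seq(1, 105 * 40, by = 40)) substr(g, p, p + 23) <- piece
  r <- realign_ungapped(piece, c(chr1 = g), 16, 0, 100)
  expect_equal(nrow(r$hits), 0)
  expect_true(r$exceeds_max_loci[["seq1"]])
  expect_gt(r$n_loci[["seq1"]], 100)
})

test_that("length filter is exclusive at the bound", {
  r <- records_of(c(strrep("A", 100), strrep("C", 99), strrep("G", 30)))
  kept <- length_filter(r, 100)
  expect_equal(kept$length, c(99, 30))
  short <- records_of(c("ACGTACGTACGTACGTACGTACGT"))
  expect_identical(length_filter(short, 100), short)
})

test_that("reclassification takes the other database's biotype", {
  pb <- records_of(c("AAACCCGGGTTTAAACCCGGGTTTA", "TTTGGGCCCAAATTTGGGCCCAAAT"),
                   c("pb1", "pb2"))
  rc <- records_of(c("AAACCCGGGTTTAAACCCGGGTTTA", "CACACACACACACACACACACACAC"),
                   c("rc1", "rc2"), biotype = c("snoRNA", "miRNA"),
                   db = "rnacentral")
  out <- reclassify_biotypes(pb, rc)
  expect_equal(out$records$biotype, c("snoRNA", "piRNA"))
  expect_equal(out$records$sequence, pb$sequence)
  expect_equal(out$log$status, "reclassified")
  expect_equal(out$log$matched_id, "rc1")
})

test_that("ambiguous multi-biotype matches stay piRNA and are logged", {
  s <- "AAACCCGGGTTTAAACCCGGGTTTA"
  pb <- records_of(s, "pb1")
  rc <- collapse_sequences(records_of(c(s, s), c("rc1", "rc2"),
                                      biotype = c("snoRNA", "rRNA"),
                                      db = "rnacentral"))
  out <- reclassify_biotypes(pb, rc)
  expect_equal(out$records$biotype, "piRNA")
  expect_equal(out$log$status, "ambiguous")
})

test_that("planted biotype conflicts are all reclassified on the fixture", {
  fix <- default_fix()
  track <- default_track()
  expect_equal(sum(track$reclass_log$status == "reclassified"),
               fix$spec$features$n_conflicts)
  expect_equal(sum(track$reclass_log$status == "ambiguous"),
               fix$spec$features$n_ambiguous)
})

test_that("integration applies the piRNA-database length rule and merges", {
  pb <- records_of(c(strrep("AC", 35), "ACGTTGCAACGTTGCAACGTTGCA",
                     "GGGTTTCCCAAAGGGTTTCCCAAA"),
                   c("pb_long", "pb_shared", "pb_uniq"))
  rc <- records_of(c("ACGTTGCAACGTTGCAACGTTGCA", "CCCAAATTTGGGCCCAAATTTGGG"),
                   c("rc_shared", "rc_uniq"), db = "rnacentral")
  out <- integrate_databases(pb, rc, 69)
  expect_equal(unname(out$counts),
               c(1, 1, 1))
  expect_false("pb_long" %in% unlist(strsplit(out$records$alias_ids, ";")))
  shared <- out$records[out$records$sequence ==
                          "ACGTTGCAACGTTGCAACGTTGCA", ]
  expect_equal(shared$primary_id, "rc_shared")
  expect_equal(shared$source_db, "pirnabank;rnacentral")
  expect_equal(shared$alias_ids, "pb_shared;rc_shared")
  # disjoint toy sets just concatenate
  out2 <- integrate_databases(records_of(rand_seq(5, 24, seed = 1),
                                         paste0("p", 1:5)),
                              records_of(rand_seq(3, 24, seed = 2),
                                         paste0("r", 1:3),
                                         db = "rnacentral"), 69)
  expect_equal(nrow(out2$records), 8)
})

test_that("coding-overlap filtering removes or flags planted features", {
  ga <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1000, 1000, 1100, 5000), c(3000, 1500, 1400, 5200)),
    strand = "+", type = c("gene", "exon", "CDS", "exon"),
    gene_id = c("g1", "g1", "g1", "g2"),
    gene_type = c("protein_coding", "protein_coding", "protein_coding",
                  "lncRNA"))
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1200, 2000, 9000), c(1228, 2028, 9028)),
    strand = "-", gene_id = paste0("p", 1:3), gene_biotype = "piRNA",
    provenance = "rnacentral", alias_ids = paste0("p", 1:3))
  strict <- exclude_coding_overlap(feats, ga, stringent = TRUE)
  expect_equal(strict$gene_id, c("p2", "p3"))
  lenient <- exclude_coding_overlap(feats, ga, stringent = FALSE)
  expect_equal(length(lenient), 3)
  expect_equal(lenient$coding_overlap, c(TRUE, FALSE, FALSE))
})

test_that("embedded piRNAs are reported only for sense containment", {
  hosts <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 1000), c(400, 1400)),
    strand = c("+", "-"), type = "gene",
    gene_id = c("lncA", "lncB"), gene_type = "lncRNA")
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(150, 1100, 390), c(178, 1128, 430)),
    strand = c("+", "+", "+"), gene_id = paste0("p", 1:3),
    gene_biotype = "piRNA", provenance = "rnacentral",
    alias_ids = paste0("p", 1:3))
  emb <- annotate_embedded(feats, hosts)
  # p1 sense-contained; p2 antisense to lncB; p3 straddles the boundary
  expect_equal(emb$pirna_id, "p1")
  expect_equal(emb$host_id, "lncA")
  emb2 <- annotate_embedded(feats, hosts, same_strand = FALSE)
  expect_setequal(emb2$pirna_id, c("p1", "p2"))
})

test_that("fixture embedded truth is recovered exactly", {
  fix <- default_fix()
  track <- default_track()
  expect_equal(nrow(track$embedded_info), nrow(fix$embedded_truth))
  expect_setequal(paste(track$embedded_info$pirna_id,
                        track$embedded_info$host_id),
                  paste(fix$embedded_truth$pirna_id,
                        fix$embedded_truth$host_id))
})

test_that("region merging respects the gap and labels genic overlap", {
  mk <- function(starts, width = 29) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, starts + width - 1), strand = "+",
    gene_id = paste0("f", seq_along(starts)), gene_biotype = "piRNA",
    provenance = "rnacentral", alias_ids = paste0("f", seq_along(starts)))
  one <- find_genomic_regions(mk(500), 1000)
  expect_equal(length(one$regions), 1)
  expect_equal(one$seq_labels$region_label, "cluster")
  two <- find_genomic_regions(mk(c(500, 11000)), 1000)
  expect_equal(length(two$regions), 2)
  ga <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 2000),
                               strand = "+", type = "gene",
                               gene_id = "g1",
                               gene_type = "protein_coding")
  five <- find_genomic_regions(mk(c(500, 700, 900, 1050, 1200)), 1000, ga)
  expect_equal(length(five$regions), 1)
  expect_equal(unique(five$seq_labels$region_label), "genic")
})

test_that("TE intersection reports one row per overlapping element", {
  te <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 130, 5000), c(129, 170, 5100)),
    strand = "+", te_name = c("TE_a", "TE_b", "TE_c"),
    te_class = c("LINE", "SINE", "LTR"), te_family = c("L1", "Alu", "ERV"),
    te_gene = c("L1PA", "AluY", "ERVK"))
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110, 9000), c(140, 9028)), strand = "+",
    gene_id = c("p1", "p2"), gene_biotype = "piRNA",
    provenance = "rnacentral", alias_ids = c("p1", "p2"))
  ti <- intersect_te(feats, te)
  expect_equal(nrow(ti), 2)           # p1 spans TE_a and TE_b; p2 none
  expect_setequal(ti$te_name, c("TE_a", "TE_b"))
  expect_equal(ti$seq_id, c("p1", "p1"))
  expect_equal(ti$overlap_len, c(20, 11))
})

test_that("forge reproduces the planted truth on the default fixture", {
  fix <- default_fix()
  track <- default_track()
  truth <- fix$truth
  kept <- truth[truth$kept_stringent, ]
  expect_setequal(track$records$primary_id, kept$primary_id)
  exp_hits <- fix$hits[fix$hits$seq_id %in% kept$primary_id &
                         fix$hits$chrom != "scaffold_1", ]
  got <- paste(track$features$gene_id,
               GenomicRanges::seqnames(track$features),
               GenomicRanges::start(track$features),
               GenomicRanges::end(track$features),
               GenomicRanges::strand(track$features))
  want <- paste(exp_hits$seq_id, exp_hits$chrom, exp_hits$start,
                exp_hits$end, exp_hits$strand)
  expect_identical(sort(got), sort(want))
  m <- match(track$records$primary_id, truth$primary_id)
  expect_equal(track$records$biotype, truth$final_biotype[m])
  rl <- merge(track$region_info, truth[, c("primary_id", "region_label")],
              by.x = "seq_id", by.y = "primary_id")
  expect_equal(rl$region_label.x, rl$region_label.y)
  expect_setequal(paste(track$te_info$seq_id, track$te_info$te_name),
                  paste(fix$te_truth$seq_id, fix$te_truth$te_name))
  mm <- merge(track$multimap_info, truth[, c("primary_id", "n_loci")],
              by.x = "seq_id", by.y = "primary_id")
  expect_equal(mm$n_loci.x, mm$n_loci.y)
})

test_that("lenient mode keeps and flags coding-overlap features", {
  fix <- default_fix()
  cfg <- run_config(forge = list(stringent_coding_filter = FALSE))
  track <- quiet(forge(cfg, fix$pirnabank, fix$rnacentral, fix$genome,
                       fix$gene_gtf, fix$te_bed))
  truth <- fix$truth
  kept <- truth[truth$kept_lenient, ]
  expect_setequal(track$records$primary_id, kept$primary_id)
  coding_ids <- truth$primary_id[truth$category == "coding_overlap"]
  flagged <- track$features$gene_id[track$features$coding_overlap]
  expect_setequal(unique(flagged), coding_ids)
})

test_that("forge is deterministic and its stage counts shrink monotonically", {
  fix <- default_fix()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  quiet(forge(run_config(), fix$pirnabank, fix$rnacentral, fix$genome,
              fix$gene_gtf, fix$te_bed, out_dir = d1))
  quiet(forge(run_config(), fix$pirnabank, fix$rnacentral, fix$genome,
              fix$gene_gtf, fix$te_bed, out_dir = d2))
  for (f in c("annotation.gtf", "annotation.fasta",
              "Genomic_Region_info.tsv", "forge_stats.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  stats <- read.delim(file.path(d1, "forge_stats.tsv"))
  for (db in c("pirnabank", "rnacentral")) {
    n <- as.numeric(stats$value[stats$key == db])
    expect_true(all(diff(n) <= 0))
  }
})

test_that("written GTF violates no length, chromosome or coding rule", {
  fix <- default_fix()
  d <- withr::local_tempdir()
  track <- quiet(forge(run_config(), fix$pirnabank, fix$rnacentral,
                       fix$genome, fix$gene_gtf, fix$te_bed, out_dir = d))
  gr <- read_gtf(file.path(d, "annotation.gtf"))
  expect_true(all(GenomicRanges::width(gr) < 100))
  expect_true(all(as.character(GenomicRanges::seqnames(gr)) %in%
                    c("chr1", "chr2")))
  ga <- fix$gene_gtf
  bad <- ga[ga$type == "CDS" |
              (ga$type == "exon" & ga$gene_type == "protein_coding")]
  expect_equal(sum(IRanges::overlapsAny(gr, bad, ignore.strand = TRUE)), 0)
})
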