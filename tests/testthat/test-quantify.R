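ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

read_df <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  data.frame(id = ids, sequence = seqs, quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

test_that("adapter trimming recovers inserts and discards short ones", {
  insert <- rand_seq(1, 25, seed = 11)
  full <- paste0(insert, ADAPTER, "ACGTA")
  tr <- trim_reads(read_df(full), ADAPTER)
  expect_equal(tr$reads$sequence, insert)
  expect_equal(nchar(tr$reads$quality), 25)
  # no adapter occurrence: unchanged
  clean <- rand_seq(1, 30, seed = 12)
  tr2 <- trim_reads(read_df(clean), ADAPTER)
  expect_equal(tr2$reads$sequence, clean)
  expect_equal(tr2$reads$trimmed_bases, 0)
  # 10-nt insert is discarded
  short <- paste0(substr(insert, 1, 10), ADAPTER)
  tr3 <- trim_reads(read_df(short), ADAPTER)
  expect_equal(nrow(tr3$reads), 0)
  expect_equal(unname(tr3$stats["discarded"]), 1)
})

test_that("trimming tolerates mismatches within the error rate", {
  insert <- rand_seq(1, 24, seed = 13)
  bad_adapter <- ADAPTER
  substr(bad_adapter, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ADAPTER, 5, 5))[1]
  read <- paste0(insert, bad_adapter)
  # 1 mismatch over 21 bases < 10% error
  expect_equal(trim_reads(read_df(read), ADAPTER)$reads$sequence, insert)
  # at 0% tolerance the imperfect adapter is not found
  strict <- trim_reads(read_df(read), ADAPTER, max_error_rate = 0)
  expect_equal(strict$reads$trimmed_bases, 0)
})

test_that("trimming recovers >=99% of simulated error-free inserts", {
  set.seed(14)
  n <- 10000
  lens <- sample(18:32, n, replace = TRUE)
  inserts <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1))
  reads <- substr(paste0(inserts, ADAPTER,
                         strrep("T", 40)), 1, 50)
  tr <- trim_reads(read_df(reads), ADAPTER)
  expect_gte(mean(tr$reads$sequence == inserts), 0.99)
})

test_that("read alignment honours the mismatch and multimapping contract", {
  set.seed(15)
  g <- rand_seq(1, 50000)
  genome <- c(chr1 = g)
  r_uniq <- substr(g, 301, 322)
  r_mm <- substr(g, 1001, 1024)
  substr(r_mm, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                  substr(r_mm, 12, 12))[1]
  al <- align_reads(read_df(c(r_uniq, r_mm)), genome)
  expect_equal(nrow(al$hits), 2)
  expect_equal(al$hits$n_hits, c(1L, 1L))
  expect_equal(al$hits$mismatches, c(0L, 1L))
  expect_equal(al$hits$start, c(301L, 1001L))
  expect_equal(unname(al$stats["unique"]), 2)
})

test_that("reads placed at more than max_loci sites come back unaligned", {
  set.seed(16)
  g <- rand_seq(1, 101 * 40 + 1000)
  piece <- rand_seq(1, 20)
  for (p in seq(1, 101 * 40, by = 40)) substr(g, p, p + 19) <- piece
  genome <- c(chr1 = g)
  oracle <- brute_scan(piece, genome, 14, 1)
  expect_gt(nrow(oracle), 100)
  al <- align_reads(read_df(piece), genome, max_loci = 100)
  expect_equal(nrow(al$hits), 0)
  expect_equal(unname(al$stats["unaligned"]), 1)
  # within the cap, placements equal the oracle's
  al2 <- align_reads(read_df(piece), genome, max_loci = 200)
  expect_identical(hit_key(al2$hits), hit_key(oracle))
})

count_fixture <- function() {
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 100, 500, 900, 935),
                             c(128, 128, 528, 950, 980)),
    strand = "+", gene_id = c("pA", "ignored", "pA", "pB", "pC"),
    gene_biotype = "piRNA", provenance = "rnacentral",
    alias_ids = "x")[-2]
  feats
}

test_that("feature counting assigns, fractions and drops ambiguity", {
  feats <- count_fixture()
  # unique read inside pB
  aln1 <- data.frame(read_id = "r1", chrom = "chr1", start = 905L,
                     end = 930L, strand = "+", mismatches = 0L,
                     n_hits = 1L, sequence = "N", weight = 1)
  ct <- count_features(aln1, feats, "fractional")
  expect_equal(unname(ct$counts["pB"]), 1)
  # read hitting both copies of multi-locus pA: fractional sums to 1
  aln2 <- data.frame(read_id = "r2", chrom = "chr1",
                     start = c(100L, 500L), end = c(125L, 525L),
                     strand = "+", mismatches = 0L, n_hits = 2L,
                     sequence = "N", weight = 0.5)
  ct2 <- count_features(aln2, feats, "fractional")
  expect_equal(unname(ct2$counts["pA"]), 1)
  # placement overlapping two distinct features is ambiguous and dropped
  aln3 <- data.frame(read_id = "r3", chrom = "chr1", start = 930L,
                     end = 955L, strand = "+", mismatches = 0L,
                     n_hits = 1L, sequence = "N", weight = 1)
  ct3 <- count_features(aln3, feats, "fractional")
  expect_equal(sum(ct3$counts), 0)
  expect_equal(unname(ct3$stats["ambiguous"]), 1)
  # antisense placements are not assigned
  aln4 <- transform(aln1, strand = "-")
  expect_equal(sum(count_features(aln4, feats)$counts), 0)
})

test_that("counting modes are ordered all >= fractional >= unique", {
  fix <- default_fix()
  track <- default_track()
  sim <- simulate_reads(fix, "two_group")
  reads <- trim_reads(sim$reads[[1]][1:4000, ], ADAPTER)$reads
  al <- align_reads(reads, fix$genome)
  c_all <- quiet(count_features(al$hits, track, "all"))$counts
  c_frac <- quiet(count_features(al$hits, track, "fractional"))$counts
  c_uni <- quiet(count_features(al$hits, track, "unique"))$counts
  expect_true(all(c_all - c_frac >= -1e-9))
  expect_true(all(c_frac - c_uni >= -1e-9))
})

test_that("EM puts unique reads on their transcript and splits ties", {
  tx <- c(t1 = rand_seq(1, 60, seed = 17), t2 = rand_seq(1, 60))
  reads <- rep(substr(tx[["t1"]], 10, 35), 10)
  q <- quantify_transcripts(reads, tx, n_bootstraps = 0)
  expect_equal(unname(q$counts), c(10, 0))
  # two identical transcripts share reads equally
  tx2 <- c(a = tx[["t1"]], b = tx[["t1"]])
  q2 <- quantify_transcripts(reads, tx2, n_bootstraps = 0)
  expect_equal(unname(q2$counts), c(5, 5))
  expect_error(quantify_transcripts(reads, character(0)), "empty")
})

test_that("EM conserves mass and has non-decreasing log-likelihood", {
  set.seed(18)
  shared <- rand_seq(1, 40)
  tx <- c(t1 = paste0(rand_seq(1, 40), shared),
          t2 = paste0(shared, rand_seq(1, 40)),
          t3 = rand_seq(1, 80))
  pool <- c(rep(tx[["t1"]], 6), rep(tx[["t2"]], 3), rep(tx[["t3"]], 1))
  reads <- vapply(sample(pool, 800, replace = TRUE), function(s) {
    p <- sample(nchar(s) - 24, 1)
    substr(s, p, p + 23)
  }, character(1), USE.NAMES = FALSE)
  q <- quantify_transcripts(reads, tx, n_bootstraps = 0)
  expect_equal(sum(q$counts), q$n_mapped, tolerance = 1e-6)
  expect_true(all(diff(q$loglik_trace) > -1e-8))
})

test_that("EM recovers a planted 60/30/10 mixture within 3 bootstrap SD", {
  set.seed(19)
  shared <- rand_seq(1, 50)
  tx <- c(t1 = paste0(rand_seq(1, 50), shared),
          t2 = paste0(shared, rand_seq(1, 50)),
          t3 = rand_seq(1, 100))
  n <- 5000
  origin <- sample(names(tx), n, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
  reads <- vapply(origin, function(t) {
    s <- tx[[t]]
    p <- sample(nchar(s) - 21, 1)
    substr(s, p, p + 20)
  }, character(1), USE.NAMES = FALSE)
  q <- quantify_transcripts(reads, tx, n_bootstraps = 50, seed = 7)
  truth <- as.numeric(table(factor(origin, levels = names(tx))))
  expect_true(all(abs(q$counts - truth) <= 3 * pmax(q$bootstrap_sd, 1)))
})

test_that("EM agrees with a likelihood-grid oracle on a tiny instance", {
  # two transcripts, three classes: {1}: 30 reads, {2}: 10, {1,2}: 20
  tx <- c(t1 = paste0(rand_seq(1, 30, seed = 20), strrep("ACGT", 10)),
          t2 = paste0(strrep("ACGT", 10), rand_seq(1, 30)))
  u1 <- substr(tx[["t1"]], 3, 24)
  u2 <- substr(tx[["t2"]], 48, 69)
  sh <- substr(tx[["t1"]], 35, 56)   # inside the shared block
  reads <- c(rep(u1, 30), rep(u2, 10), rep(sh, 20))
  q <- quantify_transcripts(reads, tx, n_bootstraps = 0)
  # grid maximisation of the observed-class log-likelihood
  grid <- seq(0.001, 0.999, by = 0.001)
  ll <- 30 * log(grid / 2) + 10 * log((1 - grid) / 2) + 20 * log(1 / 2)
  p_hat <- grid[which.max(ll)]
  expect_equal(q$counts[["t1"]] / 60, p_hat, tolerance = 0.01)
})

test_that("consensus set algebra follows the planted overlap", {
  set.seed(21)
  both <- paste0("b", 1:30); gen <- paste0("g", 1:10); tx <- paste0("t", 1:5)
  feats <- c(both, gen, tx)
  gm <- matrix(0, length(feats), 3,
               dimnames = list(feats, paste0("s", 1:3)))
  tm <- gm
  gm[c(both, gen), ] <- 50
  tm[c(both, tx), ] <- 50
  u <- quiet(consensus_expressed(gm, tm, "union", 1, 1))
  i <- quiet(consensus_expressed(gm, tm, "intersection", 1, 1))
  expect_equal(length(u$features), 45)
  expect_equal(length(i$features), 30)
  expect_true(all(i$features %in% u$features))
  expect_true(all(i$features %in% u$genomic) &&
                all(i$features %in% u$tx))
  m2 <- gm; colnames(m2) <- paste0("x", 1:3)
  expect_error(consensus_expressed(gm, m2, "union"), "different samples")
})
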