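test_that("default k follows read length and rejects too-short reads", {
  expect_identical(choose_k(50), 21L)
  expect_identical(choose_k(100), 31L)
  expect_identical(choose_k(69), 21L)
  expect_identical(choose_k(70), 31L)
  expect_error(choose_k(24), "too small")
})

test_that("mapping_params enforces k >= 11 and flags disabled split detection", {
  expect_error(mapping_params(10, 100), ">= 11")
  p <- mapping_params(21, 50)
  expect_true(p$split_enabled)
  expect_warning(p2 <- mapping_params(31, 50), "disabled")
  expect_false(p2$split_enabled)
})

test_that("index holds L - k + 1 postings per transcript and shares duplicates", {
  set.seed(7)
  s <- rand_dna(100)
  t1 <- transcriptome(
    data.frame(transcript_id = c("T1", "T2"), gene_id = c("g1", "g2"),
               chrom = c("1", "2"), strand = "+", length = 100,
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("g1", "g2"), gene_name = c("g1", "g2"),
               chrom = c("1", "2"), strand = "+", start = 1, end = 100,
               biotype = "protein_coding", stringsAsFactors = FALSE),
    data.frame(transcript_id = c("T1", "T2"), start = 1, end = 100),
    c(T1 = s, T2 = s))
  idx <- build_index(t1, k = 31)
  # identical transcripts: every k-mer posts to both
  for (i in c(1, 20, 70)) {
    h <- kmer_lookup(idx, substr(s, i, i + 30))
    expect_setequal(h$transcript_id[h$orientation == "fwd"], c("T1", "T2"))
    expect_true(all(h$pos[h$orientation == "fwd"] == i))
  }
  # 70 = L - k + 1 distinct posting positions per transcript
  pos <- unlist(lapply(1:70, function(i) {
    h <- kmer_lookup(idx, substr(s, i, i + 30))
    h$pos[h$transcript_id == "T1" & h$orientation == "fwd"]
  }))
  expect_equal(sort(unique(pos)), 1:70)
})

test_that("index lookups agree with a naive substring scan (exhaustive on toy)", {
  t <- toy_txome()
  idx <- build_index(t, k = 21)
  # naive posting table: every k-mer occurrence of every transcript
  naive <- do.call(rbind, lapply(names(t$sequences), function(id) {
    s <- t$sequences[[id]]
    n <- nchar(s) - 20L
    data.frame(kmer = substring(s, 1:n, 21:(n + 20L)),
               transcript_id = id, pos = 1:n, stringsAsFactors = FALSE)
  }))
  mism <- 0L
  for (q in unique(naive$kmer)) {
    fwd <- naive[naive$kmer == q, c("transcript_id", "pos")]
    rc <- naive[naive$kmer == revcomp(q), c("transcript_id", "pos")]
    want <- rbind(
      if (nrow(fwd)) cbind(fwd, orientation = "fwd"),
      if (nrow(rc)) cbind(rc, orientation = "rc"))
    got <- kmer_lookup(idx, q)
    if (!isTRUE(all.equal(sort_hits(got), sort_hits(want),
                          check.attributes = FALSE)))
      mism <- mism + 1L
  }
  expect_identical(mism, 0L)
  # and random k-mers (typically absent from the transcriptome)
  set.seed(31)
  for (j in 1:10) {
    km <- rand_dna(21)
    expect_equal(sort_hits(kmer_lookup(idx, km)),
                 sort_hits(naive_kmer_scan(t, km)))
  }
})

test_that("map_read recovers exact substrings, chimeras and rejects N-reads", {
  t <- toy_txome()
  idx <- build_index(t, k = 21)
  # exact substring of GC.T1
  read <- substr(t$sequences[["GC.T1"]], 101, 150)
  m <- map_read(read, idx)
  expect_equal(m$total_matched, 50)
  expect_length(m$segments, 1)
  expect_equal(m$segments[[1]]$query_start, 1)
  expect_equal(m$segments[[1]]$query_end, 50)
  expect_true("GC.T1" %in% m$segments[[1]]$hits$transcript_id)
  expect_equal(m$segments[[1]]$hits$tx_start[
    m$segments[[1]]$hits$transcript_id == "GC.T1"], 101)
  # chimeric 25|25 across GC and GB
  chim <- paste0(substr(t$sequences[["GC.T1"]], 100, 124),
                 substr(t$sequences[["GB.T1"]], 500, 524))
  mc <- map_read(chim, idx)
  expect_length(mc$segments, 2)
  expect_true(all(mc$segments[[1]]$hits$transcript_id == "GC.T1"))
  expect_true(all(mc$segments[[2]]$hits$transcript_id == "GB.T1"))
  expect_equal(mc$segments[[2]]$hits$tx_start, 500)
  # read of Ns maps nowhere
  expect_length(map_read(strrep("N", 50), idx)$segments, 0)
})

test_that("mapping is strand-symmetric", {
  t <- toy_txome()
  idx <- build_index(t, k = 21)
  read <- substr(t$sequences[["GA.T1"]], 301, 400)
  f <- map_read(read, idx)
  r <- map_read(revcomp(read), idx)
  expect_equal(f$orientation, "fwd")
  expect_equal(r$orientation, "rc")
  expect_equal(r$total_matched, f$total_matched)
  expect_equal(r$seq, f$seq)   # normalized to mapped orientation
  expect_equal(r$segments, f$segments)
})

test_that("reads generated from a transcript map with full single-segment coverage", {
  t <- simulate_transcriptome(n_genes = 6, seed = 77)
  idx <- build_index(t, k = 31)
  set.seed(12)
  for (i in 1:25) {
    id <- sample(t$transcripts$transcript_id, 1)
    L <- nchar(t$sequences[[id]])
    st <- sample(L - 99, 1)
    read <- substr(t$sequences[[id]], st, st + 99)
    if (runif(1) < 0.5) read <- revcomp(read)
    m <- map_read(read, idx)
    expect_gte(m$total_matched, 99)
    expect_true(id %in% m$segments[[1]]$hits$transcript_id)
  }
})

test_that("map_pair derives T1/T2/S/S1/S2 by set arithmetic", {
  # shared regions force controlled multi-transcript hits:
  # tx1 = A+U1, tx2 = A+B, tx3 = C+B  (A, B, C unique blocks)
  set.seed(55)
  A <- rand_dna(300); B <- rand_dna(300); C <- rand_dna(300)
  U1 <- rand_dna(300)
  mk <- function(ids, seqs, genes) {
    transcriptome(
      data.frame(transcript_id = ids, gene_id = genes,
                 chrom = as.character(seq_along(ids)), strand = "+",
                 length = nchar(seqs), stringsAsFactors = FALSE),
      data.frame(gene_id = unique(genes), gene_name = unique(genes),
                 chrom = as.character(seq_along(unique(genes))), strand = "+",
                 start = 1, end = 600, biotype = "protein_coding",
                 stringsAsFactors = FALSE),
      data.frame(transcript_id = ids, start = 1, end = nchar(seqs)),
      stats::setNames(seqs, ids))
  }
  t <- mk(c("tx1", "tx2", "tx3"),
          c(paste0(A, U1), paste0(A, B), paste0(C, B)),
          c("g1", "g2", "g3"))
  idx <- build_index(t, k = 21)
  r1 <- substr(A, 101, 200)            # hits tx1, tx2
  r2 <- revcomp(substr(B, 101, 200))   # hits tx2, tx3
  pm <- map_pair(r1, r2, idx, read_id = "p1")
  expect_setequal(pm$T1, c("tx1", "tx2"))
  expect_setequal(pm$T2, c("tx2", "tx3"))
  expect_setequal(pm$S, "tx2")
  expect_setequal(pm$S1, "tx1")
  expect_setequal(pm$S2, "tx3")
  # concordant: both mates from tx1's unique region
  pm2 <- map_pair(substr(U1, 1, 100), revcomp(substr(U1, 151, 250)), idx)
  expect_setequal(pm2$S, "tx1")
  expect_length(pm2$S1, 0)
  expect_length(pm2$S2, 0)
  # fully discordant
  pm3 <- map_pair(substr(U1, 1, 100), revcomp(substr(C, 1, 100)), idx)
  expect_length(pm3$S, 0)
  expect_setequal(pm3$S1, "tx1")
  expect_setequal(pm3$S2, "tx3")
})
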