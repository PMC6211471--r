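# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hand-assembled transcriptome: 3 genes / 5 transcripts with controlled
# sequence sharing (tx1/tx2 share a prefix within gene GA; GB has two
# isoforms sharing their first exon; GC is single-isoform).
toy_txome <- function() {
  set.seed(4242)
  exA1 <- rand_dna(400)
  exA2 <- rand_dna(300)
  exA3 <- rand_dna(200)
  exB1 <- rand_dna(350)
  exB2 <- rand_dna(250)
  exC1 <- rand_dna(500)
  tx <- data.frame(
    transcript_id = c("GA.T1", "GA.T2", "GB.T1", "GB.T2", "GC.T1"),
    gene_id = c("GA", "GA", "GB", "GB", "GC"),
    chrom = c("1", "1", "2", "2", "3"),
    strand = "+",
    length = c(900, 700, 600, 350, 500),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC"),
    gene_name = c("GA", "GB", "GC"),
    chrom = c("1", "2", "3"), strand = "+",
    start = c(1000, 2000, 3000),
    end = c(1000 + 400 + 100 + 300 + 100 + 200 - 1,
            2000 + 350 + 150 + 250 - 1, 3499),
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(transcript_id = "GA.T1",
               start = c(1000, 1500, 1900),
               end = c(1399, 1799, 2099)),
    data.frame(transcript_id = "GA.T2",
               start = c(1000, 1500), end = c(1399, 1799)),
    data.frame(transcript_id = "GB.T1",
               start = c(2000, 2500), end = c(2349, 2749)),
    data.frame(transcript_id = "GB.T2",
               start = 2000, end = 2349),
    data.frame(transcript_id = "GC.T1", start = 3000, end = 3499))
  seqs <- c(
    GA.T1 = paste0(exA1, exA2, exA3),
    GA.T2 = paste0(exA1, exA2),
    GB.T1 = paste0(exB1, exB2),
    GB.T2 = exB1,
    GC.T1 = exC1)
  transcriptome(tx, genes, exons, seqs)
}

# naive k-mer scan oracle: all occurrences of `kmer` (fwd) and its
# reverse complement (rc) across transcript sequences
naive_kmer_scan <- function(t, kmer) {
  out <- list()
  rc <- revcomp(kmer)
  for (id in names(t$sequences)) {
    s <- t$sequences[[id]]
    for (or in c("fwd", "rc")) {
      pat <- if (or == "fwd") kmer else rc
      p <- gregexpr(pat, s, fixed = TRUE)[[1]]
      p <- p[p > 0]
      # gregexpr misses overlapping matches; rescan manually
      p <- which(vapply(seq_len(max(0, nchar(s) - nchar(pat) + 1)),
                        function(i) substr(s, i, i + nchar(pat) - 1) == pat,
                        logical(1)))
      if (or == "rc" && pat == kmer) next  # palindromic: already counted
      for (x in p)
        out[[length(out) + 1]] <- data.frame(
          transcript_id = id, pos = x, orientation = or,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(transcript_id = character(0), pos = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

sort_hits <- function(df) {
  df <- df[order(df$transcript_id, df$pos, df$orientation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force feq oracle: group pairs by their exact fusion-transcript
# candidate set, discarding fragments whose 5'/3' sides share a gene
brute_feq <- function(pairs, t2g) {
  keys <- character(0)
  kept <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (length(intersect(unique(t2g[p$S1]), unique(t2g[p$S2]))) > 0) next
    kept[i] <- TRUE
    ft <- expand.grid(tx5 = p$S1, tx3 = p$S2, stringsAsFactors = FALSE)
    keys[i] <- paste(sort(paste(ft$tx5, ft$tx3, sep = "~")), collapse = ";")
  }
  table(keys[kept])
}

# brute-force support / corrected counts over a brute_feq grouping
brute_counts <- function(pairs, t2g, g5, g3) {
  tab <- brute_feq(pairs, t2g)
  support <- 0L
  corrected <- 0
  for (key in names(tab)) {
    ftx <- strsplit(key, ";", fixed = TRUE)[[1]]
    parts <- strsplit(ftx, "~", fixed = TRUE)
    hit <- any(vapply(parts, function(x)
      t2g[[x[1]]] == g5 && t2g[[x[2]]] == g3, logical(1)))
    if (hit) {
      support <- support + tab[[key]]
      corrected <- corrected + tab[[key]] / length(ftx)
    }
  }
  list(support = support, corrected = corrected)
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# exact test on a 2x2 table (sum of probabilities <= observed)
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# minimal fabricated split evidence for screen-level tests
fake_evidence <- function(read_id = "r1", r = 100,
                          qend5 = 50, qstart3 = 51,
                          cov5 = 50, cov3 = 50,
                          gene5 = "GA", gene3 = "GB",
                          tx5 = "GA.T1", tx3 = "GB.T1",
                          brk5 = 400, brk3 = 100,
                          anchor_gene = "GA", anchor_tx = "GA.T1",
                          anchor_pos = 300) {
  structure(list(
    read_id = read_id, seq = strrep("A", r), r = r,
    qstart5 = 1, qend5 = qend5, qstart3 = qstart3, qend3 = r,
    tx5 = data.frame(transcript_id = tx5, gene_id = gene5, tx_break = brk5,
                     stringsAsFactors = FALSE),
    tx3 = data.frame(transcript_id = tx3, gene_id = gene3, tx_break = brk3,
                     stringsAsFactors = FALSE),
    genes5 = gene5, genes3 = gene3,
    cov5 = cov5, cov3 = cov3,
    anchor = data.frame(transcript_id = anchor_tx, gene_id = anchor_gene,
                        pos = anchor_pos, stringsAsFactors = FALSE)),
    class = "split_evidence")
}

# minimal fabricated candidate for filter-level tests
fake_candidate <- function(gene5 = "GA", gene3 = "GB",
                           mr_support = 5, mr_corrected = mr_support,
                           sr_support = 0, sr_corrected = sr_support,
                           read_ids = sprintf("p%d", seq_len(mr_support)),
                           start5 = seq_len(mr_support) * 10L,
                           start3 = seq_len(mr_support) * 10L + 5L,
                           breakpoint = NULL, score = NULL,
                           flags = character(0)) {
  structure(list(
    gene5 = gene5, gene3 = gene3,
    mr_support = mr_support, mr_corrected = mr_corrected,
    sr_support = sr_support, sr_corrected = sr_corrected,
    read_ids = read_ids, start5 = start5, start3 = start3,
    tx5rep = rep(NA_character_, length(read_ids)),
    tx3rep = rep(NA_character_, length(read_ids)),
    breakpoint = breakpoint, motif = "unknown",
    flags = flags, source = "MR",
    score = if (is.null(score)) mr_corrected + sr_corrected else score),
    class = "fusion_candidate")
}
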