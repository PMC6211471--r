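# Classification of pairs into concordant / spanning / split / other,
# and split evidence extraction, on constructed fixtures.

make_pair_txome <- function(seed = 123) {
  set.seed(seed)
  seqs <- c(TA = rand_dna(1000), TB = rand_dna(1000))
  transcriptome(
    data.frame(transcript_id = c("TA", "TB"), gene_id = c("gA", "gB"),
               chrom = c("1", "2"), strand = "+", length = 1000,
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("gA", "gB"), gene_name = c("gA", "gB"),
               chrom = c("1", "2"), strand = "+", start = 1, end = 1000,
               biotype = "protein_coding", stringsAsFactors = FALSE),
    data.frame(transcript_id = c("TA", "TB"), start = 1, end = 1000),
    seqs)
}

test_that("the r-k-1 threshold decides spanning-pair status (boundary at 28/50)", {
  t <- make_pair_txome()
  idx <- build_index(t, k = 21)
  params <- mapping_params(21, 50)
  # each mate: 28 matched bases (= 50 - 21 - 1), rest random
  set.seed(5)
  r1 <- paste0(substr(t$sequences[["TA"]], 101, 128), rand_dna(22))
  r2 <- paste0(substr(t$sequences[["TB"]], 501, 528), rand_dna(22))
  pm <- map_pair(r1, revcomp(r2), idx)
  expect_equal(classify_pair(pm, params, t)$label, "mapped_read")
  # 27 matched bases: below threshold
  r1b <- paste0(substr(t$sequences[["TA"]], 101, 127), rand_dna(23))
  pmb <- map_pair(r1b, revcomp(r2), idx)
  expect_equal(classify_pair(pmb, params, t)$label, "unmapped/other")
})

test_that("25|25 chimeric mate with anchored pair is a split read", {
  t <- make_pair_txome()
  idx <- build_index(t, k = 21)
  params <- mapping_params(21, 50)
  chim <- paste0(substr(t$sequences[["TA"]], 376, 400),
                 substr(t$sequences[["TB"]], 500, 524))
  anchor <- substr(t$sequences[["TA"]], 200, 249)   # fully inside gene A
  pm <- map_pair(chim, revcomp(anchor), idx)
  expect_equal(classify_pair(pm, params, t)$label, "split_read")
  # anchored in neither constituent gene -> not a split read
  t3 <- make_pair_txome()
  t3$transcripts <- rbind(t3$transcripts, data.frame(
    transcript_id = "TC", gene_id = "gC", chrom = "3", strand = "+",
    length = 1000, stringsAsFactors = FALSE))
  t3$genes <- rbind(t3$genes, data.frame(
    gene_id = "gC", gene_name = "gC", chrom = "3", strand = "+",
    start = 1, end = 1000, biotype = "protein_coding", stringsAsFactors = FALSE))
  t3$exons <- rbind(t3$exons, data.frame(transcript_id = "TC", start = 1, end = 1000))
  set.seed(77)
  t3$sequences <- c(t3$sequences, c(TC = rand_dna(1000)))
  idx3 <- build_index(t3, k = 21)
  far <- substr(t3$sequences[["TC"]], 200, 249)
  pm3 <- map_pair(chim, revcomp(far), idx3)
  expect_equal(classify_pair(pm3, params, t3)$label, "unmapped/other")
})

test_that("pairs sharing a transcript are concordant", {
  t <- make_pair_txome()
  idx <- build_index(t, k = 21)
  params <- mapping_params(21, 50)
  pm <- map_pair(substr(t$sequences[["TA"]], 1, 50),
                 revcomp(substr(t$sequences[["TA"]], 201, 250)), idx)
  expect_equal(classify_pair(pm, params, t)$label, "concordant")
})

test_that("extract_split_info records first/last segment mapping and anchor", {
  t <- make_pair_txome()
  idx <- build_index(t, k = 21)
  chim <- paste0(substr(t$sequences[["TA"]], 376, 400),
                 substr(t$sequences[["TB"]], 500, 524))
  anchor <- substr(t$sequences[["TA"]], 200, 249)
  rm <- map_read(chim, idx)
  arm <- map_read(revcomp(anchor), idx)
  ev <- extract_split_info(rm, arm, t, read_id = "sr1", k = 21)
  expect_s3_class(ev, "split_evidence")
  expect_equal(ev$genes5, "gA")
  expect_equal(ev$genes3, "gB")
  expect_equal(ev$tx5$tx_break, 400)   # last 5' base of the junction
  expect_equal(ev$tx3$tx_break, 500)   # first 3' base
  expect_equal(ev$anchor$gene_id, "gA")
  expect_equal(ev$anchor$pos, 200)
  expect_error(extract_split_info(arm, rm, t), "non-split")
})

test_that("multi-isoform 5' side records all transcripts of the gene", {
  t <- toy_txome()
  idx <- build_index(t, k = 21)
  # junction inside the region shared by GB.T1 and GB.T2 (first 350 bases)
  chim <- paste0(substr(t$sequences[["GB.T1"]], 274, 300),
                 substr(t$sequences[["GC.T1"]], 200, 226))
  anchor <- substr(t$sequences[["GB.T1"]], 100, 149)
  rm <- map_read(chim, idx)
  arm <- map_read(revcomp(anchor), idx)
  ev <- extract_split_info(rm, arm, t, k = 21)
  expect_setequal(ev$tx5$transcript_id, c("GB.T1", "GB.T2"))
  expect_true(all(ev$tx5$gene_id == "GB"))
})

test_that("noise-free junction-covering fragments classify by their geometry", {
  t <- simulate_transcriptome(n_genes = 10, seed = 31)
  tr <- implant_fusions(t, 2, seed = 31)
  sim <- simulate_reads(t, tr, fusion_abundance = 40, seed = 32,
                        read_length = 100)
  idx <- build_index(t, k = 31)
  params <- mapping_params(31, 100)
  k <- 31L
  r <- 100L
  labels <- character(length(sim$reads1))
  for (i in seq_along(sim$reads1)) {
    pm <- map_pair(sim$reads1[[i]], sim$reads2[[i]], idx)
    labels[i] <- classify_pair(pm, params, t)$label
    o <- sim$origin[i, ]
    bp <- tr$breakpoint5[tr$fusion_id == o$source]
    m1 <- c(o$start, o$start + r - 1L)                       # fragment 5' mate
    m2 <- c(o$start + o$fraglen - r, o$start + o$fraglen - 1L)
    sides <- function(m) c(bp - m[1] + 1L, m[2] - bp)        # bases on 5'/3' side
    cross1 <- m1[1] <= bp && m1[2] > bp
    cross2 <- m2[1] <= bp && m2[2] > bp
    # a mate is a clean chimera when both sides carry >= k bases but
    # neither reaches the near-full threshold r-k-1 (otherwise it counts
    # as mostly mapped to its majority gene and the pair may resolve as
    # concordant or spanning instead)
    clean_split <- function(m) min(sides(m)) >= k && max(sides(m)) < r - k - 1
    anchored <- function(m, cross) !cross || max(sides(m)) >= r - k - 1
    if (!cross1 && !cross2) {
      # both mates clear of the junction: always a spanning pair
      expect_equal(labels[i], "mapped_read", info = paste("fragment", i))
    } else if ((cross1 && clean_split(m1) && anchored(m2, cross2)) ||
               (cross2 && clean_split(m2) && anchored(m1, cross1))) {
      expect_true(labels[i] %in% c("mapped_read", "split_read"),
                  info = paste("fragment", i))
    }
    # remaining geometries (minority side < k, majority side near-full,
    # both mates straddling with balanced splits) may legitimately fall
    # outside both fusion-evidence classes
  }
  expect_gt(sum(labels == "mapped_read"), 0)
  expect_gt(sum(labels == "split_read"), 0)
})
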