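# Filter cascade units: general features, inverted fusions, similarity,
# shared support, positional distribution, consistency and annotation.

test_that("general filter drops off-target chromosomes, biotypes, near genes", {
  t <- toy_txome()
  cfg <- filter_config()
  # chrM partner
  tm <- t; tm$genes$chrom[tm$genes$gene_id == "GA"] <- "MT"
  gf <- general_filter(fake_candidate("GA", "GB"), tm, cfg)
  expect_false(gf$keep); expect_true("chromosome" %in% gf$reasons)
  # lincRNA partner
  tb <- t; tb$genes$biotype[tb$genes$gene_id == "GB"] <- "lincRNA"
  gf2 <- general_filter(fake_candidate("GA", "GB"), tb, cfg)
  expect_false(gf2$keep); expect_true("biotype" %in% gf2$reasons)
  expect_true(general_filter(fake_candidate("GA", "GB"), tb,
                             filter_config(require_protein_coding = FALSE))$keep)
  # same-chromosome genes 5 kb apart with 100 kb minimum
  tc <- t
  tc$genes$chrom <- c("1", "1", "3")
  tc$genes$start <- c(1000, 8000, 3000)
  tc$genes$end <- c(2099, 9000, 3499)
  tc$exons$start[tc$exons$transcript_id %in% c("GB.T1", "GB.T2")] <- 8000
  tc$exons$end[tc$exons$transcript_id %in% c("GB.T1", "GB.T2")] <- 9000
  gf3 <- general_filter(fake_candidate("GA", "GB"), tc, cfg)
  expect_false(gf3$keep); expect_true("distance" %in% gf3$reasons)
  # different chromosomes (INF) always pass the distance rule
  expect_true(general_filter(fake_candidate("GA", "GB"), t, cfg)$keep)
  # support thresholds per evidence type
  gf4 <- general_filter(fake_candidate("GA", "GB", mr_support = 1), t, cfg, "mr")
  expect_false(gf4$keep); expect_true("mr_support" %in% gf4$reasons)
  gf5 <- general_filter(fake_candidate("GA", "GB", mr_support = 0, sr_support = 0),
                        t, cfg, "sr")
  expect_false(gf5$keep); expect_true("sr_support" %in% gf5$reasons)
})

test_that("inverted fusions keep the higher-scoring direction; ties drop both", {
  a <- fake_candidate("GA", "GB", score = 10)
  b <- fake_candidate("GB", "GA", score = 2)
  r <- inverted_fusion_filter(list(a, b))
  expect_length(r$kept, 1)
  expect_equal(r$kept[[1]]$gene5, "GA")
  expect_true("inverted" %in% r$dropped[[1]]$flags)
  # single direction unchanged
  r2 <- inverted_fusion_filter(list(a))
  expect_length(r2$kept, 1)
  # exact tie: both dropped, flagged circular
  r3 <- inverted_fusion_filter(list(fake_candidate("GA", "GB", score = 4),
                                    fake_candidate("GB", "GA", score = 4)))
  expect_length(r3$kept, 0)
  expect_true(all(vapply(r3$dropped, function(c) "circular" %in% c$flags,
                         logical(1))))
})

test_that("similarity reference finds planted duplicated-exon gene pairs", {
  t <- simulate_transcriptome(n_genes = 6, tx_per_gene = 1, seed = 15,
                              duplicate_exon = c(1, 2))
  cfg <- filter_config(sim_read_count = 300, sim_seed = 99)
  ref <- build_similarity_reference(t, cfg)
  expect_true("G001|G002" %in% ref)
  # determinism
  expect_identical(ref, build_similarity_reference(t, cfg))
  # unique-sequence transcriptome: empty reference
  t2 <- simulate_transcriptome(n_genes = 6, tx_per_gene = 1, seed = 16)
  expect_length(build_similarity_reference(t2, cfg), 0)
})

test_that("similarity filter consults all three references", {
  cand <- fake_candidate("GA", "GB")
  expect_true(similarity_filter(cand)$keep)
  expect_false(similarity_filter(cand, simref = "GA|GB")$keep)
  expect_false(similarity_filter(
    cand, paralog_db = data.frame(a = "GB", b = "GA"))$keep)  # unordered
  expect_false(similarity_filter(cand, readthrough_db = "GA|GB")$keep)
  expect_true(similarity_filter(cand, simref = "GA|GC")$keep)
})

test_that("mostly-shared supporting fragments drop the lower-scoring candidate", {
  a <- fake_candidate("GA", "GB", mr_support = 10,
                      read_ids = sprintf("p%d", 1:10))
  b <- fake_candidate("GA", "GC", mr_support = 9, mr_corrected = 4,
                      read_ids = sprintf("p%d", 1:9))   # 9 of 9 shared
  r <- shared_support_screen(list(a, b))
  expect_length(r$kept, 1)
  expect_equal(r$kept[[1]]$gene3, "GB")
  expect_true("shared_support" %in% r$dropped[[1]]$flags)
  # disjoint support: both kept
  c2 <- fake_candidate("GA", "GC", read_ids = sprintf("q%d", 1:5))
  expect_length(shared_support_screen(list(a, c2))$kept, 2)
})

test_that("positional filter collapses duplicates, trims outliers, checks junction distance", {
  cfg <- filter_config()
  # 10 supporting pairs at identical starts collapse to 1 -> below minimum
  cand <- fake_candidate("GA", "GB", mr_support = 10,
                         start5 = rep(100L, 10), start3 = rep(400L, 10))
  r <- positional_filter(cand, cfg)
  expect_false(r$keep)
  expect_equal(r$cand$mr_support, 1L)
  expect_true("mr_support" %in% r$reasons)
  # duplicate collapse can be disabled
  r_nodup <- positional_filter(cand, filter_config(dup_collapse = FALSE))
  expect_true(r_nodup$keep)
  expect_equal(r_nodup$cand$mr_support, 10L)
  # fragment-length outlier: 19 pairs at fraglen 200, 1 at 2000
  n <- 20
  start5 <- rep(301L, n)                      # b5 estimate: 301+99 = 400
  start3 <- c(rep(1L, n - 1), 1801L)          # outlier implies +1800
  start5 <- start5 - seq_len(n)               # make starts distinct
  cand2 <- fake_candidate("GA", "GB", mr_support = n,
                          start5 = start5, start3 = start3)
  r2 <- positional_filter(cand2, cfg, read_length = 100)
  expect_true(r2$keep)
  expect_equal(r2$cand$mr_support, n - 1L)
  expect_false("p20" %in% r2$cand$read_ids)
  # same-chromosome breakpoints 3 kb apart with a 100 kb minimum
  bp <- list(chrom5 = "1", chrom3 = "1", genomic_pos5 = 10000,
             genomic_pos3 = 13000, tx_pos5 = 400, tx_pos3 = 100)
  cand3 <- fake_candidate("GA", "GB", breakpoint = bp)
  r3 <- positional_filter(cand3, cfg)
  expect_false(r3$keep)
  expect_true("junction_distance" %in% r3$reasons)
  # all-equal fragment lengths pass untouched (degenerate MAD)
  cand4 <- fake_candidate("GA", "GB", mr_support = 5,
                          start5 = 101:105, start3 = 201:205)
  r4 <- positional_filter(cand4, cfg)
  expect_true(r4$keep)
  expect_equal(r4$cand$mr_support, 5L)
})

test_that("spanning/split consistency uses a two-sided binomial test, flag-only", {
  # single-evidence candidates are never tested
  c1 <- mr_sr_consistency(fake_candidate("GA", "GB", mr_support = 10))
  expect_false("mr_sr_inconsistent" %in% c1$flags)
  # balanced counts consistent with p0 = 0.5
  c2 <- mr_sr_consistency(fake_candidate("GA", "GB", mr_support = 50,
                                         sr_support = 48))
  expect_false("mr_sr_inconsistent" %in% c2$flags)
  expect_gt(stats::binom.test(48, 98, 0.5)$p.value, 0.01)
  # extreme imbalance flags
  c3 <- mr_sr_consistency(fake_candidate("GA", "GB", mr_support = 200,
                                         sr_support = 1))
  expect_true("mr_sr_inconsistent" %in% c3$flags)
  expect_lt(stats::binom.test(1, 201, 0.5)$p.value, 0.01)
})

test_that("special gene classes are flagged, never dropped", {
  db <- list(ribosomal = c("GB"), mito_translation = c("GA", "GB"))
  c1 <- annotate_special_genes(fake_candidate("GA", "GB"), db)
  expect_true("ribosomal:3" %in% c1$flags)
  expect_true(all(c("mito_translation:5", "mito_translation:3") %in% c1$flags))
  c2 <- annotate_special_genes(fake_candidate("GC", "GD"), db)
  expect_length(c2$flags, 0)
  c3 <- annotate_special_genes(fake_candidate("GA", "GB"), list())
  expect_length(c3$flags, 0)
})

test_that("with thresholds at zero and empty references filters are the identity", {
  t <- toy_txome()
  cfg <- filter_config(min_gene_distance = 0, min_mr_support = 0,
                       min_sr_support = 0, min_score = 0, dup_collapse = FALSE,
                       fraglen_z_max = Inf, min_junction_distance = 0,
                       require_protein_coding = FALSE)
  cand <- fake_candidate("GA", "GB", mr_support = 1,
                         start5 = c(5L), start3 = c(7L),
                         read_ids = "p1")
  expect_true(general_filter(cand, t, cfg)$keep)
  pf <- positional_filter(cand, cfg)
  expect_true(pf$keep)
  expect_equal(pf$cand$mr_support, cand$mr_support)
  expect_true(similarity_filter(cand)$keep)
})
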