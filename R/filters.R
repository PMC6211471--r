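# Candidate-level filters: general gene features, sequence similarity
# (simulated equivalence-class reference, paralog/read-through lists,
# shared-support screen), positional distribution (duplicate collapse,
# fragment-length outliers, junction distance), inverted fusions, and
# annotative tests.

#' Filter configuration
#'
#' All thresholds of the filtering cascade with their defaults. Distances
#' are in bases; `INF` gene distance (different chromosomes) always
#' passes.
#'
#' @param allowed_chroms chromosomes candidates may live on.
#' @param require_protein_coding drop candidates with a non-protein-coding
#'   constituent gene.
#' @param min_gene_distance minimum genomic separation of same-chromosome
#'   constituent genes.
#' @param min_mr_support minimum junction-spanning pair support (applied
#'   to deduplicated counts).
#' @param min_sr_support minimum split-read support.
#' @param min_score minimum final score (corrected spanning + split
#'   counts).
#' @param dup_collapse collapse supporting pairs with identical start
#'   positions (PCR/optical duplicates).
#' @param fraglen_z_max robust z-score bound for implied fragment lengths.
#' @param min_junction_distance minimum separation of same-chromosome
#'   breakpoints.
#' @param max_overlap maximum query overlap between the two sides of a
#'   split read.
#' @param misalign_frac single-transcript coverage fraction above which a
#'   split read is deemed a misalignment.
#' @param max_shared_support fraction of supporting fragments that may be
#'   shared with a higher-scoring candidate.
#' @param consistency_p0,consistency_alpha expected split fraction and
#'   significance level of the (annotative) spanning/split consistency
#'   test.
#' @param sim_read_count per-transcript read count of the uniform
#'   similarity simulation.
#' @param sim_seed seed of the similarity simulation.
#' @param max_postings per-k-mer postings cap of the mapper.
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(allowed_chroms = c(as.character(1:22), "X", "Y"),
                          require_protein_coding = TRUE,
                          min_gene_distance = 100000,
                          min_mr_support = 2,
                          min_sr_support = 1,
                          min_score = 3,
                          dup_collapse = TRUE,
                          fraglen_z_max = 5,
                          min_junction_distance = min_gene_distance,
                          max_overlap = 10,
                          misalign_frac = 0.85,
                          max_shared_support = 0.5,
                          consistency_p0 = 0.5,
                          consistency_alpha = 0.01,
                          sim_read_count = 1000,
                          sim_seed = 2018,
                          max_postings = 200) {
  cfg <- list(allowed_chroms = allowed_chroms,
              require_protein_coding = require_protein_coding,
              min_gene_distance = min_gene_distance,
              min_mr_support = min_mr_support,
              min_sr_support = min_sr_support,
              min_score = min_score,
              dup_collapse = dup_collapse,
              fraglen_z_max = fraglen_z_max,
              min_junction_distance = min_junction_distance,
              max_overlap = max_overlap,
              misalign_frac = misalign_frac,
              max_shared_support = max_shared_support,
              consistency_p0 = consistency_p0,
              consistency_alpha = consistency_alpha,
              sim_read_count = sim_read_count,
              sim_seed = sim_seed,
              max_postings = max_postings)
  num <- c("min_gene_distance", "min_mr_support", "min_sr_support",
           "min_score", "fraglen_z_max", "min_junction_distance",
           "max_overlap", "sim_read_count")
  for (f in num) if (cfg[[f]] < 0) stop(f, " must be >= 0")
  structure(cfg, class = "filter_config")
}

norm_chrom <- function(x) sub("^chr", "", x)

#' General-feature filter
#'
#' Drops candidates on disallowed chromosomes, with non-protein-coding
#' constituent genes (when required), with same-chromosome constituent
#' genes closer than `min_gene_distance`, or (for spanning-pair derived
#' candidates) with support below `min_mr_support`.
#'
#' @param cand a `"fusion_candidate"` record.
#' @param t a [transcriptome()].
#' @param cfg a [filter_config()].
#' @param type `"mr"` or `"sr"` (decides which support threshold applies).
#' @return list with `keep` (logical) and `reasons` (character).
#' @export
general_filter <- function(cand, t, cfg = filter_config(), type = "mr") {
  reasons <- character(0)
  g <- t$genes
  i5 <- match(cand$gene5, g$gene_id)
  i3 <- match(cand$gene3, g$gene_id)
  if (!norm_chrom(g$chrom[i5]) %in% norm_chrom(cfg$allowed_chroms) ||
      !norm_chrom(g$chrom[i3]) %in% norm_chrom(cfg$allowed_chroms))
    reasons <- c(reasons, "chromosome")
  if (cfg$require_protein_coding &&
      (g$biotype[i5] != "protein_coding" || g$biotype[i3] != "protein_coding"))
    reasons <- c(reasons, "biotype")
  d <- gene_distance(cand$gene5, cand$gene3, t)
  if (is.finite(d) && d < cfg$min_gene_distance)
    reasons <- c(reasons, "distance")
  if (type == "mr" && cand$mr_support < cfg$min_mr_support)
    reasons <- c(reasons, "mr_support")
  if (type == "sr" && cand$sr_support < cfg$min_sr_support)
    reasons <- c(reasons, "sr_support")
  list(keep = length(reasons) == 0, reasons = reasons)
}

#' Inverted-fusion filter
#'
#' When both directions (A,B) and (B,A) of a gene pair are present, only
#' the higher-scoring one is kept; an exact score tie drops both (flagged
#' as circular).
#'
#' @param cands list of `"fusion_candidate"` records with `score` fields.
#' @return list with `kept` and `dropped` candidate lists.
#' @export
inverted_fusion_filter <- function(cands) {
  keys <- vapply(cands, function(c) fge_key(c$gene5, c$gene3), character(1))
  scores <- vapply(cands, function(c) c$score, numeric(1))
  inv <- vapply(cands, function(c) fge_key(c$gene3, c$gene5), character(1))
  keep <- rep(TRUE, length(cands))
  dropped <- list()
  for (i in seq_along(cands)) {
    j <- match(inv[i], keys)
    if (is.na(j) || i == j) next
    if (scores[i] < scores[j]) {
      keep[i] <- FALSE
      cands[[i]]$flags <- unique(c(cands[[i]]$flags, "inverted"))
    } else if (scores[i] == scores[j]) {
      keep[i] <- FALSE
      cands[[i]]$flags <- unique(c(cands[[i]]$flags, "circular"))
    }
  }
  list(kept = cands[keep], dropped = cands[!keep])
}

#' Sequence-similarity reference from a uniform simulation
#'
#' Simulates an error-free paired-end sample in which every transcript
#' receives the same read count, maps it back to the transcriptome, and
#' records every gene pair whose transcripts co-occur in a concordant
#' transcript hit set. Genes sharing enough sequence to be confused by
#' the mapper necessarily co-occur, so the resulting pair list serves as
#' a data-driven paralog reference.
#'
#' @param t a [transcriptome()].
#' @param cfg a [filter_config()] (uses `sim_read_count`, `sim_seed`).
#' @param idx optional prebuilt [build_index()]; built on demand.
#' @param read_length simulated read length.
#' @return character vector of unordered gene-pair keys
#'   (`"geneA|geneB"` with sorted members).
#' @export
build_similarity_reference <- function(t, cfg = filter_config(), idx = NULL,
                                       read_length = 100) {
  if (is.null(idx)) idx <- build_index(t, choose_k(read_length), cfg$max_postings)
  sim <- simulate_reads(t, read_length = read_length,
                        n_per_transcript = cfg$sim_read_count,
                        seed = cfg$sim_seed)
  mp <- map_classify_pairs_cpp(sim$reads1, sim$reads2, idx$ptr,
                               match(idx$tx_gene, unique(idx$tx_gene)))
  pairs <- character(0)
  conc <- which(mp$class == 0L)
  gene_of <- idx$tx_gene
  seen <- new.env(parent = emptyenv())
  for (i in conc) {
    S <- mp$payload[[i]]
    if (length(S) < 2) next
    gs <- unique(gene_of[S])
    if (length(gs) < 2) next
    gs <- sort(gs)
    for (a in seq_len(length(gs) - 1)) for (b in seq((a + 1), length(gs))) {
      key <- paste(gs[a], gs[b], sep = "|")
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; pairs <- c(pairs, key) }
    }
  }
  sort(pairs)
}

pair_key_unordered <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
}

#' Sequence-similarity filter
#'
#' Drops a candidate when its (unordered) gene pair occurs in the
#' simulated similarity reference, a paralog list, or a read-through
#' (conjoined gene) list.
#'
#' @param cand a `"fusion_candidate"` record.
#' @param simref [build_similarity_reference()] output (may be empty).
#' @param paralog_db,readthrough_db character vectors of unordered pair
#'   keys (`"geneA|geneB"`) or 2-column data.frames of gene ids.
#' @return list with `keep` and `reasons`.
#' @export
similarity_filter <- function(cand, simref = character(0),
                              paralog_db = character(0),
                              readthrough_db = character(0)) {
  as_keys <- function(db) {
    if (is.data.frame(db)) pair_key_unordered(db[[1]], db[[2]]) else db
  }
  key <- pair_key_unordered(cand$gene5, cand$gene3)
  reasons <- character(0)
  if (key %in% as_keys(simref)) reasons <- c(reasons, "similarity_sim")
  if (key %in% as_keys(paralog_db)) reasons <- c(reasons, "paralog")
  if (key %in% as_keys(readthrough_db)) reasons <- c(reasons, "readthrough")
  list(keep = length(reasons) == 0, reasons = reasons)
}

#' Shared-support screen
#'
#' Spanning-pair candidates whose supporting fragments are mostly shared
#' with a better-supported candidate are redundant explanations of the
#' same reads: scanning in decreasing corrected-count order, a candidate
#' is dropped when more than `max_shared` of its fragments already
#' support a kept candidate.
#'
#' @param cands list of `"fusion_candidate"` records with `read_ids`.
#' @param max_shared maximum tolerated shared fraction (strict `>`).
#' @return list with `kept` and `dropped`.
#' @export
shared_support_screen <- function(cands, max_shared = 0.5) {
  if (length(cands) <= 1) return(list(kept = cands, dropped = list()))
  ord <- order(-vapply(cands, function(c) c$mr_corrected, numeric(1)),
               vapply(cands, function(c) fge_key(c$gene5, c$gene3), character(1)))
  kept <- list()
  dropped <- list()
  used <- character(0)
  for (i in ord) {
    c <- cands[[i]]
    frac <- if (length(c$read_ids) == 0) 0 else
      mean(c$read_ids %in% used)
    if (frac > max_shared) {
      c$flags <- unique(c(c$flags, "shared_support"))
      dropped[[length(dropped) + 1L]] <- c
    } else {
      kept[[length(kept) + 1L]] <- c
      used <- union(used, c$read_ids)
    }
  }
  list(kept = kept, dropped = dropped)
}

# robust z-scores; with MAD = 0, values off the median are infinitely
# deviant (so exact duplicates of the median pass, outliers drop)
robust_z <- function(x) {
  med <- stats::median(x)
  mad <- stats::mad(x)  # already scaled by 1.4826
  if (mad == 0) return(ifelse(x == med, 0, Inf))
  abs(x - med) / mad
}

#' Positional-distribution filter
#'
#' Applied to spanning-pair candidates:
#' 1. supporting pairs with identical (5' start, 3' start) positions are
#'    collapsed to one (duplicate removal);
#' 2. implied fragment lengths (relative to the candidate breakpoint, or
#'    to the supported extremes when no breakpoint is known) are screened
#'    with a robust z-score (median/MAD); outliers beyond `fraglen_z_max`
#'    are removed and support recomputed;
#' 3. the candidate is dropped when same-chromosome breakpoints are
#'    closer than `min_junction_distance`;
#' 4. the minimum support threshold is re-applied to the deduplicated
#'    count.
#'
#' @param cand a `"fusion_candidate"` record (with positional fields).
#' @param cfg a [filter_config()].
#' @param t a [transcriptome()].
#' @param read_length read length used to imply fragment lengths.
#' @return list with `keep`, `reasons`, and the updated `cand`.
#' @export
positional_filter <- function(cand, cfg = filter_config(), t = NULL,
                              read_length = 100) {
  reasons <- character(0)
  n <- length(cand$read_ids)
  ok <- rep(TRUE, n)
  if (n > 0 && cfg$dup_collapse) {
    ok <- !duplicated(paste(cand$start5, cand$start3))
  }
  # implied fragment length per pair: distance from the 5' mate start to
  # the breakpoint plus distance from the breakpoint to the 3' mate end
  s5 <- cand$start5[ok]
  s3 <- cand$start3[ok]
  if (sum(ok) > 1 && !anyNA(s5) && !anyNA(s3)) {
    b5 <- if (!is.null(cand$breakpoint)) cand$breakpoint$tx_pos5 else
      max(s5) + read_length - 1L
    b3 <- if (!is.null(cand$breakpoint)) cand$breakpoint$tx_pos3 else min(s3)
    fl <- (b5 - s5 + 1L) + (s3 + read_length - b3)
    z <- robust_z(fl)
    drop_out <- z > cfg$fraglen_z_max
    if (any(drop_out)) {
      idx <- which(ok)
      ok[idx[drop_out]] <- FALSE
      reasons <- c(reasons, "fraglen_outliers_removed")
    }
  }
  cand$read_ids <- cand$read_ids[ok]
  cand$start5 <- cand$start5[ok]
  cand$start3 <- cand$start3[ok]
  cand$tx5rep <- cand$tx5rep[ok]
  cand$tx3rep <- cand$tx3rep[ok]
  dedup_support <- length(cand$read_ids)
  if (dedup_support < cand$mr_support && cand$mr_support > 0) {
    cand$mr_corrected <- cand$mr_corrected * dedup_support / cand$mr_support
    cand$mr_support <- dedup_support
  }
  if (!is.null(cand$breakpoint)) {
    bp <- cand$breakpoint
    if (!is.null(bp$chrom5) && identical(bp$chrom5, bp$chrom3) &&
        abs(bp$genomic_pos5 - bp$genomic_pos3) < cfg$min_junction_distance)
      reasons <- c(reasons, "junction_distance")
  }
  if (cand$mr_support < cfg$min_mr_support)
    reasons <- c(reasons, "mr_support")
  keep <- !any(c("junction_distance", "mr_support") %in% reasons)
  list(keep = keep, reasons = reasons, cand = cand)
}

#' Spanning/split consistency flag
#'
#' When a candidate has both spanning-pair and split-read support, a
#' two-sided binomial test compares the observed split fraction with the
#' expected fraction `p0` among junction-covering reads; strongly
#' inconsistent candidates are flagged (never dropped - single-evidence
#' candidates are legitimate).
#'
#' @param cand a `"fusion_candidate"` record.
#' @param p0 expected split fraction (default 0.5).
#' @param alpha flagging threshold on the p-value.
#' @return The candidate, possibly with an `mr_sr_inconsistent` flag.
#' @export
mr_sr_consistency <- function(cand, p0 = 0.5, alpha = 0.01) {
  mr <- cand$mr_support
  sr <- cand$sr_support
  if (mr > 0 && sr > 0) {
    p <- stats::binom.test(sr, sr + mr, p = p0)$p.value
    if (p < alpha)
      cand$flags <- unique(c(cand$flags, "mr_sr_inconsistent"))
  }
  cand
}

#' Annotate special gene classes
#'
#' Adds report-only flags (mitochondrial translation, cytosolic ribosomal
#' subunit, ribonucleoprotein, ...) when a constituent gene occurs in one
#' of the supplied gene sets; candidates are never dropped on this basis.
#'
#' @param cand a `"fusion_candidate"` record.
#' @param special_db named list of gene-id character vectors.
#' @return The candidate with flags added.
#' @export
annotate_special_genes <- function(cand, special_db = list()) {
  for (nm in names(special_db)) {
    if (cand$gene5 %in% special_db[[nm]])
      cand$flags <- unique(c(cand$flags, paste0(nm, ":5")))
    if (cand$gene3 %in% special_db[[nm]])
      cand$flags <- unique(c(cand$flags, paste0(nm, ":3")))
  }
  cand
}
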