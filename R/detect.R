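#' Detect fusion genes from paired-end reads
#'
#' Runs the full detection pipeline: quasi-mapping of all read pairs to
#' the k-mer transcriptome index; classification into concordant,
#' junction-spanning (mapped read), split-read and other pairs; fusion
#' equivalence class accounting of spanning pairs (raw and corrected
#' counts per gene pair); split-read screening and junction calling;
#' the filter cascade (general features, positional distribution,
#' sequence similarity, shared support, inverted fusions); merging,
#' scoring and ranking.
#'
#' The 5'/3' orientation of each discordant pair is canonicalised from
#' the mapping orientation (the forward-mapping mate is the 5' side); for
#' split reads the segment order along the mapped orientation gives the
#' junction direction directly.
#'
#' @param reads1,reads2 mate sequences: named character vectors,
#'   `DNAStringSet`s, or FASTQ paths (optionally gzipped).
#' @param t a [transcriptome()].
#' @param k k-mer length; defaults to [choose_k()] of the read length.
#' @param config a [filter_config()].
#' @param genome optional named chromosome sequences for splice-motif
#'   annotation.
#' @param paralog_db,readthrough_db 2-column data.frames (or unordered
#'   pair-key vectors) of known paralog / read-through gene pairs.
#' @param special_db named list of gene-id vectors for report-only flags.
#' @param simref precomputed [build_similarity_reference()] (built on
#'   demand when `NULL`; set to `character(0)` to disable).
#' @param index optional prebuilt [build_index()].
#' @param verbose print per-stage candidate counts.
#' @return An object of class `"fusion_result"`: `candidates` (ranked
#'   records), `table` (data.frame view), `stages` (per-stage counts),
#'   `dropped` (per-stage drop log), `params`, `config`.
#' @export
detect_fusions <- function(reads1, reads2, t, k = NULL,
                           config = filter_config(), genome = NULL,
                           paralog_db = character(0),
                           readthrough_db = character(0),
                           special_db = list(),
                           simref = NULL, index = NULL, verbose = FALSE) {
  reads1 <- as_reads(reads1)
  reads2 <- as_reads(reads2)
  if (length(reads1) != length(reads2)) stop("mate files differ in read count")
  if (is.null(names(reads1)))
    names(reads1) <- names(reads2) <- sprintf("pair%07d", seq_along(reads1))
  r <- stats::median(nchar(reads1))
  if (is.null(k)) k <- choose_k(r)
  params <- mapping_params(k, r)
  if (is.null(index)) index <- build_index(t, k, config$max_postings)

  gene_levels <- unique(index$tx_gene)
  gcodes <- match(index$tx_gene, gene_levels)
  mp <- map_classify_pairs_cpp(unname(reads1), unname(reads2), index$ptr, gcodes)
  cls <- mp$class
  stages <- c(pairs = length(reads1),
              concordant = sum(cls == 0L), mapped_read = sum(cls == 1L),
              split_read = sum(cls == 2L), other = sum(cls == 3L))
  dropped <- list()

  ## ---- split-read (SR) pipeline ----------------------------------------
  evidence <- list()
  if (params$split_enabled) {
    for (i in which(cls == 2L)) {
      pay <- mp$payload[[i]]
      seq <- if (pay$mate == 1L) reads1[[i]] else reads2[[i]]
      seq <- toupper(seq)
      if (pay$orient == 1L) seq <- revcomp(seq)
      ev <- make_split_evidence(names(reads1)[i], seq,
                                pay$q1s, pay$q1e, pay$q2s, pay$q2e,
                                index$tx_ids[pay$tx1], pay$pos1,
                                index$tx_ids[pay$tx2], pay$pos2,
                                index$tx_ids[pay$anchor_tx], pay$anchor_pos, t)
      evidence[[length(evidence) + 1L]] <- ev
    }
  }
  stages["sr_evidence"] <- length(evidence)
  keep_mis <- vapply(evidence, misalignment_screen, logical(1),
                     t = t, frac = config$misalign_frac)
  evidence <- evidence[keep_mis]
  keep_ov <- vapply(evidence, overlap_screen, logical(1),
                    max_overlap = config$max_overlap)
  evidence <- evidence[keep_ov]
  if (config$dup_collapse && length(evidence) > 0) {
    key <- vapply(evidence, function(e)
      paste(e$tx5$tx_break[1], e$tx3$tx_break[1], min(e$anchor$pos)),
      character(1))
    evidence <- evidence[!duplicated(key)]
  }
  stages["sr_evidence_screened"] <- length(evidence)
  junctions <- call_junctions(evidence, t)
  src <- lapply(junctions, function(j) {
    structure(list(gene5 = j$gene5, gene3 = j$gene3,
                   mr_support = 0L, mr_corrected = 0,
                   sr_support = j$sr_support, sr_corrected = j$sr_support,
                   read_ids = j$read_ids,
                   start5 = integer(0), start3 = integer(0),
                   tx5rep = character(0), tx3rep = character(0),
                   breakpoint = j, motif = splice_motif(j, genome),
                   flags = character(0), source = "SR"),
              class = "fusion_candidate")
  })
  stages["sr_candidates"] <- length(src)

  ## ---- spanning-pair (MR) pipeline -------------------------------------
  # direction map from split-read junctions: for unstranded libraries the
  # mapping orientation of a spanning pair cannot identify the 5' side
  # (either fragment strand yields one fwd and one rc mate), so evidence
  # is folded onto the split-read-established direction where one exists;
  # mate 1 is taken as the 5' side otherwise, and any residual direction
  # ambiguity is resolved by the inverted-fusion filter.
  dirmap <- list()
  for (j in junctions) {
    key <- pair_key_unordered(j$gene5, j$gene3)
    if (is.null(dirmap[[key]]) || j$sr_support > dirmap[[key]]$n)
      dirmap[[key]] <- list(g5 = j$gene5, n = j$sr_support)
  }
  t2g_vec <- tx2gene(t)
  mr_pairs <- list()
  for (i in which(cls == 1L)) {
    pay <- mp$payload[[i]]
    S1 <- index$tx_ids[pay$t1]; pos1 <- stats::setNames(pay$p1, S1)
    S2 <- index$tx_ids[pay$t2]; pos2 <- stats::setNames(pay$p2, S2)
    if (length(dirmap) > 0) {
      g1 <- unique(unname(t2g_vec[S1]))
      g3 <- unique(unname(t2g_vec[S2]))
      for (ga in g1) {
        for (gb in g3) {
          d <- dirmap[[pair_key_unordered(ga, gb)]]
          if (!is.null(d) && d$g5 == gb) {
            tmp <- S1; S1 <- S2; S2 <- tmp
            tmp <- pos1; pos1 <- pos2; pos2 <- tmp
          }
          if (!is.null(d)) { g1 <- character(0); break }
        }
      }
    }
    mr_pairs[[length(mr_pairs) + 1L]] <-
      list(read_id = names(reads1)[i], S1 = S1, S2 = S2,
           pos1 = pos1, pos2 = pos2)
  }
  feq <- build_feq_table(mr_pairs, t)
  mrc <- mr_candidates(feq, t)
  stages["mr_candidates"] <- length(mrc)

  ## ---- filter cascade ---------------------------------------------------
  note <- function(c, stage, reasons) {
    data.frame(stage = stage, gene5 = c$gene5, gene3 = c$gene3,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }
  filt <- function(cands, type) {
    out <- list()
    for (c in cands) {
      gf <- general_filter(c, t, config, type)
      if (!gf$keep) {
        dropped[[length(dropped) + 1L]] <<- note(c, "general", gf$reasons)
        next
      }
      if (type == "mr") {
        pf <- positional_filter(c, config, t, read_length = r)
        if (!pf$keep) {
          dropped[[length(dropped) + 1L]] <<- note(c, "positional", pf$reasons)
          next
        }
        c <- pf$cand
      } else if (!is.null(c$breakpoint)) {
        bp <- c$breakpoint
        if (identical(bp$chrom5, bp$chrom3) &&
            abs(bp$genomic_pos5 - bp$genomic_pos3) < config$min_junction_distance) {
          dropped[[length(dropped) + 1L]] <<- note(c, "positional", "junction_distance")
          next
        }
      }
      out[[length(out) + 1L]] <- c
    }
    out
  }
  mrc <- filt(mrc, "mr")
  src <- filt(src, "sr")
  stages["after_general_positional"] <- length(mrc) + length(src)

  if (is.null(simref))
    simref <- build_similarity_reference(t, config, index, read_length = r)
  sim_keep <- function(cands) {
    out <- list()
    for (c in cands) {
      sf <- similarity_filter(c, simref, paralog_db, readthrough_db)
      if (sf$keep) out[[length(out) + 1L]] <- c
      else dropped[[length(dropped) + 1L]] <<- note(c, "similarity", sf$reasons)
    }
    out
  }
  mrc <- sim_keep(mrc)
  src <- sim_keep(src)
  ss <- shared_support_screen(mrc, config$max_shared_support)
  for (c in ss$dropped)
    dropped[[length(dropped) + 1L]] <- note(c, "shared_support", "shared_support")
  mrc <- ss$kept
  stages["after_similarity"] <- length(mrc) + length(src)

  merged <- merge_and_score(mrc, src, min_score = 0)
  inv <- inverted_fusion_filter(merged)
  for (c in inv$dropped)
    dropped[[length(dropped) + 1L]] <- note(c, "inverted", c$flags)
  final <- rank_candidates(inv$kept, config$min_score)
  final <- lapply(final, function(c) {
    c <- mr_sr_consistency(c, config$consistency_p0, config$consistency_alpha)
    annotate_special_genes(c, special_db)
  })
  stages["final"] <- length(final)

  res <- structure(list(
    candidates = final,
    table = candidates_table(final, t),
    stages = stages,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    feq = feq,
    params = params,
    config = config,
    simref = simref), class = "fusion_result")
  if (verbose) print(res)
  res
}

as_reads <- function(x) {
  if (methods::is(x, "DNAStringSet"))
    return(stats::setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      grepl("\\.(fq|fastq)(\\.gz)?$", x))
    return(read_fastq(x))
  x
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("fusion_result:", x$stages["final"], "final candidate(s) from",
      x$stages["pairs"], "read pairs\n")
  cat("  pair classes: concordant", x$stages["concordant"],
      "| spanning", x$stages["mapped_read"],
      "| split", x$stages["split_read"],
      "| other", x$stages["other"], "\n")
  if (nrow(x$table) > 0) {
    cat("  top candidates:\n")
    print(utils::head(x$table[, c("gene5", "gene3", "mr_support",
                                  "sr_support", "score", "motif")], 10))
  }
  invisible(x)
}

#' @export
summary.fusion_result <- function(object, ...) {
  cat("stage counts:\n")
  print(object$stages)
  if (!is.null(object$dropped)) {
    cat("\ndropped candidates by stage:\n")
    print(table(object$dropped$stage))
  }
  invisible(object$table)
}
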