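# Merging the spanning-pair (MR) and split-read (SR) candidate lists,
# scoring, thresholding, ranking and export.

#' Merge and score candidate lists
#'
#' Candidates are keyed by the ordered gene pair; the score of a fusion
#' gene is the sum of its corrected spanning-pair count and its corrected
#' split-read count. Candidates below `min_score` are removed and the
#' rest ranked by decreasing score (ties: more split-read support first,
#' then lexicographic gene ids).
#'
#' @param mr_cands,sr_cands lists of `"fusion_candidate"` records.
#' @param min_score minimum retained score (set 0 to keep everything,
#'   e.g. when the inverted-fusion filter runs in between).
#' @return list of merged, scored, ranked candidates.
#' @export
merge_and_score <- function(mr_cands, sr_cands, min_score = 3) {
  merged <- list()
  for (c in mr_cands) merged[[fge_key(c$gene5, c$gene3)]] <- c
  for (c in sr_cands) {
    key <- fge_key(c$gene5, c$gene3)
    if (is.null(merged[[key]])) {
      merged[[key]] <- c
    } else {
      m <- merged[[key]]
      m$sr_support <- c$sr_support
      m$sr_corrected <- c$sr_corrected
      m$breakpoint <- c$breakpoint
      m$motif <- c$motif
      m$flags <- unique(c(m$flags, c$flags))
      m$source <- "MR+SR"
      merged[[key]] <- m
    }
  }
  for (key in names(merged))
    merged[[key]]$score <- merged[[key]]$mr_corrected + merged[[key]]$sr_corrected
  rank_candidates(merged, min_score)
}

#' Threshold and rank scored candidates
#' @param cands list of scored `"fusion_candidate"` records.
#' @param min_score minimum retained score.
#' @return ranked candidate list.
#' @export
rank_candidates <- function(cands, min_score = 3) {
  if (length(cands) == 0) return(list())
  sc <- vapply(cands, function(c) c$score, numeric(1))
  cands <- cands[sc >= min_score]
  if (length(cands) == 0) return(list())
  sc <- vapply(cands, function(c) c$score, numeric(1))
  sr <- vapply(cands, function(c) c$sr_support, numeric(1))
  g5 <- vapply(cands, function(c) c$gene5, character(1))
  g3 <- vapply(cands, function(c) c$gene3, character(1))
  unname(cands[order(-sc, -sr, g5, g3)])
}

#' Candidate list as a data.frame
#'
#' @param cands list of `"fusion_candidate"` records.
#' @param t a [transcriptome()] (for symbols and chromosomes).
#' @return data.frame, one row per candidate, in the input order.
#' @export
candidates_table <- function(cands, t) {
  if (length(cands) == 0) {
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      symbol5 = character(0), symbol3 = character(0),
                      chrom5 = character(0), brpos5 = integer(0),
                      chrom3 = character(0), brpos3 = integer(0),
                      mr_support = integer(0), mr_corrected = numeric(0),
                      sr_support = integer(0), score = numeric(0),
                      motif = character(0), flags = character(0),
                      stringsAsFactors = FALSE))
  }
  g <- t$genes
  rows <- lapply(cands, function(c) {
    i5 <- match(c$gene5, g$gene_id)
    i3 <- match(c$gene3, g$gene_id)
    bp <- c$breakpoint
    data.frame(
      gene5 = c$gene5, gene3 = c$gene3,
      symbol5 = g$gene_name[i5], symbol3 = g$gene_name[i3],
      chrom5 = g$chrom[i5],
      brpos5 = if (!is.null(bp)) bp$genomic_pos5 else NA_integer_,
      chrom3 = g$chrom[i3],
      brpos3 = if (!is.null(bp)) bp$genomic_pos3 else NA_integer_,
      mr_support = c$mr_support, mr_corrected = round(c$mr_corrected, 4),
      sr_support = c$sr_support, score = round(c$score, 4),
      motif = c$motif,
      flags = paste(sort(c$flags), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export final candidates to TSV
#'
#' Deterministic tab-separated export of the ranked candidate table
#' (header always written, even for an empty list).
#'
#' @param cands ranked candidate list or a [detect_fusions()] result.
#' @param path output path.
#' @param t a [transcriptome()] (ignored when `cands` is a result object).
#' @export
export_fusions <- function(cands, path, t = NULL) {
  tab <- if (inherits(cands, "fusion_result")) cands$table else
    candidates_table(cands, t)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate TSV back
#' @param path TSV written by [export_fusions()].
#' @export
read_fusions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(flags = "character", motif = "character"))
}
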