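# Read-pair classification: concordant / mapped read (junction-spanning
# pair) / split read / other, and extraction of split-read evidence.

# length of the common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ia <- utf8ToInt(substr(a, 1L, n))
  ib <- utf8ToInt(substr(b, 1L, n))
  d <- which(ia != ib)
  if (length(d) == 0L) n else d[1L] - 1L
}

# length of the common suffix of two strings
common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  ia <- rev(utf8ToInt(substr(a, na - n + 1L, na)))
  ib <- rev(utf8ToInt(substr(b, nb - n + 1L, nb)))
  d <- which(ia != ib)
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Classify a read pair
#'
#' Labels a mapped pair as one of:
#' * `concordant` - the concordant set S is non-empty;
#' * `mapped_read` - S is empty and each mate maps (near-)fully, with at
#'   least r - k - 1 matched bases, to transcripts such that the two sides
#'   contain different genes; the pair's fragment spans the fusion
#'   junction;
#' * `split_read` - one mate is chimeric (at least two matched segments,
#'   the first and last each >= k bases, hitting transcripts of disjoint
#'   gene sets) and the other mate maps (near-)fully to a transcript of
#'   one of those genes;
#' * `unmapped/other` - anything else.
#'
#' @param pm a [map_pair()] result.
#' @param params a [mapping_params()] list.
#' @param t a [transcriptome()].
#' @return list with `label` and `detail`.
#' @export
classify_pair <- function(pm, params, t) {
  t2g <- tx2gene(t)
  if (length(pm$S) > 0)
    return(list(label = "concordant", detail = "non-empty concordant set"))
  if (length(pm$T1) > 0 && length(pm$T2) > 0) {
    g1 <- unique(t2g[pm$T1])
    g2 <- unique(t2g[pm$T2])
    if (!(length(g1) == 1 && length(g2) == 1 && g1 == g2))
      return(list(label = "mapped_read",
                  detail = "both mates near-fully mapped to different genes"))
  }
  if (isTRUE(params$split_enabled)) {
    for (mate in 1:2) {
      rm <- if (mate == 1) pm$mapping1 else pm$mapping2
      other <- if (mate == 1) pm$mapping2 else pm$mapping1
      if (is_split_mapping(rm, other, params, t2g))
        return(list(label = "split_read",
                    detail = sprintf("mate %d chimeric with anchored mate", mate)))
    }
  }
  list(label = "unmapped/other", detail = "no qualifying configuration")
}

is_split_mapping <- function(rm, other, params, t2g) {
  k <- params$k
  if (length(rm$segments) < 2) return(FALSE)
  a <- rm$segments[[1]]
  b <- rm$segments[[length(rm$segments)]]
  if (a$query_end - a$query_start + 1L < k) return(FALSE)
  if (b$query_end - b$query_start + 1L < k) return(FALSE)
  ga <- unique(t2g[a$hits$transcript_id])
  gb <- unique(t2g[b$hits$transcript_id])
  if (length(intersect(ga, gb)) > 0) return(FALSE)
  acc <- per_tx_matched(other)
  thr <- nchar(other$seq) - k - 1
  for (id in names(acc)) {
    if (acc[[id]]["bases"] >= thr && t2g[[id]] %in% c(ga, gb)) return(TRUE)
  }
  FALSE
}

# Core split-read evidence constructor shared by the per-pair reference
# path and the batched C++ path. Positions are 1-based; `seq` is the read
# in mapped orientation, so the first segment is the 5' side of the
# junction. The last segment is additionally extended leftward along each
# 3' transcript (the greedy mapper only extends rightward), which exposes
# junction micro-homology as query overlap between the two sides.
make_split_evidence <- function(read_id, seq, q1s, q1e, q2s, q2e,
                                tx1, pos1, tx2, pos2,
                                anchor_tx, anchor_pos, t) {
  t2g <- tx2gene(t)
  r <- nchar(seq)
  len5 <- q1e - q1s + 1L
  # 5' side: leftward extension only matters for coverage (misalignment screen)
  ext5 <- vapply(seq_along(tx1), function(j) {
    common_suffix_len(substr(seq, 1L, q1s - 1L),
                      substr(t$sequences[[tx1[j]]], 1L, pos1[j] - 1L))
  }, integer(1))
  cov5 <- len5 + max(ext5, 0L)
  tx5 <- data.frame(transcript_id = tx1, gene_id = unname(t2g[tx1]),
                    tx_break = pos1 + len5 - 1L, stringsAsFactors = FALSE)
  # 3' side: extend leftward along each transcript (coverage / overlap);
  # the breakpoint itself uses the maximal-5' convention - junction
  # micro-homology is assigned to the 5' side, so the 3' breakpoint is
  # the transcript position of the first query base beyond the 5'
  # segment's maximal extension
  ext3 <- vapply(seq_along(tx2), function(j) {
    common_suffix_len(substr(seq, 1L, q2s - 1L),
                      substr(t$sequences[[tx2[j]]], 1L, pos2[j] - 1L))
  }, integer(1))
  len3 <- q2e - q2s + 1L
  cov3 <- len3 + max(ext3, 0L)
  tx3 <- data.frame(transcript_id = tx2, gene_id = unname(t2g[tx2]),
                    tx_break = pos2 + (q1e + 1L - q2s),
                    stringsAsFactors = FALSE)
  structure(list(
    read_id = read_id, seq = seq, r = r,
    qstart5 = q1s, qend5 = q1e,
    qstart3 = q2s - max(ext3, 0L), qend3 = q2e,
    tx5 = tx5, tx3 = tx3,
    genes5 = unique(tx5$gene_id), genes3 = unique(tx3$gene_id),
    cov5 = cov5, cov3 = cov3,
    anchor = data.frame(transcript_id = anchor_tx,
                        gene_id = unname(t2g[anchor_tx]),
                        pos = anchor_pos, stringsAsFactors = FALSE)),
    class = "split_evidence")
}

#' Extract split-read evidence from a chimeric mapping
#'
#' Records, for the first and last matched segments of the chimeric mate,
#' the query positions, the hit transcripts with their genes, the
#' transcript-coordinate breakpoints (last matched base on the 5' side,
#' first matched base on the 3' side after leftward extension), and the
#' anchoring position of the other mate.
#'
#' @param rm the chimeric mate's [map_read()] result.
#' @param mate_rm the anchoring mate's [map_read()] result.
#' @param t a [transcriptome()].
#' @param read_id identifier for the pair.
#' @param k k-mer length used in mapping (for the anchor threshold).
#' @return A `"split_evidence"` object.
#' @export
extract_split_info <- function(rm, mate_rm, t, read_id = "", k = 31) {
  if (length(rm$segments) < 2)
    stop("extract_split_info called on a non-split mapping")
  t2g <- tx2gene(t)
  a <- rm$segments[[1]]
  b <- rm$segments[[length(rm$segments)]]
  ga <- unique(t2g[a$hits$transcript_id])
  gb <- unique(t2g[b$hits$transcript_id])
  acc <- per_tx_matched(mate_rm)
  thr <- nchar(mate_rm$seq) - k - 1
  keep <- names(acc)[vapply(names(acc), function(id)
    acc[[id]]["bases"] >= thr && t2g[[id]] %in% c(ga, gb), logical(1))]
  if (length(keep) == 0)
    stop("anchor mate not mapped to a constituent gene (contract violation)")
  make_split_evidence(
    read_id, rm$seq,
    a$query_start, a$query_end, b$query_start, b$query_end,
    a$hits$transcript_id, a$hits$tx_start,
    b$hits$transcript_id, b$hits$tx_start,
    keep, vapply(keep, function(id) unname(acc[[id]]["minpos"]), integer(1)),
    t)
}
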