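# Split-read pipeline: misalignment/overlap screens on individual split
# reads and junction calling with exact breakpoints.

#' Misalignment screen for a split read
#'
#' A split read is deemed a misalignment when more than `frac` of the
#' read is contiguously mapped to a single constituent transcript (the
#' apparent chimera is then better explained by one gene). Coverage per
#' side is the matched segment plus its maximal extension along the
#' transcript sequence.
#'
#' @param e a `"split_evidence"` record.
#' @param t a [transcriptome()] (coverage is precomputed on the evidence;
#'   kept for interface symmetry).
#' @param frac drop threshold as a fraction of read length (strict `>`;
#'   default 0.85).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
misalignment_screen <- function(e, t = NULL, frac = 0.85) {
  max(e$cov5, e$cov3) <= frac * e$r
}

#' Overlap screen for a split read
#'
#' The number of query bases claimed by both sides of the split (the 5'
#' segment end minus the extended 3' segment start). A long dual-mapped
#' stretch indicates paralog-like similarity rather than a junction.
#'
#' @param e a `"split_evidence"` record.
#' @param max_overlap maximum tolerated overlap in bases (strict `>`
#'   drops; default 10).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
overlap_screen <- function(e, max_overlap = 10) {
  (e$qend5 - e$qstart3 + 1L) <= max_overlap
}

#' Call fusion junctions from split-read evidence
#'
#' Evidence is grouped by (5' gene, 3' gene); within a group the
#' breakpoint is the modal (most frequent) genomic junction pair, with
#' ties broken by the number of reads whose anchor mate lies in the 5'
#' gene, then by the smaller genomic coordinate. Transcript-coordinate
#' breakpoints are converted to genomic coordinates through the exon
#' structure.
#'
#' @param evidence list of `"split_evidence"` records (already screened).
#' @param t a [transcriptome()].
#' @return list of `"junction_break"` records: `gene5`, `gene3`,
#'   `chrom5`, `chrom3`, `genomic_pos5`, `genomic_pos3`, `tx_pos5`,
#'   `tx_pos3`, `tx5`, `tx3`, `motif` (`"unknown"` until
#'   [splice_motif()] is applied), `sr_support`, `read_ids`.
#' @export
call_junctions <- function(evidence, t) {
  if (length(evidence) == 0) return(list())
  rows <- list()
  for (e in evidence) {
    for (g5 in e$genes5) for (g3 in e$genes3) {
      h5 <- e$tx5[e$tx5$gene_id == g5, , drop = FALSE]
      h3 <- e$tx3[e$tx3$gene_id == g3, , drop = FALSE]
      if (nrow(h5) == 0 || nrow(h3) == 0) next
      i5 <- order(h5$transcript_id)[1]
      i3 <- order(h3$transcript_id)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        gene5 = g5, gene3 = g3, read_id = e$read_id,
        tx5 = h5$transcript_id[i5], tx_pos5 = h5$tx_break[i5],
        tx3 = h3$transcript_id[i3], tx_pos3 = h3$tx_break[i3],
        anchor5 = any(e$anchor$gene_id == g5),
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, rows)
  ev$g5pos <- mapply(function(tx, p) tx_to_genomic(t, tx, p), ev$tx5, ev$tx_pos5)
  ev$g3pos <- mapply(function(tx, p) tx_to_genomic(t, tx, p), ev$tx3, ev$tx_pos3)

  out <- list()
  for (grp in split(ev, paste(ev$gene5, ev$gene3, sep = "~"))) {
    jk <- paste(grp$g5pos, grp$g3pos, sep = ":")
    tabj <- table(jk)
    cand <- names(tabj)[tabj == max(tabj)]
    if (length(cand) > 1) {
      anch <- vapply(cand, function(x) sum(grp$anchor5[jk == x]), numeric(1))
      cand <- cand[anch == max(anch)]
      cand <- sort(cand)[1]  # remaining ties: smaller genomic coordinate
    }
    sel <- which(jk == cand)[1]
    gi5 <- match(grp$gene5[1], t$genes$gene_id)
    gi3 <- match(grp$gene3[1], t$genes$gene_id)
    out[[paste(grp$gene5[1], grp$gene3[1], sep = "~")]] <- structure(list(
      gene5 = grp$gene5[1], gene3 = grp$gene3[1],
      chrom5 = t$genes$chrom[gi5], chrom3 = t$genes$chrom[gi3],
      strand5 = t$genes$strand[gi5], strand3 = t$genes$strand[gi3],
      genomic_pos5 = grp$g5pos[sel], genomic_pos3 = grp$g3pos[sel],
      tx5 = grp$tx5[sel], tx_pos5 = grp$tx_pos5[sel],
      tx3 = grp$tx3[sel], tx_pos3 = grp$tx_pos3[sel],
      motif = "unknown",
      sr_support = length(unique(grp$read_id)),
      read_ids = unique(grp$read_id)),
      class = "junction_break")
  }
  out
}

#' Splice-motif classification of a junction
#'
#' Reads the two-base donor immediately 3' of the 5' breakpoint and the
#' two-base acceptor immediately 5' of the 3' breakpoint from the genome
#' (strand-aware: on `-` genes the bases are taken from the reverse
#' complement) and classifies the junction as one of the canonical splice
#' motifs. The motif is annotative: candidates are flagged, never
#' eliminated, on its basis.
#'
#' @param j a `"junction_break"` record.
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences (names matching the annotation), or `NULL`.
#' @return One of `"GT-AG"`, `"GC-AG"`, `"AT-AC"`, `"none"`, or
#'   `"unknown"` when no genome is supplied.
#' @export
splice_motif <- function(j, genome = NULL) {
  if (is.null(genome)) return("unknown")
  if (methods::is(genome, "DNAStringSet")) {
    genome <- structure(as.character(genome), names = names(genome))
  }
  getb <- function(chrom, from, to, rc) {
    s <- genome[[chrom]]
    if (is.null(s) || from < 1 || to > nchar(s)) return(NA_character_)
    b <- toupper(substr(s, from, to))
    if (rc) revcomp(b) else b
  }
  # strand of each gene decides which genomic side is "downstream"
  donor <- if (j$strand5 == "-") {
    getb(j$chrom5, j$genomic_pos5 - 2L, j$genomic_pos5 - 1L, TRUE)
  } else {
    getb(j$chrom5, j$genomic_pos5 + 1L, j$genomic_pos5 + 2L, FALSE)
  }
  acceptor <- if (j$strand3 == "-") {
    getb(j$chrom3, j$genomic_pos3 + 1L, j$genomic_pos3 + 2L, TRUE)
  } else {
    getb(j$chrom3, j$genomic_pos3 - 2L, j$genomic_pos3 - 1L, FALSE)
  }
  if (is.na(donor) || is.na(acceptor)) return("unknown")
  key <- paste(donor, acceptor, sep = "-")
  if (key %in% c("GT-AG", "GC-AG", "AT-AC")) key else "none"
}
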