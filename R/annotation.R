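#' Construct a transcriptome object
#'
#' In-memory annotation model used throughout the package: transcript and
#' gene tables, per-transcript exon coordinates (genomic, 1-based
#' inclusive, as in GTF) and the spliced transcript sequences (5'->3' of
#' the transcript).
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `length`.
#' @param genes data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`,
#'   sorted by genomic start within each transcript.
#' @param sequences named character vector of transcript sequences.
#' @param validate check the structural invariants (default `TRUE`).
#' @return An object of class `"transcriptome"`.
#' @export
transcriptome <- function(transcripts, genes, exons, sequences, validate = TRUE) {
  sequences <- toupper(sequences)
  obj <- structure(
    list(transcripts = transcripts, genes = genes, exons = exons,
         sequences = sequences),
    class = "transcriptome")
  if (validate) validate_transcriptome(obj)
  obj
}

validate_transcriptome <- function(t) {
  tx <- t$transcripts
  if (anyDuplicated(tx$transcript_id)) stop("duplicated transcript ids")
  if (anyDuplicated(t$genes$gene_id)) stop("duplicated gene ids")
  if (!all(tx$transcript_id %in% names(t$sequences)))
    stop("missing sequence for some transcripts")
  if (!all(tx$gene_id %in% t$genes$gene_id))
    stop("transcript refers to unknown gene")
  exl <- split(t$exons, t$exons$transcript_id)
  for (id in tx$transcript_id) {
    ex <- exl[[id]]
    if (is.null(ex) || nrow(ex) == 0) stop("transcript without exons: ", id)
    if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1)
      stop("exons not sorted by genomic start: ", id)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons: ", id)
    if (sum(ex$end - ex$start + 1L) != nchar(t$sequences[[id]]))
      stop("exon lengths do not sum to sequence length: ", id)
  }
  g <- t$genes
  for (i in seq_len(nrow(g))) {
    ex <- t$exons[t$exons$transcript_id %in%
                    tx$transcript_id[tx$gene_id == g$gene_id[i]], , drop = FALSE]
    if (g$start[i] > min(ex$start) || g$end[i] < max(ex$end))
      stop("gene span does not cover member exons: ", g$gene_id[i])
  }
  invisible(t)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

n_transcripts <- function(t) nrow(t$transcripts)

tx2gene <- function(t) {
  structure(t$transcripts$gene_id, names = t$transcripts$transcript_id)
}

strip_version <- function(ids) sub("\\.\\d+$", "", ids)

#' Load a transcriptome from FASTA and GTF
#'
#' Reads spliced transcript sequences from a (multi-)FASTA and the gene
#' model from an Ensembl-style GTF (exon features with `transcript_id`,
#' `gene_id`, and optionally `gene_biotype` / `gene_name` attributes).
#' FASTA identifiers are matched to GTF transcript ids exactly, or after
#' stripping a trailing version suffix (".N"). Transcripts present in only
#' one of the two inputs are dropped with a warning. When `gene_biotype`
#' is absent all genes are treated as protein_coding (with a warning).
#'
#' @param fasta_path path to the transcriptome FASTA.
#' @param gtf_path path to the GTF.
#' @return A [transcriptome()] object.
#' @export
load_annotation <- function(fasta_path, gtf_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in GTF")
  md <- S4Vectors::mcols(gr)
  ex <- data.frame(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (!is.null(md$gene_biotype)) {
    ex$biotype <- as.character(md$gene_biotype)
  } else {
    warning("GTF has no gene_biotype attribute; treating all genes as protein_coding")
    ex$biotype <- "protein_coding"
  }
  ex$gene_name <- if (!is.null(md$gene_name)) as.character(md$gene_name) else ex$gene_id

  # match FASTA ids to GTF transcript ids (exact, then version-stripped)
  gtf_tx <- unique(ex$transcript_id)
  fa_ids <- names(seqs)
  hit <- fa_ids %in% gtf_tx
  if (!all(hit)) {
    stripped <- strip_version(fa_ids)
    fix <- !hit & stripped %in% gtf_tx
    names(seqs)[fix] <- stripped[fix]
    hit <- names(seqs) %in% gtf_tx
  }
  if (any(!hit))
    warning(sum(!hit), " FASTA transcript(s) absent from GTF; dropped")
  seqs <- seqs[hit]
  if (length(seqs) == 0) stop("annotation/sequence mismatch: zero matched transcripts")
  miss_gtf <- setdiff(gtf_tx, names(seqs))
  if (length(miss_gtf) > 0) {
    warning(length(miss_gtf), " GTF transcript(s) without sequence; dropped")
    ex <- ex[!ex$transcript_id %in% miss_gtf, , drop = FALSE]
  }

  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  first <- !duplicated(ex$transcript_id)
  tx <- data.frame(
    transcript_id = ex$transcript_id[first],
    gene_id = ex$gene_id[first],
    chrom = ex$chrom[first],
    strand = ex$strand[first],
    stringsAsFactors = FALSE)
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  seqchr <- as.character(seqs)
  names(seqchr) <- names(seqs)
  tx$length <- nchar(seqchr[tx$transcript_id])
  rownames(tx) <- NULL

  gsplit <- !duplicated(ex$gene_id)
  genes <- data.frame(
    gene_id = ex$gene_id[gsplit],
    gene_name = ex$gene_name[gsplit],
    chrom = ex$chrom[gsplit],
    strand = ex$strand[gsplit],
    biotype = ex$biotype[gsplit],
    stringsAsFactors = FALSE)
  genes$start <- vapply(genes$gene_id, function(g) min(ex$start[ex$gene_id == g]), 0)
  genes$end <- vapply(genes$gene_id, function(g) max(ex$end[ex$gene_id == g]), 0)
  genes <- genes[order(genes$gene_id),
                 c("gene_id", "gene_name", "chrom", "strand", "start", "end", "biotype")]
  rownames(genes) <- NULL

  exons <- ex[, c("transcript_id", "start", "end")]
  rownames(exons) <- NULL
  transcriptome(tx, genes, exons, seqchr[tx$transcript_id])
}

#' Write a transcriptome to FASTA and GTF
#'
#' Inverse of [load_annotation()]: emits the spliced sequences as FASTA
#' and the gene model as a GTF with gene, transcript and exon features.
#'
#' @param t a [transcriptome()].
#' @param fasta_path,gtf_path output paths.
#' @export
write_annotation <- function(t, fasta_path, gtf_path) {
  ss <- Biostrings::DNAStringSet(t$sequences)
  Biostrings::writeXStringSet(ss, fasta_path)

  lines <- character(0)
  gt <- function(chrom, feat, start, end, strand, attrs) {
    sprintf("%s\tfusionlite\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(t$genes))) {
    g <- t$genes[i, ]
    ga <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                  g$gene_id, g$gene_name, g$biotype)
    lines <- c(lines, gt(g$chrom, "gene", g$start, g$end, g$strand, ga))
    mem <- t$transcripts[t$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(mem))) {
      txid <- mem$transcript_id[j]
      ex <- t$exons[t$exons$transcript_id == txid, , drop = FALSE]
      ta <- sprintf('%s transcript_id "%s";', ga, txid)
      lines <- c(lines, gt(g$chrom, "transcript", min(ex$start), max(ex$end),
                           g$strand, ta))
      for (e in seq_len(nrow(ex))) {
        ea <- sprintf('%s exon_number "%d";', ta, e)
        lines <- c(lines, gt(g$chrom, "exon", ex$start[e], ex$end[e], g$strand, ea))
      }
    }
  }
  writeLines(lines, gtf_path)
  invisible(c(fasta = fasta_path, gtf = gtf_path))
}

#' Genomic distance between two genes
#'
#' `Inf` for genes on different chromosomes; otherwise the number of bases
#' strictly between the two gene spans (0 if the spans overlap or abut).
#'
#' @param a,b gene ids.
#' @param t a [transcriptome()].
#' @return Non-negative number of bases, or `Inf`.
#' @export
gene_distance <- function(a, b, t) {
  g <- t$genes
  ia <- match(a, g$gene_id)
  ib <- match(b, g$gene_id)
  if (is.na(ia)) stop("unknown gene id: ", a)
  if (is.na(ib)) stop("unknown gene id: ", b)
  if (g$chrom[ia] != g$chrom[ib]) return(Inf)
  max(0, max(g$start[ia], g$start[ib]) - min(g$end[ia], g$end[ib]) - 1)
}

#' Convert a transcript coordinate to a genomic coordinate
#'
#' Walks the exon structure in transcript order (strand-aware: on `-`
#' genes the transcript runs right-to-left along the genome).
#'
#' @param t a [transcriptome()].
#' @param tx_id transcript id.
#' @param pos 1-based position on the spliced transcript.
#' @return 1-based genomic coordinate.
#' @export
tx_to_genomic <- function(t, tx_id, pos) {
  i <- match(tx_id, t$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript id: ", tx_id)
  ex <- t$exons[t$exons$transcript_id == tx_id, , drop = FALSE]
  strand <- t$transcripts$strand[i]
  widths <- ex$end - ex$start + 1L
  if (pos < 1 || pos > sum(widths)) stop("position outside transcript: ", pos)
  if (strand == "-") {
    # transcript order is by decreasing genomic coordinate
    ord <- rev(seq_len(nrow(ex)))
    off <- pos
    for (e in ord) {
      if (off <= widths[e]) return(ex$end[e] - off + 1L)
      off <- off - widths[e]
    }
  } else {
    off <- pos
    for (e in seq_len(nrow(ex))) {
      if (off <= widths[e]) return(ex$start[e] + off - 1L)
      off <- off - widths[e]
    }
  }
  stop("unreachable")
}
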