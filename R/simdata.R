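# Synthetic data: random multi-gene multi-isoform transcriptomes,
# implanted fusion transcripts with known breakpoints, and error-free
# paired-end read simulation with a truncated-normal fragment model.

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# split L into n widths each >= min_w, summing to L
split_len <- function(L, n, min_w = 150L) {
  if (n == 1) return(L)
  if (L < n * min_w) min_w <- max(1L, L %/% (2L * n))
  free <- L - n * min_w
  cuts <- sort(sample.int(free + 1L, n - 1L, replace = TRUE) - 1L)
  diff(c(0L, cuts, free)) + min_w
}

#' Simulate a random transcriptome
#'
#' Generates `n_genes` genes with i.i.d. random exon sequences (so
#' cross-gene k-mer collisions are negligible at k >= 21), multi-exon
#' structures, and `tx_per_gene` isoforms per gene (isoform 1 uses all
#' exons, further isoforms drop one exon and therefore share sequence
#' with isoform 1). Genes are laid out on chromosomes 1..22 with at least
#' 1 Mb between neighbouring genes; strands are random. With
#' `duplicate_exon = c(i, j)` the first exon of gene j is an exact copy
#' of the first exon of gene i (and both are at least 600 bp), producing
#' a known paralog-like gene pair for the sequence-similarity machinery.
#'
#' @param n_genes number of genes (>= 2).
#' @param tx_per_gene isoforms per gene.
#' @param length_range range of isoform-1 transcript lengths (bases).
#' @param gc GC content of the random sequences.
#' @param seed random seed (the same seed reproduces the transcriptome
#'   exactly).
#' @param exon_range range of exon counts per gene.
#' @param intron_range range of intron lengths.
#' @param duplicate_exon `NULL` or a pair of gene indices sharing an exon.
#' @param fasta_path,gtf_path optional output paths; when given the
#'   transcriptome is also written to disk.
#' @return A [transcriptome()].
#' @export
simulate_transcriptome <- function(n_genes = 20, tx_per_gene = 2,
                                   length_range = c(1000, 3000), gc = 0.5,
                                   seed = 1,
                                   exon_range = c(2, 4),
                                   intron_range = c(200, 2000),
                                   duplicate_exon = NULL,
                                   fasta_path = NULL, gtf_path = NULL) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  set.seed(seed)
  cursor <- rep(1L, 22)
  tx_rows <- list(); gene_rows <- list(); exon_rows <- list()
  seqs <- character(0)
  dup_store <- NULL
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%03d", g)
    ci <- ((g - 1L) %% 22L) + 1L
    chrom <- as.character(ci)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(exon_range[1]:exon_range[2], 1)
    L <- sample(length_range[1]:length_range[2], 1)
    widths <- split_len(L, n_ex)
    in_dup <- !is.null(duplicate_exon) && g %in% duplicate_exon
    if (in_dup && widths[1] < 600L) {
      widths[1] <- 600L
      L <- sum(widths)
    }
    ex_seq <- vapply(widths, rand_seq, character(1), gc = gc)
    if (in_dup) {
      if (g == duplicate_exon[1]) {
        dup_store <- ex_seq[1]
      } else if (!is.null(dup_store)) {
        widths[1] <- nchar(dup_store)
        ex_seq[1] <- dup_store
        L <- sum(widths)
      }
    }
    # genomic layout (exon order along the genome; transcript order is
    # strand-aware)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor[ci]
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + widths[e] - 1L
      pos <- ends[e] + sample(intron_range[1]:intron_range[2], 1)
    }
    cursor[ci] <- ends[n_ex] + 1000000L
    # exon sequences are stored in transcript (5'->3') order; on '-'
    # genes transcript order runs right-to-left along the genome
    tx_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    gene_rows[[g]] <- data.frame(
      gene_id = gid, gene_name = gid, chrom = chrom, strand = strand,
      start = starts[1], end = ends[n_ex], biotype = "protein_coding",
      stringsAsFactors = FALSE)
    for (j in seq_len(tx_per_gene)) {
      txid <- sprintf("%sT%d", gid, j)
      keep <- seq_len(n_ex)
      if (j > 1 && n_ex >= 2) keep <- sort(sample(n_ex, n_ex - 1L))
      keep_tx_order <- tx_order[tx_order %in% keep]
      seqs[[txid]] <- paste(ex_seq[keep_tx_order], collapse = "")
      tx_rows[[txid]] <- data.frame(
        transcript_id = txid, gene_id = gid, chrom = chrom, strand = strand,
        length = sum(widths[keep]), stringsAsFactors = FALSE)
      exon_rows[[txid]] <- data.frame(
        transcript_id = txid, start = starts[keep], end = ends[keep],
        stringsAsFactors = FALSE)
    }
  }
  t <- transcriptome(do.call(rbind, tx_rows), do.call(rbind, gene_rows),
                     do.call(rbind, exon_rows), unlist(seqs))
  if (!is.null(fasta_path) && !is.null(gtf_path))
    write_annotation(t, fasta_path, gtf_path)
  t
}

#' Implant fusion transcripts
#'
#' Chooses `n_fusions` disjoint gene pairs on different chromosomes and
#' joins a 5' transcript prefix to a 3' transcript suffix, with
#' breakpoints drawn uniformly from the middle 60% of each transcript.
#' The fusion sequence is exactly
#' `prefix(tx5, breakpoint5) + suffix(tx3, breakpoint3)`; breakpoint5 is
#' the last 5' base retained, breakpoint3 the first 3' base retained
#' (transcript coordinates, converted to genomic coordinates in the
#' returned truth table).
#'
#' @param t a [transcriptome()].
#' @param n_fusions number of fusions to implant.
#' @param seed random seed.
#' @param truth_path optional TSV output path for the truth table.
#' @return data.frame truth table: `fusion_id`, `gene5`, `gene3`, `tx5`,
#'   `tx3`, `breakpoint5`, `breakpoint3`, `chrom5`, `chrom3`,
#'   `genomic_pos5`, `genomic_pos3`, `fusion_sequence`.
#' @export
implant_fusions <- function(t, n_fusions, seed = 1, truth_path = NULL) {
  set.seed(seed)
  if (n_fusions == 0) {
    out <- data.frame(fusion_id = character(0), gene5 = character(0),
                      gene3 = character(0), tx5 = character(0),
                      tx3 = character(0), breakpoint5 = integer(0),
                      breakpoint3 = integer(0), chrom5 = character(0),
                      chrom3 = character(0), genomic_pos5 = integer(0),
                      genomic_pos3 = integer(0),
                      fusion_sequence = character(0),
                      stringsAsFactors = FALSE)
    if (!is.null(truth_path))
      utils::write.table(out, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    return(out)
  }
  g <- t$genes
  avail <- g$gene_id
  rows <- list()
  for (f in seq_len(n_fusions)) {
    ok <- FALSE
    for (try in 1:100) {
      pick <- sample(avail, 2)
      if (g$chrom[match(pick[1], g$gene_id)] !=
          g$chrom[match(pick[2], g$gene_id)]) { ok <- TRUE; break }
    }
    if (!ok) stop("not enough inter-chromosomal gene pairs available")
    avail <- setdiff(avail, pick)
    tx5 <- sort(t$transcripts$transcript_id[t$transcripts$gene_id == pick[1]])[1]
    tx3 <- sort(t$transcripts$transcript_id[t$transcripts$gene_id == pick[2]])[1]
    L5 <- t$transcripts$length[match(tx5, t$transcripts$transcript_id)]
    L3 <- t$transcripts$length[match(tx3, t$transcripts$transcript_id)]
    bp5 <- sample(floor(0.2 * L5):ceiling(0.8 * L5), 1)
    bp3 <- sample(floor(0.2 * L3):ceiling(0.8 * L3), 1)
    # canonicalise junction micro-homology to the maximal-5' form: while
    # the next 5' base equals the first retained 3' base the two
    # representations produce the same fusion sequence; callers report
    # the maximal form, so the truth table stores it
    while (bp5 < L5 && bp3 < L3 &&
           substr(t$sequences[[tx5]], bp5 + 1, bp5 + 1) ==
           substr(t$sequences[[tx3]], bp3, bp3)) {
      bp5 <- bp5 + 1L
      bp3 <- bp3 + 1L
    }
    fseq <- paste0(substr(t$sequences[[tx5]], 1, bp5),
                   substr(t$sequences[[tx3]], bp3, L3))
    rows[[f]] <- data.frame(
      fusion_id = sprintf("FUS%02d", f),
      gene5 = pick[1], gene3 = pick[2], tx5 = tx5, tx3 = tx3,
      breakpoint5 = bp5, breakpoint3 = bp3,
      chrom5 = g$chrom[match(pick[1], g$gene_id)],
      chrom3 = g$chrom[match(pick[2], g$gene_id)],
      genomic_pos5 = tx_to_genomic(t, tx5, bp5),
      genomic_pos3 = tx_to_genomic(t, tx3, bp3),
      fusion_sequence = fseq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(truth_path))
    utils::write.table(out, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Simulate paired-end reads
#'
#' Error-free fragment model: fragment lengths are Normal(mean, sd)
#' truncated to `[read_length, transcript length]`; mate 1 is the first
#' `read_length` bases of the fragment and mate 2 the reverse complement
#' of its last `read_length` bases. Fusion fragments are drawn so that
#' every fragment covers the junction (start uniform among
#' junction-covering positions). Background fragments come either as a
#' fixed count per transcript (`n_per_transcript`, the uniform-abundance
#' mode used by the sequence-similarity reference) or as `n_background`
#' fragments spread evenly over all transcripts. In `"exact"` abundance
#' mode counts are exactly as requested; `"poisson"` draws them.
#' `stranded = "no"` flips each fragment with probability 1/2;
#' `dup_rate` appends exact duplicates of that fraction of fragments.
#'
#' @param t a [transcriptome()].
#' @param truths [implant_fusions()] truth table (or `NULL`).
#' @param fusion_abundance junction-covering fragments per fusion
#'   (recycled along truths).
#' @param n_per_transcript uniform per-transcript background count.
#' @param n_background total background fragments (used when
#'   `n_per_transcript` is 0).
#' @param read_length,fraglen_mean,fraglen_sd read and fragment geometry.
#' @param seed random seed.
#' @param stranded `"no"` (unstranded), `"fr"` or `"rf"`.
#' @param dup_rate fraction of fragments duplicated exactly.
#' @param abundance_mode `"exact"` or `"poisson"`.
#' @param fastq1,fastq2 optional FASTQ output paths.
#' @return list with `reads1`, `reads2` (named character vectors),
#'   `origin` (per-fragment data.frame: `read_id`, `source`, `start`,
#'   `fraglen`, `flipped`, `duplicate`).
#' @export
simulate_reads <- function(t, truths = NULL, fusion_abundance = 100,
                           n_per_transcript = 0, n_background = 0,
                           read_length = 100, fraglen_mean = 250,
                           fraglen_sd = 25, seed = 1,
                           stranded = c("no", "fr", "rf"), dup_rate = 0,
                           abundance_mode = c("exact", "poisson"),
                           fastq1 = NULL, fastq2 = NULL) {
  stranded <- match.arg(stranded)
  abundance_mode <- match.arg(abundance_mode)
  set.seed(seed)
  src_seq <- character(0); src_n <- integer(0); src_bp <- integer(0)
  ids <- t$transcripts$transcript_id
  if (n_per_transcript > 0) {
    n <- rep(as.integer(n_per_transcript), length(ids))
    if (abundance_mode == "poisson") n <- stats::rpois(length(ids), n)
    src_seq <- c(src_seq, stats::setNames(unname(t$sequences[ids]), ids))
    src_n <- c(src_n, n); src_bp <- c(src_bp, rep(NA_integer_, length(ids)))
  } else if (n_background > 0) {
    base <- n_background %/% length(ids)
    n <- rep(base, length(ids))
    extra <- n_background - base * length(ids)
    if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
    if (abundance_mode == "poisson") n <- stats::rpois(length(ids), n)
    src_seq <- c(src_seq, stats::setNames(unname(t$sequences[ids]), ids))
    src_n <- c(src_n, n); src_bp <- c(src_bp, rep(NA_integer_, length(ids)))
  }
  if (!is.null(truths) && nrow(truths) > 0) {
    ab <- rep_len(fusion_abundance, nrow(truths))
    if (abundance_mode == "poisson") ab <- stats::rpois(nrow(truths), ab)
    src_seq <- c(src_seq, stats::setNames(truths$fusion_sequence, truths$fusion_id))
    src_n <- c(src_n, as.integer(ab)); src_bp <- c(src_bp, truths$breakpoint5)
  }
  if (length(src_seq) == 0 || sum(src_n) == 0)
    stop("nothing to simulate")

  m1 <- m2 <- src <- character(0)
  st <- fl_all <- integer(0)
  for (s in seq_along(src_seq)) {
    n <- src_n[s]
    if (n == 0) next
    sq <- src_seq[[s]]
    L <- nchar(sq)
    fl <- pmin(pmax(round(stats::rnorm(n, fraglen_mean, fraglen_sd)),
                    min(read_length, L)), L)
    if (is.na(src_bp[s])) {
      start <- 1L + floor(stats::runif(n) * (L - fl + 1))
    } else {
      bp <- src_bp[s]
      lo <- pmax(1L, bp + 2L - fl)
      hi <- pmin(bp, L - fl + 1L)
      if (any(hi < lo)) stop("fragment too short to cover the junction")
      start <- lo + floor(stats::runif(n) * (hi - lo + 1))
    }
    fend <- start + fl - 1L
    m1 <- c(m1, substring(sq, start, pmin(start + read_length - 1L, fend)))
    m2 <- c(m2, revcomp(substring(sq, pmax(fend - read_length + 1L, start), fend)))
    src <- c(src, rep(names(src_seq)[s], n))
    st <- c(st, start); fl_all <- c(fl_all, fl)
  }
  ntot <- length(m1)
  flipped <- switch(stranded,
                    no = stats::runif(ntot) < 0.5,
                    fr = rep(FALSE, ntot),
                    rf = rep(TRUE, ntot))
  # sequencing the opposite strand of a fragment swaps the mate roles:
  # read 1 becomes the (already reverse-complemented) 3' end
  r1 <- ifelse(flipped, m2, m1)
  r2 <- ifelse(flipped, m1, m2)
  ids_out <- sprintf("frag%07d", seq_len(ntot))
  dup <- rep(FALSE, ntot)
  if (dup_rate > 0) {
    nd <- min(ntot, round(dup_rate * ntot))
    if (nd > 0) {
      di <- sample.int(ntot, nd)
      r1 <- c(r1, r1[di]); r2 <- c(r2, r2[di])
      ids_out <- c(ids_out, paste0(ids_out[di], "d"))
      src <- c(src, src[di]); st <- c(st, st[di])
      fl_all <- c(fl_all, fl_all[di]); flipped <- c(flipped, flipped[di])
      dup <- c(dup, rep(TRUE, nd))
    }
  }
  names(r1) <- names(r2) <- ids_out
  origin <- data.frame(read_id = ids_out, source = src, start = st,
                       fraglen = fl_all, flipped = flipped, duplicate = dup,
                       stringsAsFactors = FALSE)
  if (!is.null(fastq1)) write_fastq(r1, fastq1)
  if (!is.null(fastq2)) write_fastq(r2, fastq2)
  list(reads1 = r1, reads2 = r2, origin = origin)
}

#' Write reads to FASTQ
#' @param reads named character vector of sequences.
#' @param path output path (`.gz` for compressed output).
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", unname(qual)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path (optionally gzipped).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
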