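#' Default k-mer length for a given read length
#'
#' Short reads (< 70 bp) use k = 21, long reads k = 31; split-read
#' detection requires k to be less than half the read length.
#'
#' @param r read length in bases (>= 25).
#' @return k-mer length (21 or 31).
#' @export
choose_k <- function(r) {
  if (r < 25) stop("read length too small (< 25): no k >= 11 satisfies k < r/2")
  if (r < 70) 21L else 31L
}

#' Mapping parameters
#'
#' Bundles the k-mer length and read length used by the classification
#' thresholds. When k >= r/2 split-read detection is disabled (with a
#' warning) because a chimeric read cannot carry k matched bases on each
#' side of the junction.
#'
#' @param k k-mer length (>= 11).
#' @param r read length.
#' @return list with `k`, `r`, `split_enabled`.
#' @export
mapping_params <- function(k, r) {
  if (k < 11) stop("k must be >= 11")
  split_enabled <- k < r / 2
  if (!split_enabled)
    warning("k >= r/2: split-read detection disabled")
  list(k = as.integer(k), r = as.integer(r), split_enabled = split_enabled)
}

#' Build a k-mer index over a transcriptome
#'
#' Every length-k substring of every transcript is stored (canonical form
#' with an orientation bit) with its transcript and offset. K-mers
#' occurring more than `max_postings` times are skipped (they act as
#' mismatches during mapping). Transcripts shorter than k are skipped with
#' a warning.
#'
#' @param t a [transcriptome()].
#' @param k k-mer length (<= 31).
#' @param max_postings per-k-mer postings cap (0 = unlimited).
#' @return An object of class `"kmer_index"`.
#' @export
build_index <- function(t, k = 31, max_postings = 200) {
  if (n_transcripts(t) == 0) stop("empty transcriptome")
  short <- t$transcripts$transcript_id[t$transcripts$length < k]
  if (length(short) > 0)
    warning(length(short), " transcript(s) shorter than k skipped")
  ids <- t$transcripts$transcript_id
  ptr <- build_index_cpp(unname(t$sequences[ids]), as.integer(k),
                         as.integer(max_postings))
  structure(list(ptr = ptr, k = as.integer(k), tx_ids = ids,
                 tx_gene = t$transcripts$gene_id,
                 max_postings = as.integer(max_postings)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "over", length(x$tx_ids), "transcripts (",
      index_n_kmers_cpp(x$ptr), "distinct indexed k-mers )\n")
  invisible(x)
}

#' Look up one k-mer in the index
#'
#' @param idx a [build_index()] result.
#' @param kmer a length-k nucleotide string.
#' @return data.frame with `transcript_id`, `pos` (1-based offset) and
#'   `orientation` (`fwd` if the transcript contains the k-mer as written,
#'   `rc` if it contains its reverse complement).
#' @export
kmer_lookup <- function(idx, kmer) {
  h <- kmer_lookup_cpp(idx$ptr, kmer)
  data.frame(transcript_id = idx$tx_ids[h$tx], pos = h$pos,
             orientation = h$orientation, stringsAsFactors = FALSE)
}

#' Reverse complement of nucleotide strings
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Quasi-map a single read
#'
#' Greedy maximal-extension mapping: from the leftmost query position with
#' an indexed k-mer, the match is extended base-by-base along each hit
#' transcript while bases agree; the segment keeps the transcripts
#' supporting the maximal extension, and the scan resumes after the
#' segment. Both orientations are attempted and the one covering more
#' query bases is kept (ties go to forward). Segment coordinates refer to
#' the mapped orientation (for `rc`, to the reverse complement of `seq`).
#'
#' @param seq read sequence.
#' @param idx a [build_index()] result.
#' @return list with `orientation`, `total_matched`, `seq` (the sequence
#'   in mapped orientation) and `segments`, a list of
#'   `list(query_start, query_end, hits)` where `hits` is a data.frame
#'   of `transcript_id`, `tx_start` (both 1-based, ends inclusive).
#' @export
map_read <- function(seq, idx) {
  m <- map_read_cpp(seq, idx$ptr)
  nseg <- length(m$qstart)
  segs <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    segs[[i]] <- list(
      query_start = m$qstart[i],
      query_end = m$qend[i],
      hits = data.frame(transcript_id = idx$tx_ids[m$hit_tx[[i]]],
                        tx_start = m$hit_pos[[i]],
                        stringsAsFactors = FALSE))
  }
  nseq <- toupper(seq)
  if (m$orientation == "rc") nseq <- revcomp(nseq)
  list(orientation = m$orientation, total_matched = m$total_matched,
       seq = nseq, segments = segs)
}

per_tx_matched <- function(rm) {
  acc <- list()
  for (s in rm$segments) {
    len <- s$query_end - s$query_start + 1L
    for (j in seq_len(nrow(s$hits))) {
      id <- s$hits$transcript_id[j]
      cur <- acc[[id]]
      if (is.null(cur)) cur <- c(bases = 0L, minpos = .Machine$integer.max)
      cur["bases"] <- cur["bases"] + len
      cur["minpos"] <- min(cur["minpos"], s$hits$tx_start[j])
      acc[[id]] <- cur
    }
  }
  acc
}

#' Quasi-map a read pair
#'
#' Maps both mates and derives the transcript hit sets used by the fusion
#' equivalence class machinery: `T1`/`T2` contain the transcripts to which
#' a mate maps (near-)fully, i.e. with at least r - k - 1 matched bases
#' (r = mate length); partial split hits do not enter `T1`/`T2`.
#' `S = T1 n T2` is the concordant set, `S1 = T1 - S` and `S2 = T2 - S`
#' the discordant sets.
#'
#' @param seq1,seq2 mate sequences.
#' @param idx a [build_index()] result.
#' @param read_id identifier carried through to downstream records.
#' @return list with `read_id`, `mapping1`, `mapping2` (see [map_read()]),
#'   and character vectors `T1`, `T2`, `S`, `S1`, `S2`.
#' @export
map_pair <- function(seq1, seq2, idx, read_id = "") {
  m1 <- map_read(seq1, idx)
  m2 <- map_read(seq2, idx)
  k <- idx$k
  thr1 <- nchar(seq1) - k - 1
  thr2 <- nchar(seq2) - k - 1
  a1 <- per_tx_matched(m1)
  a2 <- per_tx_matched(m2)
  T1 <- names(a1)[vapply(a1, function(x) x["bases"] >= thr1, logical(1))]
  T2 <- names(a2)[vapply(a2, function(x) x["bases"] >= thr2, logical(1))]
  S <- intersect(T1, T2)
  list(read_id = read_id, mapping1 = m1, mapping2 = m2,
       T1 = T1, T2 = T2, S = S,
       S1 = setdiff(T1, S), S2 = setdiff(T2, S))
}
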