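# Fusion equivalence classes: grouping junction-spanning (mapped-read)
# pairs by their set of candidate fusion transcripts, and the raw /
# multiplicity-corrected fragment counts per fusion gene derived from
# that grouping.

ftx_key <- function(tx5, tx3) paste(tx5, tx3, sep = "~")
fge_key <- function(g5, g3) paste(g5, g3, sep = "~")

#' Fusion transcript candidates from discordant hit sets
#'
#' The full ordered cross product S1 x S2: every (5' transcript,
#' 3' transcript) combination a discordant read pair could jointly
#' originate from.
#'
#' @param S1,S2 character vectors of discordant transcript ids (disjoint).
#' @return data.frame with columns `tx5`, `tx3` (one row per ordered pair).
#' @export
fusion_transcripts <- function(S1, S2) {
  if (length(intersect(S1, S2)) > 0) stop("S1 and S2 must be disjoint")
  if (length(S1) == 0 || length(S2) == 0)
    return(data.frame(tx5 = character(0), tx3 = character(0),
                      stringsAsFactors = FALSE))
  g <- expand.grid(tx3 = S2, tx5 = S1, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(tx5 = g$tx5, tx3 = g$tx3, stringsAsFactors = FALSE)
}

#' Build the fusion equivalence class table
#'
#' Partitions mapped-read pairs into equivalence classes indexed by their
#' set of fusion-transcript candidates: pairs with identical candidate
#' sets share a class whose count is the number of such pairs. Fragments
#' whose candidate set involves two transcripts of the same gene (the 5'
#' and 3' sides share a gene) are discarded entirely.
#'
#' @param pairs list of records, each with `read_id`, `S1`, `S2`
#'   (character vectors of 5'- and 3'-side transcript ids) and optionally
#'   `pos1`, `pos2` (named integer vectors: mate start position on each
#'   transcript, used downstream for positional filtering).
#' @param t a [transcriptome()].
#' @return An object of class `"feq_table"`: classes with their counts
#'   and member fusion transcripts, the fusion-transcript and fusion-gene
#'   universes, and the retained pair records.
#' @export
build_feq_table <- function(pairs, t) {
  t2g <- tx2gene(t)
  classes <- list()
  retained <- list()
  discarded <- 0L
  for (p in pairs) {
    if (length(p$S1) == 0 || length(p$S2) == 0) next
    g5 <- unique(unname(t2g[p$S1]))
    g3 <- unique(unname(t2g[p$S2]))
    if (length(intersect(g5, g3)) > 0) { discarded <- discarded + 1L; next }
    ft <- fusion_transcripts(p$S1, p$S2)
    keys <- sort(ftx_key(ft$tx5, ft$tx3))
    ck <- paste(keys, collapse = ";")
    if (is.null(classes[[ck]])) {
      classes[[ck]] <- list(ftx = keys, count = 0L, read_ids = character(0))
    }
    classes[[ck]]$count <- classes[[ck]]$count + 1L
    classes[[ck]]$read_ids <- c(classes[[ck]]$read_ids, p$read_id)
    retained[[p$read_id]] <- p
  }
  ftx_all <- sort(unique(as.character(unlist(lapply(classes, `[[`, "ftx")))))
  parts <- strsplit(ftx_all, "~", fixed = TRUE)
  ftx_g5 <- vapply(parts, function(x) unname(t2g[x[1]]), character(1))
  ftx_g3 <- vapply(parts, function(x) unname(t2g[x[2]]), character(1))
  names(ftx_g5) <- names(ftx_g3) <- ftx_all
  structure(list(classes = classes,
                 ftx_universe = ftx_all,
                 ftx_gene5 = ftx_g5, ftx_gene3 = ftx_g3,
                 fge_universe = sort(unique(fge_key(ftx_g5, ftx_g3))),
                 pairs = retained,
                 n_retained = length(retained),
                 n_discarded = discarded),
            class = "feq_table")
}

#' @export
print.feq_table <- function(x, ...) {
  cat("feq_table:", length(x$classes), "equivalence classes,",
      length(x$ftx_universe), "fusion transcripts,",
      length(x$fge_universe), "fusion genes;",
      x$n_retained, "retained /", x$n_discarded, "discarded fragments\n")
  invisible(x)
}

# class keys (within tbl) supporting a fusion gene
supporting_classes <- function(fge, tbl) {
  g <- fge_key(fge[1], fge[2])
  members <- names(tbl$ftx_gene5)[fge_key(tbl$ftx_gene5, tbl$ftx_gene3) == g]
  if (length(members) == 0) return(character(0))
  keep <- vapply(tbl$classes, function(cl) any(cl$ftx %in% members), logical(1))
  names(tbl$classes)[keep]
}

#' Raw support count of a fusion gene
#'
#' Sum of class counts c_j over all equivalence classes containing at
#' least one fusion transcript of the gene pair.
#'
#' @param fge character vector `c(gene5, gene3)`.
#' @param tbl a [build_feq_table()] result.
#' @param t a [transcriptome()] (unused, kept for interface symmetry).
#' @return Integer count (0 for unknown gene pairs).
#' @export
support_count <- function(fge, tbl, t = NULL) {
  ck <- supporting_classes(fge, tbl)
  if (length(ck) == 0) return(0L)
  sum(vapply(tbl$classes[ck], `[[`, integer(1), "count"))
}

#' Raw support count of a single fusion transcript
#' @param tx5,tx3 transcript ids of the ordered pair.
#' @param tbl a [build_feq_table()] result.
#' @return Integer count.
#' @export
support_count_ftx <- function(tx5, tx3, tbl) {
  key <- ftx_key(tx5, tx3)
  keep <- vapply(tbl$classes, function(cl) key %in% cl$ftx, logical(1))
  if (!any(keep)) return(0L)
  sum(vapply(tbl$classes[keep], `[[`, integer(1), "count"))
}

#' Multiplicity-corrected support count of a fusion gene
#'
#' Each supporting class j contributes c_j * w_j once per fusion gene,
#' with w_j = 1 / (number of fusion transcripts in the class), so reads
#' compatible with many candidate fusion transcripts are down-weighted.
#' Always `corrected_count(fge) <= support_count(fge)`.
#'
#' @inheritParams support_count
#' @return Non-negative real.
#' @export
corrected_count <- function(fge, tbl, t = NULL) {
  ck <- supporting_classes(fge, tbl)
  if (length(ck) == 0) return(0)
  sum(vapply(tbl$classes[ck],
             function(cl) cl$count / length(cl$ftx), numeric(1)))
}

#' Fusion-gene candidates from a feq table
#'
#' One candidate per fusion gene with its raw and corrected counts and
#' the per-supporting-pair positional information (5'/3' mate start
#' positions on a representative transcript of each constituent gene)
#' used by the positional filters.
#'
#' @param tbl a [build_feq_table()] result.
#' @param t a [transcriptome()].
#' @return list of candidate records (class `"fusion_candidate"` each).
#' @export
mr_candidates <- function(tbl, t) {
  t2g <- tx2gene(t)
  out <- list()
  for (g in tbl$fge_universe) {
    gs <- strsplit(g, "~", fixed = TRUE)[[1]]
    ck <- supporting_classes(gs, tbl)
    rid <- unique(unlist(lapply(tbl$classes[ck], `[[`, "read_ids")))
    start5 <- start3 <- rep(NA_integer_, length(rid))
    tx5rep <- tx3rep <- rep(NA_character_, length(rid))
    for (i in seq_along(rid)) {
      p <- tbl$pairs[[rid[i]]]
      c5 <- sort(p$S1[t2g[p$S1] == gs[1]])
      c3 <- sort(p$S2[t2g[p$S2] == gs[2]])
      if (length(c5) > 0 && !is.null(p$pos1)) {
        tx5rep[i] <- c5[1]
        start5[i] <- unname(p$pos1[c5[1]])
      }
      if (length(c3) > 0 && !is.null(p$pos2)) {
        tx3rep[i] <- c3[1]
        start3[i] <- unname(p$pos2[c3[1]])
      }
    }
    out[[g]] <- structure(list(
      gene5 = gs[1], gene3 = gs[2],
      mr_support = support_count(gs, tbl),
      mr_corrected = corrected_count(gs, tbl),
      sr_support = 0L, sr_corrected = 0,
      read_ids = rid, start5 = start5, start3 = start3,
      tx5rep = tx5rep, tx3rep = tx3rep,
      breakpoint = NULL, motif = "unknown",
      flags = character(0), source = "MR"),
      class = "fusion_candidate")
  }
  out
}
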