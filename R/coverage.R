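## Per-contig, per-strand coverage tracks (reads/bp) with bedGraph I/O.

#' Create an empty coverage track
#'
#' A coverage track holds one numeric vector per contig and strand
#' (reads/bp at 1 nt resolution) plus a label (e.g. "IP" or "SMI").
#'
#' @param contigs Named integer vector of contig lengths.
#' @param label Track label.
#' @return An object of class `coverage_track`.
#' @export
new_coverage_track <- function(contigs, label = "track") {
  stopifnot(!is.null(names(contigs)), all(contigs > 0))
  mk <- function() lapply(as.list(contigs), function(n) numeric(n))
  structure(list(contigs = contigs, plus = mk(), minus = mk(),
                 label = label),
            class = "coverage_track")
}

strand_slot <- function(strand) {
  if (strand == "+") "plus" else if (strand == "-") "minus"
  else stop("strand must be '+' or '-'")
}

#' Add coverage over intervals
#'
#' Increments the track by `weight` reads/bp over each interval (1-based
#' closed), clipped at contig bounds.
#'
#' @param track `coverage_track`.
#' @param chrom,start,end,strand Parallel vectors describing intervals.
#' @param weight Per-interval coverage increment (recycled).
#' @return The updated track.
#' @export
add_coverage <- function(track, chrom, start, end, strand, weight = 1) {
  stopifnot(inherits(track, "coverage_track"))
  weight <- rep_len(weight, length(chrom))
  for (i in seq_along(chrom)) {
    sl <- strand_slot(strand[i])
    if (!chrom[i] %in% names(track$contigs)) {
      stop("unknown contig: ", chrom[i])
    }
    len <- track$contigs[[chrom[i]]]
    s <- max(1L, start[i]); e <- min(len, end[i])
    if (e >= s) {
      track[[sl]][[chrom[i]]][s:e] <- track[[sl]][[chrom[i]]][s:e] + weight[i]
    }
  }
  track
}

#' Extract strand-oriented coverage over a region
#'
#' Returns the coverage vector over `[start, end]` (1-based closed),
#' zero-padded outside contig bounds, reversed for the minus strand so the
#' result always reads 5' to 3'.
#'
#' @param track `coverage_track`.
#' @param chrom,start,end,strand Region description.
#' @return Numeric vector of length `end - start + 1`.
#' @export
coverage_region <- function(track, chrom, start, end, strand) {
  sl <- strand_slot(strand)
  len <- track$contigs[[chrom]]
  out <- numeric(end - start + 1)
  s <- max(1L, start); e <- min(len, end)
  if (e >= s) out[(s - start + 1):(e - start + 1)] <- track[[sl]][[chrom]][s:e]
  if (strand == "-") out <- rev(out)
  out
}

#' Total reads/bp mass of a track
#' @param track `coverage_track`.
#' @return Sum of coverage over both strands and all contigs.
#' @export
coverage_total <- function(track) {
  sum(vapply(track$plus, sum, numeric(1))) +
    sum(vapply(track$minus, sum, numeric(1)))
}

#' Write a coverage track as stranded bedGraph
#'
#' Two files are written: `<prefix>.plus.bedGraph` and
#' `<prefix>.minus.bedGraph` (0-based half-open, via rtracklayer).
#'
#' @param track `coverage_track`.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_coverage_bedgraph <- function(track, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedGraph"),
             minus = paste0(prefix, ".minus.bedGraph"))
  for (sl in c("plus", "minus")) {
    grl <- lapply(names(track$contigs), function(chrom) {
      v <- track[[sl]][[chrom]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values != 0
      if (!any(keep)) return(GRanges())
      GRanges(chrom, IRanges(starts[keep], ends[keep]),
              score = r$values[keep])
    })
    gr <- unlist(GRangesList(grl))
    seqlengths(gr) <- track$contigs[seqlevels(gr)]
    rtracklayer::export(gr, paths[[sl]], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a stranded bedGraph pair into a coverage track
#'
#' @param prefix Path prefix used by [write_coverage_bedgraph()].
#' @param contigs Named integer vector of contig lengths.
#' @param label Track label.
#' @return `coverage_track`.
#' @export
read_coverage_bedgraph <- function(prefix, contigs, label = "track") {
  track <- new_coverage_track(contigs, label)
  for (sl in c("plus", "minus")) {
    path <- paste0(prefix, ".", sl, ".bedGraph")
    if (!file.exists(path)) next
    gr <- rtracklayer::import(path, format = "bedGraph")
    for (i in seq_along(gr)) {
      chrom <- as.character(seqnames(gr))[i]
      track[[sl]][[chrom]][start(gr)[i]:end(gr)[i]] <-
        track[[sl]][[chrom]][start(gr)[i]:end(gr)[i]] + mcols(gr)$score[i]
    }
  }
  track
}
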