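## Brute-force oracles and light random-fixture builders, kept independent
## of the package's GRanges-based implementations: plain data frames and
## O(n*m) loops throughout.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## ---- random annotation fixtures -------------------------------------

## Builds a small GenomeAnnotation directly (no I/O): genes with random
## exon structures, a fraction with a second isoform that either skips an
## internal exon or adds an extra exon inside an intron of isoform 1.
random_annotation <- function(seed, n_genes = 5, max_exons = 8) {
  set.seed(seed)
  cursor <- 1000L
  exon_rows <- list()
  gene_rows <- list()
  for (g in seq_len(n_genes)) {
    n_ex <- sample(1:max_exons, 1)
    ex_len <- sample(50:200, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(100:1500, n_ex - 1, replace = TRUE)
              else integer(0)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- pos; ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + (if (e < n_ex) in_len[e] else 0L) + 1L
    }
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("g%02d", g)
    exon_rows[[length(exon_rows) + 1]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      start = starts, end = ends, strand = strand,
      stringsAsFactors = FALSE)
    if (n_ex >= 3 && runif(1) < 0.5) {
      if (runif(1) < 0.5) {
        ## isoform skipping one internal exon
        skip <- sample(2:(n_ex - 1), 1)
        s2 <- starts[-skip]; e2 <- ends[-skip]
      } else {
        ## isoform with an extra exon inside one intron of isoform 1
        k <- sample(n_ex - 1, 1)
        gap_lo <- ends[k] + 1L; gap_hi <- starts[k + 1] - 1L
        w <- min(50L, gap_hi - gap_lo - 9L)
        if (w >= 10) {
          es <- gap_lo + 5L
          s2 <- sort(c(starts, es)); e2 <- sort(c(ends, es + w - 1L))
        } else {
          s2 <- starts; e2 <- ends
        }
      }
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t2"),
        start = s2, end = e2, strand = strand, stringsAsFactors = FALSE)
    }
    gene_rows[[g]] <- data.frame(
      gene_id = gid, chrom = "chrT", strand = strand,
      start = starts[1], end = ends[n_ex],
      biotype = sample(c("protein_coding", "noncoding"), 1),
      stringsAsFactors = FALSE)
    cursor <- ends[n_ex] + sample(500:2000, 1)
  }
  genes <- do.call(rbind, gene_rows)
  exdf <- do.call(rbind, exon_rows)
  exons <- GRanges("chrT", IRanges(exdf$start, exdf$end),
                   strand = exdf$strand)
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    gene_id = exdf$gene_id, transcript_id = exdf$transcript_id,
    biotype = genes$biotype[match(exdf$gene_id, genes$gene_id)])
  tx <- unique(exdf[, c("gene_id", "transcript_id")])
  transcripts <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    sel <- exdf$transcript_id == tx$transcript_id[i]
    data.frame(transcript_id = tx$transcript_id[i],
               gene_id = tx$gene_id[i], chrom = "chrT",
               strand = genes$strand[match(tx$gene_id[i], genes$gene_id)],
               start = min(exdf$start[sel]), end = max(exdf$end[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         cds = GRanges(),
         contigs = c(chrT = cursor + 5000L)),
    class = "GenomeAnnotation")
}

## ---- intron-set oracle ----------------------------------------------

## Candidate introns per transcript, exon-conflict removal, identical-
## candidate de-duplication (smallest transcript id), then greedy overlap
## resolution by transcript id -- all with scalar loops on data frames.
oracle_intron_set <- function(ann) {
  ex <- data.frame(
    gene_id = S4Vectors::mcols(ann$exons)$gene_id,
    tx = S4Vectors::mcols(ann$exons)$transcript_id,
    start = start(ann$exons), end = end(ann$exons),
    strand = as.character(strand(ann$exons)),
    stringsAsFactors = FALSE)
  out <- list()
  for (gid in sort(unique(ex$gene_id))) {
    gex <- ex[ex$gene_id == gid, ]
    cand <- list()
    for (tx in sort(unique(gex$tx))) {
      te <- gex[gex$tx == tx, ]
      te <- te[order(te$start), ]
      if (nrow(te) < 2) next
      for (k in seq_len(nrow(te) - 1)) {
        s <- te$end[k] + 1L; e <- te$start[k + 1] - 1L
        if (e >= s) cand[[length(cand) + 1]] <-
          data.frame(start = s, end = e, tx = tx, stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    ## drop candidates overlapping any exon of the gene
    ok <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ok[i] <- !any(cand$start[i] <= gex$end & cand$end[i] >= gex$start)
    }
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    ## de-duplicate identical, keep smallest tx
    cand <- cand[order(cand$start, cand$end, cand$tx), , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$start, cand$end)), , drop = FALSE]
    ## greedy keep by tx then start
    cand <- cand[order(cand$tx, cand$start), , drop = FALSE]
    kept <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      if (!nrow(kept) ||
          !any(cand$start[i] <= kept$end & cand$end[i] >= kept$start)) {
        kept <- rbind(kept, cand[i, ])
      }
    }
    kept <- kept[order(kept$start), , drop = FALSE]
    strand <- gex$strand[1]
    n <- nrow(kept)
    kept$ordinal <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    kept$gene_id <- gid
    kept$strand <- strand
    out[[gid]] <- kept
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), ordinal = integer(),
                      strand = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$start),
      c("gene_id", "start", "end", "ordinal", "strand")]
}

intron_set_as_df <- function(introns) {
  df <- data.frame(
    gene_id = S4Vectors::mcols(introns)$gene_id,
    start = start(introns), end = end(introns),
    ordinal = S4Vectors::mcols(introns)$ordinal,
    strand = as.character(strand(introns)),
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), ]
  rownames(df) <- NULL
  df
}

## ---- interval oracles -----------------------------------------------

## strand-matched >=1 bp overlap count, O(n*m)
oracle_count_overlaps <- function(fs, fe, fstr, ps, pe, pstr) {
  n <- length(fs)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- sum(ps <= fe[i] & pe >= fs[i] & pstr == fstr[i])
  }
  out
}

## nearest edge-gap distance with smaller-start tie rule, O(n*m)
oracle_closest <- function(fs, fe, ps, pe, max_search = Inf) {
  n <- length(fs)
  dist <- rep(NA_real_, n); pk <- rep(NA_integer_, n)
  if (!length(ps)) return(list(distance = dist, peak = pk))
  for (i in seq_len(n)) {
    gaps <- pmax(0, pmax(ps - fe[i], fs[i] - pe) - 1)
    best <- min(gaps)
    if (best <= max_search) {
      cand <- which(gaps == best)
      pk[i] <- cand[which.min(ps[cand])]
      dist[i] <- best
    }
  }
  list(distance = dist, peak = pk)
}

## exact hypergeometric upper tail by pmf summation with choose()
oracle_hyper_p <- function(k, n1, n2, N) {
  if (k == 0) return(1)
  i <- k:min(n1, n2)
  sum(choose(n1, i) * choose(N - n1, n2 - i)) / choose(N, n2)
}

## BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
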