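## CLIP peak analysis: significance filter, genomic-context annotation,
## nearest-feature distances, metaprofiles, motif windows.

#' Filter CLIP peaks on enrichment and significance
#'
#' Keeps peaks with `log2fc >= min_log2fc` and `padj <= max_padj`, both
#' bounds inclusive. Defaults are the conventional CLIP reproducible-peak
#' thresholds (log2 fold change over size-matched input >= 3, adjusted
#' p-value <= 0.001).
#'
#' @param peaks `GRanges` with metadata columns `log2fc` and `padj`.
#' @param min_log2fc,max_padj Thresholds (inclusive).
#' @return Filtered `GRanges`; retained/total counts attached as attribute
#'   `"counts"`.
#' @export
filter_peaks <- function(peaks, min_log2fc = 3, max_padj = 0.001) {
  stopifnot(is(peaks, "GRanges"))
  md <- mcols(peaks)
  if (is.null(md$log2fc) || is.null(md$padj)) {
    stop("peaks must carry 'log2fc' and 'padj' metadata columns")
  }
  keep <- md$log2fc >= min_log2fc & md$padj <= max_padj
  out <- peaks[keep]
  attr(out, "counts") <- c(retained = sum(keep), total = length(peaks))
  out
}

#' Annotate peaks by genomic context
#'
#' Assigns each peak exactly one category by strand-matched overlap, in a
#' fixed priority order (first matching category wins):
#' CDS exon > 5' UTR > 3' UTR > noncoding exon > protein-coding intron >
#' noncoding intron > intergenic.
#'
#' @param peaks `GRanges`.
#' @param ann `GenomeAnnotation`.
#' @param introns Optional intron set (from [build_unique_intron_set()]);
#'   built from `ann` when omitted.
#' @param priority Character vector giving the category order.
#' @return `peaks` with an added `category` metadata column; category
#'   fractions attached as attribute `"fractions"`.
#' @export
annotate_peaks <- function(peaks, ann, introns = NULL,
                           priority = c("cds_exon", "utr5", "utr3",
                                        "noncoding_exon",
                                        "protein_coding_intron",
                                        "noncoding_intron")) {
  stopifnot(is(peaks, "GRanges"), inherits(ann, "GenomeAnnotation"))
  if (is.null(introns)) introns <- build_unique_intron_set(ann)
  introns <- classify_intron_context(introns, ann)
  regions <- annotation_regions(ann, introns)
  category <- rep("intergenic", length(peaks))
  unassigned <- rep(TRUE, length(peaks))
  for (cat in priority) {
    reg <- regions[[cat]]
    if (is.null(reg) || !length(reg)) next
    hit <- overlapsAny(peaks, reg, ignore.strand = FALSE)
    category[unassigned & hit] <- cat
    unassigned <- unassigned & !hit
  }
  mcols(peaks)$category <- category
  frac <- table(factor(category, levels = c(priority, "intergenic")))
  attr(peaks, "fractions") <- frac / max(1L, length(peaks))
  peaks
}

## Category region sets used by annotate_peaks: CDS, 5'/3' UTR (exonic
## minus CDS, split by transcript orientation), noncoding exons, and the
## classified introns.
annotation_regions <- function(ann, introns) {
  ex <- ann$exons
  pc_genes <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  nc_ex <- granges(ex[!(mcols(ex)$gene_id %in% pc_genes)])
  cds <- if (length(ann$cds)) granges(ann$cds) else GRanges()
  utr5 <- GRanges(); utr3 <- GRanges()
  if (length(ann$cds)) {
    for (tx in unique(mcols(ann$cds)$transcript_id)) {
      te <- granges(ex[mcols(ex)$transcript_id == tx])
      tc <- granges(ann$cds[mcols(ann$cds)$transcript_id == tx])
      u <- setdiff(te, tc, ignore.strand = FALSE)
      if (!length(u)) next
      plus <- as.character(strand(te))[1] == "+"
      cds_lo <- min(start(tc)); cds_hi <- max(end(tc))
      before <- end(u) < cds_lo      # genomically upstream of the CDS
      after <- start(u) > cds_hi
      if (plus) {
        utr5 <- c(utr5, u[before]); utr3 <- c(utr3, u[after])
      } else {
        utr5 <- c(utr5, u[after]); utr3 <- c(utr3, u[before])
      }
    }
  }
  ctx <- mcols(introns)$context
  list(
    cds_exon = cds,
    utr5 = utr5,
    utr3 = utr3,
    noncoding_exon = nc_ex,
    protein_coding_intron = granges(introns[ctx == "protein_coding_intron"]),
    noncoding_intron = granges(introns[ctx == "noncoding_intron"])
  )
}

#' Distance from features to the closest peak
#'
#' For each feature, the gap in nt to the nearest peak edge (0 when the
#' feature overlaps or abuts a peak). Ties are broken toward the peak with
#' the smaller genomic start. Features with no peak within `max_search`
#' get `NA` distance.
#'
#' @param features `GRanges` (points or intervals).
#' @param peaks `GRanges`.
#' @param max_search Maximum distance to report (nt); default `Inf`.
#' @param ignore_strand Match peaks on either strand (default `TRUE`, the
#'   convention of coordinate-closest searches).
#' @return data.frame with `distance` (nt, `NA` when out of range) and
#'   `peak` (index into `peaks`, `NA` likewise), one row per feature.
#' @export
closest_peak_distance <- function(features, peaks, max_search = Inf,
                                  ignore_strand = TRUE) {
  stopifnot(is(features, "GRanges"), is(peaks, "GRanges"))
  n <- length(features)
  out <- data.frame(distance = rep(NA_real_, n), peak = rep(NA_integer_, n))
  if (!length(peaks) || !n) return(out)
  ## candidate pairs within the search radius, then explicit edge-gap
  ## distances with a deterministic tie rule (smaller peak start wins)
  gap <- if (is.finite(max_search)) max_search + 1 else {
    max(c(end(features), end(peaks))) - min(c(start(features), start(peaks)))
  }
  hits <- findOverlaps(features, peaks, maxgap = gap,
                       ignore.strand = ignore_strand)
  if (!length(hits)) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  d <- pmax(0, pmax(start(peaks)[s] - end(features)[q],
                    start(features)[q] - end(peaks)[s]) - 1)
  o <- order(q, d, start(peaks)[s])
  q <- q[o]; s <- s[o]; d <- d[o]
  first <- !duplicated(q)
  q <- q[first]; s <- s[first]; d <- d[first]
  ok <- d <= max_search
  out$distance[q[ok]] <- d[ok]
  out$peak[q[ok]] <- s[ok]
  out
}

#' Exon-anchored metaprofile of a coverage track
#'
#' Averages strand-oriented coverage across exons: an upstream intronic
#' flank, the exon body rescaled to a fixed number of bins, and a
#' downstream intronic flank (transcript orientation, so the downstream
#' flank starts at the donor splice site of the following intron). Flank
#' coverage is averaged in `flank_bin`-nt bins; the body in
#' `body_bins` equal-width bins.
#'
#' @param track `coverage_track`.
#' @param ann `GenomeAnnotation`.
#' @param flank Intronic flank length in nt (default 300).
#' @param body_bins Number of exon-body bins (default 100).
#' @param flank_bin Flank bin width in nt (default 10).
#' @return data.frame of class `metaprofile` with `bin`, `region`
#'   (`upstream_flank`/`body`/`downstream_flank`), `mean`, `sem`, `n`.
#' @export
exon_metaprofile <- function(track, ann, flank = 300, body_bins = 100,
                             flank_bin = 10) {
  ex <- ann$exons
  nf <- flank %/% flank_bin
  mat <- matrix(NA_real_, nrow = length(ex), ncol = nf + body_bins + nf)
  for (i in seq_along(ex)) {
    chrom <- as.character(seqnames(ex))[i]
    st <- as.character(strand(ex))[i]
    s <- start(ex)[i]; e <- end(ex)[i]
    cov <- coverage_region(track, chrom, s - flank, e + flank, st)
    up <- cov[seq_len(flank)]
    body <- cov[(flank + 1):(flank + (e - s + 1))]
    down <- cov[(flank + (e - s + 1) + 1):length(cov)]
    mat[i, ] <- c(
      bin_means(up, nf),
      bin_means(body, body_bins),
      bin_means(down, nf)
    )
  }
  region <- c(rep("upstream_flank", nf), rep("body", body_bins),
              rep("downstream_flank", nf))
  structure(
    data.frame(
      bin = seq_len(ncol(mat)),
      region = region,
      mean = colMeans(mat, na.rm = TRUE),
      sem = apply(mat, 2, function(v) {
        v <- v[is.finite(v)]
        if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      }),
      n = nrow(mat),
      stringsAsFactors = FALSE
    ),
    class = c("metaprofile", "data.frame")
  )
}

## mean of v partitioned into nbins near-equal consecutive chunks
bin_means <- function(v, nbins) {
  idx <- ceiling(seq_along(v) / length(v) * nbins)
  as.numeric(tapply(v, factor(idx, levels = seq_len(nbins)), mean))
}

## median of v per chunk (used where aggregation is median-based)
bin_medians <- function(v, nbins) {
  idx <- ceiling(seq_along(v) / length(v) * nbins)
  as.numeric(tapply(v, factor(idx, levels = seq_len(nbins)), median))
}

#' Pre-miRNA-anchored metaprofile
#'
#' Each pre-miR is extended by `extend` nt on both sides, the region
#' coverage is strand-oriented and rescaled to a common `scale_to`-nt
#' axis divided into `bins` bins; within each bin the median coverage is
#' taken per feature, then averaged across features (mean +/- SEM).
#'
#' @param track `coverage_track`.
#' @param pre_mirs `GRanges` of pre-miR coordinates.
#' @param extend Extension in nt on each side (default 2000).
#' @param scale_to Common scaled axis length in nt (default 5000).
#' @param bins Number of bins over the scaled axis (default 100).
#' @return `metaprofile` data.frame with `bin`, `scaled_nt`, `mean`,
#'   `sem`, `n`.
#' @export
premir_metaprofile <- function(track, pre_mirs, extend = 2000,
                               scale_to = 5000, bins = 100) {
  stopifnot(is(pre_mirs, "GRanges"))
  mat <- matrix(NA_real_, nrow = length(pre_mirs), ncol = bins)
  for (i in seq_along(pre_mirs)) {
    chrom <- as.character(seqnames(pre_mirs))[i]
    st <- as.character(strand(pre_mirs))[i]
    cov <- coverage_region(track, chrom, start(pre_mirs)[i] - extend,
                           end(pre_mirs)[i] + extend, st)
    ## rescale to the common axis, then median-bin
    scaled <- approx(seq_along(cov), cov, n = scale_to)$y
    mat[i, ] <- bin_medians(scaled, bins)
  }
  structure(
    data.frame(
      bin = seq_len(bins),
      scaled_nt = round(seq(0.5, bins - 0.5) / bins * scale_to),
      mean = colMeans(mat, na.rm = TRUE),
      sem = apply(mat, 2, function(v) {
        v <- v[is.finite(v)]
        if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      }),
      n = nrow(mat),
      stringsAsFactors = FALSE
    ),
    class = c("metaprofile", "data.frame")
  )
}

#' CLIP signal map around cassette exons, by splicing direction
#'
#' For each cassette-exon event two windows are profiled in transcript
#' orientation: an acceptor-side window (250 nt of intron upstream of the
#' 3' splice site plus 50 nt into the exon) and a donor-side window (50 nt
#' of exon upstream of the 5' splice site plus 250 nt of intron
#' downstream). Per 50-bp bin the signal is RPKM(IP) / RPKM(SMI), with a
#' pseudocount of 1 read added to both bin read totals, then averaged
#' across events separately for each direction class.
#'
#' @param ip,smi `coverage_track` pair (CLIP IP and size-matched input).
#' @param events data.frame with columns `chrom`, `strand`, `exon_start`,
#'   `exon_end`, `delta_psi`, `direction` (`"higher_in_OE"` /
#'   `"lower_in_OE"`).
#' @param min_delta_psi Events with `|delta_psi|` below this are dropped
#'   (default 0.2).
#' @param intron_ext,exon_ext Window extents in nt (defaults 250 and 50).
#' @param bin Averaging bin width in nt (default 50).
#' @return data.frame with `direction`, `side` (`acceptor`/`donor`),
#'   `bin`, `mean`, `sem`, `n` (events).
#' @export
cassette_exon_map <- function(ip, smi, events, min_delta_psi = 0.2,
                              intron_ext = 250, exon_ext = 50, bin = 50) {
  stopifnot(all(c("chrom", "strand", "exon_start", "exon_end",
                  "delta_psi", "direction") %in% names(events)))
  events <- events[abs(events$delta_psi) >= min_delta_psi, , drop = FALSE]
  if (!nrow(events)) stop("no events pass the |delta PSI| threshold")
  wlen <- intron_ext + exon_ext
  nb <- ceiling(wlen / bin)
  ip_m <- coverage_total(ip) / 1e6
  smi_m <- coverage_total(smi) / 1e6
  out <- list()
  for (dir in unique(events$direction)) {
    ev <- events[events$direction == dir, , drop = FALSE]
    acc <- matrix(NA_real_, nrow(ev), nb)
    don <- matrix(NA_real_, nrow(ev), nb)
    for (i in seq_len(nrow(ev))) {
      plus <- ev$strand[i] == "+"
      s <- ev$exon_start[i]; e <- ev$exon_end[i]
      if (e - s + 1 < exon_ext) {
        warning("event ", i, " (", dir, "): exon shorter than the exonic ",
                "window; clipping")
      }
      if (plus) {
        acc_rng <- c(s - intron_ext, s + exon_ext - 1)
        don_rng <- c(e - exon_ext + 1, e + intron_ext)
      } else {
        acc_rng <- c(e - exon_ext + 1, e + intron_ext)
        don_rng <- c(s - intron_ext, s + exon_ext - 1)
      }
      st <- ev$strand[i]
      acc[i, ] <- rpkm_ratio_bins(
        coverage_region(ip, ev$chrom[i], acc_rng[1], acc_rng[2], st),
        coverage_region(smi, ev$chrom[i], acc_rng[1], acc_rng[2], st),
        nb, bin, ip_m, smi_m)
      don[i, ] <- rpkm_ratio_bins(
        coverage_region(ip, ev$chrom[i], don_rng[1], don_rng[2], st),
        coverage_region(smi, ev$chrom[i], don_rng[1], don_rng[2], st),
        nb, bin, ip_m, smi_m)
    }
    for (side in c("acceptor", "donor")) {
      m <- if (side == "acceptor") acc else don
      out[[paste(dir, side)]] <- data.frame(
        direction = dir, side = side, bin = seq_len(nb),
        mean = colMeans(m, na.rm = TRUE),
        sem = apply(m, 2, function(v) {
          v <- v[is.finite(v)]
          if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
        }),
        n = nrow(m), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

## per-bin RPKM(IP)/RPKM(SMI) with +1 read pseudocount in both totals
rpkm_ratio_bins <- function(ipv, smiv, nb, bin, ip_millions, smi_millions) {
  idx <- ceiling(seq_along(ipv) / bin)
  idx[idx > nb] <- nb
  f <- factor(idx, levels = seq_len(nb))
  ip_sum <- as.numeric(tapply(ipv, f, sum))
  smi_sum <- as.numeric(tapply(smiv, f, sum))
  blen <- as.numeric(tapply(ipv, f, length))
  rpkm_ip <- (ip_sum + 1) / (blen / 1000) / ip_millions
  rpkm_smi <- (smi_sum + 1) / (blen / 1000) / smi_millions
  rpkm_ip / rpkm_smi
}

#' Sequence windows around peak centers for motif analysis
#'
#' Extracts the 101-nt window (center +/- 50 nt) around each peak's
#' midpoint (floor of the interval midpoint), reverse-complemented for
#' minus-strand peaks. Windows truncated at contig edges are clipped and
#' flagged.
#'
#' @param peaks `GRanges`.
#' @param genome `Biostrings::DNAStringSet` keyed by contig name.
#' @param flank Flank on each side of the center (default 50).
#' @return `DNAStringSet` named `peak_<i>`; logical attribute
#'   `"clipped"` marks edge-truncated windows.
#' @export
motif_windows <- function(peaks, genome, flank = 50) {
  stopifnot(is(peaks, "GRanges"), is(genome, "DNAStringSet"))
  n <- length(peaks)
  seqs <- vector("list", n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(peaks))[i]
    if (!chrom %in% names(genome)) stop("contig missing from genome: ", chrom)
    center <- (start(peaks)[i] + end(peaks)[i]) %/% 2
    len <- length(genome[[chrom]])
    s <- center - flank; e <- center + flank
    if (s < 1 || e > len) {
      clipped[i] <- TRUE
      s <- max(1L, s); e <- min(len, e)
    }
    w <- Biostrings::subseq(genome[[chrom]], s, e)
    if (as.character(strand(peaks))[i] == "-") {
      w <- Biostrings::reverseComplement(w)
    }
    seqs[[i]] <- w
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("peak_", seq_len(n))
  attr(out, "clipped") <- clipped
  out
}
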