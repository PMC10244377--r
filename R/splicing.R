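## Junction-read splicing efficiency: SE = ee / (ee + ei), its contrasts
## across genotypes, and its relation to CLIP cluster counts.

#' Read a junction count table from TSV
#'
#' Expected columns: `gene_id`, `intron_index`, `sample`, `ee` (exon-exon
#' junction-spanning reads), `ei` (exon-intron junction-spanning reads,
#' donor- and acceptor-side combined).
#'
#' @param path TSV file path.
#' @return data.frame in long format.
#' @export
read_junction_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "intron_index", "sample", "ee", "ei")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("junction table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_junction_counts(tab)
  tab
}

validate_junction_counts <- function(counts) {
  if (any(counts$ee < 0 | counts$ei < 0)) {
    stop("junction counts must be non-negative")
  }
  if (any(counts$ee != round(counts$ee) | counts$ei != round(counts$ei))) {
    stop("junction counts must be integers")
  }
  invisible(TRUE)
}

#' Splicing efficiency from junction-spanning reads
#'
#' Computes the splicing-efficiency statistic SE = ee / (ee + ei), the
#' fraction of junction-spanning reads that are exon-exon (spliced), per
#' intron and per sample. At the gene ("transcript") level, `ee` and `ei`
#' are summed over the gene's unique introns first, then divided. Rows with
#' total junction coverage below `min_reads` have SE set to `NA` (flagged
#' missing, never zero).
#'
#' @param counts Long-format junction count table (see
#'   [read_junction_counts()]).
#' @param level `"intron"` (default) or `"gene"`.
#' @param min_reads Minimum `ee + ei` for SE to be defined (default 10).
#' @return data.frame with key columns (`gene_id`, `intron_index` unless
#'   gene level), `sample`, `ee`, `ei`, `coverage` and `se`.
#' @examples
#' tab <- data.frame(gene_id = "g1", intron_index = 1, sample = "s1",
#'                   ee = 30L, ei = 10L)
#' splicing_efficiency(tab, min_reads = 1)$se  # 0.75
#' @export
splicing_efficiency <- function(counts, level = c("intron", "gene"),
                                min_reads = 10) {
  level <- match.arg(level)
  stopifnot(min_reads >= 1)
  validate_junction_counts(counts)
  if (level == "gene") {
    agg <- stats::aggregate(cbind(ee, ei) ~ gene_id + sample, data = counts,
                            FUN = sum)
    counts <- agg
  }
  counts$coverage <- counts$ee + counts$ei
  counts$se <- ifelse(counts$coverage >= min_reads,
                      counts$ee / counts$coverage, NA_real_)
  counts
}

#' Per-intron difference in splicing efficiency between conditions
#'
#' Averages SE over the samples (replicates) present in each table, then
#' takes the per-intron difference mean(SE in `se_a`) - mean(SE in `se_b`).
#' Introns with no defined SE on either side are dropped and counted.
#'
#' @param se_a,se_b SE tables from [splicing_efficiency()] (intron level);
#'   `se_a` is the condition, `se_b` the reference.
#' @return data.frame with `gene_id`, `intron_index`, `se_a`, `se_b`,
#'   `delta_se`; the number of dropped introns is attached as attribute
#'   `"n_dropped"`.
#' @export
delta_splicing_efficiency <- function(se_a, se_b) {
  key <- c("gene_id", "intron_index")
  stopifnot(all(key %in% names(se_a)), all(key %in% names(se_b)))
  mean_se <- function(tab) {
    agg <- stats::aggregate(se ~ gene_id + intron_index, data = tab,
                            FUN = mean, na.action = stats::na.omit)
    agg
  }
  a <- mean_se(se_a); b <- mean_se(se_b)
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no shared introns with defined SE between the tables")
  n_total <- length(unique(paste(c(se_a$gene_id, se_b$gene_id),
                                 c(se_a$intron_index, se_b$intron_index))))
  out <- data.frame(
    gene_id = m$gene_id, intron_index = m$intron_index,
    se_a = m$se_a, se_b = m$se_b, delta_se = m$se_a - m$se_b,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_total - nrow(out)
  out
}

#' Count CLIP clusters overlapping introns or genes
#'
#' Counts peaks overlapping each intron by at least 1 bp, strand-matched.
#' At the gene level a peak is counted once per gene even when it spans
#' several of the gene's introns.
#'
#' @param introns `GRanges` from [build_unique_intron_set()].
#' @param peaks `GRanges` peak set.
#' @param level `"intron"` (default) or `"gene"`.
#' @return data.frame with `gene_id` (and `intron_index` at intron level)
#'   and `n_clusters`.
#' @export
count_clusters_per_feature <- function(introns, peaks,
                                       level = c("intron", "gene")) {
  level <- match.arg(level)
  stopifnot(is(introns, "GRanges"), is(peaks, "GRanges"))
  bad <- setdiff(unique(as.character(seqnames(peaks))),
                 unique(as.character(seqnames(introns))))
  if (length(bad)) {
    stop("peak contig(s) absent from the intron set: ",
         paste(bad, collapse = ", "))
  }
  if (level == "intron") {
    n <- countOverlaps(introns, peaks, ignore.strand = FALSE)
    data.frame(
      gene_id = mcols(introns)$gene_id,
      intron_index = mcols(introns)$ordinal,
      n_clusters = as.integer(n),
      stringsAsFactors = FALSE
    )
  } else {
    hits <- findOverlaps(introns, peaks, ignore.strand = FALSE)
    gene_hit <- unique(data.frame(
      gene_id = mcols(introns)$gene_id[queryHits(hits)],
      peak = subjectHits(hits)
    ))
    tab <- table(gene_hit$gene_id)
    genes <- unique(mcols(introns)$gene_id)
    data.frame(
      gene_id = genes,
      n_clusters = as.integer(ifelse(genes %in% names(tab),
                                     tab[genes], 0L)),
      stringsAsFactors = FALSE
    )
  }
}

#' Bin features by CLIP-cluster count and attach SE values
#'
#' Assigns each feature the unique cluster-count bin containing its count
#' and joins the per-sample SE values. Default bins: 0, 1-2, 3-5, >=6.
#'
#' @param se Intron-level SE table from [splicing_efficiency()].
#' @param cluster_counts From [count_clusters_per_feature()] (intron
#'   level).
#' @param bins Increasing integer vector of lower bin edges (default
#'   `c(0, 1, 3, 6)`).
#' @param min_group_size Bins with fewer features are flagged (attribute
#'   `"small_bins"`), not dropped. Default 10.
#' @return data.frame with the SE columns plus `n_clusters` and `bin`
#'   (ordered factor).
#' @export
group_se_by_cluster_count <- function(se, cluster_counts,
                                      bins = c(0, 1, 3, 6),
                                      min_group_size = 10) {
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  labels <- bin_labels(bins)
  m <- merge(se, cluster_counts, by = c("gene_id", "intron_index"))
  idx <- findInterval(m$n_clusters, bins)
  if (any(idx == 0)) stop("cluster count below the first bin edge")
  m$bin <- factor(labels[idx], levels = labels, ordered = TRUE)
  per_feature <- unique(m[, c("gene_id", "intron_index", "bin")])
  occ <- table(per_feature$bin)
  attr(m, "small_bins") <- names(occ)[occ > 0 & occ < min_group_size]
  m
}

bin_labels <- function(bins) {
  n <- length(bins)
  lab <- character(n)
  for (i in seq_len(n)) {
    if (i < n) {
      hi <- bins[i + 1] - 1
      lab[i] <- if (hi == bins[i]) as.character(bins[i])
                else paste0(bins[i], "-", hi)
    } else {
      lab[i] <- paste0(">=", bins[i])
    }
  }
  lab
}

#' Compare splicing efficiency across cluster-count bins
#'
#' Kruskal-Wallis omnibus test followed by Dunn's all-pairs test with
#' Benjamini-Hochberg adjustment, on per-feature per-sample SE values
#' pooled within bins. Groups with fewer than 2 observations are excluded
#' with a warning.
#'
#' @param grouping Output of [group_se_by_cluster_count()].
#' @param value Column holding the value to compare (default `"se"`).
#' @param group Column holding the group label (default `"bin"`).
#' @return List with `kruskal` (see [kruskal_wallis()]), `dunn`
#'   (data.frame), and `summary` (per-bin n, median, quartiles).
#' @export
compare_se_groups <- function(grouping, value = "se", group = "bin") {
  df <- grouping[is.finite(grouping[[value]]), c(group, value)]
  names(df) <- c("group", "value")
  df$group <- droplevels(factor(df$group))
  groups <- split(df$value, df$group)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >=2 occupied groups")
  summ <- do.call(rbind, lapply(names(groups), function(gname) {
    v <- groups[[gname]]
    data.frame(group = gname, n = length(v), median = median(v),
               q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(
    kruskal = kruskal_wallis(groups),
    dunn = dunn_all_pairs(groups, adjust = "BH"),
    summary = summ
  )
}
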