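## miRNA expression analysis: median-of-ratios normalization, the manual
## log2 fold-change formula, DE filters, peak-distance categories, and the
## miR-target anticorrelation filter.

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over features of
#' count_ij / (geometric mean of feature i across samples), restricted to
#' features with nonzero counts in every sample; factors are rescaled to
#' have geometric mean 1.
#'
#' @param counts Integer matrix, features x samples.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no feature has nonzero counts in all samples; ",
         "filter the matrix before normalizing")
  }
  lgm <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  f <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - lgm))
  })
  f <- f / exp(mean(log(f)))
  f
}

#' Normalize a count matrix by size factors
#'
#' @param counts Features x samples matrix.
#' @param factors Size factors (from [size_factors()] by default).
#' @return Matrix of normalized counts (counts / factor per sample).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  sweep(counts, 2, factors, "/")
}

#' Manual log2 fold change between two conditions
#'
#' log2FC = log2((N_x + 1) / (N_y + 1)), where N is the per-condition
#' mean of normalized counts.
#'
#' @param norm_counts Normalized count matrix (features x samples).
#' @param condition_map Named character vector mapping sample (column)
#'   names to condition labels.
#' @param x,y Condition labels (x over y).
#' @return Named numeric vector of log2 fold changes per feature.
#' @examples
#' m <- matrix(c(7, 7, 3, 3), 1, dimnames = list("f", paste0("s", 1:4)))
#' manual_log2fc(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"), "a", "b")  # 1
#' @export
manual_log2fc <- function(norm_counts, condition_map, x, y) {
  norm_counts <- as.matrix(norm_counts)
  cx <- names(condition_map)[condition_map == x]
  cy <- names(condition_map)[condition_map == y]
  if (!length(cx) || !length(cy)) {
    stop("both conditions need at least one sample")
  }
  nx <- rowMeans(norm_counts[, cx, drop = FALSE])
  ny <- rowMeans(norm_counts[, cy, drop = FALSE])
  log2((nx + 1) / (ny + 1))
}

#' baseMean of a normalized count matrix
#'
#' Mean of normalized counts across all samples (both conditions), per
#' feature.
#'
#' @param norm_counts Normalized count matrix.
#' @return Named numeric vector.
#' @export
base_mean <- function(norm_counts) {
  rowMeans(as.matrix(norm_counts))
}

#' Differential-expression table for the synthetic pipeline
#'
#' Assembles a DE result table (baseMean, manual log2FC, p, padj) from a
#' raw count matrix. Per-feature p-values come from a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test between the two conditions,
#' BH-adjusted; externally computed tables with the same columns are
#' accepted by [de_filter()] unchanged.
#'
#' @param counts Raw count matrix (features x samples).
#' @param condition_map Named sample -> condition map.
#' @param x,y Condition labels (x over y).
#' @return data.frame with `feature`, `baseMean`, `log2FC`, `p`, `padj`.
#' @export
de_table <- function(counts, condition_map, x, y) {
  nf <- size_factors(counts)
  nc <- normalize_counts(counts, nf)
  cx <- names(condition_map)[condition_map == x]
  cy <- names(condition_map)[condition_map == y]
  p <- apply(nc, 1, function(v) {
    suppressWarnings(wilcox.test(v[cx], v[cy], exact = FALSE)$p.value)
  })
  p[is.na(p)] <- 1
  data.frame(
    feature = rownames(nc),
    baseMean = base_mean(nc),
    log2FC = manual_log2fc(nc, condition_map, x, y),
    p = p,
    padj = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Differential-expression filter
#'
#' Keeps features with `|log2FC| >= 1`, `padj <= 0.05` and
#' `baseMean >= 5` (miRs) or `>= 10` (genes); all bounds inclusive.
#'
#' @param results data.frame with `log2FC`, `padj`, `baseMean` columns.
#' @param kind `"mir"` (baseMean cutoff 5) or `"gene"` (cutoff 10).
#' @param min_abs_log2fc,max_padj Thresholds (defaults 1 and 0.05).
#' @return Subset of `results` with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
de_filter <- function(results, kind = c("mir", "gene"),
                      min_abs_log2fc = 1, max_padj = 0.05) {
  kind <- match.arg(kind)
  min_base_mean <- if (kind == "mir") 5 else 10
  keep <- abs(results$log2FC) >= min_abs_log2fc &
    results$padj <= max_padj &
    results$baseMean >= min_base_mean
  keep[is.na(keep)] <- FALSE
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Categorize miRs by CLIP-peak distance and host-intron context
#'
#' Assigns each mature miR one of four mutually exclusive categories, in
#' precedence order: `lt2kb` when the distance to the closest peak is at
#' most `dist_bound` nt; otherwise `gt2kb_protein_coding_intron` /
#' `gt2kb_noncoding_intron` when the miR lies within a classified intron;
#' otherwise `other`.
#'
#' @param mirs `GRanges` of mature miR coordinates (names = miR ids).
#' @param peaks `GRanges` peak set.
#' @param introns Classified intron set (from
#'   [classify_intron_context()]).
#' @param dist_bound Distance bound in nt (default 2000, inclusive).
#' @return data.frame with `mir_id`, `category`, `distance`, `host_intron`
#'   (index into `introns` or `NA`).
#' @export
categorize_mirs <- function(mirs, peaks, introns, dist_bound = 2000) {
  stopifnot(is(mirs, "GRanges"), is(peaks, "GRanges"),
            is(introns, "GRanges"))
  if (is.null(mcols(introns)$context)) {
    stop("introns must carry a 'context' column; run classify_intron_context")
  }
  nd <- closest_peak_distance(mirs, peaks, max_search = Inf)
  host <- findOverlaps(mirs, introns, type = "within", ignore.strand = FALSE)
  host_idx <- rep(NA_integer_, length(mirs))
  host_idx[queryHits(host)] <- subjectHits(host)
  category <- rep("other", length(mirs))
  in_intron <- !is.na(host_idx)
  ctx <- mcols(introns)$context[host_idx[in_intron]]
  category[in_intron] <- ifelse(ctx == "protein_coding_intron",
                                "gt2kb_protein_coding_intron",
                                "gt2kb_noncoding_intron")
  near <- !is.na(nd$distance) & nd$distance <= dist_bound
  category[near] <- "lt2kb"
  ids <- names(mirs)
  if (is.null(ids)) ids <- paste0("mir_", seq_along(mirs))
  data.frame(
    mir_id = ids,
    category = category,
    distance = nd$distance,
    host_intron = host_idx,
    stringsAsFactors = FALSE
  )
}

#' Compare miR expression across peak-distance categories
#'
#' Per-miR statistic is log2(baseMean) of normalized counts;
#' Kruskal-Wallis omnibus plus Dunn's all-pairs test with BH adjustment.
#' Categories with fewer than 2 members are excluded with a warning.
#'
#' @param assignment From [categorize_mirs()].
#' @param norm_counts Normalized miR count matrix (rownames = miR ids).
#' @return List with `kruskal`, `dunn`, `summary` (per-category n and
#'   median log2 baseMean), and `values` (per-miR table).
#' @export
compare_mir_expression <- function(assignment, norm_counts) {
  bm <- base_mean(norm_counts)
  common <- intersect(assignment$mir_id, names(bm))
  if (length(common) < 3) stop("too few miRs shared with the count matrix")
  df <- data.frame(
    group = assignment$category[match(common, assignment$mir_id)],
    value = log2(bm[common]),
    stringsAsFactors = FALSE
  )
  groups <- split(df$value, df$group)
  small <- lengths(groups) < 2
  if (any(small)) {
    warning("excluding category(ies) with <2 miRs: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2) stop("need >=2 categories with >=2 miRs")
  summ <- do.call(rbind, lapply(names(groups), function(gname) {
    v <- groups[[gname]]
    data.frame(category = gname, n = length(v),
               median_log2_baseMean = median(v), stringsAsFactors = FALSE)
  }))
  list(
    kruskal = kruskal_wallis(groups),
    dunn = dunn_all_pairs(groups, adjust = "BH"),
    summary = summ,
    values = df
  )
}

#' Filter miR-target pairs by anticorrelation and target score
#'
#' Keeps (miR, gene) pairs whose fold changes have strictly opposite signs
#' (both nonzero) and whose target-prediction score is at least
#' `min_score` (default 60, inclusive).
#'
#' @param mir_fc DE table for miRs (columns `feature`, `log2FC`).
#' @param mrna_fc DE table for genes (columns `feature`, `log2FC`).
#' @param target_scores data.frame with `mir_id`, `gene_id`, `score`.
#' @param min_score Minimum score (default 60).
#' @return data.frame of retained pairs with both fold changes and the
#'   score.
#' @export
mir_target_filter <- function(mir_fc, mrna_fc, target_scores,
                              min_score = 60) {
  stopifnot(all(c("mir_id", "gene_id", "score") %in% names(target_scores)))
  mfc <- setNames(mir_fc$log2FC, mir_fc$feature)
  gfc <- setNames(mrna_fc$log2FC, mrna_fc$feature)
  ts <- target_scores
  ts$mir_log2fc <- mfc[ts$mir_id]
  ts$gene_log2fc <- gfc[ts$gene_id]
  keep <- !is.na(ts$mir_log2fc) & !is.na(ts$gene_log2fc) &
    ts$mir_log2fc != 0 & ts$gene_log2fc != 0 &
    sign(ts$mir_log2fc) == -sign(ts$gene_log2fc) &
    ts$score >= min_score
  out <- ts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
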