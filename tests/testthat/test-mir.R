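## miR expression: normalization, manual fold change, DE filters,
## distance categories, target anticorrelation filter.

test_that("median-of-ratios size factors", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  ## doubling one column doubles its factor relative to the other
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)
  ## normalization cancels the scale
  nc <- normalize_counts(m2)
  expect_equal(nc[, 1], nc[, 2])
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("size factors agree with the DESeq2 reference up to rescaling", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  ## odd feature count: the median is a single ratio, so the arithmetic
  ## median of ratios equals DESeq2's exp(median(log ratios)) exactly
  m <- matrix(rnbinom(606, mu = 100, size = 3), ncol = 6)
  m <- m[seq_len(101), ]
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("s", 1:6)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("manual log2 fold change formula and antisymmetry", {
  m <- matrix(c(7, 7, 3, 3), 1,
              dimnames = list("f1", paste0("s", 1:4)))
  cm <- c(s1 = "x", s2 = "x", s3 = "y", s4 = "y")
  expect_equal(unname(manual_log2fc(m, cm, "x", "y")), 1.0)
  expect_equal(unname(manual_log2fc(m, cm, "x", "x")), 0)
  set.seed(2)
  m2 <- matrix(rpois(40, 50), 10, 4,
               dimnames = list(paste0("f", 1:10), names(cm)))
  expect_equal(manual_log2fc(m2, cm, "x", "y"),
               -manual_log2fc(m2, cm, "y", "x"))
  expect_error(manual_log2fc(m, cm, "x", "zzz"), "at least one sample")
})

test_that("DE filter boundaries match hand enumeration on a toy table", {
  tab <- data.frame(
    feature = sprintf("f%02d", 1:20),
    baseMean = c(5, 4.9, 10, 9.9, 100, 100, 100, 100, 5, 5,
                 50, 50, 50, 50, 3, 1000, 6, 7, 8, 9),
    log2FC = c(1.0, 1.5, 1.0, 1.5, 0.9, -0.99, 2, -2, -1.0, 0,
               1.01, -1.01, 0.5, -0.5, 3, 1, 1, -1, 2, -3),
    padj = c(0.05, 0.04, 0.05, 0.04, 0.01, 0.01, 0.051, 0.05, 0.05, 0.01,
             0.2, 0.001, 0.001, 0.001, 0.001, 0.06, NA, 0.05, 0.049, 1),
    stringsAsFactors = FALSE)
  ## hand enumeration, miR rules: |FC| >= 1 & padj <= 0.05 & baseMean >= 5
  keep_mir <- with(tab, abs(log2FC) >= 1 & !is.na(padj) & padj <= 0.05 &
                     baseMean >= 5)
  got <- de_filter(tab, kind = "mir")
  expect_equal(got$feature, tab$feature[keep_mir])
  expect_equal(got$direction, ifelse(got$log2FC > 0, "up", "down"))
  ## boundary row f01 (exactly at all three cutoffs) is retained
  expect_true("f01" %in% got$feature)
  ## gene rules raise the baseMean cutoff to 10
  keep_gene <- with(tab, abs(log2FC) >= 1 & !is.na(padj) & padj <= 0.05 &
                      baseMean >= 10)
  expect_equal(de_filter(tab, kind = "gene")$feature,
               tab$feature[keep_gene])
  expect_false("f01" %in% de_filter(tab, kind = "gene")$feature)
})

test_that("miR categories follow distance precedence and partition", {
  introns <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1000, 20000), c(9000, 29000)), "+")
  S4Vectors::mcols(introns) <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2"), ordinal = 1L,
    host_biotype = c("protein_coding", "noncoding"),
    context = c("protein_coding_intron", "noncoding_intron"))
  peaks <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 5050), "+")
  mirs <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(3000, 8000, 25000, 60000),
                             width = 22), "+")
  names(mirs) <- paste0("m", 1:4)
  res <- categorize_mirs(mirs, peaks, introns)
  ## m1: 1978 nt from the peak, inside a pc intron -> lt2kb by precedence
  expect_equal(res$distance[1], 1978)
  expect_equal(res$category[1], "lt2kb")
  ## m2: 2949 nt away, inside the pc intron -> intron-context category
  expect_equal(res$distance[2], 2949)
  expect_equal(res$category[2], "gt2kb_protein_coding_intron")
  ## m3: far, inside noncoding intron
  expect_equal(res$category[3], "gt2kb_noncoding_intron")
  ## m4: far, intergenic
  expect_equal(res$category[4], "other")
  ## categories partition the set
  expect_equal(sum(table(res$category)), length(mirs))
})

test_that("category assignment matches generator truth labels", {
  cfg <- sim_config(seed = 13)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  mc <- simulate_mir_counts(toy, peaks, cfg)
  cls <- classify_intron_context(toy$introns, toy$annotation)
  assign <- categorize_mirs(mir_granges(toy$mirs), peaks, cls)
  agree <- mean(assign$category ==
                  mc$truth$category[match(assign$mir_id, mc$truth$mir_id)])
  expect_gte(agree, 0.99)
})

test_that("planted near-peak expression effect is detected", {
  cfg <- sim_config(seed = 13)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  mc <- simulate_mir_counts(toy, peaks, cfg)
  cls <- classify_intron_context(toy$introns, toy$annotation)
  assign <- categorize_mirs(mir_granges(toy$mirs), peaks, cls)
  cmp <- compare_mir_expression(assign, normalize_counts(mc$counts))
  meds <- setNames(cmp$summary$median_log2_baseMean, cmp$summary$category)
  expect_equal(names(which.max(meds)), "lt2kb")
  expect_lt(cmp$kruskal$p.value, 1e-6)
})

test_that("single-member categories are excluded with a warning", {
  counts <- matrix(rpois(40, 100), 10, 4,
                   dimnames = list(paste0("m", 1:10), paste0("s", 1:4)))
  assign <- data.frame(
    mir_id = paste0("m", 1:10),
    category = c(rep("lt2kb", 5), rep("other", 4), "gt2kb_noncoding_intron"),
    stringsAsFactors = FALSE)
  expect_warning(compare_mir_expression(assign, counts),
                 "gt2kb_noncoding_intron")
})

test_that("null miR category comparison is calm on one seeded run", {
  cfg <- sim_config(seed = 17,
                    mir_model = list(near_peak_effect = 0,
                                     noncoding_effect = 0, frac_de = 0))
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  mc <- simulate_mir_counts(toy, peaks, cfg)
  groups <- split(log2(base_mean(normalize_counts(mc$counts)) + 0.5),
                  mc$truth$category)
  groups <- groups[lengths(groups) >= 2]
  expect_gt(kruskal_wallis(groups)$p.value, 0.05)
})

test_that("negative binomial approaches Poisson as dispersion vanishes", {
  cfg <- sim_config(seed = 19,
                    mir_model = list(dispersion = 1e-6, near_peak_effect = 0,
                                     noncoding_effect = 0, frac_de = 0,
                                     n_samples = 50L))
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  mc <- simulate_mir_counts(toy, peaks, cfg)
  vm <- apply(mc$counts, 1, var) / rowMeans(mc$counts)
  expect_lt(abs(median(vm) - 1), 0.1)
})

test_that("target filter keeps anticorrelated pairs above the score cutoff", {
  mir_fc <- data.frame(feature = c("mA", "mB", "mC", "mD"),
                       log2FC = c(1.2, 1.2, -1, 0))
  gene_fc <- data.frame(feature = c("gA", "gB", "gC", "gD"),
                        log2FC = c(-0.8, 0.8, 1, -2))
  scores <- data.frame(
    mir_id = c("mA", "mB", "mC", "mC", "mD"),
    gene_id = c("gA", "gB", "gC", "gC", "gD"),
    score = c(70, 95, 60, 59, 80))
  got <- mir_target_filter(mir_fc, gene_fc, scores)
  ## (mA,gA,70) kept; (mB,gB) same sign dropped; (mC,gC,60) kept at the
  ## inclusive boundary, the 59 duplicate dropped; zero-FC miR dropped
  expect_equal(nrow(got), 2)
  expect_setequal(got$mir_id, c("mA", "mC"))
  expect_equal(got$score[got$mir_id == "mC"], 60)
})

test_that("DE table pipeline finds planted differential miRs", {
  cfg <- sim_config(seed = 23)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  mc <- simulate_mir_counts(toy, peaks, cfg)
  det <- de_table(mc$counts, mc$condition_map, "pert", "ctrl")
  de <- de_filter(det, kind = "mir")
  ## planted-DE miRs dominate the detections
  truth_de <- mc$truth$mir_id[mc$truth$de]
  expect_gt(nrow(de), 0)
  expect_gt(mean(de$feature %in% truth_de), 0.8)
})
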