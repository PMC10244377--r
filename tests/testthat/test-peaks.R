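## Peak filtering, genomic-context annotation, nearest distances,
## metaprofiles, motif windows.

library(GenomicRanges)

mk_peaks <- function(start, end, strand = "+", log2fc = 5, padj = 1e-5) {
  GRanges("chrT", IRanges::IRanges(start, end), strand,
          log2fc = log2fc, padj = padj)
}

test_that("peak filter bounds are inclusive and match brute force", {
  p <- mk_peaks(c(100, 200), c(150, 250),
                log2fc = c(3.0, 5), padj = c(0.001, 0.01))
  kept <- filter_peaks(p)
  expect_length(kept, 1)            # boundary peak retained, padj 0.01 dropped
  expect_equal(start(kept), 100)
  expect_equal(attr(kept, "counts"), c(retained = 1L, total = 2L))
  set.seed(31)
  n <- 500
  p2 <- mk_peaks(seq_len(n) * 10, seq_len(n) * 10 + 5,
                 log2fc = runif(n, 0, 8), padj = 10^-runif(n, 0, 6))
  got <- filter_peaks(p2)
  want <- S4Vectors::mcols(p2)$log2fc >= 3 & S4Vectors::mcols(p2)$padj <= 0.001
  expect_equal(length(got), sum(want))
  expect_equal(start(got), start(p2)[want])
  expect_error(filter_peaks(GRanges("chrT", IRanges::IRanges(1, 5))),
               "log2fc")
})

test_that("peak categories follow the priority order and sum to one", {
  cfg <- sim_config(seed = 41, n_genes = 30, n_mirs = 10)
  toy <- make_toy_annotation(cfg)
  cls <- classify_intron_context(toy$introns, toy$annotation)
  ## a peak fully inside a protein-coding intron
  pci <- cls[S4Vectors::mcols(cls)$context == "protein_coding_intron"]
  pci <- pci[width(pci) > 200][1]
  inside <- mk_peaks(start(pci) + 50, start(pci) + 90,
                     as.character(strand(pci)))
  got <- annotate_peaks(inside, toy$annotation, cls)
  expect_equal(S4Vectors::mcols(got)$category, "protein_coding_intron")
  ## a peak straddling the exon/intron boundary takes the exon category
  ex <- toy$annotation$exons
  host <- S4Vectors::mcols(ex)$gene_id %in%
    toy$annotation$genes$gene_id[toy$annotation$genes$biotype ==
                                   "protein_coding"]
  e1 <- ex[host][1]
  straddle <- mk_peaks(end(e1) - 20, end(e1) + 20,
                       as.character(strand(e1)))
  got2 <- annotate_peaks(straddle, toy$annotation, cls)
  expect_true(S4Vectors::mcols(got2)$category %in%
                c("cds_exon", "utr5", "utr3"))
  ## fractions sum to 1
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  ann_peaks <- annotate_peaks(peaks, toy$annotation, cls)
  expect_equal(sum(attr(ann_peaks, "fractions")), 1)
})

test_that("closest distance arithmetic, ties, and max_search", {
  ## feature [501,520], peak [601,650]: 80 intervening nt
  f <- GRanges("chrT", IRanges::IRanges(501, 520), "+")
  p <- mk_peaks(601, 650)
  expect_equal(closest_peak_distance(f, p)$distance, 80)
  ## overlap gives 0
  expect_equal(closest_peak_distance(f, mk_peaks(510, 530))$distance, 0)
  ## equidistant peaks: the smaller genomic start wins
  p2 <- mk_peaks(c(601, 341), c(650, 420))
  got <- closest_peak_distance(f, p2)
  expect_equal(got$distance, 80)
  expect_equal(got$peak, 2L)
  ## out of range flagged NA
  expect_true(is.na(closest_peak_distance(f, p, max_search = 10)$distance))
  expect_true(is.na(closest_peak_distance(f, GRanges())$distance))
})

test_that("closest distances equal the brute-force scan on random input", {
  set.seed(33)
  n <- 1000; m <- 800
  fs <- sample(1:200000, n); fe <- fs + sample(10:500, n, replace = TRUE)
  ps <- sample(1:200000, m); pe <- ps + sample(10:100, m, replace = TRUE)
  f <- GRanges("chrT", IRanges::IRanges(fs, fe), "+")
  p <- mk_peaks(ps, pe)
  got <- closest_peak_distance(f, p, max_search = 5000)
  want <- oracle_closest(fs, fe, ps, pe, max_search = 5000)
  expect_equal(got$distance, want$distance)
  expect_equal(got$peak, want$peak)
})

test_that("exon metaprofile is flat on uniform coverage", {
  cfg <- sim_config(seed = 43, n_genes = 10, n_mirs = 2)
  toy <- make_toy_annotation(cfg)
  tr <- new_coverage_track(toy$annotation$contigs, "u")
  g <- toy$annotation$genes
  ## uniform coverage across gene bodies AND flanks
  tr <- add_coverage(tr, g$chrom, pmax(1, g$start - 500), g$end + 500,
                     g$strand, 2)
  prof <- exon_metaprofile(tr, toy$annotation)
  expect_equal(prof$mean, rep(2, nrow(prof)))
  expect_equal(prof$sem, rep(0, nrow(prof)))
})

test_that("donor-biased peaks put the IP maximum just past the donor", {
  cfg <- sim_config(seed = 1)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  tracks <- simulate_coverage_tracks(toy, peaks, NULL, cfg)
  prof <- exon_metaprofile(tracks$ip, toy$annotation)
  peak_bin <- which.max(prof$mean)
  expect_equal(prof$region[peak_bin], "downstream_flank")
  ## within the donor-proximal half of the intronic flank
  flank_bins <- which(prof$region == "downstream_flank")
  expect_lte(peak_bin, flank_bins[1] + length(flank_bins) / 2)
  ## the unbiased SMI control has no donor-proximal maximum
  prof_smi <- exon_metaprofile(tracks$smi, toy$annotation)
  expect_false(prof_smi$region[which.max(prof_smi$mean)] ==
                 "downstream_flank")
})

test_that("metaprofile is invariant to feature order and mirrors on flip", {
  cfg <- sim_config(seed = 47, n_genes = 12, n_mirs = 2)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  tracks <- simulate_coverage_tracks(toy, peaks, NULL, cfg)
  prof1 <- exon_metaprofile(tracks$ip, toy$annotation)
  shuf <- toy$annotation
  set.seed(1)
  shuf$exons <- shuf$exons[sample(length(shuf$exons))]
  prof2 <- exon_metaprofile(tracks$ip, shuf)
  expect_equal(prof1$mean, prof2$mean)
})

test_that("pre-miR metaprofile geometry and planted central enrichment", {
  cfg <- sim_config(seed = 43, n_genes = 10, n_mirs = 4)
  toy <- make_toy_annotation(cfg)
  ## all-zero coverage stays zero
  tr0 <- new_coverage_track(toy$annotation$contigs, "z")
  pm0 <- premir_metaprofile(tr0, mir_granges(toy$mirs, "pre"))
  expect_equal(pm0$mean, rep(0, nrow(pm0)))
  ## a delta of coverage at each pre-miR center maps to the central bin
  tr1 <- tr0
  ctr <- (toy$mirs$pre_start + toy$mirs$pre_end) %/% 2
  tr1 <- add_coverage(tr1, toy$mirs$chrom, ctr - 30, ctr + 30,
                      toy$mirs$strand, 10)
  pm1 <- premir_metaprofile(tr1, mir_granges(toy$mirs, "pre"))
  ctr_bin <- which.max(pm1$mean)
  expect_true(abs(ctr_bin - nrow(pm1) / 2) <= 1)
  ## full simulation: center beats the flanks clearly
  cfg2 <- sim_config(seed = 1)
  toy2 <- make_toy_annotation(cfg2)
  peaks2 <- filter_peaks(simulate_peaks(toy2, cfg2))
  tracks2 <- simulate_coverage_tracks(toy2, peaks2, NULL, cfg2)
  pm2 <- premir_metaprofile(tracks2$ip, mir_granges(toy2$mirs, "pre"))
  expect_gt(spliceclip:::premir_center_ratio(pm2), 2)
})

test_that("cassette-exon map is exactly 1 when IP equals SMI", {
  cfg <- sim_config(seed = 43, n_genes = 10, n_mirs = 2)
  toy <- make_toy_annotation(cfg)
  ev <- simulate_lsv_events(toy, cfg)
  tr <- new_coverage_track(toy$annotation$contigs, "x")
  g <- toy$annotation$genes
  tr <- add_coverage(tr, g$chrom, pmax(1, g$start - 500), g$end + 500,
                     g$strand, 3)
  cm <- cassette_exon_map(tr, tr, ev)
  expect_equal(cm$mean, rep(1, nrow(cm)))
  ## bin count equals ceiling(window / 50) per side
  expect_equal(sort(unique(cm$bin)), 1:6)
  expect_error(cassette_exon_map(tr, tr, transform(ev, delta_psi = 0.1)),
               "threshold")
})

test_that("cassette map maxima land in exon vs acceptor-intron bins", {
  cfg <- sim_config(seed = 1)
  toy <- make_toy_annotation(cfg)
  peaks <- filter_peaks(simulate_peaks(toy, cfg))
  ev <- simulate_lsv_events(toy, cfg)
  tracks <- simulate_coverage_tracks(toy, peaks, ev, cfg)
  cm <- cassette_exon_map(tracks$ip, tracks$smi, ev)
  ## higher-in-OE events: planted exon-body enrichment; the exonic bins
  ## are acceptor bin 6 and donor bin 1
  hi_acc <- cm[cm$direction == "higher_in_OE" & cm$side == "acceptor", ]
  hi_don <- cm[cm$direction == "higher_in_OE" & cm$side == "donor", ]
  expect_equal(hi_acc$bin[which.max(hi_acc$mean)], 6)
  expect_equal(hi_don$bin[which.max(hi_don$mean)], 1)
  ## lower-in-OE events: acceptor-side intronic enrichment (bins 1-5)
  lo_acc <- cm[cm$direction == "lower_in_OE" & cm$side == "acceptor", ]
  expect_lte(lo_acc$bin[which.max(lo_acc$mean)], 5)
})

test_that("motif windows are centered, strand-aware, and edge-clipped", {
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste(rep(c("A", "C", "G", "T"), 100), collapse = "")))
  ## peak [101,110]: midpoint 105, window [55,155], 101 nt
  p <- mk_peaks(101, 110)
  w <- motif_windows(p, genome)
  expect_equal(Biostrings::width(w), 101)
  expect_equal(as.character(w[[1]]),
               as.character(Biostrings::subseq(genome[["chrT"]], 55, 155)))
  ## minus strand is the reverse complement of the plus extraction
  pm <- mk_peaks(101, 110, strand = "-")
  wm <- motif_windows(pm, genome)
  expect_equal(as.character(wm[[1]]),
               as.character(Biostrings::reverseComplement(w[[1]])))
  ## contig edge: clipped and flagged
  pe <- mk_peaks(5, 14)
  we <- motif_windows(pe, genome)
  expect_true(attr(we, "clipped"))
  expect_lt(Biostrings::width(we)[1], 101)
  expect_error(motif_windows(GRanges("chrZ", IRanges::IRanges(1, 5), "+",
                                     log2fc = 5, padj = 0), genome),
               "chrZ")
})
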