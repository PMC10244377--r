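## Annotation model: GTF parsing, intron-set construction, splice sites,
## host-biotype classification.

write_mini_gtf <- function(path) {
  lines <- c(
    paste("chrT", "test", "gene", 1, 300, ".", "+", ".",
          'gene_id "g1"; gene_biotype "protein_coding";', sep = "\t"),
    paste("chrT", "test", "transcript", 1, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chrT", "test", "exon", 1, 100, ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chrT", "test", "exon", 201, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.t1"; gene_biotype "protein_coding";',
          sep = "\t")
  )
  writeLines(lines, path)
  path
}

test_that("GTF import keeps 1-based closed exon coordinates", {
  gtf <- write_mini_gtf(tempfile(fileext = ".gtf"))
  ann <- load_annotation(gtf)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$transcripts), 1)
  ex <- ann$exons
  expect_equal(start(ex), c(1, 201))
  expect_equal(end(ex), c(100, 300))
  expect_equal(ann$genes$biotype, "protein_coding")
})

test_that("malformed GTF lines fail with a line number", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "t", "exon", 100, 50, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")
  ), bad)
  expect_error(load_annotation(bad), "line 1")

  short <- tempfile(fileext = ".gtf")
  writeLines("chrT\tonly\tthree", short)
  expect_error(load_annotation(short), "9 tab-separated")
})

test_that("toy annotation round-trips through GTF identically", {
  toy <- make_toy_annotation(sim_config(seed = 5, n_genes = 6, n_mirs = 4))
  path <- tempfile(fileext = ".gtf")
  write_annotation(toy$annotation, path)
  back <- load_annotation(path)
  expect_equal(back$genes, toy$annotation$genes)
  expect_equal(back$transcripts, toy$annotation$transcripts)
  expect_equal(start(back$exons), start(toy$annotation$exons))
  expect_equal(end(back$exons), end(toy$annotation$exons))
  expect_equal(as.character(strand(back$exons)),
               as.character(strand(toy$annotation$exons)))
  ## second round trip is byte-identical
  path2 <- tempfile(fileext = ".gtf")
  write_annotation(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("single-transcript intron set has the expected gaps and ordinals", {
  ## hand-built gene: exons [1,100],[201,300],[401,500] on + strand
  exons <- GRanges("chrT", IRanges(c(1, 201, 401), c(100, 300, 500)), "+")
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    gene_id = "g1", transcript_id = "g1.t1", biotype = "protein_coding")
  ann <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                       start = 1L, end = 500L, biotype = "protein_coding",
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "g1.t1", gene_id = "g1",
                             chrom = "chrT", strand = "+", start = 1L,
                             end = 500L, stringsAsFactors = FALSE),
    exons = exons, cds = GRanges(), contigs = c(chrT = 1000L)),
    class = "GenomeAnnotation")
  introns <- build_unique_intron_set(ann)
  expect_equal(start(introns), c(101, 301))
  expect_equal(end(introns), c(200, 400))
  expect_equal(S4Vectors::mcols(introns)$ordinal, c(1L, 2L))
  ## minus strand: ordinals count from the 3' end of the genome axis
  strand(ann$exons) <- "-"
  ann$genes$strand <- "-"
  ann$transcripts$strand <- "-"
  introns_m <- build_unique_intron_set(ann)
  expect_equal(S4Vectors::mcols(introns_m)$ordinal, c(2L, 1L))
})

test_that("redundant introns deduplicate and exon conflicts drop introns", {
  ## two isoforms share intron [101,200]; isoform 2 has an exon inside
  ## isoform 1's intron [301,400], so that intron is dropped entirely
  mk_ex <- function(starts, ends, tx) {
    g <- GRanges("chrT", IRanges(starts, ends), "+")
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      gene_id = "g1", transcript_id = tx, biotype = "protein_coding")
    g
  }
  exons <- c(mk_ex(c(1, 201, 401), c(100, 300, 500), "g1.t1"),
             mk_ex(c(1, 201, 330, 401), c(100, 300, 360, 500), "g1.t2"))
  ann <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                       start = 1L, end = 500L, biotype = "protein_coding",
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = c("g1.t1", "g1.t2"),
                             gene_id = "g1", chrom = "chrT", strand = "+",
                             start = 1L, end = 500L,
                             stringsAsFactors = FALSE),
    exons = exons, cds = GRanges(), contigs = c(chrT = 1000L)),
    class = "GenomeAnnotation")
  introns <- build_unique_intron_set(ann)
  df <- intron_set_as_df(introns)
  expect_true(any(df$start == 101 & df$end == 200))
  expect_false(any(df$start == 301 & df$end == 400))
  ## t2's sub-introns [301,329] and [361,400] survive instead
  expect_true(any(df$start == 301 & df$end == 329))
  expect_true(any(df$start == 361 & df$end == 400))
  ## single-exon genes: no introns, no error
  single <- exons[1]
  ann2 <- ann
  ann2$exons <- single
  expect_length(build_unique_intron_set(ann2), 0)
})

test_that("intron set equals the brute-force oracle on random annotations", {
  for (seed in 1:60) {
    ann <- random_annotation(seed, n_genes = 6)
    got <- intron_set_as_df(build_unique_intron_set(ann))
    want <- oracle_intron_set(ann)
    expect_equal(got[, c("gene_id", "start", "end", "ordinal", "strand")],
                 want, info = paste("seed", seed))
  }
})

test_that("introns of one gene never overlap each other (property)", {
  violations <- 0L
  for (seed in 1:500) {
    ann <- random_annotation(seed + 1000, n_genes = 3)
    introns <- build_unique_intron_set(ann)
    if (!length(introns)) next
    df <- intron_set_as_df(introns)
    exdf <- data.frame(gene_id = S4Vectors::mcols(ann$exons)$gene_id,
                       start = start(ann$exons), end = end(ann$exons))
    for (gid in unique(df$gene_id)) {
      d <- df[df$gene_id == gid, ]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
        violations <- violations + 1L
      }
      e <- exdf[exdf$gene_id == gid, ]
      for (k in seq_len(nrow(d))) {
        if (any(d$start[k] <= e$end & d$end[k] >= e$start)) {
          violations <- violations + 1L
        }
      }
    }
  }
  expect_equal(violations, 0L)
})

test_that("splice sites follow strand orientation", {
  gr <- GRanges("chrT", IRanges(c(101, 101), c(200, 200)), c("+", "-"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = c("a", "b"),
                                               ordinal = c(1L, 1L))
  ss <- splice_sites(gr)
  expect_equal(ss$donor, c(101, 200))
  expect_equal(ss$acceptor, c(200, 101))
  ## donor-acceptor span equals intron width across a generated fixture
  toy <- make_toy_annotation(sim_config(seed = 3, n_genes = 20, n_mirs = 5))
  ss2 <- splice_sites(toy$introns)
  expect_equal(abs(ss2$donor - ss2$acceptor) + 1, width(toy$introns))
  ## undefined strand is rejected
  expect_error(splice_sites(GRanges("chrT", IRanges(1, 5), "*")), "strand")
})

test_that("intron context follows the host gene biotype", {
  cfg <- sim_config(seed = 2, n_genes = 40, n_mirs = 5, frac_noncoding = 0.3)
  toy <- make_toy_annotation(cfg)
  cls <- classify_intron_context(toy$introns, toy$annotation)
  ctx <- S4Vectors::mcols(cls)$context
  bt <- toy$annotation$genes$biotype[
    match(S4Vectors::mcols(cls)$gene_id, toy$annotation$genes$gene_id)]
  expect_equal(ctx == "protein_coding_intron", bt == "protein_coding")
  ## bookkeeping: per-class counts equal what the gene table implies
  expect_equal(unname(as.vector(attr(cls, "counts"))),
               unname(as.vector(table(ifelse(bt == "protein_coding",
                                             "protein_coding_intron",
                                             "noncoding_intron")))))
  ## unknown host gene errors
  bad <- cls
  S4Vectors::mcols(bad)$gene_id[1] <- "nope"
  expect_error(classify_intron_context(bad, toy$annotation), "unknown host")
})
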