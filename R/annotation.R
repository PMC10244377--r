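## Annotation model: GTF parsing, unique non-overlapping intron sets,
## splice-site coordinates, intron host-biotype classification.

#' Load a gene annotation from GTF
#'
#' Reads a GTF file (Ensembl/GENCODE dialect) and builds a
#' `GenomeAnnotation` object: a gene table, a transcript table, exon and CDS
#' ranges, and contig lengths. Coordinates stay 1-based closed, the native
#' GTF convention, held in `GRanges`.
#'
#' Biotype is taken from the `gene_biotype` attribute, falling back to
#' `gene_type`, and defaults to `"noncoding"` when neither is present. For
#' downstream classification only the binary distinction protein-coding
#' versus noncoding is used.
#'
#' @param path Path to a GTF file with `gene`, `transcript` and `exon`
#'   features (optionally `CDS`).
#' @param contig_lengths Optional named integer vector of contig lengths;
#'   when absent, lengths are taken from the GTF header or inferred as the
#'   maximum annotated end per contig.
#' @return A `GenomeAnnotation` object (S3 list) with elements `genes`
#'   (data.frame), `transcripts` (data.frame), `exons` (`GRanges` with
#'   `gene_id`, `transcript_id`), `cds` (`GRanges`, possibly empty) and
#'   `contigs` (named integer).
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "spliceclip")
#' if (nzchar(gtf)) ann <- load_annotation(gtf)
#' @export
load_annotation <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- mcols(gr)
  if (is.null(md$type) || is.null(md$gene_id)) {
    stop("GTF must carry 'type' and 'gene_id' attributes: ", path)
  }
  biotype <- md$gene_biotype
  if (is.null(biotype)) biotype <- md$gene_type
  if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))
  biotype[is.na(biotype)] <- "noncoding"
  md$biotype <- biotype
  mcols(gr) <- md

  is_gene <- md$type == "gene"
  is_tx   <- md$type == "transcript"
  is_exon <- md$type == "exon"
  is_cds  <- md$type == "CDS"
  if (!any(is_exon)) stop("GTF contains no exon features: ", path)

  exons <- gr[is_exon]
  mcols(exons) <- DataFrame(
    gene_id = md$gene_id[is_exon],
    transcript_id = md$transcript_id[is_exon],
    biotype = md$biotype[is_exon]
  )
  cds <- gr[is_cds]
  if (length(cds)) {
    mcols(cds) <- DataFrame(
      gene_id = md$gene_id[is_cds],
      transcript_id = md$transcript_id[is_cds]
    )
  } else {
    mcols(cds) <- NULL
  }

  ## gene table: explicit gene features, else derived from exon spans
  if (any(is_gene)) {
    gg <- gr[is_gene]
    genes <- data.frame(
      gene_id = mcols(gg)$gene_id,
      chrom = as.character(seqnames(gg)),
      strand = as.character(strand(gg)),
      start = start(gg), end = end(gg),
      biotype = mcols(gg)$biotype,
      stringsAsFactors = FALSE
    )
  } else {
    sp <- split(exons, mcols(exons)$gene_id)
    rg <- unlist(range(sp))
    genes <- data.frame(
      gene_id = names(rg),
      chrom = as.character(seqnames(rg)),
      strand = as.character(strand(rg)),
      start = start(rg), end = end(rg),
      biotype = vapply(split(mcols(exons)$biotype, mcols(exons)$gene_id),
                       `[`, character(1), 1),
      stringsAsFactors = FALSE
    )
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  if (any(is_tx)) {
    tt <- gr[is_tx]
    transcripts <- data.frame(
      transcript_id = mcols(tt)$transcript_id,
      gene_id = mcols(tt)$gene_id,
      chrom = as.character(seqnames(tt)),
      strand = as.character(strand(tt)),
      start = start(tt), end = end(tt),
      stringsAsFactors = FALSE
    )
  } else {
    sp <- split(exons, mcols(exons)$transcript_id)
    rg <- unlist(range(sp))
    transcripts <- data.frame(
      transcript_id = names(rg),
      gene_id = vapply(split(mcols(exons)$gene_id,
                             mcols(exons)$transcript_id),
                       `[`, character(1), 1),
      chrom = as.character(seqnames(rg)),
      strand = as.character(strand(rg)),
      start = start(rg), end = end(rg),
      stringsAsFactors = FALSE
    )
  }
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
  rownames(transcripts) <- NULL

  contigs <- contig_lengths
  if (is.null(contigs)) {
    sl <- seqlengths(gr)
    if (all(is.na(sl))) {
      sl <- tapply(end(gr), as.character(seqnames(gr)), max)
      sl <- setNames(as.integer(sl), names(sl))
    }
    contigs <- sl
  }

  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         cds = cds, contigs = contigs),
    class = "GenomeAnnotation"
  )
  validate_annotation(ann)
  ann
}

## cheap line-level sanity pass so malformed input fails with a line number
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    }
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    }
    if (e < s) {
      stop("invalid GTF line ", i, ": end (", e, ") < start (", s, ")")
    }
  }
  invisible(TRUE)
}

validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  ex <- ann$exons
  if (!all(as.character(strand(ex)) %in% c("+", "-"))) {
    stop("exons with undefined strand are not supported")
  }
  ## exons must lie within their gene span
  gidx <- match(mcols(ex)$gene_id, ann$genes$gene_id)
  if (anyNA(gidx)) stop("exon with unknown gene_id")
  bad <- start(ex) < ann$genes$start[gidx] | end(ex) > ann$genes$end[gidx]
  if (any(bad)) {
    stop("validation error: ", sum(bad), " exon(s) outside their gene span (",
         paste(head(unique(mcols(ex)$gene_id[bad]), 3), collapse = ", "), ")")
  }
  ## exons within one transcript must not overlap each other
  sp <- split(ex, mcols(ex)$transcript_id)
  ok <- vapply(sp, function(g) {
    g <- sort(g)
    length(g) < 2 || all(start(g)[-1] > end(g)[-length(g)])
  }, logical(1))
  if (!all(ok)) {
    stop("validation error: overlapping exons within transcript(s): ",
         paste(head(names(sp)[!ok], 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits gene, transcript, exon and CDS features with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes. Round-trips with
#' [load_annotation()].
#'
#' @param ann A `GenomeAnnotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  g <- ann$genes
  gene_gr <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand,
                     type = "gene", gene_id = g$gene_id,
                     transcript_id = NA_character_, gene_biotype = g$biotype)
  t <- ann$transcripts
  bt <- g$biotype[match(t$gene_id, g$gene_id)]
  tx_gr <- GRanges(t$chrom, IRanges(t$start, t$end), strand = t$strand,
                   type = "transcript", gene_id = t$gene_id,
                   transcript_id = t$transcript_id, gene_biotype = bt)
  ex <- ann$exons
  ex_gr <- granges(ex)
  mcols(ex_gr) <- DataFrame(
    type = "exon", gene_id = mcols(ex)$gene_id,
    transcript_id = mcols(ex)$transcript_id,
    gene_biotype = g$biotype[match(mcols(ex)$gene_id, g$gene_id)]
  )
  all_gr <- c(gene_gr, tx_gr, ex_gr)
  if (length(ann$cds)) {
    cd <- ann$cds
    cds_gr <- granges(cd)
    mcols(cds_gr) <- DataFrame(
      type = "CDS", gene_id = mcols(cd)$gene_id,
      transcript_id = mcols(cd)$transcript_id,
      gene_biotype = g$biotype[match(mcols(cd)$gene_id, g$gene_id)]
    )
    all_gr <- c(all_gr, cds_gr)
  }
  ## rtracklayer expects CDS features to carry a phase
  mcols(all_gr)$phase <- ifelse(mcols(all_gr)$type == "CDS", 0L, NA_integer_)
  all_gr <- sort(all_gr, ignore.strand = TRUE)
  sl <- ann$contigs[intersect(names(ann$contigs),
                              as.character(seqlevels(all_gr)))]
  seqlengths(all_gr)[names(sl)] <- sl
  rtracklayer::export(all_gr, path, format = "gtf")
  invisible(path)
}

#' Build the unique non-overlapping intron set of an annotation
#'
#' For each gene, candidate introns are the gaps between consecutive exons
#' of each transcript. Candidates identical across transcripts are emitted
#' once; any candidate overlapping an exon of any transcript of the same
#' gene is dropped entirely; among remaining overlapping candidates the one
#' from the lexicographically smallest transcript id is kept. Ordinal
#' indices are assigned 1-based from the 5' end of the gene (strand-aware).
#' Single-exon genes contribute no introns.
#'
#' @param ann A `GenomeAnnotation` from [load_annotation()] or
#'   [make_toy_annotation()].
#' @return A sorted `GRanges` with metadata columns `gene_id`, `ordinal`
#'   (integer, 5' to 3'), `host_biotype`, and `source_tx` (the transcript
#'   the kept instance came from).
#' @export
build_unique_intron_set <- function(ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  ex <- ann$exons
  ## flat vectors once; per-gene work stays in base R for speed
  ex_gene <- mcols(ex)$gene_id
  ex_tx <- mcols(ex)$transcript_id
  ex_start <- start(ex); ex_end <- end(ex)
  out <- vector("list", nrow(ann$genes))
  for (gi in seq_len(nrow(ann$genes))) {
    gid <- ann$genes$gene_id[gi]
    sel <- which(ex_gene == gid)
    if (length(sel) < 2) next
    gs <- ex_start[sel]; ge <- ex_end[sel]; gt <- ex_tx[sel]
    cs <- ce <- integer(0); ct <- character(0)
    for (tx in sort(unique(gt))) {
      tsel <- gt == tx
      if (sum(tsel) < 2) next
      o <- order(gs[tsel])
      ts <- gs[tsel][o]; te <- ge[tsel][o]
      istart <- te[-length(te)] + 1L
      iend <- ts[-1] - 1L
      keep <- iend >= istart
      cs <- c(cs, istart[keep]); ce <- c(ce, iend[keep])
      ct <- c(ct, rep(tx, sum(keep)))
    }
    if (!length(cs)) next
    ## drop candidates hitting any exon of the same gene (any transcript)
    ok <- !vapply(seq_along(cs),
                  function(k) any(cs[k] <= ge & ce[k] >= gs),
                  logical(1))
    cs <- cs[ok]; ce <- ce[ok]; ct <- ct[ok]
    if (!length(cs)) next
    ## de-duplicate identical candidates, keeping smallest transcript id
    o <- order(cs, ce, ct)
    cs <- cs[o]; ce <- ce[o]; ct <- ct[o]
    dup <- duplicated(paste(cs, ce))
    cs <- cs[!dup]; ce <- ce[!dup]; ct <- ct[!dup]
    ## among remaining overlapping candidates keep the one from the
    ## smallest transcript id, greedily
    o <- order(ct, cs)
    cs <- cs[o]; ce <- ce[o]; ct <- ct[o]
    ks <- ke <- integer(0); kt <- character(0)
    for (k in seq_along(cs)) {
      if (!length(ks) || !any(cs[k] <= ke & ce[k] >= ks)) {
        ks <- c(ks, cs[k]); ke <- c(ke, ce[k]); kt <- c(kt, ct[k])
      }
    }
    o <- order(ks)
    ks <- ks[o]; ke <- ke[o]; kt <- kt[o]
    n <- length(ks)
    ord <- if (ann$genes$strand[gi] == "+") seq_len(n) else rev(seq_len(n))
    out[[gi]] <- data.frame(
      start = ks, end = ke, source_tx = kt, gene_id = gid,
      ordinal = as.integer(ord),
      strand = ann$genes$strand[gi], chrom = ann$genes$chrom[gi],
      host_biotype = ann$genes$biotype[gi], stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    res <- GRanges()
    mcols(res) <- DataFrame(source_tx = character(), gene_id = character(),
                            ordinal = integer(), host_biotype = character())
    return(res)
  }
  df <- do.call(rbind, out)
  res <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(res) <- DataFrame(source_tx = df$source_tx, gene_id = df$gene_id,
                          ordinal = df$ordinal,
                          host_biotype = df$host_biotype)
  sl <- ann$contigs[intersect(names(ann$contigs), seqlevels(res))]
  if (length(sl)) seqlengths(res)[names(sl)] <- sl
  sort(res, ignore.strand = TRUE)
}

#' Donor and acceptor splice-site coordinates of introns
#'
#' The donor (5' splice site) is the intron boundary adjacent to the
#' upstream exon in transcript orientation; the acceptor (3' splice site)
#' the boundary adjacent to the downstream exon. Coordinates are the
#' genomic positions (1-based) of the first and last intronic base in
#' transcript orientation: on the + strand donor = start and acceptor =
#' end; on the - strand donor = end and acceptor = start.
#'
#' @param introns `GRanges` of introns (from [build_unique_intron_set()]).
#' @return data.frame with columns `gene_id`, `ordinal`, `donor`,
#'   `acceptor` (genomic coordinates, nt).
#' @export
splice_sites <- function(introns) {
  stopifnot(is(introns, "GRanges"))
  st <- as.character(strand(introns))
  if (!all(st %in% c("+", "-"))) stop("introns must have a defined strand")
  plus <- st == "+"
  data.frame(
    gene_id = if (!is.null(mcols(introns)$gene_id)) mcols(introns)$gene_id
              else NA_character_,
    ordinal = if (!is.null(mcols(introns)$ordinal)) mcols(introns)$ordinal
              else NA_integer_,
    donor = ifelse(plus, start(introns), end(introns)),
    acceptor = ifelse(plus, end(introns), start(introns)),
    stringsAsFactors = FALSE
  )
}

#' Classify introns by host-gene biotype
#'
#' Labels each intron `protein_coding_intron` or `noncoding_intron`
#' according to its host gene's biotype class.
#'
#' @param introns `GRanges` from [build_unique_intron_set()].
#' @param ann The `GenomeAnnotation` the introns came from.
#' @return The input `GRanges` with an added `context` metadata column;
#'   class counts are attached as attribute `"counts"`.
#' @export
classify_intron_context <- function(introns, ann) {
  stopifnot(is(introns, "GRanges"), inherits(ann, "GenomeAnnotation"))
  gidx <- match(mcols(introns)$gene_id, ann$genes$gene_id)
  if (anyNA(gidx)) {
    stop("intron(s) with unknown host gene: ",
         paste(head(unique(mcols(introns)$gene_id[is.na(gidx)]), 3),
               collapse = ", "))
  }
  bt <- ann$genes$biotype[gidx]
  ctx <- ifelse(bt == "protein_coding", "protein_coding_intron",
                "noncoding_intron")
  mcols(introns)$context <- ctx
  attr(introns, "counts") <- table(ctx)
  introns
}

#' Write an intron set as BED6
#'
#' Name field is `gene_id|ordinal`, score 0. rtracklayer converts to BED's
#' 0-based half-open convention on export.
#'
#' @param introns `GRanges` from [build_unique_intron_set()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  gr <- granges(introns)
  mcols(gr)$name <- paste0(mcols(introns)$gene_id, "|",
                           mcols(introns)$ordinal)
  mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
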