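## Synthetic-data generator. Produces every input the pipeline consumes
## with planted, machine-readable effects: a toy multi-exon annotation
## hosting intronic miRs, donor-biased CLIP peaks, junction counts whose
## splicing efficiency depends on peak count and genotype dose, miR counts
## with peak-distance-dependent expression, gene lists with constructed
## overlap, and AFM force-curve grids with group-specific moduli.

#' Simulation configuration
#'
#' Assembles the generator configuration with the package's default study
#' conditions. Every generator derives its randomness from `seed` plus a
#' fixed per-generator offset, so a config fully determines all outputs.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides for any top-level element (partial lists are
#'   merged element-wise).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    contig = "chrT",
    contig_length = NULL,            # auto from layout when NULL
    n_genes = 150,
    exons_per_gene = c(2L, 8L),
    exon_length = c(100L, 300L),
    intron_length = c(500L, 8000L),
    intergenic_gap = c(2000L, 8000L),
    frac_noncoding = 0.3,
    frac_second_isoform = 0.3,       # fraction of genes with a skipped-exon isoform
    utr_length = 50L,                # CDS trimmed this much at each transcript end
    n_mirs = 200L,
    frac_mirs_intronic = 0.6,
    frac_mirs_near_peaks = 0.4,
    mature_mir_length = 22L,
    pre_mir_length = 70L,
    genotypes = data.frame(
      label = c("KO", "Fneg", "WT", "OE"),
      dose = c(0, 0.5, 1, 2),
      stringsAsFactors = FALSE
    ),
    n_replicates = 4L,
    se_model = list(beta0 = 0.8, beta1 = -0.05, beta2 = 0.05),
    reads_per_intron = 200L,
    cluster_bins = c(0, 1, 3, 6),
    peaks = list(
      rate = 2.0,                    # mean peaks per intron (Poisson)
      donor_bias_scale = 150,        # nt, exponential distance from donor
      width = c(30L, 80L),
      frac_intronic = 0.87,
      frac_subthreshold = 0.1,
      mir_peak_max_gap = 1500,
      mir_peak_on_frac = 0.5,        # fraction of miR peaks overlapping the miR
      mir_peak_gap_scale = 300,      # nt, exponential gap for the rest
      peak_height = 50               # reads/bp contributed to IP coverage
    ),
    mir_model = list(
      base_log_mean = log(100),
      near_peak_effect = 1.5,
      noncoding_effect = 0.5,
      dispersion = 0.3,
      n_samples = 16L,
      frac_de = 0.2,                 # miRs planted differential between halves
      de_log2fc = 2
    ),
    lsv = list(n_events = 60L, delta_psi = c(0.2, 0.6)),
    ## event piles must dominate the donor-biased peak background so the
    ## cassette-exon map shows the planted direction-specific pattern
    coverage = list(gene_floor = 1, event_height = 40),
    afm = list(
      groups = c(AGO_KO = 1.0, Dox_AGO2 = 2.5,
                 AGO_KO_LIS1_OE = 3.5, Dox_AGO2_LIS1_OE = 5.0),  # kPa
      noise_frac = 0.05,
      additive_noise = 1e-11,        # 10 pN noise floor
      grid = c(8L, 8L),
      z_step = 1e-9,
      pre_contact = 200e-9,
      max_indent = 600e-9,
      contact_jitter = 20e-9,
      dome_height = 2e-6,
      nu = 0.5, theta = 22
    ),
    interactome = list(n1 = 100L, n2 = 100L, N = 1000L, k = 20L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "sim_config")
}

## per-generator RNG scopes: derived deterministically from the master seed
seed_for <- function(config, offset) {
  ## double arithmetic avoids integer overflow for large master seeds
  set.seed((as.numeric(config$seed) * 101 + offset) %% 2147483647)
}

runi <- function(n, rng) {
  if (rng[1] == rng[2]) rep(rng[1], n)
  else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

#' Generate a toy genome annotation with intron-hosted miRNAs
#'
#' Lays multi-exon genes sequentially on one contig with random exon and
#' intron lengths, assigns protein-coding/noncoding biotypes, adds a
#' skipped-exon second isoform to a fraction of genes, builds CDS records
#' (exons trimmed by a UTR margin at transcript ends) for protein-coding
#' genes, and places mature/pre-miR records inside introns (a configured
#' fraction) or intergenically.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (`GenomeAnnotation`), `mirs`
#'   (data.frame: `mir_id`, `chrom`, `strand`, mature and pre coordinates,
#'   `host_gene`, `host_ordinal`, `host_context`, `near_peak` flag) and
#'   `introns` (the unique intron set of the annotation).
#' @export
make_toy_annotation <- function(config = sim_config()) {
  seed_for(config, 1L)
  ng <- config$n_genes
  n_nc <- round(config$frac_noncoding * ng)
  biotype <- rep("protein_coding", ng)
  if (n_nc > 0) biotype[sample(ng, n_nc)] <- "noncoding"
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  n_ex <- runi(ng, config$exons_per_gene)
  second <- runif(ng) < config$frac_second_isoform & n_ex >= 3

  cursor <- 1000L
  exon_rows <- list()
  cds_rows <- list()
  gene_rows <- list()
  for (g in seq_len(ng)) {
    ex_len <- runi(n_ex[g], config$exon_length)
    in_len <- if (n_ex[g] > 1) runi(n_ex[g] - 1, config$intron_length)
              else integer(0)
    starts <- integer(n_ex[g]); ends <- integer(n_ex[g])
    pos <- cursor
    for (e in seq_len(n_ex[g])) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + (if (e < n_ex[g]) in_len[e] else 0L) + 1L
    }
    gid <- sprintf("gene%03d", g)
    tx1 <- paste0(gid, ".t1")
    exon_rows[[length(exon_rows) + 1]] <- data.frame(
      gene_id = gid, transcript_id = tx1, start = starts, end = ends,
      strand = strand[g], stringsAsFactors = FALSE
    )
    if (second[g]) {
      skip <- sample(2:(n_ex[g] - 1), 1)
      tx2 <- paste0(gid, ".t2")
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = tx2,
        start = starts[-skip], end = ends[-skip],
        strand = strand[g], stringsAsFactors = FALSE
      )
    }
    if (biotype[g] == "protein_coding") {
      u <- config$utr_length
      cs <- starts; ce <- ends
      cs[1] <- min(cs[1] + u, ce[1])
      ce[n_ex[g]] <- max(ce[n_ex[g]] - u, cs[n_ex[g]])
      cds_rows[[length(cds_rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = tx1, start = cs, end = ce,
        strand = strand[g], stringsAsFactors = FALSE
      )
    }
    gene_rows[[g]] <- data.frame(
      gene_id = gid, chrom = config$contig, strand = strand[g],
      start = starts[1], end = ends[n_ex[g]], biotype = biotype[g],
      stringsAsFactors = FALSE
    )
    cursor <- ends[n_ex[g]] + runi(1, config$intergenic_gap)
  }
  genes <- do.call(rbind, gene_rows)
  contig_len <- cursor + 10000L
  if (!is.null(config$contig_length)) {
    if (config$contig_length < contig_len) {
      stop("genes exceed the contig; increase contig_length to at least ",
           contig_len)
    }
    contig_len <- config$contig_length
  }
  exdf <- do.call(rbind, exon_rows)
  exons <- GRanges(config$contig, IRanges(exdf$start, exdf$end),
                   strand = exdf$strand)
  mcols(exons) <- DataFrame(gene_id = exdf$gene_id,
                            transcript_id = exdf$transcript_id,
                            biotype = genes$biotype[
                              match(exdf$gene_id, genes$gene_id)])
  cds <- GRanges()
  if (length(cds_rows)) {
    cdf <- do.call(rbind, cds_rows)
    cds <- GRanges(config$contig, IRanges(cdf$start, cdf$end),
                   strand = cdf$strand)
    mcols(cds) <- DataFrame(gene_id = cdf$gene_id,
                            transcript_id = cdf$transcript_id)
  }
  tx <- unique(exdf[, c("gene_id", "transcript_id")])
  tx_rng <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    sel <- exdf$transcript_id == tx$transcript_id[i]
    data.frame(start = min(exdf$start[sel]), end = max(exdf$end[sel]))
  }))
  transcripts <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = config$contig,
    strand = genes$strand[match(tx$gene_id, genes$gene_id)],
    start = tx_rng$start, end = tx_rng$end, stringsAsFactors = FALSE
  )
  transcripts <- transcripts[order(transcripts$transcript_id), ]
  rownames(transcripts) <- NULL
  genes <- genes[order(genes$gene_id), ]
  rownames(genes) <- NULL
  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         cds = cds, contigs = setNames(contig_len, config$contig)),
    class = "GenomeAnnotation"
  )
  introns <- build_unique_intron_set(ann)
  mirs <- place_mirs(ann, introns, config)
  list(annotation = ann, mirs = mirs, introns = introns)
}

place_mirs <- function(ann, introns, config) {
  nm <- config$n_mirs
  n_intr_mir <- round(config$frac_mirs_intronic * nm)
  n_near <- round(config$frac_mirs_near_peaks * nm)
  pre_len <- config$pre_mir_length
  mat_len <- config$mature_mir_length
  margin <- 100L
  wide <- which(width(introns) >= pre_len + 2 * margin)
  rows <- vector("list", nm)
  contig_len <- unname(ann$contigs[1])
  gene_rng <- IRanges(ann$genes$start, ann$genes$end)
  for (i in seq_len(nm)) {
    if (i <= n_intr_mir && length(wide)) {
      host <- sample(wide, 1)
      lo <- start(introns)[host] + margin
      hi <- end(introns)[host] - margin - pre_len
      ps <- sample(lo:hi, 1)
      strand <- as.character(strand(introns))[host]
      ctx <- mcols(introns)$host_biotype[host]
      rows[[i]] <- data.frame(
        mir_id = sprintf("mir%03d", i), chrom = config$contig,
        strand = strand, pre_start = ps, pre_end = ps + pre_len - 1L,
        host_gene = mcols(introns)$gene_id[host],
        host_ordinal = mcols(introns)$ordinal[host],
        host_context = ifelse(ctx == "protein_coding",
                              "protein_coding_intron", "noncoding_intron"),
        stringsAsFactors = FALSE
      )
    } else {
      ## intergenic: rejection-sample a spot outside all gene spans
      repeat {
        ps <- sample(seq(1000L, contig_len - pre_len - 1000L), 1)
        cand <- IRanges(ps - 2000L, ps + pre_len + 2000L)
        if (!any(overlapsAny(cand, gene_rng))) break
      }
      rows[[i]] <- data.frame(
        mir_id = sprintf("mir%03d", i), chrom = config$contig,
        strand = sample(c("+", "-"), 1), pre_start = ps,
        pre_end = ps + pre_len - 1L,
        host_gene = NA_character_, host_ordinal = NA_integer_,
        host_context = "intergenic", stringsAsFactors = FALSE
      )
    }
  }
  mirs <- do.call(rbind, rows)
  off <- (pre_len - mat_len) %/% 2
  mirs$mature_start <- mirs$pre_start + off
  mirs$mature_end <- mirs$mature_start + mat_len - 1L
  mirs$near_peak <- FALSE
  mirs$near_peak[sample(nm, n_near)] <- TRUE
  mirs
}

#' GRanges of mature (or pre-) miR coordinates
#'
#' @param mirs miR table from [make_toy_annotation()].
#' @param what `"mature"` or `"pre"`.
#' @return Named `GRanges`.
#' @export
mir_granges <- function(mirs, what = c("mature", "pre")) {
  what <- match.arg(what)
  s <- if (what == "mature") mirs$mature_start else mirs$pre_start
  e <- if (what == "mature") mirs$mature_end else mirs$pre_end
  gr <- GRanges(mirs$chrom, IRanges(s, e), strand = mirs$strand)
  names(gr) <- mirs$mir_id
  gr
}

#' Simulate a CLIP peak set with donor-site positional bias
#'
#' Peaks are planted per intron with Poisson counts and donor-biased
#' positions (truncated-exponential distance from the donor splice site);
#' one peak is placed within `mir_peak_max_gap` nt of each near-peak
#' flagged miR; non-intronic (exonic/intergenic) peaks are added so the
#' overall intronic fraction matches `frac_intronic`; a fraction of
#' sub-threshold peaks (failing the significance filter) is appended.
#'
#' @param toy Output of [make_toy_annotation()].
#' @param config A [sim_config()].
#' @return `GRanges` with metadata `log2fc`, `padj`, `truth_category`
#'   (`intronic`/`exonic`/`intergenic`), `truth_significant`, `truth_mir`.
#' @export
simulate_peaks <- function(toy, config = sim_config()) {
  seed_for(config, 2L)
  ann <- toy$annotation; introns <- toy$introns; mirs <- toy$mirs
  pc <- config$peaks
  contig_len <- unname(ann$contigs[1])
  rows <- list()
  add_row <- function(s, e, strand, cat, mir = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      start = s, end = e, strand = strand, cat = cat, mir = mir,
      stringsAsFactors = FALSE
    )
  }
  ## intronic peaks, donor-biased
  n_per <- rpois(length(introns), pc$rate)
  for (i in seq_along(introns)) {
    if (n_per[i] == 0) next
    iw <- width(introns)[i]
    st <- as.character(strand(introns))[i]
    for (k in seq_len(n_per[i])) {
      w <- runi(1, pc$width)
      if (iw <= w + 2) next
      off <- min(floor(rexp(1, 1 / pc$donor_bias_scale)), iw - w - 1)
      if (st == "+") {
        s <- start(introns)[i] + off
      } else {
        s <- end(introns)[i] - off - w + 1
      }
      add_row(s, s + w - 1L, st, "intronic")
    }
  }
  ## one peak on or near each flagged miR: a fraction overlap the mature
  ## miR itself, the rest sit an exponentially distributed gap away
  flagged <- which(mirs$near_peak)
  for (i in flagged) {
    w <- runi(1, pc$width)
    gap <- if (runif(1) < pc$mir_peak_on_frac) -w %/% 2
           else ceiling(min(rexp(1, 1 / pc$mir_peak_gap_scale),
                            pc$mir_peak_max_gap))
    if (!is.na(mirs$host_gene[i])) {
      sel <- mcols(introns)$gene_id == mirs$host_gene[i] &
        mcols(introns)$ordinal == mirs$host_ordinal[i]
      host <- which(sel)[1]
      s <- mirs$mature_end[i] + gap
      if (s + w - 1 > end(introns)[host]) {
        s <- max(start(introns)[host], mirs$mature_start[i] - gap - w + 1)
      }
      cat <- "intronic"
    } else {
      s <- mirs$mature_end[i] + gap
      cat <- "intergenic"
    }
    add_row(s, s + w - 1L, mirs$strand[i], cat, mirs$mir_id[i])
  }
  if (!length(rows)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(log2fc = numeric(), padj = numeric(),
                           truth_category = character(),
                           truth_significant = logical(),
                           truth_mir = character())
    return(gr)
  }
  ## top up non-intronic peaks to reach the planted intronic fraction
  tab <- do.call(rbind, rows)
  n_intr <- sum(tab$cat == "intronic")
  n_non_now <- sum(tab$cat != "intronic")
  n_non_target <- round(n_intr * (1 - pc$frac_intronic) / pc$frac_intronic)
  n_add <- max(0L, n_non_target - n_non_now)
  ex <- ann$exons
  gene_rng <- IRanges(ann$genes$start, ann$genes$end)
  for (k in seq_len(n_add)) {
    w <- runi(1, pc$width)
    if (k %% 2 == 0 && length(ex)) {
      j <- sample(length(ex), 1)
      if (width(ex)[j] > w + 2) {
        s <- start(ex)[j] + sample.int(width(ex)[j] - w, 1) - 1L
        add_row(s, s + w - 1L, as.character(strand(ex))[j], "exonic")
        next
      }
    }
    repeat {
      s <- sample(seq(1000L, contig_len - w - 1000L), 1)
      if (!any(overlapsAny(IRanges(s, s + w - 1L), gene_rng))) break
    }
    add_row(s, s + w - 1L, sample(c("+", "-"), 1), "intergenic")
  }
  tab <- do.call(rbind, rows)
  n_sig <- nrow(tab)
  ## sub-threshold peaks (fail the log2fc/padj filter)
  n_sub <- round(pc$frac_subthreshold * n_sig)
  for (k in seq_len(n_sub)) {
    w <- runi(1, pc$width)
    s <- sample(seq(1000L, contig_len - w - 1000L), 1)
    add_row(s, s + w - 1L, sample(c("+", "-"), 1), "background")
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  sig <- seq_len(n) <= n_sig
  log2fc <- ifelse(sig, runif(n, 3, 8), runif(n, 0, 2.9))
  padj <- ifelse(sig, 10^-runif(n, 3.1, 10), 10^-runif(n, 0, 2.9))
  gr <- GRanges(config$contig, IRanges(tab$start, tab$end),
                strand = tab$strand,
                log2fc = log2fc, padj = padj,
                truth_category = ifelse(sig, tab$cat, "background"),
                truth_significant = sig,
                truth_mir = tab$mir)
  seqlengths(gr) <- setNames(contig_len, config$contig)
  sort(gr, ignore.strand = TRUE)
}

#' Simulate junction counts with peak- and dose-dependent splicing
#'
#' For intron i with cluster count c and genotype dose d, the planted
#' splicing efficiency is
#' SE = clip(beta0 + beta1 * g(c) + beta2 * log2(1 + d), 0.01, 0.99),
#' where g(c) in 0..3 codes the cluster-count bin (`cluster_bins`). Each
#' sample draws ee ~ Binomial(reads, SE), ei = reads - ee.
#'
#' @param toy Output of [make_toy_annotation()].
#' @param peaks Peak set (significant peaks; see [simulate_peaks()] and
#'   [filter_peaks()]).
#' @param config A [sim_config()].
#' @return List with `counts` (long junction table), `sample_info`
#'   (sample -> genotype), and `truth` (per intron and genotype: cluster
#'   count, bin code, true SE).
#' @export
simulate_junction_counts <- function(toy, peaks, config = sim_config()) {
  seed_for(config, 3L)
  introns <- toy$introns
  cc <- count_clusters_per_feature(introns, peaks, level = "intron")
  gcode <- findInterval(cc$n_clusters, config$cluster_bins) - 1L
  sm <- config$se_model
  gt <- config$genotypes
  reads <- config$reads_per_intron
  counts <- list(); truth <- list(); samples <- list()
  for (gi in seq_len(nrow(gt))) {
    se_true <- pmin(pmax(sm$beta0 + sm$beta1 * gcode +
                           sm$beta2 * log2(1 + gt$dose[gi]), 0.01), 0.99)
    truth[[gi]] <- data.frame(
      gene_id = cc$gene_id, intron_index = cc$intron_index,
      n_clusters = cc$n_clusters, bin_code = gcode,
      genotype = gt$label[gi], true_se = se_true,
      stringsAsFactors = FALSE
    )
    for (r in seq_len(config$n_replicates)) {
      smp <- paste0(gt$label[gi], "_rep", r)
      ee <- rbinom(nrow(cc), reads, se_true)
      counts[[smp]] <- data.frame(
        gene_id = cc$gene_id, intron_index = cc$intron_index,
        sample = smp, ee = ee, ei = reads - ee,
        stringsAsFactors = FALSE
      )
      samples[[smp]] <- data.frame(sample = smp, genotype = gt$label[gi],
                                   stringsAsFactors = FALSE)
    }
  }
  list(
    counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
    sample_info = do.call(rbind, c(samples, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))
  )
}

## brute-force nearest-gap distance, used for generator truth bookkeeping
truth_min_gap <- function(s1, e1, s2, e2) {
  n <- length(s1)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gap <- pmax(0, pmax(s2 - e1[i], s1[i] - e2) - 1)
    out[i] <- if (length(gap)) min(gap) else NA_real_
  }
  out
}

#' Simulate miR counts with peak-distance-dependent expression
#'
#' Truth categories are derived from the realized geometry (brute-force
#' distance from each mature miR to the significant peak set, plus the
#' recorded host-intron context). Counts follow a negative binomial with
#' mean exp(base + near_peak_effect * [lt2kb] + noncoding_effect *
#' [gt2kb noncoding intron]) and variance mu + dispersion * mu^2; a
#' fraction of miRs gets an extra planted fold change between the two
#' sample halves (conditions `ctrl` / `pert`).
#'
#' @param toy Output of [make_toy_annotation()].
#' @param peaks Significant peak set.
#' @param config A [sim_config()].
#' @return List with `counts` (matrix miRs x samples), `condition_map`,
#'   and `truth` (per miR: category, distance, planted DE flag and sign).
#' @export
simulate_mir_counts <- function(toy, peaks, config = sim_config()) {
  seed_for(config, 4L)
  mirs <- toy$mirs
  mm <- config$mir_model
  d <- truth_min_gap(mirs$mature_start, mirs$mature_end,
                     start(peaks), end(peaks))
  category <- ifelse(
    !is.na(d) & d <= 2000, "lt2kb",
    ifelse(mirs$host_context == "protein_coding_intron",
           "gt2kb_protein_coding_intron",
           ifelse(mirs$host_context == "noncoding_intron",
                  "gt2kb_noncoding_intron", "other"))
  )
  nm <- nrow(mirs)
  ns <- mm$n_samples
  mu0 <- exp(mm$base_log_mean +
               mm$near_peak_effect * (category == "lt2kb") +
               mm$noncoding_effect * (category == "gt2kb_noncoding_intron"))
  de <- runif(nm) < mm$frac_de
  de_sign <- ifelse(runif(nm) < 0.5, 1, -1)
  cond <- rep(c("ctrl", "pert"), length.out = ns)
  counts <- matrix(0L, nm, ns,
                   dimnames = list(mirs$mir_id, paste0("s", seq_len(ns))))
  size <- 1 / mm$dispersion
  for (j in seq_len(ns)) {
    mu <- mu0 * ifelse(de & cond[j] == "pert",
                       2^(mm$de_log2fc * de_sign), 1)
    counts[, j] <- rnbinom(nm, mu = mu, size = size)
  }
  list(
    counts = counts,
    condition_map = setNames(cond, colnames(counts)),
    truth = data.frame(
      mir_id = mirs$mir_id, category = category, distance = d,
      de = de, de_sign = ifelse(de, de_sign, 0L),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate miR -> gene target scores with planted anticorrelated targets
#'
#' Builds a score table in which planted-DE miRs have one high-scoring
#' target gene whose (synthetic) fold change opposes the miR's, plus
#' random low/high-score decoy pairs; also returns a synthetic gene DE
#' table consistent with the planted signs.
#'
#' @param mir_truth `truth` from [simulate_mir_counts()].
#' @param config A [sim_config()].
#' @return List with `scores` (mir_id, gene_id, score) and `gene_de`
#'   (feature, log2FC).
#' @export
simulate_target_scores <- function(mir_truth, config = sim_config()) {
  seed_for(config, 8L)
  de <- mir_truth[mir_truth$de != 0 & mir_truth$de_sign != 0, , drop = FALSE]
  n <- nrow(de)
  genes <- sprintf("tgene%03d", seq_len(max(1L, 2L * n)))
  scores <- data.frame(
    mir_id = de$mir_id,
    gene_id = genes[seq_len(n)],
    score = round(runif(n, 60, 100)),
    stringsAsFactors = FALSE
  )
  decoys <- data.frame(
    mir_id = sample(mir_truth$mir_id, n, replace = TRUE),
    gene_id = genes[seq_len(n) + n],
    score = round(runif(n, 10, 59)),
    stringsAsFactors = FALSE
  )
  gene_de <- data.frame(
    feature = genes,
    log2FC = c(-de$de_sign * runif(n, 1, 2), runif(n, -2, 2)),
    stringsAsFactors = FALSE
  )
  list(scores = rbind(scores, decoys), gene_de = gene_de)
}

#' Simulate cassette-exon event tables
#'
#' Samples internal exons of multi-exon genes as cassette exons, assigns
#' direction classes (`higher_in_OE` / `lower_in_OE`) alternately, and
#' draws |delta PSI| uniformly within the configured range (sign follows
#' the direction).
#'
#' @param toy Output of [make_toy_annotation()].
#' @param config A [sim_config()].
#' @return data.frame with `chrom`, `strand`, `exon_start`, `exon_end`,
#'   `delta_psi`, `direction`.
#' @export
simulate_lsv_events <- function(toy, config = sim_config()) {
  seed_for(config, 5L)
  ex <- toy$annotation$exons
  ex1 <- ex[mcols(ex)$transcript_id %in%
              paste0(unique(mcols(ex)$gene_id), ".t1")]
  internal <- unlist(lapply(split(seq_along(ex1),
                                  mcols(ex1)$transcript_id), function(ix) {
    if (length(ix) < 3) return(integer(0))
    o <- ix[order(start(ex1)[ix])]
    o[-c(1, length(o))]
  }))
  n <- min(config$lsv$n_events, length(internal))
  pick <- sample(internal, n)
  dpsi <- runif(n, config$lsv$delta_psi[1], config$lsv$delta_psi[2])
  dir <- rep(c("higher_in_OE", "lower_in_OE"), length.out = n)
  data.frame(
    chrom = as.character(seqnames(ex1))[pick],
    strand = as.character(strand(ex1))[pick],
    exon_start = start(ex1)[pick],
    exon_end = end(ex1)[pick],
    delta_psi = ifelse(dir == "higher_in_OE", dpsi, -dpsi),
    direction = dir,
    stringsAsFactors = FALSE
  )
}

#' Simulate IP and SMI coverage tracks
#'
#' IP coverage: a uniform floor over gene bodies, read piles over each
#' significant peak (hence donor-biased intronic signal and on-miR
#' signal), and direction-class piles around cassette-exon events
#' (exon-body enrichment for `higher_in_OE`, acceptor-side intronic
#' enrichment for `lower_in_OE`). SMI: the same gene-body floor with mild
#' block noise and no positional structure.
#'
#' @param toy Output of [make_toy_annotation()].
#' @param peaks Significant peak set.
#' @param events From [simulate_lsv_events()] (or `NULL`).
#' @param config A [sim_config()].
#' @return List with `ip` and `smi` coverage tracks.
#' @export
simulate_coverage_tracks <- function(toy, peaks, events = NULL,
                                     config = sim_config()) {
  seed_for(config, 6L)
  ann <- toy$annotation
  cv <- config$coverage
  g <- ann$genes
  ## assemble all intervals first, then write each track in one pass
  ip_iv <- list(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                           strand = g$strand, weight = cv$gene_floor),
                data.frame(chrom = as.character(seqnames(peaks)),
                           start = start(peaks), end = end(peaks),
                           strand = as.character(strand(peaks)),
                           weight = config$peaks$peak_height))
  if (!is.null(events) && nrow(events)) {
    higher <- events$direction == "higher_in_OE"
    if (any(higher)) {
      ev <- events[higher, ]
      ip_iv[[length(ip_iv) + 1]] <- data.frame(
        chrom = ev$chrom, start = ev$exon_start, end = ev$exon_end,
        strand = ev$strand, weight = cv$event_height)
    }
    if (any(!higher)) {
      ev <- events[!higher, ]
      plus <- ev$strand == "+"
      ip_iv[[length(ip_iv) + 1]] <- data.frame(
        chrom = ev$chrom,
        start = ifelse(plus, ev$exon_start - 250L, ev$exon_end + 1L),
        end = ifelse(plus, ev$exon_start - 1L, ev$exon_end + 250L),
        strand = ev$strand, weight = cv$event_height)
    }
  }
  ## mild block noise on SMI (no positional structure)
  noise <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    blocks <- seq(g$start[i], g$end[i], by = 500L)
    data.frame(chrom = g$chrom[i], start = blocks,
               end = pmin(blocks + 499L, g$end[i]), strand = g$strand[i],
               weight = runif(length(blocks), 0, 0.2))
  }))
  smi_iv <- list(ip_iv[[1]], noise)
  build <- function(ivs, label) {
    iv <- do.call(rbind, ivs)
    add_coverage(new_coverage_track(ann$contigs, label), iv$chrom,
                 iv$start, iv$end, iv$strand, iv$weight)
  }
  list(ip = build(ip_iv, "IP"), smi = build(smi_iv, "SMI"))
}

#' Simulate a random genome sequence for the annotation contigs
#'
#' @param toy Output of [make_toy_annotation()].
#' @param config A [sim_config()].
#' @return `Biostrings::DNAStringSet` keyed by contig.
#' @export
simulate_genome <- function(toy, config = sim_config()) {
  seed_for(config, 7L)
  contigs <- toy$annotation$contigs
  seqs <- lapply(contigs, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Simulate AFM force-curve grids with group-specific moduli
#'
#' Each group gets a pixel grid over a dome-shaped colony (Gaussian
#' height profile). Per pixel, an approach curve is generated on a 1 nm
#' z-grid: a pre-contact baseline (constant offset plus the additive
#' noise floor), then the conical Hertz force with multiplicative
#' Gaussian noise. The contact position is jittered around the
#' dome-derived surface height.
#'
#' @param config A [sim_config()].
#' @param groups Named numeric vector of true moduli in kPa (defaults to
#'   `config$afm$groups`).
#' @param grid Grid dimensions `c(nrow, ncol)` (default from config).
#' @param dome Give the colony a dome height profile (default `TRUE`;
#'   `FALSE` makes a flat sample).
#' @return Named list per group: `force_curve_set` with elements
#'   `curves`, `dims`, `truth_E_kPa`, `truth_height` (m, matrix),
#'   `truth_z0` (contact positions, matrix).
#' @export
simulate_force_curves <- function(config = sim_config(),
                                  groups = NULL, grid = NULL,
                                  dome = TRUE) {
  seed_for(config, 9L)
  af <- config$afm
  if (is.null(groups)) groups <- af$groups
  if (is.null(grid)) grid <- af$grid
  nr <- grid[1]; ncg <- grid[2]
  ci <- (nr + 1) / 2; cj <- (ncg + 1) / 2
  sigma <- max(nr, ncg) / 3
  out <- list()
  for (gname in names(groups)) {
    E <- groups[[gname]] * 1000  # Pa
    curves <- vector("list", nr * ncg)
    hmat <- zmat <- matrix(NA_real_, nr, ncg)
    idx <- 0L
    for (i in seq_len(nr)) {
      for (j in seq_len(ncg)) {
        idx <- idx + 1L
        h <- if (dome) {
          af$dome_height * exp(-((i - ci)^2 + (j - cj)^2) / (2 * sigma^2))
        } else 0
        z0 <- 1e-5 - h + runif(1, -af$contact_jitter, af$contact_jitter)
        z <- seq(z0 - af$pre_contact, z0 + af$max_indent, by = af$z_step)
        delta <- pmax(z - z0, 0)
        f_true <- hertz_cone_force(E, delta, af$nu, af$theta)
        offset <- runif(1, -2e-11, 2e-11)
        force <- f_true * (1 + rnorm(length(z), 0, af$noise_frac)) +
          rnorm(length(z), 0, af$additive_noise) + offset
        curves[[idx]] <- list(z = z, force = force, row = i, col = j)
        hmat[i, j] <- h
        zmat[i, j] <- z0
      }
    }
    out[[gname]] <- list(curves = curves, dims = c(nr, ncg),
                         truth_E_kPa = groups[[gname]],
                         truth_height = hmat, truth_z0 = zmat)
  }
  out
}

#' Simulate two gene lists with an exactly planted overlap
#'
#' @param config A [sim_config()]; sizes from `config$interactome`
#'   (n1, n2, universe N, overlap k).
#' @return List with `set_a`, `set_b`, `universe`, `k`.
#' @export
simulate_interactomes <- function(config = sim_config()) {
  seed_for(config, 10L)
  it <- config$interactome
  stopifnot(it$k <= min(it$n1, it$n2),
            it$n1 + it$n2 - it$k <= it$N)
  universe <- sprintf("g%04d", seq_len(it$N))
  shared <- sample(universe, it$k)
  rest <- base::setdiff(universe, shared)
  a_only <- sample(rest, it$n1 - it$k)
  b_only <- sample(base::setdiff(rest, a_only), it$n2 - it$k)
  list(set_a = c(shared, a_only), set_b = c(shared, b_only),
       universe = universe, k = it$k)
}
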