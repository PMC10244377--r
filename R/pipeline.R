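## End-to-end orchestration: simulate -> intron set -> splicing efficiency
## -> peak analysis -> miR analysis -> overlap -> AFM, with one report
## directory and a deterministic summary JSON.

#' Run the full synthetic-data analysis pipeline
#'
#' Generates every input with [sim_config()] defaults (or an override),
#' runs each analysis stage, writes per-stage TSV/JSON outputs under
#' `outdir`, and returns (and writes) a summary with the key statistics.
#' Identical config and seed give a byte-identical summary JSON.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param stages Character vector of stages to run, a subset of
#'   `c("splicing", "peaks", "mir", "overlap", "afm")`; the simulation
#'   always runs.
#' @return The summary list, invisibly; files are written under `outdir`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("run"),
                         stages = c("splicing", "peaks", "mir", "overlap",
                                    "afm")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed,
                  thresholds = list(
                    peak_min_log2fc = 3, peak_max_padj = 0.001,
                    de_min_abs_log2fc = 1, de_max_padj = 0.05,
                    de_min_base_mean_mir = 5, de_min_base_mean_gene = 10,
                    mir_distance_bound_nt = 2000, min_delta_psi = 0.2,
                    delta_range_nm = c(150, 500), nu = 0.5, theta_deg = 22,
                    cluster_bins = config$cluster_bins
                  ))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- simulate ------------------------------------------------------
  sim <- run_stage("simulate", {
    toy <- make_toy_annotation(config)
    peaks_all <- simulate_peaks(toy, config)
    peaks <- filter_peaks(peaks_all)
    write_annotation(toy$annotation, file.path(outdir, "toy.gtf"))
    write_intron_bed(toy$introns, file.path(outdir, "introns.bed"))
    list(toy = toy, peaks_all = peaks_all, peaks = peaks)
  })
  toy <- sim$toy
  peaks <- sim$peaks
  introns_cls <- classify_intron_context(toy$introns, toy$annotation)
  summary$simulate <- list(
    n_genes = nrow(toy$annotation$genes),
    n_introns = length(toy$introns),
    n_peaks_total = length(sim$peaks_all),
    n_peaks_significant = length(peaks),
    n_mirs = nrow(toy$mirs)
  )

  if ("splicing" %in% stages) {
    summary$splicing <- run_stage("splicing", {
      jc <- simulate_junction_counts(toy, peaks, config)
      write.table(jc$counts, file.path(outdir, "junction_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      se <- splicing_efficiency(jc$counts, level = "intron", min_reads = 10)
      write.table(se, file.path(outdir, "splicing_efficiency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cc <- count_clusters_per_feature(toy$introns, peaks, "intron")
      grouping <- group_se_by_cluster_count(se, cc,
                                            bins = config$cluster_bins)
      cmp <- compare_se_groups(grouping)
      ## per-genotype bin medians and the OE vs Fneg delta
      gm <- genotype_bin_medians(se, cc, jc$sample_info,
                                 config$cluster_bins)
      oe <- se[se$sample %in%
                 jc$sample_info$sample[jc$sample_info$genotype == "OE"], ]
      fn <- se[se$sample %in%
                 jc$sample_info$sample[jc$sample_info$genotype == "Fneg"], ]
      dse <- delta_splicing_efficiency(oe, fn)
      write.table(dse, file.path(outdir, "delta_se_OE_vs_Fneg.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(
        mean_se = mean(se$se, na.rm = TRUE),
        bin_medians = setNames(as.list(cmp$summary$median),
                               cmp$summary$group),
        kruskal_p = cmp$kruskal$p.value,
        n_dunn_pairs_sig = sum(cmp$dunn$padj < 0.05),
        genotype_bin_medians = gm,
        median_delta_se_OE_vs_Fneg = median(dse$delta_se)
      )
    })
  }

  if ("peaks" %in% stages) {
    summary$peaks <- run_stage("peaks", {
      annotated <- annotate_peaks(peaks, toy$annotation,
                                  introns = introns_cls)
      frac <- attr(annotated, "fractions")
      intronic_frac <- unname(frac[["protein_coding_intron"]] +
                                frac[["noncoding_intron"]])
      events <- simulate_lsv_events(toy, config)
      tracks <- simulate_coverage_tracks(toy, peaks, events, config)
      prof_ip <- exon_metaprofile(tracks$ip, toy$annotation)
      prof_smi <- exon_metaprofile(tracks$smi, toy$annotation)
      write.table(prof_ip, file.path(outdir, "exon_metaprofile_ip.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      pm <- premir_metaprofile(tracks$ip, mir_granges(toy$mirs, "pre"))
      cmap <- cassette_exon_map(tracks$ip, tracks$smi, events)
      write.table(cmap, file.path(outdir, "cassette_exon_map.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      genome <- simulate_genome(toy, config)
      mw <- motif_windows(peaks, genome)
      Biostrings::writeXStringSet(mw, file.path(outdir,
                                                "motif_windows.fasta"))
      list(
        category_fractions = as.list(setNames(as.numeric(frac),
                                              names(frac))),
        intronic_fraction = intronic_frac,
        exon_profile_max_region =
          prof_ip$region[which.max(prof_ip$mean)],
        premir_center_vs_flank = premir_center_ratio(pm),
        n_motif_windows = length(mw)
      )
    })
  }

  if ("mir" %in% stages) {
    summary$mir <- run_stage("mir", {
      mc <- simulate_mir_counts(toy, peaks, config)
      write.table(mc$counts, file.path(outdir, "mir_counts.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      nc <- normalize_counts(mc$counts)
      assign <- categorize_mirs(mir_granges(toy$mirs, "mature"), peaks,
                                introns_cls)
      write.table(assign, file.path(outdir, "mir_categories.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cmp <- compare_mir_expression(assign, nc)
      det <- de_table(mc$counts, mc$condition_map, "pert", "ctrl")
      de <- de_filter(det, kind = "mir")
      ts <- simulate_target_scores(mc$truth, config)
      pairs <- mir_target_filter(det, ts$gene_de, ts$scores)
      list(
        category_counts = as.list(table(assign$category)),
        median_log2_basemean = setNames(
          as.list(cmp$summary$median_log2_baseMean), cmp$summary$category),
        kruskal_p = cmp$kruskal$p.value,
        n_de_mirs = nrow(de),
        n_target_pairs = nrow(pairs),
        truth_agreement = mean(
          assign$category == mc$truth$category[
            match(assign$mir_id, mc$truth$mir_id)])
      )
    })
  }

  if ("overlap" %in% stages) {
    summary$overlap <- run_stage("overlap", {
      il <- simulate_interactomes(config)
      res <- hypergeometric_overlap(il$set_a, il$set_b, il$universe)
      list(k = res$k, expected = res$expected,
           representation_factor = res$representation_factor,
           p = res$p.value)
    })
  }

  if ("afm" %in% stages) {
    summary$afm <- run_stage("afm", {
      fc <- simulate_force_curves(config)
      centers <- list()
      for (gname in names(fc)) {
        map <- build_modulus_map(fc[[gname]])
        vals <- colony_center_values(map$modulus, map$height)
        ## degenerate center regions (tiny grids): widen to the full
        ## colony mask, then to all fitted pixels
        if (length(vals) < 2) {
          vals <- colony_center_values(map$modulus, map$height,
                                       erode_margin = 0)
        }
        if (length(vals) < 2) vals <- map$modulus[is.finite(map$modulus)]
        centers[[gname]] <- vals
      }
      cmp <- compare_stiffness(centers)
      list(
        group_medians = setNames(as.list(cmp$summary$median),
                                 cmp$summary$group),
        kruskal_p = cmp$kruskal$p.value,
        max_games_howell_p = max(cmp$games_howell$p.value)
      )
    })
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

## per-genotype, per-bin median SE (replicates pooled)
genotype_bin_medians <- function(se, cluster_counts, sample_info, bins) {
  grouping <- group_se_by_cluster_count(se, cluster_counts, bins = bins)
  grouping$genotype <- sample_info$genotype[
    match(grouping$sample, sample_info$sample)]
  out <- list()
  for (gt in unique(grouping$genotype)) {
    sub <- grouping[grouping$genotype == gt & is.finite(grouping$se), ]
    out[[gt]] <- setNames(
      as.list(tapply(sub$se, droplevels(sub$bin), median)),
      levels(droplevels(sub$bin)))
  }
  out
}

## central 10% of the scaled pre-miR axis (the pre-miR body and its
## immediate vicinity) vs the two outer fifths
premir_center_ratio <- function(profile, center_frac = 0.1) {
  nb <- nrow(profile)
  half <- max(1L, round(nb * center_frac / 2))
  mid <- nb %/% 2
  center <- profile$mean[max(1, mid - half + 1):min(nb, mid + half)]
  fifth <- nb %/% 5
  flank <- profile$mean[c(seq_len(fifth), (nb - fifth + 1):nb)]
  mean(center) / max(mean(flank), .Machine$double.eps)
}
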