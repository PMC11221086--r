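# End-to-end orchestration of the TE-centric integration analysis on a
# dataset bundle: TE enrichment, genomic annotation, DMR calling and
# quadrant integration, motif enrichment, loop-anchor and loop
# classification with motif orientation, permutation tests, and signal
# profiles — with a consolidated machine-readable summary.

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                              format(Sys.time(), "%H:%M:%S"), ...))
}

#' Run the full TE-centric integration pipeline
#'
#' Executes every analysis stage on a synthetic bundle (generated from
#' `config` unless one is supplied): TE-hierarchy enrichment of up/down
#' differential ATAC peaks by count and cumulative length at all three
#' levels, genomic-annotation enrichment, DMR calling plus quadrant
#' integration against accessibility, CTCF motif enrichment in CTCF-up-B2
#' peaks, loop-anchor classification (NLA/LLA/ULA, Jaccard), loop
#' classification and motif orientation, binned CTCF-peak profiles over
#' anchors, three resampling permutation tests, and a signal profile over
#' up-B2 peaks. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory; when given, one TSV per stage
#'   and `summary.json` are written there.
#' @param bundle optional pre-generated [simulate_dataset()] bundle (its
#'   own config is then used for seeding).
#' @param perm_iter permutation iterations per test (default 200).
#' @param quiet suppress stage messages.
#' @return list of class `pipeline_report` with all stage results and a
#'   `summary` list of scalar key numbers.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         bundle = NULL, perm_iter = 200, quiet = FALSE) {
  if (is.null(bundle)) {
    stage_msg(quiet, "simulate: generating bundle (seed %d)", config$seed)
    bundle <- simulate_dataset(config)
  } else {
    config <- bundle$config
  }
  rule <- overlap_rule(0.5, 0.5, TRUE)
  atac <- bundle$atac
  up <- atac[atac$direction == "up", , drop = FALSE]
  down <- atac[atac$direction == "down", , drop = FALSE]
  stage_msg(quiet, "te_enrichment: %d up / %d down of %d peaks",
            nrow(up), nrow(down), nrow(atac))
  enr <- list()
  for (dirn in c("up", "down")) {
    fg <- if (dirn == "up") up else down
    for (mode in c("count", "length")) {
      for (level in c("te_class", "sine_family", "b2_subtype")) {
        e <- enrich_te(fg, atac, bundle$te, rule, level, mode)
        e$direction <- dirn
        enr[[length(enr) + 1]] <- e
      }
    }
  }
  te_enrichment <- do.call(rbind, enr)

  stage_msg(quiet, "annotation: promoter/gene_body/intergenic enrichment")
  annotation <- enrich_annotation(up, atac, bundle$genes)

  stage_msg(quiet, "methylation: filtering %d CpGs", length(bundle$cpg$pos))
  cpg <- filter_cpgs(bundle$cpg)
  dmrs <- call_dmrs(cpg)
  b2 <- bundle$te[bundle$te$te_family == "B2", , drop = FALSE]
  quad <- quadrant_integration(dmrs, atac, b2, rule)
  stage_msg(quiet, "methylation: %d DMRs (%d hypo), %d quadrant pairs",
            nrow(dmrs), sum(dmrs$status == "hypo"), nrow(quad$pairs))

  ctcf <- bundle$ctcf
  ctcf_up <- ctcf[ctcf$direction == "up", , drop = FALSE]
  up_b2_i <- unique(region_intersect(sort_regions(ctcf_up), sort_regions(b2),
                                     rule)$query_i)
  ctcf_up_b2 <- sort_regions(ctcf_up)[up_b2_i, , drop = FALSE]
  stage_msg(quiet, "motif: %d CTCF-up-B2 peaks vs %d CTCF peaks",
            nrow(ctcf_up_b2), nrow(ctcf))
  motif <- motif_enrichment(ctcf_up_b2, ctcf, bundle$genome, bundle$pwm)

  stage_msg(quiet, "loops: classifying anchors and loops")
  cls <- classify_anchors(bundle$wt_loops, bundle$ko_loops)
  loop_class <- classify_loops(bundle$wt_loops, bundle$ko_loops, cls)
  ko <- bundle$ko_loops
  left <- data.frame(chrom = ko$chrom, start = ko$start1, end = ko$end1)
  right <- data.frame(chrom = ko$chrom, start = ko$start2, end = ko$end2)
  lh <- scan_regions(bundle$pwm, left, bundle$genome)
  rh <- scan_regions(bundle$pwm, right, bundle$genome)
  orientation <- orient_loops(ko, lh, rh)
  nla_profile <- anchor_bin_profile(cls$nla, ctcf_up, n_bins = 100)
  ula_profile <- anchor_bin_profile(cls$ula, ctcf_up, n_bins = 100)
  linked <- link_deg_loops(bundle$degs, bundle$genes, loop_class, ctcf_up_b2)
  stage_msg(quiet, "loops: %d NLA / %d LLA / %d ULA (Jaccard %.3f); %d linked DEGs",
            nrow(cls$nla), nrow(cls$lla), nrow(cls$ula), cls$jaccard,
            length(unique(linked$gene)))

  stage_msg(quiet, "permutation: %d iterations per test", perm_iter)
  atac_up_b2_i <- unique(region_intersect(sort_regions(up), sort_regions(b2),
                                          rule)$query_i)
  atac_up_b2 <- sort_regions(up)[atac_up_b2_i, , drop = FALSE]
  universe_anchors <- sort_regions(rbind(cls$nla[, c("chrom", "start", "end")],
                                         cls$lla[, c("chrom", "start", "end")],
                                         cls$ula[, c("chrom", "start", "end")]))
  tss <- tss_positions(bundle$genes)
  promoters <- sort_regions(data.frame(
    chrom = tss$chrom, start = pmax(0, tss$pos - 3000), end = tss$pos + 3000,
    gene = tss$gene, stringsAsFactors = FALSE))
  deg_prom <- promoters[promoters$gene %in%
                          bundle$degs$gene[bundle$degs$p < 0.05], , drop = FALSE]
  new_anchors <- loop_anchors(loop_class[loop_class$klass == "new", , drop = FALSE])
  perms <- list(
    atac_up_b2_vs_ctcf_up = perm_test(
      atac_up_b2, atac, ctcf_up, "num_overlaps", perm_iter, "greater",
      seed = config$seed + 101L),
    nla_vs_ctcf_up_b2 = perm_test(
      cls$nla[, c("chrom", "start", "end")], universe_anchors, ctcf_up_b2,
      "num_overlaps", perm_iter, "greater", seed = config$seed + 102L),
    deg_prom_vs_new_anchors = perm_test(
      deg_prom[, c("chrom", "start", "end")],
      promoters[, c("chrom", "start", "end")],
      new_anchors[, c("chrom", "start", "end")],
      "num_overlaps", perm_iter, "greater", seed = config$seed + 103L)
  )

  stage_msg(quiet, "profiles: signal over %d up-B2 peaks", nrow(atac_up_b2))
  prof_mat <- compute_matrix(bundle$track, atac_up_b2, flank_up = 1000,
                             flank_down = 1000, body_bins = 50, bin_size = 10,
                             skip_zeros = TRUE,
                             chrom_sizes = vapply(bundle$genome, nchar, 0))
  profile <- mean_profile(prof_mat)

  sub_up_cnt <- te_enrichment[te_enrichment$level == "b2_subtype" &
                                te_enrichment$direction == "up" &
                                te_enrichment$mode == "count", ]
  sub_up_len <- te_enrichment[te_enrichment$level == "b2_subtype" &
                                te_enrichment$direction == "up" &
                                te_enrichment$mode == "length", ]
  top_cnt <- sub_up_cnt[which.min(sub_up_cnt$p_adj), ]
  top_len <- sub_up_len[which.min(sub_up_len$p_adj), ]
  summary <- list(
    n_atac_peaks = nrow(atac), n_atac_up = nrow(up), n_atac_down = nrow(down),
    n_atac_up_b2 = nrow(atac_up_b2),
    top_up_b2_subtype_count = top_cnt$category,
    top_up_b2_subtype_count_fe = top_cnt$fold_enrichment,
    top_up_b2_subtype_count_padj = top_cnt$p_adj,
    top_up_b2_subtype_length = top_len$category,
    top_up_b2_subtype_length_fe = top_len$fold_enrichment,
    top_up_b2_subtype_length_padj = top_len$p_adj,
    n_cpg_retained = length(cpg$pos),
    n_dmr = nrow(dmrs), n_dmr_hypo = sum(dmrs$status == "hypo"),
    n_quadrant_pairs = nrow(quad$pairs),
    q4_b2_fold_enrichment = if (is.null(quad$fisher)) NA else quad$fisher$fold_enrichment,
    q4_b2_p = if (is.null(quad$fisher)) NA else quad$fisher$p,
    n_ctcf_peaks = nrow(ctcf), n_ctcf_up = nrow(ctcf_up),
    n_ctcf_up_b2 = nrow(ctcf_up_b2),
    motif_fg_rate = motif$observed_in / max(1, motif$observed_in + motif$observed_out),
    motif_bg_rate = motif$background_in /
      max(1, motif$background_in + motif$background_out),
    motif_fold_enrichment = motif$fold_enrichment, motif_p = motif$p,
    n_nla = nrow(cls$nla), n_lla = nrow(cls$lla), n_ula = nrow(cls$ula),
    anchor_jaccard = cls$jaccard,
    n_new_loops = sum(loop_class$klass == "new"),
    n_lost_loops = sum(loop_class$klass == "lost"),
    n_unchanged_loops = sum(loop_class$klass == "unchanged"),
    convergent_fraction = orientation$summary$convergent,
    divergent_fraction = orientation$summary$divergent,
    tandem_fraction = orientation$summary$tandem,
    n_unclassified_loops = orientation$summary$n_unclassified,
    nla_profile_center_mean = mean(nla_profile$profile[41:60]),
    ula_profile_center_mean = mean(ula_profile$profile[41:60]),
    n_linked_deg_genes = length(unique(linked$gene)),
    perm_atac_up_b2_ctcf_up_z = perms$atac_up_b2_vs_ctcf_up$z,
    perm_atac_up_b2_ctcf_up_p = perms$atac_up_b2_vs_ctcf_up$p_empirical,
    perm_nla_ctcf_up_b2_z = perms$nla_vs_ctcf_up_b2$z,
    perm_nla_ctcf_up_b2_p = perms$nla_vs_ctcf_up_b2$p_empirical,
    perm_nla_ctcf_up_b2_obs_over_exp = perms$nla_vs_ctcf_up_b2$obs_over_expected,
    perm_deg_new_anchor_z = perms$deg_prom_vs_new_anchors$z,
    perm_deg_new_anchor_p = perms$deg_prom_vs_new_anchors$p_empirical,
    profile_n_regions = nrow(prof_mat$values),
    profile_max = max(profile)
  )
  report <- structure(list(
    bundle = bundle, te_enrichment = te_enrichment, annotation = annotation,
    dmrs = dmrs, quadrant = quad, motif = motif, anchors = cls,
    loop_class = loop_class, orientation = orientation,
    nla_profile = nla_profile, ula_profile = ula_profile,
    linked_degs = linked, permutation = perms, profile = profile,
    summary = summary), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' One TSV per stage plus `summary.json` (stable schema; byte-identical
#' across reruns with the same configuration and seeds).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(report$te_enrichment, "te_enrichment.tsv")
  tsv(report$annotation, "annotation_enrichment.tsv")
  tsv(report$dmrs, "dmrs.tsv")
  tsv(report$quadrant$pairs, "quadrant_pairs.tsv")
  tsv(report$motif, "motif_enrichment.tsv")
  tsv(report$loop_class, "loop_class.tsv")
  tsv(report$orientation$calls, "loop_orientation.tsv")
  tsv(report$linked_degs, "linked_degs.tsv")
  tsv(data.frame(bin = seq_along(report$profile), mean_signal = report$profile),
      "signal_profile.tsv")
  perm_df <- do.call(rbind, lapply(names(report$permutation), function(nm) {
    p <- report$permutation[[nm]]
    data.frame(test = nm, statistic = p$statistic, observed = p$observed,
               null_mean = p$null_mean, null_sd = p$null_sd, z = p$z,
               p_empirical = p$p_empirical, n_iter = p$n_iter,
               stringsAsFactors = FALSE)
  }))
  tsv(perm_df, "permutation_tests.tsv")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  s <- x$summary
  cat(sprintf("  ATAC: %d peaks (%d up, %d down); top up B2 subtype: %s (FE %.2f)\n",
              s$n_atac_peaks, s$n_atac_up, s$n_atac_down,
              s$top_up_b2_subtype_count, s$top_up_b2_subtype_count_fe))
  cat(sprintf("  DMRs: %d (%d hypo); quadrant pairs %d (B2~Q4 FE %.2f)\n",
              s$n_dmr, s$n_dmr_hypo, s$n_quadrant_pairs, s$q4_b2_fold_enrichment))
  cat(sprintf("  Anchors: %d NLA / %d LLA / %d ULA, Jaccard %.3f\n",
              s$n_nla, s$n_lla, s$n_ula, s$anchor_jaccard))
  cat(sprintf("  Loops: %d new, %d lost, %d unchanged; convergent %.2f\n",
              s$n_new_loops, s$n_lost_loops, s$n_unchanged_loops,
              s$convergent_fraction))
  invisible(x)
}
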