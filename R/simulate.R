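# Synthetic-data generator: a toy multi-chromosome genome with a TE
# hierarchy, genes, differential ATAC/CTCF peak tables, per-CpG
# methylation with planted hypomethylated regions, a CTCF-like PWM with
# planted motif instances, WT/KO chromatin loops whose KO-specific anchors
# sit on planted motif-bearing B2 elements, DEGs wired to B2-anchored new
# loops, and a signal track. Every planted signal is recorded in the truth
# labels so downstream recovery can be audited.

#' Default synthetic-dataset configuration
#'
#' The defaults define the study conditions exercised by the test-suite
#' and the acceptance script: a 2 x 5 Mb genome, ~3,000 non-overlapping TE
#' elements with a rodent-style class mix, differential ATAC peaks with a
#' planted odds-ratio-5 up-enrichment on the B3 subtype, CTCF motifs
#' planted in 60% of CTCF-up-B2 peak elements versus 10% elsewhere, 500
#' loops per genotype with a 70% convergent orientation mix, and 50 planted
#' hypomethylated regions at a -0.3 methylation difference with binomial
#' read noise at coverage 10.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_te number of TE elements.
#' @param te_class_mix,sine_family_mix,b2_subtype_mix named proportion
#'   vectors (each sums to 1).
#' @param te_len named list of (min, max) element lengths per class.
#' @param n_genes,gene_len,n_degs gene-model and DEG parameters.
#' @param n_peaks,peak_len,frac_peaks_on_te ATAC peak parameters.
#' @param target_subtype B2 subtype carrying the planted up-enrichment.
#' @param up_odds_ratio planted odds ratio of up-assignment for peaks on
#'   the target subtype versus all other peaks.
#' @param base_up_rate,down_rate baseline direction rates.
#' @param n_ctcf_peaks,ctcf_peak_len,n_ctcf_up_b2 CTCF peak parameters.
#' @param motif_rate_fg,motif_rate_bg planted-motif rates inside
#'   CTCF-up-B2 elements and elsewhere.
#' @param n_loops loops per genotype.
#' @param anchor_width anchor size in bp.
#' @param frac_specific fraction of loops specific to each genotype.
#' @param loop_span (min, max) anchor separation in bp.
#' @param orientation_mix named proportions over convergent / divergent /
#'   tandem.
#' @param n_dmr,dmr_delta,dmr_n_cpg,dmr_cpg_spacing,dmr_frac_b2 planted
#'   hypo-DMR layout: count, methylation difference, CpGs per region,
#'   spacing, and the fraction hosted on B2 elements (the rest sit on
#'   other TE classes).
#' @param n_dmr_hyper planted hyper regions (methylation difference
#'   `-dmr_delta`, hosted on non-B2 TEs), so both methylation directions
#'   and all accessibility quadrants are populated.
#' @param n_null_cpg,meth_baseline,meth_coverage,n_rep methylation noise
#'   model: baseline methylation level, per-sample binomial coverage,
#'   replicates per group.
#' @param n_linked_genes DEGs whose promoters are planted on anchors of
#'   B2-anchored new loops.
#' @return named list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 42,
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
    n_te = 3000,
    te_class_mix = c(SINE = 0.55, LINE = 0.25, LTR = 0.15, DNA = 0.05),
    sine_family_mix = c(B2 = 0.5, B1 = 0.3, ID = 0.1, MIR = 0.1),
    b2_subtype_mix = c(B3 = 0.30, B3A = 0.25, B2_Mm2 = 0.20,
                       B2_Mm1t = 0.15, B2_Mm1a = 0.10),
    te_len = list(SINE = c(120, 220), LINE = c(500, 3000),
                  LTR = c(300, 2000), DNA = c(100, 1000)),
    n_genes = 300, gene_len = c(5000, 50000), n_degs = 60,
    n_peaks = 3000, peak_len = c(200, 600), frac_peaks_on_te = 0.6,
    target_subtype = "B3", up_odds_ratio = 5,
    base_up_rate = 0.08, down_rate = 0.05,
    n_ctcf_peaks = 1500, ctcf_peak_len = c(200, 400), n_ctcf_up_b2 = 300,
    motif_rate_fg = 0.6, motif_rate_bg = 0.1,
    n_loops = 500, anchor_width = 5000, frac_specific = 0.3,
    loop_span = c(2e5, 2e6),
    orientation_mix = c(convergent = 0.7, divergent = 0.1, tandem = 0.2),
    n_dmr = 50, dmr_delta = -0.3, dmr_n_cpg = 10, dmr_cpg_spacing = 15,
    dmr_frac_b2 = 0.7, n_dmr_hyper = 20,
    n_null_cpg = 50000, meth_baseline = 0.9, meth_coverage = 10, n_rep = 2,
    n_linked_genes = 20) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(te_class_mix) - 1) < 1e-9,
            abs(sum(sine_family_mix) - 1) < 1e-9,
            abs(sum(b2_subtype_mix) - 1) < 1e-9,
            abs(sum(orientation_mix) - 1) < 1e-9,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0))
  structure(cfg, class = "synthetic_config")
}

# run `code` under a local seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# allocate exact counts for a proportion vector over n items (largest
# remainders), then shuffle labels
mix_labels <- function(n, mix) {
  raw <- mix * n
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1
  }
  sample(rep(names(mix), k))
}

# place n intervals of the given widths uniformly, non-overlapping with
# `occupied` and with each other; batch rejection sampling
place_nonoverlapping <- function(widths, chrom_sizes, occupied = NULL,
                                 max_rounds = 300) {
  n <- length(widths)
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    stringsAsFactors = FALSE)
  occ <- if (is.null(occupied) || nrow(occupied) == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  } else sort_regions(occupied[, c("chrom", "start", "end")])
  remaining <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (length(remaining) == 0) break
    w <- widths[remaining]
    chrom <- sample(names(chrom_sizes), length(remaining), replace = TRUE,
                    prob = chrom_sizes)
    room <- chrom_sizes[chrom] - w
    if (any(room < 0)) stop("an element is longer than its chromosome")
    start <- floor(runif(length(remaining), 0, room + 1))
    cand <- data.frame(chrom = chrom, start = start, end = start + w,
                       id = remaining, stringsAsFactors = FALSE)
    cand <- cand[order(cand$chrom, cand$start, cand$end, method = "radix"), ]
    if (nrow(occ) > 0) {
      hit <- unique(overlap_pairs(cand[, c("chrom", "start", "end")], occ)$query_i)
      if (length(hit) > 0) cand <- cand[-hit, , drop = FALSE]
    }
    if (nrow(cand) == 0) next
    keep <- logical(nrow(cand))
    cur_chrom <- ""; cur_end <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (cand$chrom[i] != cur_chrom) { cur_chrom <- cand$chrom[i]; cur_end <- -Inf }
      if (cand$start[i] >= cur_end) { keep[i] <- TRUE; cur_end <- cand$end[i] }
    }
    cand <- cand[keep, , drop = FALSE]
    out$chrom[cand$id] <- cand$chrom
    out$start[cand$id] <- cand$start
    out$end[cand$id] <- cand$end
    occ <- sort_regions(rbind(occ, cand[, c("chrom", "start", "end")]))
    remaining <- setdiff(remaining, cand$id)
  }
  if (length(remaining) > 0) {
    stop(sprintf("could not place %d element(s): genome too crowded (reduce counts or lengths)",
                 length(remaining)))
  }
  out
}

clamp_start <- function(start, width, size) pmax(0, pmin(start, size - width))

# CTCF-like 12 bp PWM: dominant base 0.85 per position
ctcf_like_pwm <- function() {
  consensus <- c("C", "C", "A", "C", "T", "A", "G", "G", "T", "G", "G", "C")
  m <- matrix(0.05, nrow = 4, ncol = length(consensus), dimnames = list(BASES, NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 0.85
  pwm(m, name = "CTCF_like")
}

pwm_consensus <- function(x) paste(BASES[apply(x$probs, 2, which.max)], collapse = "")

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' See [synthetic_config()] for the planted signals. Deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle` with elements `genome`
#'   (named character vector of chromosome sequences), `te`, `genes`,
#'   `atac`, `ctcf` (differential region tables), `cpg` (a `cpg_table`),
#'   `pwm`, `wt_loops`, `ko_loops`, `degs`, `track` (bedGraph-style) and
#'   `truth` (planted labels and realized rates).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_bundle(config))
}

generate_bundle <- function(cfg) {
  sizes <- cfg$chrom_sizes
  ## ---- TE annotation -------------------------------------------------
  te_class <- mix_labels(cfg$n_te, cfg$te_class_mix)
  widths <- numeric(cfg$n_te)
  for (cl in names(cfg$te_len)) {
    i <- te_class == cl
    widths[i] <- floor(runif(sum(i), cfg$te_len[[cl]][1], cfg$te_len[[cl]][2] + 1))
  }
  demand <- sum(widths)
  if (demand > 0.8 * sum(sizes)) {
    stop(sprintf("TE bp demand (%s) exceeds 80%% of the genome (%s): infeasible config",
                 format(demand, big.mark = ","), format(sum(sizes), big.mark = ",")))
  }
  te_pos <- place_nonoverlapping(widths, sizes)
  te <- data.frame(chrom = te_pos$chrom, start = te_pos$start, end = te_pos$end,
                   strand = ".", te_class = te_class,
                   te_family = NA_character_, te_subtype = NA_character_,
                   stringsAsFactors = FALSE)
  is_sine <- te$te_class == "SINE"
  te$te_family[is_sine] <- mix_labels(sum(is_sine), cfg$sine_family_mix)
  te$te_family[!is_sine] <- paste0(te$te_class[!is_sine], "_fam")
  is_b2 <- !is.na(te$te_family) & te$te_family == "B2"
  te$te_subtype[is_b2] <- mix_labels(sum(is_b2), cfg$b2_subtype_mix)
  te$te_subtype[!is_b2] <- paste0(te$te_family[!is_b2], "_sub")
  te <- sort_regions(te)
  te$te_id <- seq_len(nrow(te))

  ## ---- motif sites on B2 elements -----------------------------------
  mot <- ctcf_like_pwm()
  w_mot <- mot$width
  b2_idx <- which(te$te_family == "B2")
  if (length(b2_idx) < cfg$n_ctcf_up_b2) stop("not enough B2 elements for n_ctcf_up_b2")
  s_up <- sample(b2_idx, cfg$n_ctcf_up_b2)                 # CTCF-up B2 elements
  n_fg_motif <- round(cfg$motif_rate_fg * length(s_up))
  fg_motif_el <- sample(s_up, n_fg_motif)                  # motif-bearing subset
  bg_b2 <- setdiff(b2_idx, s_up)
  n_bg_motif <- round(cfg$motif_rate_bg * length(bg_b2))
  bg_motif_el <- sample(bg_b2, n_bg_motif)
  motif_el <- c(fg_motif_el, bg_motif_el)
  te$has_motif <- te$te_id %in% motif_el
  te$motif_strand <- NA_character_
  # motif site at the element center; strand for background sites random,
  # for loop-anchor sites set below by the loop orientation draw
  motif_center <- function(i) floor((te$start[i] + te$end[i]) / 2) - floor(w_mot / 2)
  te$motif_strand[bg_motif_el] <- sample(c("+", "-"), length(bg_motif_el), replace = TRUE)

  ## ---- loops ---------------------------------------------------------
  n_shared <- cfg$n_loops - round(cfg$frac_specific * cfg$n_loops)
  n_spec <- cfg$n_loops - n_shared
  aw <- cfg$anchor_width
  half <- floor(aw / 2)
  el_center_all <- floor((te$start + te$end) / 2)
  # per-chromosome sorted registry of reserved anchor intervals (all width
  # aw, mutually non-overlapping), so freeness checks are O(log n)
  reg <- new.env(parent = emptyenv())
  reg_free <- function(chrom, s) {
    e <- s + aw
    if (s < 0 || e > sizes[chrom]) return(FALSE)
    v <- get0(chrom, envir = reg)
    if (is.null(v)) return(TRUE)
    i <- findInterval(s, v$starts)
    if (i >= 1 && v$ends[i] > s) return(FALSE)
    if (i < length(v$starts) && v$starts[i + 1] < e) return(FALSE)
    TRUE
  }
  reg_add <- function(chrom, s) {
    v <- get0(chrom, envir = reg)
    if (is.null(v)) v <- list(starts = numeric(), ends = numeric())
    i <- findInterval(s, v$starts)
    v$starts <- append(v$starts, s, after = i)
    v$ends <- append(v$ends, s + aw, after = i)
    assign(chrom, v, envir = reg)
  }
  reg_del <- function(chrom, s) {
    v <- get(chrom, envir = reg)
    i <- which(v$starts == s)[1]
    v$starts <- v$starts[-i]; v$ends <- v$ends[-i]
    assign(chrom, v, envir = reg)
  }
  draw_partner <- function(chrom, center) {
    for (try in 1:200) {
      span <- floor(runif(1, cfg$loop_span[1], cfg$loop_span[2] + 1))
      dir <- sample(c(-1, 1), 1)
      c2 <- center + dir * span
      if (reg_free(chrom, c2 - half)) return(c2)
    }
    NA_real_
  }
  loop_rows <- list()
  # KO-specific loops: one anchor centered on a motif-bearing CTCF-up B2
  # element (shuffled; elements whose anchor would collide or fall off the
  # chromosome are passed over)
  eligible <- fg_motif_el[el_center_all[fg_motif_el] >= half &
                            el_center_all[fg_motif_el] <=
                              sizes[te$chrom[fg_motif_el]] - half]
  ko_anchor_el <- integer(0)
  for (el in sample(eligible)) {
    if (length(ko_anchor_el) >= n_spec) break
    c1 <- el_center_all[el]
    chrom <- te$chrom[el]
    if (!reg_free(chrom, c1 - half)) next
    reg_add(chrom, c1 - half)
    c2 <- draw_partner(chrom, c1)
    if (is.na(c2)) {
      reg_del(chrom, c1 - half)
      next
    }
    reg_add(chrom, c2 - half)
    ko_anchor_el <- c(ko_anchor_el, el)
    loop_rows[[length(loop_rows) + 1]] <- data.frame(
      chrom = chrom, c1 = c1, c2 = c2, set = "ko_specific",
      anchor_el = el, stringsAsFactors = FALSE)
  }
  if (length(ko_anchor_el) < n_spec) {
    stop("not enough motif-bearing CTCF-up B2 elements to host KO-specific anchors")
  }
  draw_free_loop <- function(set) {
    for (try in 1:500) {
      chrom <- sample(names(sizes), 1, prob = sizes)
      c1 <- floor(runif(1, half, sizes[chrom] - half))
      if (!reg_free(chrom, c1 - half)) next
      reg_add(chrom, c1 - half)
      c2 <- draw_partner(chrom, c1)
      if (is.na(c2)) {
        reg_del(chrom, c1 - half)
        next
      }
      reg_add(chrom, c2 - half)
      return(data.frame(chrom = chrom, c1 = c1, c2 = c2, set = set,
                        anchor_el = NA_integer_, stringsAsFactors = FALSE))
    }
    stop("could not place a loop: genome too crowded")
  }
  for (k in seq_len(n_spec)) loop_rows[[length(loop_rows) + 1]] <- draw_free_loop("wt_specific")
  for (k in seq_len(n_shared)) loop_rows[[length(loop_rows) + 1]] <- draw_free_loop("shared")
  loopdf <- do.call(rbind, loop_rows)
  # orientation truth: exact counts per the mix, shuffled over all loops;
  # strands are assigned in genomic (left/right) order, so convergent
  # means left +, right - regardless of which anchor was placed first
  loopdf$orientation <- mix_labels(nrow(loopdf), cfg$orientation_mix)
  loopdf$left_c <- pmin(loopdf$c1, loopdf$c2)
  loopdf$right_c <- pmax(loopdf$c1, loopdf$c2)
  tandem_strand <- sample(c("+", "-"), nrow(loopdf), replace = TRUE)
  loopdf$left_strand <- ifelse(loopdf$orientation == "convergent", "+",
                        ifelse(loopdf$orientation == "divergent", "-",
                               tandem_strand))
  loopdf$right_strand <- ifelse(loopdf$orientation == "convergent", "-",
                         ifelse(loopdf$orientation == "divergent", "+",
                                tandem_strand))

  ## ---- motif site registry (element sites + anchor sites) ------------
  site <- function(chrom, center, strand) {
    data.frame(chrom = chrom, start = center - floor(w_mot / 2),
               strand = strand, stringsAsFactors = FALSE)
  }
  sites <- list()
  for (i in seq_len(nrow(loopdf))) {
    sites[[length(sites) + 1]] <- site(loopdf$chrom[i], loopdf$left_c[i],
                                       loopdf$left_strand[i])
    sites[[length(sites) + 1]] <- site(loopdf$chrom[i], loopdf$right_c[i],
                                       loopdf$right_strand[i])
  }
  # record the anchor-element motif strands in the TE truth (the element
  # can be the left or the right anchor after canonical ordering)
  spec_rows <- which(loopdf$set == "ko_specific")
  el_of <- loopdf$anchor_el[spec_rows]
  te$motif_strand[el_of] <- ifelse(
    loopdf$left_c[spec_rows] == el_center_all[el_of],
    loopdf$left_strand[spec_rows], loopdf$right_strand[spec_rows])
  # non-anchor motif-bearing foreground elements get a random strand
  loose_fg <- setdiff(fg_motif_el, ko_anchor_el)
  te$motif_strand[loose_fg] <- sample(c("+", "-"), length(loose_fg), replace = TRUE)
  for (i in c(loose_fg, bg_motif_el)) {
    sites[[length(sites) + 1]] <- site(te$chrom[i], motif_center(i) + floor(w_mot / 2),
                                       te$motif_strand[i])
  }
  sitedf <- do.call(rbind, sites)
  sitedf$end <- sitedf$start + w_mot
  # drop duplicate/overlapping later plantings (first writer wins)
  o <- order(sitedf$chrom, sitedf$start)
  sitedf <- sitedf[o, , drop = FALSE]
  keep <- logical(nrow(sitedf)); cur_chrom <- ""; cur_end <- -Inf
  for (i in seq_len(nrow(sitedf))) {
    if (sitedf$chrom[i] != cur_chrom) { cur_chrom <- sitedf$chrom[i]; cur_end <- -Inf }
    if (sitedf$start[i] >= cur_end) { keep[i] <- TRUE; cur_end <- sitedf$end[i] }
  }
  sitedf <- sitedf[keep, , drop = FALSE]

  ## ---- genome sequence ------------------------------------------------
  # i.i.d. uniform bases; motif instances overwritten in the base vector
  # before the (expensive) collapse to one string per chromosome
  cons <- pwm_consensus(mot)
  cons_rc <- revcomp(cons)
  genome <- vapply(names(sizes), function(ch) {
    v <- sample(BASES, sizes[ch], replace = TRUE)
    s <- sitedf[sitedf$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      ins <- if (s$strand[i] == "+") cons else cons_rc
      v[(s$start[i] + 1):(s$start[i] + w_mot)] <- strsplit(ins, "")[[1]]
    }
    paste(v, collapse = "")
  }, "")

  ## ---- ATAC differential peaks ---------------------------------------
  n_on_te <- round(cfg$frac_peaks_on_te * cfg$n_peaks)
  host <- sample(seq_len(nrow(te)), n_on_te, replace = FALSE)
  pw <- floor(runif(cfg$n_peaks, cfg$peak_len[1], cfg$peak_len[2] + 1))
  atac <- data.frame(chrom = character(cfg$n_peaks), start = numeric(cfg$n_peaks),
                     end = numeric(cfg$n_peaks), stringsAsFactors = FALSE)
  ctr <- floor((te$start[host] + te$end[host]) / 2)
  s1 <- clamp_start(ctr - floor(pw[seq_len(n_on_te)] / 2),
                    pw[seq_len(n_on_te)], sizes[te$chrom[host]])
  atac$chrom[seq_len(n_on_te)] <- te$chrom[host]
  atac$start[seq_len(n_on_te)] <- s1
  atac$end[seq_len(n_on_te)] <- s1 + pw[seq_len(n_on_te)]
  rest <- (n_on_te + 1):cfg$n_peaks
  ch <- sample(names(sizes), length(rest), replace = TRUE, prob = sizes)
  st0 <- floor(runif(length(rest), 0, sizes[ch] - pw[rest]))
  atac$chrom[rest] <- ch; atac$start[rest] <- st0; atac$end[rest] <- st0 + pw[rest]
  atac <- sort_regions(atac)
  # planted direction: odds-ratio up-assignment on target-subtype peaks
  target_te <- sort_regions(te[te$te_subtype == cfg$target_subtype &
                                 !is.na(te$te_subtype), , drop = FALSE])
  on_target <- rep(FALSE, nrow(atac))
  on_target[unique(region_intersect(atac, target_te, overlap_rule())$query_i)] <- TRUE
  p0 <- cfg$base_up_rate
  odds1 <- cfg$up_odds_ratio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  dirn <- rep("ns", nrow(atac))
  n_t <- sum(on_target); n_o <- sum(!on_target)
  up_t <- sample(which(on_target), round(p1 * n_t))
  up_o <- sample(which(!on_target), round(p0 * n_o))
  dirn[c(up_t, up_o)] <- "up"
  not_up <- which(dirn == "ns")
  dirn[sample(not_up, round(cfg$down_rate * length(not_up)))] <- "down"
  atac$log2fc <- ifelse(dirn == "up", runif(nrow(atac), 0.7, 2.5),
                 ifelse(dirn == "down", -runif(nrow(atac), 0.7, 2.5),
                        runif(nrow(atac), -0.5, 0.5)))
  atac$fdr <- ifelse(dirn == "ns", runif(nrow(atac), 0.05, 1),
                     runif(nrow(atac), 1e-5, 0.049))
  atac$direction <- classify_direction(atac$log2fc, atac$fdr)
  stopifnot(identical(atac$direction, dirn))

  ## ---- CTCF differential peaks ---------------------------------------
  cw <- floor(runif(cfg$n_ctcf_peaks, cfg$ctcf_peak_len[1], cfg$ctcf_peak_len[2] + 1))
  n_up_b2 <- length(s_up)
  ctcf <- data.frame(chrom = character(cfg$n_ctcf_peaks),
                     start = numeric(cfg$n_ctcf_peaks),
                     end = numeric(cfg$n_ctcf_peaks), stringsAsFactors = FALSE)
  ctr2 <- floor((te$start[s_up] + te$end[s_up]) / 2)
  s2 <- clamp_start(ctr2 - floor(cw[seq_len(n_up_b2)] / 2),
                    cw[seq_len(n_up_b2)], sizes[te$chrom[s_up]])
  ctcf$chrom[seq_len(n_up_b2)] <- te$chrom[s_up]
  ctcf$start[seq_len(n_up_b2)] <- s2
  ctcf$end[seq_len(n_up_b2)] <- s2 + cw[seq_len(n_up_b2)]
  crest <- (n_up_b2 + 1):cfg$n_ctcf_peaks
  ch <- sample(names(sizes), length(crest), replace = TRUE, prob = sizes)
  st0 <- floor(runif(length(crest), 0, sizes[ch] - cw[crest]))
  ctcf$chrom[crest] <- ch; ctcf$start[crest] <- st0; ctcf$end[crest] <- st0 + cw[crest]
  cdir <- c(rep("up", n_up_b2),
            sample(c("up", "down", "ns"), length(crest), replace = TRUE,
                   prob = c(0.05, 0.05, 0.9)))
  ctcf$log2fc <- ifelse(cdir == "up", runif(nrow(ctcf), 0.7, 2.5),
                 ifelse(cdir == "down", -runif(nrow(ctcf), 0.7, 2.5),
                        runif(nrow(ctcf), -0.5, 0.5)))
  ctcf$fdr <- ifelse(cdir == "ns", runif(nrow(ctcf), 0.05, 1),
                     runif(nrow(ctcf), 1e-5, 0.049))
  ctcf <- sort_regions(ctcf)
  ctcf$direction <- classify_direction(ctcf$log2fc, ctcf$fdr)

  ## ---- genes and DEGs -------------------------------------------------
  # genes (other than the deliberately linked ones) keep their promoters
  # clear of the KO-specific (new-loop) anchors so the planted DEG-loop
  # wiring is exactly the reported set
  spec_df <- loopdf[loopdf$set == "ko_specific", , drop = FALSE]
  margin <- 3000 + 1000
  avoid_df <- data.frame(
    chrom = rep(spec_df$chrom, 2),
    start = pmax(0, c(spec_df$left_c, spec_df$right_c) - half - margin),
    end = c(spec_df$left_c, spec_df$right_c) - half + aw + margin,
    stringsAsFactors = FALSE)
  avoid_env <- new.env(parent = emptyenv())
  for (ch in unique(avoid_df$chrom)) {
    a <- avoid_df[avoid_df$chrom == ch, , drop = FALSE]
    m <- region_merge(sort_regions(a))
    assign(ch, list(starts = m$start, ends = m$end), envir = avoid_env)
  }
  clear_of_anchors <- function(chrom, s, e) {
    v <- get0(chrom, envir = avoid_env)
    if (is.null(v)) return(TRUE)
    i <- findInterval(s, v$starts)
    if (i >= 1 && v$ends[i] > s) return(FALSE)
    if (i < length(v$starts) && v$starts[i + 1] < e) return(FALSE)
    TRUE
  }
  gl <- floor(runif(cfg$n_genes, cfg$gene_len[1], cfg$gene_len[2] + 1))
  n_link <- cfg$n_linked_genes
  new_loops_df <- loopdf[loopdf$set == "ko_specific", , drop = FALSE]
  link_loops <- sample(seq_len(nrow(new_loops_df)), n_link)
  genes <- data.frame(chrom = character(cfg$n_genes), start = numeric(cfg$n_genes),
                      end = numeric(cfg$n_genes), strand = sample(c("+", "-"),
                      cfg$n_genes, replace = TRUE),
                      gene = sprintf("gene%03d", seq_len(cfg$n_genes)),
                      stringsAsFactors = FALSE)
  # linked genes: TSS at the centre of the partner (non-element) anchor
  for (j in seq_len(n_link)) {
    L <- new_loops_df[link_loops[j], ]
    # TSS at the centre of the partner (non-element) anchor
    tss <- if (L$left_c == el_center_all[L$anchor_el]) L$right_c else L$left_c
    if (genes$strand[j] == "+") {
      genes$start[j] <- tss; genes$end[j] <- min(tss + gl[j], sizes[L$chrom] - 1)
    } else {
      genes$end[j] <- tss; genes$start[j] <- max(0, tss - gl[j])
    }
    genes$chrom[j] <- L$chrom
  }
  # all other genes: promoters clear of new-loop anchors, >= 10 kb from
  # chromosome edges
  for (j in (n_link + 1):cfg$n_genes) {
    placed <- FALSE
    for (try in 1:300) {
      chrom <- sample(names(sizes), 1, prob = sizes)
      s <- floor(runif(1, 10000, sizes[chrom] - 10000 - gl[j]))
      if (clear_of_anchors(chrom, s - 3000, s + gl[j] + 3000)) {
        genes$chrom[j] <- chrom; genes$start[j] <- s; genes$end[j] <- s + gl[j]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place a gene away from new-loop anchors")
  }
  linked_genes <- genes$gene[seq_len(n_link)]
  other_deg <- sample((n_link + 1):cfg$n_genes, cfg$n_degs - n_link)
  is_deg <- c(seq_len(n_link), other_deg)
  degs <- data.frame(gene = genes$gene,
                     log2fc = stats::rnorm(cfg$n_genes, 0, 1),
                     p = runif(cfg$n_genes, 0.05, 1), stringsAsFactors = FALSE)
  degs$p[is_deg] <- runif(length(is_deg), 1e-6, 0.049)
  genes_sorted <- sort_regions(genes)

  ## ---- loop tables ----------------------------------------------------
  mk_loops <- function(df, genotype) {
    loops(df$chrom, df$left_c - half, df$left_c - half + aw,
          df$right_c - half, df$right_c - half + aw, genotype)
  }
  ko_loops <- mk_loops(loopdf[loopdf$set %in% c("ko_specific", "shared"), ], "KO")
  wt_loops <- mk_loops(loopdf[loopdf$set %in% c("wt_specific", "shared"), ], "WT")

  ## ---- methylation -----------------------------------------------------
  # hypo regions hosted on B2 (preferring elements that also carry an
  # ATAC peak, so the quadrant integration has overlapping pairs); hyper
  # regions on other TE classes from a lower baseline
  span <- (cfg$dmr_n_cpg - 1) * cfg$dmr_cpg_spacing
  wide <- region_width(te) >= span + 4
  pick_hosts <- function(pool, n) {
    if (length(pool) < n) stop("not enough wide TE elements to host planted DMRs")
    preferred <- intersect(pool, host)
    if (length(preferred) >= n) sample(preferred, n)
    else c(preferred, sample(setdiff(pool, preferred), n - length(preferred)))
  }
  n_dmr_b2 <- round(cfg$dmr_frac_b2 * cfg$n_dmr)
  pool_b2 <- setdiff(which(te$te_family == "B2" & wide), s_up)
  pool_other <- which(te$te_family != "B2" & wide)
  hypo_el <- c(pick_hosts(pool_b2, n_dmr_b2),
               pick_hosts(pool_other, cfg$n_dmr - n_dmr_b2))
  hyper_el <- pick_hosts(setdiff(pool_other, hypo_el), cfg$n_dmr_hyper)
  dmr_el <- c(hypo_el, hyper_el)
  dmr_status <- rep(c("hypo", "hyper"), c(length(hypo_el), length(hyper_el)))
  dmr_truth <- data.frame(chrom = te$chrom[dmr_el],
                          start = te$start[dmr_el] + 2,
                          end = te$start[dmr_el] + 2 + span + 1,
                          status = dmr_status, stringsAsFactors = FALSE)
  n_pl <- nrow(dmr_truth)
  cpg_chrom <- rep(dmr_truth$chrom, each = cfg$dmr_n_cpg)
  cpg_pos <- rep(dmr_truth$start, each = cfg$dmr_n_cpg) +
    rep((seq_len(cfg$dmr_n_cpg) - 1) * cfg$dmr_cpg_spacing, n_pl)
  planted <- rep(dmr_truth$status, each = cfg$dmr_n_cpg)
  nch <- sample(names(sizes), cfg$n_null_cpg, replace = TRUE, prob = sizes)
  npos <- floor(runif(cfg$n_null_cpg, 0, sizes[nch]))
  cpg_chrom <- c(cpg_chrom, nch); cpg_pos <- c(cpg_pos, npos)
  planted <- c(planted, rep("none", cfg$n_null_cpg))
  dup <- duplicated(paste(cpg_chrom, cpg_pos))
  cpg_chrom <- cpg_chrom[!dup]; cpg_pos <- cpg_pos[!dup]; planted <- planted[!dup]
  n_cpg <- length(cpg_pos)
  samples <- c(paste0("WT_", seq_len(cfg$n_rep)), paste0("KO_", seq_len(cfg$n_rep)))
  groups <- stats::setNames(rep(c("WT", "KO"), each = cfg$n_rep), samples)
  beta <- matrix(cfg$meth_baseline, nrow = n_cpg, ncol = length(samples),
                 dimnames = list(NULL, samples))
  beta[planted == "hypo", groups == "KO"] <- cfg$meth_baseline + cfg$dmr_delta
  hyper_base <- cfg$meth_baseline + cfg$dmr_delta - 0.1
  beta[planted == "hyper", groups == "WT"] <- hyper_base
  beta[planted == "hyper", groups == "KO"] <- hyper_base - cfg$dmr_delta
  total <- matrix(stats::rpois(n_cpg * length(samples), cfg$meth_coverage),
                  nrow = n_cpg, dimnames = list(NULL, samples))
  meth <- matrix(stats::rbinom(n_cpg * length(samples), as.vector(total),
                               as.vector(beta)),
                 nrow = n_cpg, dimnames = list(NULL, samples))
  cpg <- cpg_table(cpg_chrom, cpg_pos, meth, total, groups)

  ## ---- signal track ----------------------------------------------------
  track <- coverage_track(atac, ifelse(atac$direction == "up", 5, 2))

  ## ---- truth -----------------------------------------------------------
  realized <- list(
    up_rate_target = length(up_t) / max(1, n_t),
    up_rate_other = length(up_o) / max(1, n_o),
    motif_rate_fg = n_fg_motif / length(s_up),
    motif_rate_bg = n_bg_motif / max(1, length(bg_b2)),
    convergent_fraction = mean(loopdf$orientation == "convergent")
  )
  truth <- list(
    target_subtype = cfg$target_subtype,
    peak_direction = atac$direction,
    peak_on_target = on_target,
    ctcf_up_b2_elements = te$te_id %in% s_up,
    motif_elements = te$has_motif,
    motif_strand = te$motif_strand,
    loop_set = loopdf$set,
    loop_orientation = loopdf$orientation,
    loop_left_strand = loopdf$left_strand,
    loop_right_strand = loopdf$right_strand,
    dmr_regions = dmr_truth,
    linked_genes = sort(linked_genes),
    deg_genes = sort(genes$gene[is_deg]),
    realized = realized
  )
  structure(list(config = cfg, genome = genome, te = te,
                 genes = genes_sorted, atac = atac, ctcf = ctcf, cpg = cpg,
                 pwm = mot, wt_loops = wt_loops, ko_loops = ko_loops,
                 degs = degs, track = track, loop_table = loopdf,
                 truth = truth),
            class = "synthetic_bundle")
}

#' Piecewise-constant coverage track from weighted regions
#'
#' Sums region weights over the genome and returns the disjoint non-zero
#' segments (a bedGraph-style table).
#'
#' @param x region table.
#' @param weight per-region weight (recycled).
#' @return region table with a `value` column.
#' @export
coverage_track <- function(x, weight = 1) {
  weight <- rep_len(weight, nrow(x))
  out <- list()
  for (chrom in unique(x$chrom)) {
    i <- x$chrom == chrom
    ev <- data.frame(pos = c(x$start[i], x$end[i]),
                     dw = c(weight[i], -weight[i]))
    ev <- stats::aggregate(dw ~ pos, data = ev, FUN = sum)
    ev <- ev[order(ev$pos), ]
    val <- cumsum(ev$dw)
    n <- nrow(ev)
    if (n < 2) next
    seg <- data.frame(chrom = chrom, start = ev$pos[-n], end = ev$pos[-1],
                      value = val[-n], stringsAsFactors = FALSE)
    seg <- seg[seg$value != 0 & seg$end > seg$start, , drop = FALSE]
    out[[chrom]] <- seg
  }
  if (length(out) == 0) {
    x0 <- regions(character(), numeric(), numeric()); x0$value <- numeric()
    return(x0)
  }
  sort_regions(do.call(rbind, out))
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic_bundle: %d chrom (%s bp), %d TEs, %d genes, ",
                     "%d ATAC peaks, %d CTCF peaks, %d CpGs, %d WT / %d KO loops\n"),
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$te), nrow(x$genes), nrow(x$atac), nrow(x$ctcf),
              length(x$cpg$pos), nrow(x$wt_loops), nrow(x$ko_loops)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Writes every component in its plain-text exchange format: genome FASTA,
#' te_bed annotation, gene TSV, differential ATAC/CTCF tables, CpG table,
#' JASPAR-style PWM, WT/KO BEDPE, DEG TSV, bedGraph track, and the truth
#' labels as JSON.
#'
#' @param bundle a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return named vector of the paths written, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$genome),
                              p("genome.fa"))
  write_te_annotation(bundle$te, p("te.bed"))
  write_genes(bundle$genes, p("genes.tsv"))
  write_diff_table(bundle$atac, p("atac_diff.tsv"))
  write_diff_table(bundle$ctcf, p("ctcf_diff.tsv"))
  write_cpg_table(bundle$cpg, p("cpg.tsv"))
  write_pwm(bundle$pwm, p("motif.pfm"))
  write_loops(bundle$wt_loops, p("wt_loops.bedpe"))
  write_loops(bundle$ko_loops, p("ko_loops.bedpe"))
  con <- file(p("degs.tsv"), "w", encoding = "UTF-8")
  writeLines("#gene\tlog2fc\tp", con)
  writeLines(paste(bundle$degs$gene, format(bundle$degs$log2fc, trim = TRUE),
                   format(bundle$degs$p, trim = TRUE), sep = "\t"), con)
  close(con)
  write_bedgraph(bundle$track, p("track.bedgraph"))
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(genome = p("genome.fa"), te = p("te.bed"), genes = p("genes.tsv"),
              atac = p("atac_diff.tsv"), ctcf = p("ctcf_diff.tsv"),
              cpg = p("cpg.tsv"), pwm = p("motif.pfm"),
              wt_loops = p("wt_loops.bedpe"), ko_loops = p("ko_loops.bedpe"),
              degs = p("degs.tsv"), track = p("track.bedgraph"),
              truth = p("truth.json")))
}
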