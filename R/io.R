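# Readers and writers for the plain-text formats the pipeline consumes.
# Everything is normalized to 0-based half-open coordinates on the way in.

read_table_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^(track|browser)\\b", lines) & nzchar(lines)
  lines[keep]
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Classify differential direction from fold-change and FDR
#'
#' A region is `up` iff `fdr < alpha` and `log2fc >= tau`, `down` iff
#' `fdr < alpha` and `log2fc <= -tau`, otherwise `ns`. Defaults follow the
#' common differential-peak thresholds FDR < 0.05 and |log2FC| >= 0.585
#' (i.e. a 1.5-fold change).
#'
#' @param log2fc numeric log2 fold-changes (KO/WT convention).
#' @param fdr numeric FDR values in \[0, 1\].
#' @param alpha FDR threshold (default 0.05).
#' @param tau absolute log2 fold-change threshold (default 0.585).
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
classify_direction <- function(log2fc, fdr, alpha = 0.05, tau = 0.585) {
  ifelse(fdr < alpha & log2fc >= tau, "up",
         ifelse(fdr < alpha & log2fc <= -tau, "down", "ns"))
}

#' Read a region file (BED, narrowPeak, or differential-peak table)
#'
#' `bed` accepts BED3-BED6; `narrowPeak` the 10-column ENCODE layout;
#' `diff_table` a headered TSV with at least `chrom`, `start`, `end`,
#' `log2fc`, `fdr` columns (leading `#` on the header allowed), from which
#' the differential direction is assigned with [classify_direction()].
#' `track`/`browser` lines and `#` comment lines are skipped.
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"diff_table"`.
#' @param alpha,tau direction thresholds for `diff_table` (see
#'   [classify_direction()]).
#' @return sorted region table; for `diff_table` with extra columns
#'   `log2fc`, `fdr`, `direction`.
#' @export
read_regions <- function(path, format = c("bed", "narrowPeak", "diff_table"),
                         alpha = 0.05, tau = 0.585) {
  format <- match.arg(format)
  lines <- read_table_lines(path)
  if (format == "diff_table") {
    # header is the first line; a leading '#' is stripped
    header <- sub("^#", "", lines[1])
    cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
    need <- c("chrom", "start", "end", "log2fc", "fdr")
    miss <- setdiff(need, cols)
    if (length(miss) > 0) {
      stop(sprintf("diff_table %s: missing column(s) %s", path,
                   paste(miss, collapse = ", ")))
    }
    body <- lines[-1]
    body <- body[!grepl("^#", body)]
    if (length(body) == 0) {
      x <- regions(character(), numeric(), numeric())
      x$log2fc <- numeric()
      x$fdr <- numeric()
      x$direction <- character()
      return(x)
    }
    f <- split_fields(body)
    m <- do.call(rbind, f)
    colnames(m) <- cols[seq_len(ncol(m))]
    x <- data.frame(
      chrom = m[, "chrom"],
      start = as.numeric(m[, "start"]),
      end = as.numeric(m[, "end"]),
      strand = ".",
      name = if ("name" %in% cols) m[, "name"] else NA_character_,
      score = NA_real_,
      log2fc = as.numeric(m[, "log2fc"]),
      fdr = as.numeric(m[, "fdr"]),
      stringsAsFactors = FALSE
    )
    x$direction <- classify_direction(x$log2fc, x$fdr, alpha = alpha, tau = tau)
    validate_regions(x, what = sprintf("diff_table %s", path))
    return(sort_regions(x))
  }
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) return(regions(character(), numeric(), numeric()))
  f <- split_fields(lines)
  ncol_min <- if (format == "narrowPeak") 10L else 3L
  nf <- lengths(f)
  if (any(nf < ncol_min)) {
    stop(sprintf("%s line %d: expected >= %d columns, got %d",
                 path, which(nf < ncol_min)[1], ncol_min, min(nf)))
  }
  get <- function(i) vapply(f, function(r) if (length(r) >= i) r[i] else NA_character_, "")
  x <- data.frame(
    chrom = get(1), start = as.numeric(get(2)), end = as.numeric(get(3)),
    stringsAsFactors = FALSE
  )
  nm <- get(4); sc <- get(5); st <- get(6)
  x$strand <- ifelse(is.na(st) | !(st %in% c("+", "-")), ".", st)
  x$name <- ifelse(is.na(nm) | nm == ".", NA_character_, nm)
  x$score <- suppressWarnings(as.numeric(ifelse(is.na(sc) | sc == ".", NA, sc)))
  x <- x[, c("chrom", "start", "end", "strand", "name", "score")]
  if (format == "narrowPeak") {
    x$signal_value <- as.numeric(get(7))
    x$p_value <- as.numeric(get(8))
    x$q_value <- as.numeric(get(9))
    x$peak <- as.numeric(get(10))
  }
  validate_regions(x, what = path)
  sort_regions(x)
}

#' Write a region table as BED6 (or wider) TSV
#'
#' Emits a single `#`-prefixed header line followed by tab-separated rows;
#' `NA` name/score become `.`. Reading the file back with [read_regions()]
#' reproduces the records.
#'
#' @param x region table.
#' @param path output path.
#' @param extra_cols additional column names of `x` to append after BED6.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path, extra_cols = character()) {
  validate_regions(x)
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), ".", format(x$score, trim = TRUE, scientific = FALSE)) else "."
  cols <- c("chrom", "start", "end", "name", "score", "strand", extra_cols)
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, trim = TRUE, scientific = FALSE),
    end = format(x$end, trim = TRUE, scientific = FALSE),
    name = rep_len(name, nrow(x)), score = rep_len(score, nrow(x)),
    strand = rep_len(strand, nrow(x)), stringsAsFactors = FALSE
  )
  for (cc in extra_cols) out[[cc]] <- x[[cc]]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Write a differential-region table
#'
#' Headered TSV (`#chrom start end log2fc fdr`) readable with
#' `read_regions(format = "diff_table")`; the direction column is not
#' written because it is derived from the thresholds on read.
#'
#' @param x region table with `log2fc` and `fdr` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tlog2fc\tfdr", con)
  if (nrow(x) > 0) {
    fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
    writeLines(paste(x$chrom, fmt(x$start), fmt(x$end),
                     format(x$log2fc, trim = TRUE),
                     format(x$fdr, trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a TE annotation (te_bed or RepeatMasker .out)
#'
#' `te_bed` has columns chrom, start, end, te_class, te_family, te_subtype
#' (0-based half-open). `repeatmasker_out` is the standard 15-column
#' RepeatMasker layout (two header lines, 1-based begin, strand `C` for
#' complement); its "class/family" string is split on `/` into
#' te_class/te_family (a record-level warning is raised and family set to
#' the class when there is no `/`), and the repeat name becomes te_subtype.
#'
#' @param path file path.
#' @param format `"te_bed"` or `"repeatmasker_out"`.
#' @return sorted region table with `te_class`, `te_family`, `te_subtype`.
#' @export
read_te_annotation <- function(path, format = c("te_bed", "repeatmasker_out")) {
  format <- match.arg(format)
  lines <- read_table_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (format == "te_bed") {
    if (length(lines) == 0) {
      x <- regions(character(), numeric(), numeric())
      x$te_class <- x$te_family <- x$te_subtype <- character()
      return(x)
    }
    f <- split_fields(lines)
    if (any(lengths(f) < 6)) {
      stop(sprintf("%s: te_bed needs 6 columns (chrom start end class family subtype)", path))
    }
    m <- do.call(rbind, lapply(f, function(r) r[1:6]))
    x <- data.frame(
      chrom = m[, 1], start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
      strand = ".", name = NA_character_, score = NA_real_,
      te_class = m[, 4], te_family = m[, 5], te_subtype = m[, 6],
      stringsAsFactors = FALSE
    )
  } else {
    # RepeatMasker .out: skip the 2 banner lines + blank; whitespace-separated
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    raw <- raw[!grepl("^\\s*(SW|score)\\b", raw)]
    if (length(raw) == 0) {
      x <- regions(character(), numeric(), numeric())
      x$te_class <- x$te_family <- x$te_subtype <- character()
      return(x)
    }
    f <- strsplit(trimws(raw), "\\s+")
    if (any(lengths(f) < 11)) {
      stop(sprintf("%s: RepeatMasker rows need >= 11 fields", path))
    }
    m <- do.call(rbind, lapply(f, function(r) r[1:11]))
    clsfam <- m[, 11]
    has_slash <- grepl("/", clsfam, fixed = TRUE)
    if (any(!has_slash)) {
      warning(sprintf("%s: %d record(s) with unsplittable class/family; family set to class",
                      path, sum(!has_slash)))
    }
    te_class <- ifelse(has_slash, sub("/.*$", "", clsfam), clsfam)
    te_family <- ifelse(has_slash, sub("^[^/]*/", "", clsfam), clsfam)
    x <- data.frame(
      chrom = m[, 5],
      start = as.numeric(m[, 6]) - 1,  # 1-based begin -> 0-based
      end = as.numeric(m[, 7]),
      strand = ifelse(m[, 9] == "C", "-", "+"),
      name = m[, 10], score = as.numeric(m[, 1]),
      te_class = te_class, te_family = te_family, te_subtype = m[, 10],
      stringsAsFactors = FALSE
    )
  }
  bad <- !nzchar(x$te_class) | !nzchar(x$te_family) | !nzchar(x$te_subtype)
  if (any(bad)) stop(sprintf("%s: empty TE hierarchy field at row %d", path, which(bad)[1]))
  validate_regions(x, what = path)
  sort_regions(x)
}

#' Write a TE annotation as te_bed
#' @param x TE region table with te_class/te_family/te_subtype.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tte_class\tte_family\tte_subtype", con)
  if (nrow(x) > 0) {
    writeLines(paste(x$chrom, format(x$start, trim = TRUE, scientific = FALSE),
                     format(x$end, trim = TRUE, scientific = FALSE),
                     x$te_class, x$te_family, x$te_subtype, sep = "\t"), con)
  }
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Anchors are canonically ordered on read (left anchor starts before the
#' right anchor). Inter-chromosomal rows are skipped with a warning that
#' reports the skipped count. The genotype is taken from column 7 when
#' present, else from the `genotype` argument.
#'
#' @param path BEDPE path (>= 6 columns).
#' @param genotype genotype label applied when the file has no 7th column.
#' @return data.frame with `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `genotype`, sorted by (chrom, start1, start2).
#' @export
read_loops <- function(path, genotype = NA_character_) {
  lines <- read_table_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start1 = numeric(), end1 = numeric(),
                      start2 = numeric(), end2 = numeric(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  f <- split_fields(lines)
  if (any(lengths(f) < 6)) {
    stop(sprintf("%s line %d: BEDPE needs >= 6 columns", path, which(lengths(f) < 6)[1]))
  }
  m <- do.call(rbind, lapply(f, function(r) r[1:6]))
  gt <- vapply(f, function(r) if (length(r) >= 7) r[7] else genotype, "")
  x <- data.frame(
    chrom1 = m[, 1], start1 = as.numeric(m[, 2]), end1 = as.numeric(m[, 3]),
    chrom2 = m[, 4], start2 = as.numeric(m[, 5]), end2 = as.numeric(m[, 6]),
    genotype = gt, stringsAsFactors = FALSE
  )
  bad_coord <- x$start1 >= x$end1 | x$start2 >= x$end2
  if (any(bad_coord)) {
    stop(sprintf("%s line %d: anchor with start >= end", path, which(bad_coord)[1]))
  }
  inter <- x$chrom1 != x$chrom2
  if (any(inter)) {
    warning(sprintf("%s: skipped %d inter-chromosomal loop(s)", path, sum(inter)))
    x <- x[!inter, , drop = FALSE]
  }
  loops(x$chrom1, x$start1, x$end1, x$start2, x$end2, x$genotype)
}

#' Construct a loop table with canonical anchor ordering
#'
#' @param chrom chromosome (both anchors; intra-chromosomal only).
#' @param start1,end1,start2,end2 anchor coordinates (0-based half-open).
#' @param genotype genotype label per loop (e.g. `"WT"`, `"KO"`).
#' @return sorted loop data.frame; anchors swapped where needed so that
#'   `start1 < start2` (ties broken by end).
#' @export
loops <- function(chrom, start1, end1, start2, end2, genotype = NA_character_) {
  swap <- start2 < start1 | (start2 == start1 & end2 < end1)
  s1 <- ifelse(swap, start2, start1); e1 <- ifelse(swap, end2, end1)
  s2 <- ifelse(swap, start1, start2); e2 <- ifelse(swap, end1, end2)
  x <- data.frame(chrom = as.character(chrom), start1 = s1, end1 = e1,
                  start2 = s2, end2 = e2,
                  genotype = rep_len(as.character(genotype), length(chrom)),
                  stringsAsFactors = FALSE)
  if (nrow(x) > 0) {
    stopifnot(all(x$start1 < x$end1), all(x$start2 < x$end2))
  }
  x <- x[order(x$chrom, x$start1, x$start2, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write loops as BEDPE
#' @param x loop table from [loops()] / [read_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tgenotype", con)
  if (nrow(x) > 0) {
    fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
    writeLines(paste(x$chrom, fmt(x$start1), fmt(x$end1),
                     x$chrom, fmt(x$start2), fmt(x$end2), x$genotype, sep = "\t"), con)
  }
  invisible(path)
}

#' Extract the anchors of a loop table as a region table
#' @param x loop table.
#' @param side `"both"` (default), `"left"` or `"right"`.
#' @return region table of anchors with a `loop_id` column (row index in
#'   `x`) and a `side` column.
#' @export
loop_anchors <- function(x, side = c("both", "left", "right")) {
  side <- match.arg(side)
  left <- data.frame(chrom = x$chrom, start = x$start1, end = x$end1,
                     loop_id = seq_len(nrow(x)), side = "left",
                     stringsAsFactors = FALSE)
  right <- data.frame(chrom = x$chrom, start = x$start2, end = x$end2,
                      loop_id = seq_len(nrow(x)), side = "right",
                      stringsAsFactors = FALSE)
  out <- switch(side, both = rbind(left, right), left = left, right = right)
  out$strand <- "."
  sort_regions(out)
}

#' Read a per-CpG methylation count table
#'
#' Format: headered TSV with columns `chrom`, `pos` (0-based CpG position)
#' and, per sample, `<sample>.meth` and `<sample>.total` read counts. The
#' group map assigns each sample to WT or KO.
#'
#' @param path file path.
#' @param groups named character vector, `sample -> "WT"|"KO"`, covering
#'   every sample in the header.
#' @return object of class `cpg_table`: list with `chrom`, `pos` (sorted),
#'   integer matrices `meth` and `total` (CpGs x samples) and the `groups`
#'   vector.
#' @export
read_cpg_table <- function(path, groups) {
  lines <- read_table_lines(path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (!all(c("chrom", "pos") %in% cols)) {
    stop(sprintf("%s: CpG table needs 'chrom' and 'pos' columns", path))
  }
  meth_cols <- grep("\\.meth$", cols, value = TRUE)
  samples <- sub("\\.meth$", "", meth_cols)
  if (length(samples) == 0) stop(sprintf("%s: no '<sample>.meth' columns", path))
  total_cols <- paste0(samples, ".total")
  if (!all(total_cols %in% cols)) {
    stop(sprintf("%s: missing total column(s) %s", path,
                 paste(setdiff(total_cols, cols), collapse = ", ")))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    warning(sprintf("%s: empty CpG table", path))
    return(cpg_table(character(), numeric(),
                     matrix(0L, 0, length(samples), dimnames = list(NULL, samples)),
                     matrix(0L, 0, length(samples), dimnames = list(NULL, samples)),
                     groups))
  }
  f <- split_fields(body)
  m <- do.call(rbind, f)
  colnames(m) <- cols[seq_len(ncol(m))]
  meth <- matrix(as.integer(m[, meth_cols, drop = FALSE]), ncol = length(samples),
                 dimnames = list(NULL, samples))
  total <- matrix(as.integer(m[, total_cols, drop = FALSE]), ncol = length(samples),
                  dimnames = list(NULL, samples))
  cpg_table(m[, "chrom"], as.numeric(m[, "pos"]), meth, total, groups)
}

#' Construct a per-CpG count object
#'
#' @param chrom,pos CpG coordinates (0-based).
#' @param meth,total integer matrices of methylated / total read counts,
#'   one column per sample (matching column names).
#' @param groups named character vector `sample -> "WT"|"KO"`.
#' @return `cpg_table` object, sorted by (chrom, pos).
#' @export
cpg_table <- function(chrom, pos, meth, total, groups) {
  samples <- colnames(meth)
  if (is.null(samples) || !identical(samples, colnames(total))) {
    stop("meth/total must have matching sample column names")
  }
  missing_group <- setdiff(samples, names(groups))
  if (length(missing_group) > 0) {
    stop(sprintf("sample(s) without group assignment: %s",
                 paste(missing_group, collapse = ", ")))
  }
  groups <- groups[samples]
  if (!all(groups %in% c("WT", "KO"))) stop("groups must be 'WT' or 'KO'")
  if (!all(table(factor(groups, levels = c("WT", "KO"))) >= 1)) {
    stop("need at least one sample per group")
  }
  if (any(meth > total)) {
    stop(sprintf("methylated > total at CpG row %d", which(rowSums(meth > total) > 0)[1]))
  }
  if (any(meth < 0) || any(total < 0)) stop("negative read counts")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate CpG position: %s", key[which(duplicated(key))[1]]))
  }
  o <- order(chrom, pos, method = "radix")
  structure(list(chrom = as.character(chrom)[o], pos = as.numeric(pos)[o],
                 meth = meth[o, , drop = FALSE], total = total[o, , drop = FALSE],
                 groups = groups),
            class = "cpg_table")
}

#' @export
print.cpg_table <- function(x, ...) {
  cat(sprintf("cpg_table: %d CpGs, %d samples (%s)\n", length(x$pos),
              ncol(x$meth), paste(sprintf("%s=%s", colnames(x$meth), x$groups),
                                  collapse = ", ")))
  invisible(x)
}

#' Write a per-CpG count table
#' @param x `cpg_table` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  samples <- colnames(x$meth)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#chrom\tpos\t",
                    paste(c(rbind(paste0(samples, ".meth"), paste0(samples, ".total"))),
                          collapse = "\t")), con)
  if (length(x$pos) > 0) {
    cells <- matrix("", nrow = length(x$pos), ncol = 2 * length(samples))
    cells[, seq(1, ncol(cells), 2)] <- format(x$meth, trim = TRUE)
    cells[, seq(2, ncol(cells), 2)] <- format(x$total, trim = TRUE)
    writeLines(paste(x$chrom, format(x$pos, trim = TRUE, scientific = FALSE),
                     apply(cells, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path bedGraph path (chrom, start, end, value; `track` lines skipped).
#' @return sorted region table with a `value` column.
#' @export
read_bedgraph <- function(path) {
  lines <- read_table_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    x <- regions(character(), numeric(), numeric()); x$value <- numeric(); return(x)
  }
  f <- split_fields(lines)
  if (any(lengths(f) < 4)) stop(sprintf("%s: bedGraph needs 4 columns", path))
  m <- do.call(rbind, lapply(f, function(r) r[1:4]))
  x <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                  end = as.numeric(m[, 3]), value = as.numeric(m[, 4]),
                  stringsAsFactors = FALSE)
  validate_regions(x, what = path)
  sort_regions(x)
}

#' Write a bedGraph signal track
#' @param x region table with a `value` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tvalue", con)
  if (nrow(x) > 0) {
    fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
    writeLines(paste(x$chrom, fmt(x$start), fmt(x$end), fmt(x$value), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene model table
#'
#' Headered TSV with columns `chrom`, `start`, `end`, `strand`, `gene`.
#' TSS is `start` for `+` genes and `end` for `-` genes.
#'
#' @param path file path.
#' @return sorted region table with a `gene` column; strand is mandatory.
#' @export
read_genes <- function(path) {
  lines <- read_table_lines(path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "start", "end", "strand", "gene")
  if (!all(need %in% cols)) {
    stop(sprintf("%s: gene table needs columns %s", path, paste(need, collapse = ", ")))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    x <- regions(character(), numeric(), numeric()); x$gene <- character(); return(x)
  }
  m <- do.call(rbind, split_fields(body))
  colnames(m) <- cols[seq_len(ncol(m))]
  x <- data.frame(chrom = m[, "chrom"], start = as.numeric(m[, "start"]),
                  end = as.numeric(m[, "end"]), strand = m[, "strand"],
                  gene = m[, "gene"], stringsAsFactors = FALSE)
  if (!all(x$strand %in% c("+", "-"))) {
    stop(sprintf("%s: every gene needs strand '+' or '-'", path))
  }
  validate_regions(x, what = path)
  sort_regions(x)
}

#' Write a gene model table
#' @param x gene region table (chrom, start, end, strand, gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tstrand\tgene", con)
  if (nrow(x) > 0) {
    fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
    writeLines(paste(x$chrom, fmt(x$start), fmt(x$end), x$strand, x$gene, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' Headered TSV with columns `gene`, `log2fc`, `p`. DEG status is assigned
#' as `p < alpha` (default 0.05).
#'
#' @param path file path.
#' @param alpha DEG p-value threshold.
#' @return data.frame with `gene`, `log2fc`, `p`, `is_deg`.
#' @export
read_deg_table <- function(path, alpha = 0.05) {
  lines <- read_table_lines(path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% cols)) {
    stop(sprintf("%s: DEG table needs columns %s", path, paste(need, collapse = ", ")))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    return(data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      is_deg = logical(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, split_fields(body))
  colnames(m) <- cols[seq_len(ncol(m))]
  data.frame(gene = m[, "gene"], log2fc = as.numeric(m[, "log2fc"]),
             p = as.numeric(m[, "p"]),
             is_deg = as.numeric(m[, "p"]) < alpha, stringsAsFactors = FALSE)
}
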