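# Log-odds PWM scanning with strand-aware best-hit reporting (max-score
# convention) and motif enrichment of one region set against another.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x width numeric matrix (rows A, C, G, T) of counts or
#'   probabilities. Columns are scaled to probabilities, then a pseudocount
#'   is added per cell and each column renormalized, so every probability
#'   is strictly positive.
#' @param background background base frequencies (A, C, G, T), summing
#'   to 1; default uniform.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @param name motif name.
#' @return object of class `pwm` with `probs`, `logodds` (log2
#'   probability over background), `width`, `background`, `name`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.01,
                name = "motif") {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 1, all(mat >= 0), pseudocount > 0,
            length(background) == 4, abs(sum(background) - 1) < 1e-6,
            all(background > 0))
  rownames(mat) <- BASES
  probs <- sweep(mat, 2, colSums(mat), "/")
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  structure(list(probs = probs, logodds = log2(probs / background),
                 width = ncol(mat), background = background, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, max score %.2f bits\n", x$name, x$width,
              pwm_max_score(x)))
  invisible(x)
}

#' Maximum attainable PWM log-odds score
#' @param x a [pwm()].
#' @return numeric scalar (sum over positions of the best base's log-odds).
#' @export
pwm_max_score <- function(x) sum(apply(x$logodds, 2, max))

#' Read a JASPAR-style PWM text file
#'
#' Accepts the JASPAR layout: an optional `>name` line followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path file path.
#' @param ... passed to [pwm()] (background, pseudocount).
#' @return a [pwm()] object.
#' @export
read_pwm <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (grepl("^>", lines[1])) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop(sprintf("%s: expected 4 base rows", path))
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    base <- NA_character_
    if (parts[1] %in% BASES) { base <- parts[1]; parts <- parts[-1] }
    list(base = base, vals = as.numeric(parts))
  })
  bases <- vapply(rows, function(r) r$base, "")
  m <- do.call(rbind, lapply(rows, function(r) r$vals))
  if (!any(is.na(bases))) m <- m[match(BASES, bases), , drop = FALSE]
  pwm(m, name = name, ...)
}

#' Write a PWM in JASPAR-style text
#' @param x a [pwm()].
#' @param path output path.
#' @param counts optional 4 x width count matrix to write instead of the
#'   probabilities.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path, counts = NULL) {
  m <- if (is.null(counts)) x$probs else counts
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  for (i in 1:4) {
    writeLines(sprintf("%s [ %s ]", BASES[i],
                       paste(format(m[i, ], trim = TRUE, digits = 15),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x character scalar over A, C, G, T, N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Per-window log-odds scores on the + orientation of `seq_codes` (integer
# codes 1..4, NA for N); windows containing NA score NA.
window_scores <- function(codes, logodds) {
  w <- ncol(logodds)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  s <- rep(0, n)
  for (j in seq_len(w)) {
    s <- s + logodds[, j][codes[j:(j + n - 1)]]
  }
  s
}

#' Best PWM hit in a sequence (both strands)
#'
#' Scores every window of the sequence on both strands with the PWM's log2
#' odds (the minus strand scores the reverse complement) and reports the
#' single best hit. Windows containing `N` are skipped. Ties are broken by
#' smaller offset, then by `+` strand.
#'
#' @param x a [pwm()].
#' @param sequence character scalar over A, C, G, T, N (case-insensitive).
#' @param threshold pass threshold on the best score; default 80% of the
#'   maximum attainable score.
#' @return list with `best_score`, `strand` (`"+"`/`"-"`, `NA` when every
#'   window contains an N), `offset` (0-based start of the hit within the
#'   sequence) and `passes`.
#' @export
scan_best <- function(x, sequence, threshold = 0.8 * pwm_max_score(x)) {
  stopifnot(inherits(x, "pwm"), is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < x$width) stop(sprintf("sequence (%d bp) shorter than motif (%d bp)", n, x$width))
  codes <- match(strsplit(sequence, "")[[1]], BASES)
  fwd <- window_scores(codes, x$logodds)
  rc_codes <- rev(5L - codes)  # A<->T, C<->G; NA stays NA
  rev_raw <- window_scores(rc_codes, x$logodds)
  # hit at offset i (0-based) on '-' strand = window i of the original
  # sequence scored on the reverse complement: rc window index n-w-i
  rev_s <- rev(rev_raw)
  cand <- data.frame(
    offset = c(seq_along(fwd), seq_along(rev_s)) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev_s))),
    score = c(fwd, rev_s), stringsAsFactors = FALSE
  )
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(best_score = NA_real_, strand = NA_character_,
                offset = NA_integer_, passes = FALSE))
  }
  # best score; ties -> smaller offset, then '+' strand
  cand <- cand[order(-cand$score, cand$offset, cand$strand), , drop = FALSE]
  best <- cand[1, ]
  list(best_score = best$score, strand = best$strand,
       offset = as.integer(best$offset), passes = best$score >= threshold)
}

#' Extract region sequences from a genome
#'
#' @param x region table.
#' @param genome named `Biostrings::DNAStringSet` (or a named character
#'   vector of chromosome sequences).
#' @return character vector of sequences, one per region.
#' @export
region_sequences <- function(x, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  vapply(seq_len(nrow(x)), function(i) {
    chrom <- x$chrom[i]
    if (!(chrom %in% names(genome))) {
      stop(sprintf("chromosome '%s' not in genome", chrom))
    }
    L <- length(genome[[chrom]])
    if (x$start[i] < 0 || x$end[i] > L) {
      stop(sprintf("region %s:%s-%s outside genome bounds (length %d)",
                   chrom, format(x$start[i], scientific = FALSE),
                   format(x$end[i], scientific = FALSE), L))
    }
    as.character(Biostrings::subseq(genome[[chrom]], x$start[i] + 1, x$end[i]))
  }, "")
}

#' Best PWM hit per region
#'
#' @param x a [pwm()].
#' @param regions region table.
#' @param genome named `DNAStringSet` or character vector.
#' @param threshold pass threshold (default 80% of the PWM maximum).
#' @return data.frame with one row per region: `best_score`, `strand`,
#'   `offset`, `passes`.
#' @export
scan_regions <- function(x, regions, genome,
                         threshold = 0.8 * pwm_max_score(x)) {
  seqs <- region_sequences(regions, genome)
  hits <- lapply(seqs, function(s) scan_best(x, s, threshold))
  data.frame(
    best_score = vapply(hits, function(h) h$best_score, 0),
    strand = vapply(hits, function(h) h$strand, ""),
    offset = vapply(hits, function(h) as.integer(h$offset), 0L),
    passes = vapply(hits, function(h) h$passes, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Motif enrichment of a foreground region set over a background
#'
#' Fisher's exact test on {contains a passing hit, does not} x
#' {foreground, background excluding foreground}.
#'
#' @param foreground,background region tables; foreground regions present
#'   in the background (by coordinates) are removed from the background
#'   side of the table.
#' @param genome named `DNAStringSet` or character vector.
#' @param x a [pwm()].
#' @param threshold pass threshold (default 80% of the PWM maximum).
#' @return data.frame row: cells, `fold_enrichment` (foreground hit rate
#'   over background-set hit rate), `odds_ratio`, `p`.
#' @export
motif_enrichment <- function(foreground, background, genome, x,
                             threshold = 0.8 * pwm_max_score(x)) {
  fg_hit <- scan_regions(x, foreground, genome, threshold)$passes
  bg <- background[!(region_key(background) %in% region_key(foreground)), ,
                   drop = FALSE]
  bg_hit <- if (nrow(bg) > 0) scan_regions(x, bg, genome, threshold)$passes else logical(0)
  a <- sum(fg_hit); b <- length(fg_hit) - a
  cc <- sum(bg_hit); d <- length(bg_hit) - cc
  ft <- fisher_test(a, b, cc, d)
  all_in <- a + cc; all_n <- length(fg_hit) + length(bg_hit)
  fe <- if (all_in > 0 && length(fg_hit) > 0) {
    (a / length(fg_hit)) / (all_in / all_n)
  } else NA_real_
  data.frame(observed_in = a, observed_out = b, background_in = cc,
             background_out = d, fold_enrichment = fe,
             odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
}
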