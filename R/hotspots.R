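# Sliding-window detection of GWAS hotspots: genomic regions carrying
# trait-associated loci for several wax traits, within or across classes.

#' Sliding-window locus counts
#'
#' Tiles every chromosome with windows of `window_bp` whose starts advance
#' by `step_frac * window_bp`, and counts in each window the loci (peak
#' SNPs) whose position falls inside it. Windows are 0-based half-open
#' `[start, start + window_bp)`; a 1-based peak position `p` lies in a
#' window iff `start < p <= start + window_bp`.
#'
#' @param loci data frame with columns `chrom` and `peak_pos` (and usually
#'   `trait`, `class`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_bp window size (default 200 kb).
#' @param step_frac step as a fraction of the window (default one-fifth).
#' @return data frame `chrom`, `start`, `end`, `count`.
#' @export
window_counts <- function(loci, chrom_lengths, window_bp = 2e5,
                          step_frac = 0.2) {
  chrom_lengths <- as_chrom_lengths(chrom_lengths)
  step <- max(1, round(step_frac * window_bp))
  rows <- lapply(names(chrom_lengths), function(chr) {
    starts <- seq(0, max(0, chrom_lengths[[chr]] - 1), by = step)
    pos <- loci$peak_pos[loci$chrom == chr]
    cnt <- vapply(starts, function(s)
      sum(pos > s & pos <= s + window_bp), integer(1))
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window_bp, chrom_lengths[[chr]]),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical hotspot threshold
#'
#' The minimum locus count a window must carry to be flagged: the `q`-th
#' quantile of the genome-wide per-window count distribution, rounded up to
#' an integer, with a floor of 2 (a one-locus "hotspot" is meaningless).
#'
#' @param counts integer vector of per-window counts (or the data frame from
#'   [window_counts()]).
#' @param q quantile (default 0.95).
#' @return integer threshold >= 2.
#' @export
empirical_threshold <- function(counts, q = 0.95) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0L) stop("counts must be non-empty")
  max(2L, as.integer(ceiling(stats::quantile(counts, q, names = FALSE))))
}

#' Call GWAS hotspots
#'
#' Counts loci in sliding windows, derives the flagging threshold from the
#' `q`-th quantile of the window counts, and merges all partially
#' overlapping qualifying windows into hotspots whose boundaries are the
#' entirety (union) of those windows. In `"intraclass"` mode the loci
#' should already be restricted to one wax class (class-sum traits
#' included); in `"interclass"` mode a hotspot is kept only if its member
#' loci span two or more classes (and the supplied loci should exclude the
#' grand-total trait).
#'
#' @param loci data frame with `chrom`, `peak_pos`, `trait`, `class`.
#' @param chrom_lengths named numeric vector.
#' @param mode `"intraclass"` or `"interclass"`.
#' @param window_bp,step_frac,q scan parameters (see [window_counts()] and
#'   [empirical_threshold()]).
#' @param threshold optional integer overriding the empirical threshold.
#' @return data frame of hotspots: `chrom`, `start`, `end` (0-based
#'   half-open), `n_loci`, `n_traits`, `classes`, `label`, with member locus
#'   rows in the list column `members`.
#' @export
call_hotspots <- function(loci, chrom_lengths,
                          mode = c("intraclass", "interclass"),
                          window_bp = 2e5, step_frac = 0.2, q = 0.95,
                          threshold = NULL) {
  mode <- match.arg(mode)
  chrom_lengths <- as_chrom_lengths(chrom_lengths)
  wc <- window_counts(loci, chrom_lengths, window_bp, step_frac)
  thr <- if (is.null(threshold)) empirical_threshold(wc$count, q) else
    as.integer(threshold)

  qual <- wc[wc$count >= thr, , drop = FALSE]
  hs <- list()
  for (chr in unique(qual$chrom)) {
    qc <- qual[qual$chrom == chr, , drop = FALSE]
    qc <- qc[order(qc$start), , drop = FALSE]
    # merge windows that partially overlap into maximal runs
    grp <- cumsum(c(1, as.integer(qc$start[-1] >= cummax(qc$end[-nrow(qc)]))))
    for (g in unique(grp)) {
      b <- qc[grp == g, , drop = FALSE]
      s <- min(b$start); e <- max(b$end)
      mem <- loci[loci$chrom == chr & loci$peak_pos > s & loci$peak_pos <= e,
                  , drop = FALSE]
      cls <- sort(unique(mem$class))
      if (mode == "interclass" && length(cls) < 2) next
      hs[[length(hs) + 1L]] <- data.frame(
        chrom = chr, start = s, end = e, n_loci = nrow(mem),
        n_traits = length(unique(mem$trait)),
        classes = paste(cls, collapse = ","),
        label = if (mode == "interclass") "interclass" else
          paste0("intraclass(", paste(cls, collapse = ","), ")"),
        stringsAsFactors = FALSE)
      hs[[length(hs)]]$members <- list(mem)
    }
  }
  out <- if (length(hs)) do.call(rbind, hs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_loci = integer(), n_traits = integer(), classes = character(),
               label = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "window_bp") <- window_bp
  out
}

#' Coincident hotspot pairs between two scans
#'
#' A pair of hotspots (one from each set) is coincident when their interval
#' overlap is at least `min_overlap` of the shorter interval.
#'
#' @param set_a,set_b hotspot data frames (columns `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param min_overlap minimum overlap fraction (default 0.5).
#' @return data frame of pairs with the overlap fraction.
#' @export
hotspot_coincidence <- function(set_a, set_b, min_overlap = 0.5) {
  rows <- list()
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      if (set_a$chrom[i] != set_b$chrom[j]) next
      ov <- min(set_a$end[i], set_b$end[j]) - max(set_a$start[i], set_b$start[j])
      if (ov <= 0) next
      frac <- ov / min(set_a$end[i] - set_a$start[i],
                       set_b$end[j] - set_b$start[j])
      if (frac >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = i, b = j, chrom = set_a$chrom[i], overlap_bp = ov,
          overlap_frac = frac, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = integer(), b = integer(), chrom = character(),
               overlap_bp = numeric(), overlap_frac = numeric())
  rownames(out) <- NULL
  out
}
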