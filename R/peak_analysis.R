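# Sliding-window peak calling in the style of ChIPOTle: fixed windows tiled
# at a regular step, a Gaussian null for the window mean with sigma taken
# from the reflected negative half of the probe-value distribution, and
# Bonferroni correction over all evaluated windows.

#' Peak-calling configuration
#'
#' Defaults follow the tiled-array analysis this package reimplements:
#' 240 bp windows stepped every 60 bp with a corrected P-value cutoff of
#' 1e-5.
#'
#' @param window Window width in bp.
#' @param step Step size in bp (must be <= `window`).
#' @param p_cutoff Cutoff applied to the Bonferroni-corrected one-sided
#'   window P-value.
#' @param min_probes Minimum probes per evaluated window.
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(window = 240, step = 60, p_cutoff = 1e-5,
                             min_probes = 2) {
  stopifnot(window > 0, step > 0, step <= window,
            p_cutoff > 0, p_cutoff < 1, min_probes >= 1)
  structure(list(window = window, step = step, p_cutoff = p_cutoff,
                 min_probes = min_probes), class = "peak_call_config")
}

#' Normalize a probe track
#'
#' Removes the most repetitive probes (the top `repetitive_fraction` by
#' absolute signal; 1.1% by default) and background-subtracts so that the
#' distribution of retained values is centred over 0 (median subtraction).
#'
#' @param track A [probe_track()].
#' @param repetitive_fraction Fraction of probes removed as repetitive;
#'   set to 0 for pure centring.
#' @return A normalized `probe_track`.
#' @export
normalize_track <- function(track, repetitive_fraction = 0.011) {
  validate_probe_track(track)
  values <- track_values(track)
  n <- length(values)
  if (n == 0L) stop("cannot normalize an empty track")
  stopifnot(repetitive_fraction >= 0, repetitive_fraction < 1)
  n_drop <- floor(n * repetitive_fraction + 1e-9)
  keep_global <- rep(TRUE, n)
  if (n_drop > 0L) {
    keep_global[order(-abs(values))[seq_len(n_drop)]] <- FALSE
  }
  centre <- stats::median(values[keep_global])
  offset <- 0L
  chroms <- lapply(track$chroms, function(ch) {
    idx <- offset + seq_len(nrow(ch))
    offset <<- offset + nrow(ch)
    ch <- ch[keep_global[idx], , drop = FALSE]
    ch$value <- ch$value - centre
    rownames(ch) <- NULL
    ch
  })
  probe_track(chroms, condition = track$condition)
}

#' Null standard deviation from the reflected negative half
#'
#' Assuming unbound probes scatter symmetrically about 0 after
#' normalization, the negative values are reflected about 0 to estimate the
#' background sd without contamination from (positive) binding signal.
#'
#' @param track A normalized `probe_track`.
#' @return Estimated background sd; 0 when no negative values exist
#'   (noise-free tracks).
#' @export
estimate_null_sd <- function(track) {
  values <- track_values(track)
  neg <- values[values < 0]
  if (length(neg) == 0L) return(0)
  sqrt(mean(neg^2))
}

window_pvalues <- function(mean, n, sigma) {
  if (sigma <= 0) {
    # noise-free degenerate null: any positive mean is a certain signal
    return(ifelse(mean > 0, 0, 1))
  }
  stats::pnorm(mean / (sigma / sqrt(n)), lower.tail = FALSE)
}

#' Call binding peaks on a normalized probe track
#'
#' Windows of width `cfg$window` are tiled every `cfg$step` from position 0
#' to the last probe of each chromosome.  A window's statistic is the mean
#' probe value (probes belong to a window iff their midpoint lies in the
#' half-open window interval); its one-sided P-value comes from a Gaussian
#' null with sd `sigma/sqrt(n_probes)` and is Bonferroni-multiplied by the
#' number of evaluated windows across the whole track.  Overlapping or
#' book-ended significant windows merge into peaks; the peak area is the
#' sum of probe values over the merged span and the peak P the minimum
#' member P.
#'
#' @param track A normalized [probe_track()].
#' @param cfg A [peak_call_config()].
#' @param sigma Background sd; estimated with [estimate_null_sd()] when
#'   `NULL`.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `area`, `p_value`, `n_probes`.
#' @export
call_peaks <- function(track, cfg = peak_call_config(), sigma = NULL) {
  validate_probe_track(track)
  if (is.null(sigma)) sigma <- estimate_null_sd(track)

  per_chrom <- list()
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    if (nrow(ch) == 0L) {
      message("no probes on ", chrom, "; skipping")
      next
    }
    starts <- seq(0, max(ch$mid), by = cfg$step)
    # probes with mid in [s, s + window): integer-safe half-open counts
    hi <- findInterval(starts + cfg$window - 0.5, ch$mid)
    lo <- findInterval(starts - 0.5, ch$mid)
    n_w <- hi - lo
    csum <- cumsum(c(0, ch$value))
    sums <- csum[hi + 1L] - csum[lo + 1L]
    eval_ok <- n_w >= cfg$min_probes
    per_chrom[[chrom]] <- data.frame(
      chrom = chrom, start = starts[eval_ok],
      end = starts[eval_ok] + cfg$window,
      mean = sums[eval_ok] / n_w[eval_ok], n = n_w[eval_ok]
    )
  }
  windows <- do.call(rbind, per_chrom)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), area = numeric(),
                      p_value = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(windows) || nrow(windows) == 0L) return(empty)

  n_eval <- nrow(windows)   # genome-wide Bonferroni multiplier
  p_raw <- window_pvalues(windows$mean, windows$n, sigma)
  windows$p_corr <- pmin(1, p_raw * n_eval)
  sig <- windows[windows$p_corr <= cfg$p_cutoff, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)

  peaks <- list()
  for (chrom in unique(sig$chrom)) {
    s <- sig[sig$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, s$start[-1] > cummax(s$end[-nrow(s)])))
    ch <- track$chroms[[chrom]]
    for (g in split(seq_len(nrow(s)), grp)) {
      start <- min(s$start[g]); end <- max(s$end[g])
      in_span <- ch$mid >= start & ch$mid < end
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end,
        area = sum(ch$value[in_span]),
        p_value = min(s$p_corr[g]),
        n_probes = sum(in_span), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Signal area of a track over an interval
#'
#' Sum of the probe values whose midpoints fall in the half-open interval
#' `[start, end)`.  The area may be negative (regions depleted in the
#' experimental sample relative to total carry negative log2 ratios).
#'
#' @param track A normalized [probe_track()].
#' @param chrom,start,end Interval (0-based half-open).
#' @return Numeric area with attributes `n_probes` and `no_probes` (flag
#'   set when the interval contains no probe; the area is then 0).
#' @export
peak_area_over <- function(track, chrom, start, end) {
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) {
    return(structure(0, n_probes = 0L, no_probes = TRUE))
  }
  sel <- ch$mid >= start & ch$mid < end
  structure(sum(ch$value[sel]), n_probes = sum(sel),
            no_probes = !any(sel))
}

intervals_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Fraction of features overlapped by peaks
#'
#' A feature counts as overlapped iff it shares at least 1 bp with any
#' peak.
#'
#' @param peaks,features Data frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(peaks, features) {
  if (nrow(features) == 0L) stop("no features supplied")
  if (nrow(peaks) == 0L) return(0)
  hits <- GenomicRanges::countOverlaps(intervals_to_granges(features),
                                       intervals_to_granges(peaks),
                                       minoverlap = 1L)
  mean(hits >= 1L)
}

#' Base-pair composition of peaks by annotation class
#'
#' Peak base pairs are partitioned among a priority-ordered list of
#' annotation sets: a base pair is attributed to the first annotation class
#' that covers it; uncovered base pairs fall into class `"other"`.
#'
#' @param peaks Data frame with `chrom`, `start`, `end`.
#' @param annotations Named list of such data frames, in priority order.
#' @return Named numeric vector of base-pair fractions summing to 1.
#' @export
bp_composition <- function(peaks, annotations) {
  peak_gr <- GenomicRanges::reduce(intervals_to_granges(peaks))
  total <- sum(GenomicRanges::width(peak_gr))
  if (total == 0) stop("no peak base pairs")
  remaining <- peak_gr
  fractions <- numeric(0)
  for (cls in names(annotations)) {
    ann <- GenomicRanges::reduce(intervals_to_granges(annotations[[cls]]))
    covered <- GenomicRanges::intersect(remaining, ann)
    fractions[cls] <- sum(GenomicRanges::width(covered)) / total
    remaining <- GenomicRanges::setdiff(remaining, ann)
  }
  fractions["other"] <- sum(GenomicRanges::width(remaining)) / total
  fractions
}

#' Assign called peaks to origins
#'
#' Each peak is assigned to the origin with the largest base-pair overlap;
#' ties break by the smaller midpoint distance, then by lexicographic
#' origin name.  Peaks overlapping no origin get `NA`.
#'
#' @param peaks Peak data frame from [call_peaks()].
#' @param origins Origin table from [read_origin_table()].
#' @return `peaks` with an added `origin` column.
#' @export
assign_peaks_to_origins <- function(peaks, origins) {
  peaks$origin <- rep(NA_character_, nrow(peaks))
  if (nrow(peaks) == 0L || nrow(origins) == 0L) return(peaks)
  pg <- intervals_to_granges(peaks)
  og <- intervals_to_granges(origins)
  hits <- GenomicRanges::findOverlaps(pg, og, minoverlap = 1L)
  if (length(hits) == 0L) return(peaks)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov_bp <- GenomicRanges::width(IRanges::pintersect(pg[qh], og[sh]))
  pk_mid <- (peaks$start + peaks$end) / 2
  or_mid <- (origins$start + origins$end) / 2
  mid_dist <- abs(pk_mid[qh] - or_mid[sh])
  for (i in unique(qh)) {
    cand <- which(qh == i)
    cand <- cand[order(-ov_bp[cand], mid_dist[cand], origins$name[sh[cand]])]
    peaks$origin[i] <- origins$name[sh[cand[1L]]]
  }
  peaks
}
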