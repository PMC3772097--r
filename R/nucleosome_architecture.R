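# Nucleosome occupancy around ORC binding sites: profiles are anchored on
# the start of the extended ACS (EACS) on the T-rich strand, oriented so
# that +x is 3' of the EACS, binned at 4 bp, and averaged per origin
# group.  The nucleosome-depleted region (NDR) is the gap between the end
# of the -1 nucleosome and the start of the +1 nucleosome.

#' Anchor nucleosome signal around origin ACS positions
#'
#' Every origin's occupancy values within `span` bp of its anchor (the
#' T-rich-strand start of the EACS, `acs_pos`) are mapped to relative
#' coordinates, flipped for minus-strand ACSs so that positive x always
#' points 3' of the element, binned at `bin` bp, and averaged.  Origins
#' lacking an ACS annotation are omitted.
#'
#' @param track A [probe_track()] holding occupancy values.
#' @param origins Origin table with `acs_pos` and `acs_strand`.
#' @param span Half-width of the profile in bp (default 1000).
#' @param bin Bin width in bp (default 4).
#' @return An object of class `anchored_profile`: `bins` (left edges of
#'   the relative bins), `mean` (across-origin average), `matrix`
#'   (origins x bins), `n_origins`.
#' @export
anchor_profiles <- function(track, origins, span = 1000, bin = 4) {
  origins <- origins[!is.na(origins$acs_pos) & !is.na(origins$acs_strand), ,
                     drop = FALSE]
  if (nrow(origins) == 0L) stop("no origins with an annotated ACS")
  edges <- seq(-span, span - bin, by = bin)
  n_bins <- length(edges)
  mat <- matrix(NA_real_, nrow = nrow(origins), ncol = n_bins,
                dimnames = list(origins$name, edges))
  for (i in seq_len(nrow(origins))) {
    ch <- track$chroms[[origins$chrom[i]]]
    if (is.null(ch)) next
    anchor <- origins$acs_pos[i]
    sel <- ch$mid >= anchor - span & ch$mid <= anchor + span
    if (!any(sel)) next
    rel <- if (origins$acs_strand[i] == "+") {
      ch$mid[sel] - anchor
    } else {
      anchor - ch$mid[sel]
    }
    keep <- rel >= -span & rel < span
    b <- floor((rel[keep] + span) / bin) + 1L
    sums <- tapply(ch$value[sel][keep], b, sum)
    cnts <- tapply(rep(1, sum(keep)), b, sum)
    idx <- as.integer(names(sums))
    mat[i, idx] <- sums / cnts
  }
  structure(list(bins = edges, bin = bin,
                 mean = colMeans(mat, na.rm = TRUE),
                 matrix = mat, n_origins = nrow(origins)),
            class = "anchored_profile")
}

#' @export
print.anchored_profile <- function(x, ...) {
  cat("anchored_profile: ", x$n_origins, " origins, bins of ", x$bin,
      " bp over [", min(x$bins), ", ", max(x$bins) + x$bin, ")\n", sep = "")
  invisible(x)
}

#' Call the nucleosome-depleted region on an anchored signal
#'
#' Nucleosomal runs are maximal stretches of bins whose signal is at or
#' above `threshold`.  The +1 nucleosome is the first run starting at or
#' 3' of the anchor (relative coordinate 0); the -1 nucleosome is the last
#' run ending at or 5' of the anchor.  Both are searched within
#' `search` bp of the anchor.  The NDR width is `plus1_start -
#' minus1_end`.  When either flanking nucleosome is absent within the
#' search window, the measurement is flagged unbounded.
#'
#' @param signal Numeric vector of binned occupancy (one value per bin).
#' @param bins Left edges of the relative-coordinate bins.
#' @param threshold Occupancy threshold defining nucleosomal signal
#'   (conventionally 0.5 x the track median, see [ndr_measurements()]).
#' @param anchor Relative coordinate of the anchor (default 0).
#' @param search Search half-window in bp (default 600).
#' @return List `ndr_width`, `minus1_end`, `plus1_start`, `unbounded`.
#' @export
call_ndr <- function(signal, bins, threshold, anchor = 0, search = 600) {
  stopifnot(length(signal) == length(bins))
  bin <- if (length(bins) > 1L) bins[2] - bins[1] else 1
  above <- !is.na(signal) & signal >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, ends[-length(ends)] + 1L)
  run_start <- bins[starts_i[r$values]]
  run_end <- bins[ends[r$values]] + bin     # half-open end
  in_search <- run_end > anchor - search & run_start < anchor + search
  run_start <- run_start[in_search]; run_end <- run_end[in_search]
  plus_ok <- run_start >= anchor
  minus_ok <- run_end <= anchor
  if (!any(plus_ok) || !any(minus_ok)) {
    return(list(ndr_width = NA_real_, minus1_end = NA_real_,
                plus1_start = NA_real_, unbounded = TRUE))
  }
  plus1_start <- min(run_start[plus_ok])
  minus1_end <- max(run_end[minus_ok])
  list(ndr_width = plus1_start - minus1_end,
       minus1_end = minus1_end, plus1_start = plus1_start,
       unbounded = FALSE)
}

#' Per-origin NDR measurements for a nucleosome track
#'
#' Anchors the track at each origin's ACS ([anchor_profiles()]), then
#' calls the NDR per origin with [call_ndr()].  The nucleosome threshold
#' defaults to `threshold_fraction` times the median occupancy of the
#' whole track.
#'
#' @param track Occupancy [probe_track()].
#' @param origins Origin table with ACS annotations.
#' @param threshold_fraction Fraction of the track median defining
#'   nucleosomal occupancy (default 0.5).
#' @param span,bin,search Passed to [anchor_profiles()] / [call_ndr()].
#' @return Data frame `origin`, `ndr_width`, `minus1_end`, `plus1_start`,
#'   `unbounded`.
#' @export
ndr_measurements <- function(track, origins, threshold_fraction = 0.5,
                             span = 1000, bin = 4, search = 600) {
  prof <- anchor_profiles(track, origins, span = span, bin = bin)
  threshold <- threshold_fraction * stats::median(track_values(track))
  rows <- lapply(rownames(prof$matrix), function(name) {
    m <- call_ndr(prof$matrix[name, ], prof$bins, threshold,
                  search = search)
    data.frame(origin = name, ndr_width = m$ndr_width,
               minus1_end = m$minus1_end, plus1_start = m$plus1_start,
               unbounded = m$unbounded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                mean_x = mean(x), mean_y = mean(y)))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate convention: identical constant groups are indistinguishable
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    return(list(statistic = 0, p_value = p,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

#' Per-group NDR change between two conditions
#'
#' Matches origins between the wild-type and mutant measurements (origins
#' present in only one condition are dropped with a notice), computes the
#' per-origin width change `delta = wt - mutant`, the per-group mean
#' change, and a two-sided Welch t-test comparing the deltas of each pair
#' of groups.
#'
#' @param wt,mutant Data frames from [ndr_measurements()].
#' @param groups Data frame `origin`, `group`.
#' @return List with `deltas` (per-origin data frame), `group_means`, and
#'   `tests` (one row per group pair: means, Welch t, two-sided P).
#' @export
delta_ndr <- function(wt, mutant, groups) {
  merged <- merge(wt[c("origin", "ndr_width")],
                  mutant[c("origin", "ndr_width")],
                  by = "origin", suffixes = c("_wt", "_mut"))
  dropped <- setdiff(union(wt$origin, mutant$origin), merged$origin)
  if (length(dropped) > 0L) {
    message(length(dropped), " unmatched origin(s) dropped")
  }
  merged <- merge(merged, groups, by = "origin")
  merged$delta <- merged$ndr_width_wt - merged$ndr_width_mut
  merged <- merged[is.finite(merged$delta), , drop = FALSE]
  group_means <- tapply(merged$delta, merged$group, mean)
  gs <- sort(unique(merged$group))
  tests <- list()
  if (length(gs) >= 2L) {
    for (i in seq_len(length(gs) - 1L)) {
      for (j in seq(i + 1L, length(gs))) {
        wt_ <- welch_test(merged$delta[merged$group == gs[i]],
                          merged$delta[merged$group == gs[j]])
        tests[[length(tests) + 1L]] <- data.frame(
          group_a = gs[i], group_b = gs[j],
          mean_a = wt_$mean_x, mean_b = wt_$mean_y,
          statistic = wt_$statistic, p_value = wt_$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(deltas = merged,
       group_means = group_means,
       tests = if (length(tests) > 0L) do.call(rbind, tests) else NULL)
}
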