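# Joint classification of origins from in-vivo depletion ratios and
# in-vitro binding signal.  Two routes exist: thresholds on EMSA-derived
# Kd folds, and k-means clusters of genomic-EMSA signal profiles.

#' Ratio class of an in-vivo depletion ratio
#'
#' Origins with `ratio <= 0.3` are `sensitive` (low in-vivo affinity),
#' origins with `ratio >= 0.8` are `resistant` (high in-vivo affinity);
#' the bounds are inclusive.  Everything between is `moderate`.
#'
#' @param ratio Numeric orc2-1/ORC2 peak-area ratios (may be negative).
#' @param sensitive_max,resistant_min Band edges.
#' @return Character vector in `{sensitive, moderate, resistant}`.
#' @export
ratio_class <- function(ratio, sensitive_max = 0.3, resistant_min = 0.8) {
  out <- rep(NA_character_, length(ratio))
  out[ratio <= sensitive_max] <- "sensitive"
  out[ratio >= resistant_min] <- "resistant"
  out[ratio > sensitive_max & ratio < resistant_min] <- "moderate"
  out
}

#' In-vivo affinity ratios over wild-type peak coordinates
#'
#' For every origin with an assigned wild-type (ORC2) peak, the mutant
#' (orc2-1) signal area is computed over the *wild-type* peak's
#' coordinates — no mutant peak call is needed — and the orc2-1/ORC2
#' peak-area ratio with its class is reported.  Origins whose wild-type
#' area is not positive are flagged unclassifiable.
#'
#' @param orc2_track,orc21_track Normalized wild-type and mutant
#'   [probe_track()]s.
#' @param orc2_peaks Peaks called on the wild-type track, already assigned
#'   to origins ([assign_peaks_to_origins()]).
#' @param origins Origin table.
#' @return Data frame with columns `origin`, `chrom`, `start`, `end`,
#'   `orc2_area`, `orc21_area`, `ratio`, `ratio_class`, `unclassifiable`.
#' @export
in_vivo_ratio <- function(orc2_track, orc21_track, orc2_peaks, origins) {
  if (!"origin" %in% names(orc2_peaks)) {
    orc2_peaks <- assign_peaks_to_origins(orc2_peaks, origins)
  }
  pk <- orc2_peaks[!is.na(orc2_peaks$origin), , drop = FALSE]
  # one peak per origin: keep the larger-area peak if several were assigned
  pk <- pk[order(pk$origin, -pk$area), , drop = FALSE]
  pk <- pk[!duplicated(pk$origin), , drop = FALSE]
  n <- nrow(pk)
  orc2_area <- numeric(n); orc21_area <- numeric(n)
  for (i in seq_len(n)) {
    orc2_area[i] <- peak_area_over(orc2_track, pk$chrom[i],
                                   pk$start[i], pk$end[i])
    orc21_area[i] <- peak_area_over(orc21_track, pk$chrom[i],
                                    pk$start[i], pk$end[i])
  }
  unclassifiable <- orc2_area <= 0
  ratio <- ifelse(unclassifiable, NA_real_, orc21_area / orc2_area)
  data.frame(origin = pk$origin, chrom = pk$chrom,
             start = pk$start, end = pk$end,
             orc2_area = orc2_area, orc21_area = orc21_area,
             ratio = ratio, ratio_class = ratio_class(ratio),
             unclassifiable = unclassifiable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-origin genomic-EMSA signal profiles and their total
#'
#' The gEMSA binding strength of an origin at each ORC concentration is a
#' peak area, defined in one of two modes.  In `chip_coordinates` mode the
#' area is summed over the coordinates of the origin's in-vivo ORC2 ChIP
#' peak, and may be negative for depleted regions.  In `called_peaks` mode
#' peaks are called independently on each gEMSA track and the origin's
#' signal is the area of its assigned peak, or 0 when no peak was called.
#' The three per-concentration signals are summed into the "total gEMSA
#' signal".
#'
#' @param gemsa_tracks Named list of normalized [probe_track()]s; names are
#'   the ORC concentrations, e.g. `c("0.3", "3", "30")`.
#' @param origins Origin table.
#' @param mode `"chip_coordinates"` or `"called_peaks"`.
#' @param orc2_peaks Origin-assigned wild-type ChIP peaks (required in
#'   `chip_coordinates` mode).
#' @param cfg [peak_call_config()] used in `called_peaks` mode.
#' @return Data frame with one row per origin: `origin`, one `signal_*`
#'   column per concentration, `total`, `mode`.
#' @export
total_gemsa_signal <- function(gemsa_tracks, origins,
                               mode = c("chip_coordinates", "called_peaks"),
                               orc2_peaks = NULL,
                               cfg = peak_call_config()) {
  mode <- match.arg(mode)
  if (length(gemsa_tracks) == 0L || is.null(names(gemsa_tracks))) {
    stop("gemsa_tracks must be a named list of tracks")
  }
  concs <- names(gemsa_tracks)

  if (mode == "chip_coordinates") {
    if (is.null(orc2_peaks)) {
      stop("chip_coordinates mode requires orc2_peaks")
    }
    if (!"origin" %in% names(orc2_peaks)) {
      orc2_peaks <- assign_peaks_to_origins(orc2_peaks, origins)
    }
    pk <- orc2_peaks[!is.na(orc2_peaks$origin), , drop = FALSE]
    pk <- pk[order(pk$origin, -pk$area), , drop = FALSE]
    pk <- pk[!duplicated(pk$origin), , drop = FALSE]
    sig <- sapply(concs, function(cc) {
      vapply(seq_len(nrow(pk)), function(i) {
        as.numeric(peak_area_over(gemsa_tracks[[cc]], pk$chrom[i],
                                  pk$start[i], pk$end[i]))
      }, numeric(1))
    })
    sig <- matrix(sig, nrow = nrow(pk),
                  dimnames = list(NULL, paste0("signal_", concs)))
    out <- data.frame(origin = pk$origin, sig, total = rowSums(sig),
                      mode = mode, stringsAsFactors = FALSE)
  } else {
    sig <- matrix(0, nrow = nrow(origins), ncol = length(concs),
                  dimnames = list(NULL, paste0("signal_", concs)))
    for (j in seq_along(concs)) {
      pks <- call_peaks(gemsa_tracks[[concs[j]]], cfg)
      pks <- assign_peaks_to_origins(pks, origins)
      pks <- pks[!is.na(pks$origin), , drop = FALSE]
      areas <- tapply(pks$area, pks$origin, function(a) a[which.max(abs(a))])
      hit <- match(origins$name, names(areas))
      sig[!is.na(hit), j] <- unlist(areas)[hit[!is.na(hit)]]
    }
    out <- data.frame(origin = origins$name, sig, total = rowSums(sig),
                      mode = mode, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

lloyd_restart <- function(mat, k) {
  ctr <- mat[sample.int(nrow(mat), k), , drop = FALSE]
  if (anyDuplicated(ctr)) return(NULL)
  tryCatch(
    suppressWarnings(stats::kmeans(mat, ctr, iter.max = 100,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
}

#' Cluster gEMSA signal profiles by restarted k-means
#'
#' k-means (Lloyd iterations, Euclidean distance on the raw signal
#' 3-vectors) is restarted many times from random initial centres sampled
#' from the data; the solution with the lowest total within-cluster sum of
#' squares is kept.  Clusters are labelled `Weak`, `Moderate`, `Strong` by
#' ascending centroid mean, which removes the label-permutation ambiguity.
#'
#' @param mat Numeric matrix, one row per origin, one column per ORC
#'   concentration.
#' @param k Number of clusters (default 3).
#' @param restarts Number of random restarts (default 10000).
#' @param seed Integer seed making the clustering reproducible.
#' @return List with `cluster` (character vector of labels per row),
#'   `centers` (k x ncol matrix, rows ordered Weak..Strong), `tot_withinss`.
#' @export
cluster_gemsa <- function(mat, k = 3, restarts = 10000, seed = 1L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < k) stop("need at least k rows to form k clusters")
  labels <- c("Weak", "Moderate", "Strong")
  if (k > length(labels)) labels <- c(labels, paste0("C", seq_len(k - 3L) + 3L))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    km <- lloyd_restart(mat, k)
    if (!is.null(km) &&
        (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) stop("no k-means restart converged")
  ord <- order(rowMeans(best$centers))
  relabel <- character(k)
  relabel[ord] <- labels[seq_len(k)]
  list(cluster = relabel[best$cluster],
       centers = best$centers[ord, , drop = FALSE],
       tot_withinss = best$tot.withinss)
}

#' Joint origin classification from the gEMSA-cluster route
#'
#' High in-vivo affinity (resistant) origins falling in the `Weak`
#' in-vitro cluster are called `chromatin_dependent`; resistant origins in
#' the `Moderate` or `Strong` clusters are `dna_dependent`; sensitive
#' origins in the `Weak` cluster are `weak`; everything else is
#' `unclassified`.  Origins on the exclusion list (core-X telomeric ARSs
#' by default) are dropped before classification.
#'
#' @param affinities Output of [in_vivo_ratio()].
#' @param profiles Output of [total_gemsa_signal()] with an added
#'   `cluster` column (see [cluster_gemsa()]).
#' @param exclude Character vector of origin names to drop.
#' @return Data frame `origin`, `call`, `route`.
#' @export
classify_joint <- function(affinities, profiles, exclude = character()) {
  stopifnot("cluster" %in% names(profiles))
  df <- merge(affinities[c("origin", "ratio_class")],
              profiles[c("origin", "cluster")], by = "origin")
  df <- df[!df$origin %in% exclude, , drop = FALSE]
  call <- rep("unclassified", nrow(df))
  resistant <- df$ratio_class %in% "resistant"
  sensitive <- df$ratio_class %in% "sensitive"
  call[resistant & df$cluster == "Weak"] <- "chromatin_dependent"
  call[resistant & df$cluster %in% c("Moderate", "Strong")] <- "dna_dependent"
  call[sensitive & df$cluster == "Weak"] <- "weak"
  data.frame(origin = df$origin, call = call, route = "gemsa_clusters",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Origin classification from the EMSA Kd-threshold route
#'
#' Resistant origins with Kd folds at most 3x the reference are
#' `dna_dependent`; resistant origins with folds above 10x (or censored,
#' "ND") are `chromatin_dependent`; resistant origins between 3x and 10x
#' are `complex` (some combination of intrinsic DNA and extrinsic
#' chromatin interactions); sensitive origins with folds above 4x are
#' `weak`; all remaining origins are `unclassified`.
#'
#' @param affinities Output of [in_vivo_ratio()] (or any data frame with
#'   `origin` and `ratio_class`).
#' @param folds Named numeric vector of Kd folds per origin (`Inf` for
#'   censored), see [normalize_kd()].
#' @return Data frame `origin`, `call`, `route`.
#' @export
classify_by_emsa <- function(affinities, folds) {
  df <- affinities[affinities$origin %in% names(folds), , drop = FALSE]
  fold <- folds[df$origin]
  call <- rep("unclassified", nrow(df))
  resistant <- df$ratio_class %in% "resistant"
  sensitive <- df$ratio_class %in% "sensitive"
  call[resistant & fold <= 3] <- "dna_dependent"
  call[resistant & fold > 10] <- "chromatin_dependent"
  call[resistant & fold > 3 & fold <= 10] <- "complex"
  call[sensitive & fold > 4] <- "weak"
  data.frame(origin = df$origin, call = call, route = "emsa_thresholds",
             stringsAsFactors = FALSE, row.names = NULL)
}
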