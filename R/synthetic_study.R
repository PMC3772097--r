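# Synthetic-study generator: a complete in-silico version of the
# two-assay design.  Every origin carries a planted mechanistic class, an
# intrinsic (naked-DNA) dissociation constant kd_dna driving the EMSA and
# gEMSA observables, and an effective in-vivo dissociation constant
# kd_vivo driving the ChIP observables.  The ratio kd_dna / kd_vivo is
# the origin's chromatin boost: at chromatin-dependent origins it is an
# order of magnitude larger than elsewhere, which is precisely the
# signature the classification pipeline must recover.

ACS_CONSENSUS <- "TTTTATGTTTA"   # 11 bp T-rich-strand ORC binding core

#' Configuration of a synthetic origin study
#'
#' Defaults define the study conditions used throughout the package's
#' validation: 40 origins per mechanistic class, a 10-fold ORC depletion,
#' gEMSA ORC concentrations of 0.3, 3 and 30 nM, EMSA titrations at 0.3,
#' 3, 15 and 30 nM in triplicate, and per-probe Gaussian noise of 0.15 on
#' the log2 scale.
#'
#' @param n_per_class Named integer vector of origins per class; classes
#'   among `chromatin_dependent`, `dna_dependent`, `weak`, `complex`.
#' @param origin_spacing Distance between consecutive origin centres (bp).
#' @param margin Origin-free genome margin on each side (bp).
#' @param probe_spacing Array probe spacing (bp).
#' @param orc_concs gEMSA ORC concentrations (nM).
#' @param in_vivo_orc_conc Notional wild-type nuclear ORC availability
#'   (nM); only the depletion ratio matters for ratio recovery.
#' @param depletion_factor Fold reduction of ORC in the orc2-1-like
#'   mutant (default 10).
#' @param noise_sd Per-probe Gaussian noise sd (log2 units).
#' @param titration_concs EMSA titration concentrations (nM).
#' @param titration_replicates Replicates per titration.
#' @param titration_noise_sd Gaussian sd of fraction-bound noise,
#'   truncated to `[0, 1]`.
#' @param peak_amplitude Log2-ratio peak height at full occupancy.
#' @param footprint Binding-peak footprint width (bp), raised-cosine
#'   shaped.
#' @param kd_dna_ranges,kd_vivo_ranges Named lists of `c(min, max)` nM
#'   ranges per class for the intrinsic and effective in-vivo Kds.
#' @param reference_kd Intrinsic Kd (nM) of the reference origin whose
#'   titration anchors Kd normalization.
#' @param nuc_spacing Spacing of nucleosome occupancy values (bp).
#' @param nuc_noise_sd Noise sd on occupancy values.
#' @param ndr_5p_margin Distance from the NDR's 5' edge to the ACS anchor
#'   (bp); the anchor lies inside the NDR, whose centre falls 3' of it.
#' @param ndr_width_mean Named vector of mean true NDR widths per class
#'   (bp).
#' @param ndr_width_sd Sd of true NDR widths (bp).
#' @param encroachment Named vector: per-side NDR shrinkage in the
#'   ORC-loss mutant (bp).
#' @param trep_mean Named vector of mean replication times per class
#'   (min).
#' @param trep_sd Sd of replication times (min).
#' @param hu_p_wt Named vector: probability that an origin of a class is
#'   HU-resistant in wild type.
#' @param hu_detect_p Probability that each study detects an origin.
#' @param seed Integer RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_per_class = c(chromatin_dependent = 40, dna_dependent = 40, weak = 40),
    origin_spacing = 4000,
    margin = 2000,
    probe_spacing = 10,
    orc_concs = c(0.3, 3, 30),
    in_vivo_orc_conc = 30,
    depletion_factor = 10,
    noise_sd = 0.15,
    titration_concs = c(0.3, 3, 15, 30),
    titration_replicates = 3,
    titration_noise_sd = 0.02,
    peak_amplitude = 2.0,
    footprint = 240,
    kd_dna_ranges = list(chromatin_dependent = c(120, 500),
                         dna_dependent = c(4, 20),
                         weak = c(100, 300),
                         complex = c(25, 70)),
    kd_vivo_ranges = list(chromatin_dependent = c(0.05, 0.3),
                          dna_dependent = c(0.05, 0.3),
                          weak = c(30, 60),
                          complex = c(0.1, 0.8)),
    reference_kd = 7.223,
    nuc_spacing = 4,
    nuc_noise_sd = 0.05,
    ndr_5p_margin = 80,
    ndr_width_mean = c(chromatin_dependent = 230, dna_dependent = 200,
                       weak = 200, complex = 200),
    ndr_width_sd = 15,
    encroachment = c(chromatin_dependent = 10, dna_dependent = 60,
                     weak = 60, complex = 60),
    trep_mean = c(chromatin_dependent = 18, dna_dependent = 30,
                  weak = 28, complex = 24),
    trep_sd = 4,
    hu_p_wt = c(chromatin_dependent = 0.75, dna_dependent = 0.2,
                weak = 0.45, complex = 0.4),
    hu_detect_p = 0.7,
    seed = 1L) {
  stopifnot(all(n_per_class >= 0), origin_spacing > 0, probe_spacing > 0,
            depletion_factor > 0, noise_sd >= 0, peak_amplitude > 0,
            footprint > 0, all(orc_concs > 0),
            length(titration_concs) >= 3)
  cfg <- as.list(environment())
  cfg$genome_length <- 2 * margin + sum(n_per_class) * origin_spacing
  structure(cfg, class = "simulation_config")
}

#' Expected orc2-1/ORC2 ratio of an origin under the occupancy model
#'
#' The wild-type ChIP signal is proportional to the equilibrium occupancy
#' at the nuclear ORC concentration `C`; the mutant signal to the
#' occupancy at `C / depletion_factor`.  With the effective in-vivo Kd
#' `kd_eff = kd_dna / boost`, the noise-free peak-area ratio is
#' `occupancy(C/d, kd_eff) / occupancy(C, kd_eff)`, bounded in (0, 1].
#'
#' @param kd_dna Intrinsic ORC-DNA dissociation constant (nM).
#' @param boost Chromatin boost dividing `kd_dna` to give the effective
#'   in-vivo Kd (unitless, >= 1 means in vivo binds tighter).
#' @param cfg A [simulation_config()].
#' @return Expected ratio in (0, 1].
#' @export
simulate_in_vivo_ratio <- function(kd_dna, boost, cfg = simulation_config()) {
  kd_eff <- kd_dna / boost
  c_wt <- cfg$in_vivo_orc_conc
  occupancy(c_wt / cfg$depletion_factor, kd_eff) / occupancy(c_wt, kd_eff)
}

raised_cosine <- function(dist, half_width) {
  shape <- 0.5 * (1 + cos(pi * dist / half_width))
  shape[abs(dist) > half_width] <- 0
  shape
}

draw_range <- function(n, range) stats::runif(n, range[1], range[2])

simulated_signal_track <- function(mids, centers, heights, cfg, condition) {
  value <- stats::rnorm(length(mids), 0, cfg$noise_sd)
  half <- cfg$footprint / 2
  for (i in seq_along(centers)) {
    sel <- which(mids >= centers[i] - half & mids <= centers[i] + half)
    value[sel] <- value[sel] +
      heights[i] * raised_cosine(mids[sel] - centers[i], half)
  }
  probe_track(list(chrS = data.frame(mid = mids, value = value)),
              condition = condition)
}

simulated_nucleosome_track <- function(mids, origins, truth, cfg,
                                       encroach_by_class, condition) {
  value <- 1 + stats::rnorm(length(mids), 0, cfg$nuc_noise_sd)
  m <- cfg$ndr_5p_margin
  for (i in seq_len(nrow(origins))) {
    e <- encroach_by_class[[truth$true_class[i]]]
    wd <- truth$ndr_width_true[i]
    if (wd - 2 * e <= 0) next
    anchor <- origins$acs_pos[i]
    # NDR occupies relative coordinates [-m + e, -m + wd - e): the ACS
    # anchor sits inside the NDR, whose centre lies 3' of it
    if (origins$acs_strand[i] == "+") {
      lo <- anchor - m + e
      hi <- anchor - m + wd - e
    } else {
      lo <- anchor + m - wd + e + 1
      hi <- anchor + m - e + 1
    }
    sel <- which(mids >= lo & mids < hi)
    value[sel] <- stats::rnorm(length(sel), 0, cfg$nuc_noise_sd)
  }
  probe_track(list(chrS = data.frame(mid = mids, value = value)),
              condition = condition)
}

#' Generate a complete synthetic origin study
#'
#' Builds a genome with planted consensus ACS instances, an origin table,
#' wild-type and ORC-depleted ChIP probe tracks, gEMSA tracks at the
#' three ORC concentrations (driven by the intrinsic Kd only — naked DNA
#' carries no chromatin boost), EMSA titration tables including a
#' reference-origin titration, nucleosome occupancy tracks for wild-type
#' and an ORC-loss mutant, a replication-timing table, and the per-origin
#' ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `genome`, `origins`, `tracks` (named:
#'   `ORC2`, `orc2_1`, `gemsa` sub-list keyed by concentration),
#'   `titrations`, `nucleosome` (named: `wt`, `orc_minus`), `timing`,
#'   `truth`, `config`.
#' @export
generate_study <- function(cfg = simulation_config()) {
  n_total <- sum(cfg$n_per_class)
  if (n_total == 0L) stop("no origins configured")
  if (cfg$genome_length <
      2 * cfg$margin + n_total * cfg$origin_spacing) {
    stop("genome too short to place origins with flanks")
  }
  if (cfg$margin < 1200 || cfg$origin_spacing < 2 * 1200) {
    stop("genome too short to place origins with flanks")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(classes)
  kd_dna <- kd_vivo <- numeric(n)
  for (cls in unique(classes)) {
    sel <- classes == cls
    kd_dna[sel] <- draw_range(sum(sel), cfg$kd_dna_ranges[[cls]])
    kd_vivo[sel] <- draw_range(sum(sel), cfg$kd_vivo_ranges[[cls]])
  }
  boost <- kd_dna / kd_vivo

  centers <- cfg$margin + (seq_len(n) - 0.5) * cfg$origin_spacing
  centers <- round(centers)
  strand <- rep(c("+", "-"), length.out = n)
  acs_pos <- ifelse(strand == "+", centers - 5L, centers + 5L)
  names <- sprintf("ORI%03d", seq_len(n))

  # genome with planted ACS instances (yeast-like AT-rich composition)
  bases <- sample(DNA_BASES, cfg$genome_length, replace = TRUE,
                  prob = c(0.31, 0.19, 0.19, 0.31))
  acs_f <- strsplit(ACS_CONSENSUS, "")[[1]]
  acs_r <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ACS_CONSENSUS))), "")[[1]]
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      bases[(acs_pos[i] + 1):(acs_pos[i] + 11)] <- acs_f
    } else {
      bases[(acs_pos[i] - 9):(acs_pos[i] + 1)] <- acs_r
    }
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrS"

  origins <- data.frame(
    name = names, chrom = "chrS",
    start = centers - 300L, end = centers + 300L,
    status = "confirmed", acs_pos = acs_pos, acs_strand = strand,
    telomeric_core_x = FALSE, stringsAsFactors = FALSE)

  truth <- data.frame(
    origin = names, true_class = classes,
    kd_dna = kd_dna, kd_vivo = kd_vivo, chromatin_boost = boost,
    expected_ratio = simulate_in_vivo_ratio(kd_dna, boost, cfg),
    stringsAsFactors = FALSE)

  mids <- seq(floor(cfg$probe_spacing / 2), cfg$genome_length - 1,
              by = cfg$probe_spacing)
  amp <- cfg$peak_amplitude
  c_wt <- cfg$in_vivo_orc_conc
  tracks <- list(
    ORC2 = simulated_signal_track(
      mids, centers, amp * occupancy(c_wt, kd_vivo), cfg, "ORC2"),
    orc2_1 = simulated_signal_track(
      mids, centers, amp * occupancy(c_wt / cfg$depletion_factor, kd_vivo),
      cfg, "orc2-1"),
    gemsa = stats::setNames(lapply(cfg$orc_concs, function(cc) {
      simulated_signal_track(mids, centers, amp * occupancy(cc, kd_dna),
                             cfg, paste0("gEMSA_", cc, "nM"))
    }), as.character(cfg$orc_concs)))

  titr <- expand.grid(origin = c(names, "REF"),
                      replicate = seq_len(cfg$titration_replicates),
                      conc_nM = cfg$titration_concs,
                      stringsAsFactors = FALSE)
  kd_all <- c(stats::setNames(kd_dna, names), REF = cfg$reference_kd)
  frac <- occupancy(titr$conc_nM, kd_all[titr$origin]) +
    stats::rnorm(nrow(titr), 0, cfg$titration_noise_sd)
  titr$fraction_bound <- pmin(1, pmax(0, frac))
  titr <- titr[order(titr$origin, titr$replicate, titr$conc_nM), ]
  rownames(titr) <- NULL

  truth$ndr_width_true <- pmax(
    150, round(stats::rnorm(n, cfg$ndr_width_mean[classes],
                            cfg$ndr_width_sd)))
  nuc_mids <- seq(0, cfg$genome_length - 1, by = cfg$nuc_spacing)
  no_encroach <- stats::setNames(rep(0, length(cfg$encroachment)),
                                 names(cfg$encroachment))
  nucleosome <- list(
    wt = simulated_nucleosome_track(nuc_mids, origins, truth, cfg,
                                    no_encroach, "nuc_WT_G1"),
    orc_minus = simulated_nucleosome_track(nuc_mids, origins, truth, cfg,
                                           cfg$encroachment,
                                           "nuc_orc1-161_G1"))

  truth$true_trep <- stats::rnorm(n, cfg$trep_mean[classes], cfg$trep_sd)
  hu_true <- ifelse(stats::runif(n) < cfg$hu_p_wt[classes],
                    "HUr_WT", "HUr_rad53")
  observe <- function() {
    detected <- stats::runif(n) < cfg$hu_detect_p
    ifelse(!detected, "not_detected",
           ifelse(hu_true == "HUr_WT", "fires_WT", "fires_rad53_only"))
  }
  timing <- data.frame(origin = names, trep = truth$true_trep,
                       hu_study1 = observe(), hu_study2 = observe(),
                       stringsAsFactors = FALSE)
  truth$hu_true <- hu_true

  list(genome = genome, origins = origins, tracks = tracks,
       titrations = titr, nucleosome = nucleosome, timing = timing,
       truth = truth, config = cfg)
}

#' Run the full classification pipeline on a synthetic study
#'
#' Normalizes the ChIP and gEMSA tracks, calls peaks on the wild-type
#' ChIP track, computes orc2-1/ORC2 ratios over the wild-type peak
#' coordinates, sums per-concentration gEMSA signal over the same
#' coordinates, clusters the signal profiles with restarted k-means, and
#' issues the joint classification.
#'
#' @param study Output of [generate_study()].
#' @param cfg Peak-calling configuration.
#' @param restarts k-means restarts (see [cluster_gemsa()]).
#' @param seed Seed for the clustering restarts.
#' @param repetitive_fraction Passed to [normalize_track()].
#' @return List with `peaks`, `affinities`, `profiles`, `classification`.
#' @export
classify_study <- function(study, cfg = peak_call_config(),
                           restarts = 1000, seed = 1L,
                           repetitive_fraction = 0) {
  orc2 <- normalize_track(study$tracks$ORC2, repetitive_fraction)
  orc21 <- normalize_track(study$tracks$orc2_1, repetitive_fraction)
  gemsa <- lapply(study$tracks$gemsa, normalize_track, repetitive_fraction)

  peaks <- call_peaks(orc2, cfg)
  peaks <- assign_peaks_to_origins(peaks, study$origins)
  affinities <- in_vivo_ratio(orc2, orc21, peaks, study$origins)
  profiles <- total_gemsa_signal(gemsa, study$origins,
                                 mode = "chip_coordinates",
                                 orc2_peaks = peaks)
  sig_cols <- grep("^signal_", names(profiles), value = TRUE)
  cl <- cluster_gemsa(as.matrix(profiles[sig_cols]), k = 3,
                      restarts = restarts, seed = seed)
  profiles$cluster <- cl$cluster
  exclude <- study$origins$name[study$origins$telomeric_core_x]
  classification <- classify_joint(affinities, profiles, exclude = exclude)
  list(peaks = peaks, affinities = affinities, profiles = profiles,
       classification = classification)
}

#' Accuracy of a classification against the planted truth
#'
#' The denominator is every origin in the truth table; origins the
#' pipeline failed to call (no peak, or call `unclassified`) count as
#' errors.
#'
#' @param classification Data frame `origin`, `call`.
#' @param truth Truth table from [generate_study()].
#' @return Fraction of origins whose call equals the planted class.
#' @export
classification_accuracy <- function(classification, truth) {
  hit <- match(truth$origin, classification$origin)
  call <- ifelse(is.na(hit), "missing", classification$call[hit])
  mean(call == truth$true_class)
}
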