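# Apparent-Kd estimation from EMSA titrations.  The binding model is the
# one-site hyperbola with Bmax fixed at 1:
#
#     fraction bound  theta(c) = c / (Kd + c)
#
# fitted by least squares in log(Kd), with the estimate censored when the
# fitted Kd exceeds the assay's resolvable range.

#' Equilibrium occupancy of a one-site binding reaction
#'
#' `occupancy(conc, kd) = conc / (conc + kd)` with Bmax = 1, so that
#' occupancy is 0.5 at `conc == kd`, 0 at zero concentration, and strictly
#' increasing in concentration.
#'
#' @param conc Free protein concentration (nM), >= 0.
#' @param kd Dissociation constant (nM), > 0.
#' @return Fraction bound in `[0, 1)`.
#' @export
occupancy <- function(conc, kd) {
  if (any(kd <= 0)) stop("kd must be positive")
  if (any(conc < 0)) stop("conc must be non-negative")
  conc / (conc + kd)
}

#' Construct a Kd estimate
#'
#' @param kd Apparent Kd (nM); `NA` when censored.
#' @param stderr Standard error (nM) from the fit curvature or across
#'   replicates.
#' @param censored Logical; `TRUE` for "ND" / "> bound" estimates whose
#'   binding was too weak to determine an apparent Kd.  Censored estimates
#'   compare as greater than any finite threshold.
#' @param censor_bound Bound (nM) above which estimates are censored.
#' @param n_replicates Number of replicate fits combined.
#' @return An object of class `kd_estimate`.
#' @export
kd_estimate <- function(kd, stderr = NA_real_, censored = FALSE,
                        censor_bound = 420, n_replicates = 1L) {
  if (!censored && (is.na(kd) || kd <= 0)) {
    stop("kd must be positive when not censored")
  }
  structure(list(kd = if (censored) NA_real_ else kd,
                 stderr = stderr, censored = censored,
                 censor_bound = censor_bound,
                 n_replicates = n_replicates),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (x$censored) {
    cat("apparent Kd: ND (> ", x$censor_bound, " nM)\n", sep = "")
  } else {
    cat("apparent Kd: ", format(x$kd, digits = 4), " +/- ",
        format(x$stderr, digits = 3), " nM\n", sep = "")
  }
  invisible(x)
}

hyperbola_sse <- function(kd, conc, fraction) {
  sum((fraction - conc / (conc + kd))^2)
}

#' Fit an apparent Kd to an EMSA titration
#'
#' Least-squares fit of the one-site hyperbola with Bmax constrained to 1.
#' The single parameter is optimised on the log scale over a wide bracket,
#' which cannot fail to converge; the standard error comes from the
#' Gauss-Newton curvature of the residual surface.  The estimate is
#' censored ("ND") when the fitted Kd exceeds `censor_bound` or when
#' essentially no binding was observed (all fractions below
#' `min_signal`).
#'
#' @param conc Concentrations (nM); at least 3 distinct values.
#' @param fraction Fractions bound in `[0, 1]`, same length as `conc`.
#' @param censor_bound Censoring bound (nM); defaults to 420, just above
#'   the weakest binding the assay resolves.
#' @param min_signal Fraction-bound floor below which the curve is treated
#'   as showing no binding.
#' @return A [kd_estimate()].
#' @export
fit_apparent_kd <- function(conc, fraction, censor_bound = 420,
                            min_signal = 0.02) {
  stopifnot(length(conc) == length(fraction))
  if (length(unique(conc)) < 3L) {
    stop("at least 3 distinct concentrations required")
  }
  if (any(fraction < 0 | fraction > 1)) {
    stop("fractions bound must lie in [0, 1]")
  }
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (max(fraction) < min_signal) {
    return(kd_estimate(NA, censored = TRUE, censor_bound = censor_bound))
  }
  # bracket generous enough that the bound never binds for real titrations
  lo <- log(min(conc[conc > 0]) * 1e-4)
  hi <- log(max(conc) * 1e6)
  opt <- stats::optimize(function(lk) hyperbola_sse(exp(lk), conc, fraction),
                         interval = c(lo, hi), tol = 1e-12)
  kd <- exp(opt$minimum)
  if (kd > censor_bound) {
    return(kd_estimate(NA, censored = TRUE, censor_bound = censor_bound))
  }
  # curvature-based stderr: J_i = d theta / d Kd = -c_i / (Kd + c_i)^2
  jac <- -conc / (kd + conc)^2
  dof <- max(length(conc) - 1L, 1L)
  sigma2 <- opt$objective / dof
  se <- if (sum(jac^2) > 0) sqrt(sigma2 / sum(jac^2)) else NA_real_
  kd_estimate(kd, stderr = se, censor_bound = censor_bound)
}

#' Fit apparent Kds for a titration table with replicates
#'
#' Each replicate is fitted independently; the reported apparent Kd is the
#' mean of the replicate estimates with the standard error of that mean,
#' matching how triplicate EMSAs are conventionally summarised.  An origin
#' is censored when the majority of its replicates are censored.
#'
#' @param titrations Data frame with columns `origin`, `conc_nM`,
#'   `fraction_bound`, `replicate`.
#' @param censor_bound Censoring bound passed to [fit_apparent_kd()].
#' @return Named list of [kd_estimate()]s, one per origin.
#' @export
fit_titration_table <- function(titrations, censor_bound = 420) {
  required <- c("origin", "conc_nM", "fraction_bound", "replicate")
  stopifnot(all(required %in% names(titrations)))
  out <- list()
  for (origin in unique(titrations$origin)) {
    rows <- titrations[titrations$origin == origin, , drop = FALSE]
    fits <- lapply(split(rows, rows$replicate), function(rep_rows) {
      fit_apparent_kd(rep_rows$conc_nM, rep_rows$fraction_bound,
                      censor_bound = censor_bound)
    })
    cens <- vapply(fits, `[[`, logical(1), "censored")
    if (mean(cens) > 0.5) {
      out[[origin]] <- kd_estimate(NA, censored = TRUE,
                                   censor_bound = censor_bound,
                                   n_replicates = length(fits))
    } else {
      kds <- vapply(fits[!cens], `[[`, numeric(1), "kd")
      se <- if (length(kds) > 1L) stats::sd(kds) / sqrt(length(kds)) else NA_real_
      out[[origin]] <- kd_estimate(mean(kds), stderr = se,
                                   censor_bound = censor_bound,
                                   n_replicates = length(fits))
    }
  }
  out
}

#' Normalize an apparent Kd to a reference origin
#'
#' The fold is `kd / reference_kd`; the canonical reference is the
#' high-affinity silencer origin ARS317 (apparent Kd 7.223 nM), the
#' internal standard of every assay.  A censored input yields a censored
#' fold, represented as `Inf` so that it satisfies every ">" threshold.
#'
#' @param est A [kd_estimate()] (or positive number).
#' @param reference A non-censored [kd_estimate()] (or positive number).
#' @return Numeric fold; `Inf` for censored estimates.
#' @export
normalize_kd <- function(est, reference) {
  ref_kd <- if (inherits(reference, "kd_estimate")) {
    if (reference$censored) stop("reference Kd must not be censored")
    reference$kd
  } else {
    if (is.na(reference) || reference <= 0) stop("invalid reference Kd")
    reference
  }
  if (inherits(est, "kd_estimate")) {
    if (est$censored) return(Inf)
    est$kd / ref_kd
  } else {
    ifelse(is.na(est), Inf, est / ref_kd)
  }
}

#' Classify a normalized Kd fold against affinity thresholds
#'
#' Folds are binned into the bands used throughout the analysis:
#' `tight` (<= 3x the reference), `intermediate` (3-4x), `weak4x` (4-5x),
#' `weak5x` (5-10x) and `very_weak10x` (> 10x).  Censored folds (`Inf`)
#' satisfy every ">" threshold and land in `very_weak10x`.
#'
#' @param fold Numeric vector of Kd folds relative to the reference
#'   (`Inf` for censored).
#' @param thresholds Named list of band edges.
#' @return Character vector of band labels.
#' @export
kd_threshold_class <- function(fold,
                               thresholds = list(tight = 3, weak4 = 4,
                                                 weak5 = 5, very_weak = 10)) {
  stopifnot(thresholds$tight <= thresholds$weak4,
            thresholds$weak4 <= thresholds$weak5,
            thresholds$weak5 <= thresholds$very_weak)
  out <- rep(NA_character_, length(fold))
  out[fold <= thresholds$tight] <- "tight"
  out[fold > thresholds$tight & fold <= thresholds$weak4] <- "intermediate"
  out[fold > thresholds$weak4 & fold <= thresholds$weak5] <- "weak4x"
  out[fold > thresholds$weak5 & fold <= thresholds$very_weak] <- "weak5x"
  out[fold > thresholds$very_weak] <- "very_weak10x"
  out
}
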