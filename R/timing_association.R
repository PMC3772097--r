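# Association between origin classes and activation timing: replication
# time (Trep) group comparisons, hydroxyurea firing-status combination
# across two studies, in-vivo vs in-vitro affinity correlations, and
# set-overlap statistics.

#' Combine hydroxyurea firing calls from two studies
#'
#' An origin that fired in HU in wild-type cells in either study is
#' HU-resistant (`HUr_WT`); an origin that fired in HU only in rad53
#' mutant cells in one or both studies is HU-sensitive (`HUr_rad53`);
#' origins detected in neither study are `unknown`.
#'
#' @param study1,study2 Character vectors of per-origin calls in
#'   `{fires_WT, fires_rad53_only, not_detected}`.
#' @return Character vector in `{HUr_WT, HUr_rad53, unknown}`.
#' @export
combine_hu_status <- function(study1, study2) {
  valid <- c("fires_WT", "fires_rad53_only", "not_detected")
  stopifnot(length(study1) == length(study2),
            all(study1 %in% valid), all(study2 %in% valid))
  out <- rep("unknown", length(study1))
  out[study1 == "fires_rad53_only" | study2 == "fires_rad53_only"] <- "HUr_rad53"
  out[study1 == "fires_WT" | study2 == "fires_WT"] <- "HUr_WT"
  out
}

#' Compare mean replication times between origin classes
#'
#' Computes per-group means of Trep and a two-sided Welch t-test for each
#' requested pair of groups.  Groups with fewer than 2 timed origins are
#' flagged and excluded from testing.  Identical degenerate groups return
#' P = 1 by convention.
#'
#' @param timing Data frame with `origin` and `trep` (minutes; `NA`
#'   allowed, excluded pairwise).
#' @param classes Data frame with `origin` and `call` (group label).
#' @param pairs Optional list of 2-vectors of group labels to compare;
#'   all pairs by default.
#' @return List with `groups` (label, n, mean) and `tests` (pairs with
#'   Welch statistic and two-sided P).
#' @export
group_trep_test <- function(timing, classes, pairs = NULL) {
  df <- merge(timing[c("origin", "trep")], classes[c("origin", "call")],
              by = "origin")
  df <- df[is.finite(df$trep), , drop = FALSE]
  if (nrow(df) == 0L) stop("no timed origins in the supplied classes")
  groups <- do.call(rbind, lapply(split(df$trep, df$call), function(v) {
    data.frame(n = length(v), mean = mean(v))
  }))
  groups <- data.frame(group = rownames(groups), groups,
                       row.names = NULL, stringsAsFactors = FALSE)
  testable <- groups$group[groups$n >= 2L]
  if (is.null(pairs)) {
    pairs <- if (length(testable) >= 2L) {
      combn_list(testable)
    } else list()
  }
  tests <- lapply(pairs, function(pr) {
    if (!all(pr %in% testable)) {
      return(data.frame(group_a = pr[1], group_b = pr[2],
                        mean_a = NA_real_, mean_b = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        insufficient_n = TRUE, stringsAsFactors = FALSE))
    }
    w <- welch_test(df$trep[df$call == pr[1]], df$trep[df$call == pr[2]])
    data.frame(group_a = pr[1], group_b = pr[2],
               mean_a = w$mean_x, mean_b = w$mean_y,
               statistic = w$statistic, p_value = w$p_value,
               insufficient_n = FALSE, stringsAsFactors = FALSE)
  })
  list(groups = groups,
       tests = if (length(tests) > 0L) do.call(rbind, tests) else NULL)
}

combn_list <- function(x) {
  out <- list()
  for (i in seq_len(length(x) - 1L)) {
    for (j in seq(i + 1L, length(x))) {
      out[[length(out) + 1L]] <- c(x[i], x[j])
    }
  }
  out
}

#' Correlate in-vivo and in-vitro affinity measures
#'
#' Pearson product-moment and Spearman rank correlations (tie-averaged
#' ranks) with two-sided P-values from the t approximation
#' `t = r * sqrt((n-2) / (1-r^2))`.  Pairs with missing values are
#' excluded; a zero-variance input is flagged and returns no coefficient.
#'
#' @param x,y Paired numeric vectors (e.g. orc2-1/ORC2 ratios and total
#'   gEMSA signals).
#' @return List with `n`, `pearson` (`r`, `p`), `spearman` (`rho`, `p`),
#'   `degenerate` flag.
#' @export
affinity_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(n = n, pearson = list(r = NA_real_, p = NA_real_),
                spearman = list(rho = NA_real_, p = NA_real_),
                degenerate = TRUE))
  }
  cor_t_p <- function(r) {
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  r <- stats::cor(x, y)
  rho <- stats::cor(rank(x), rank(y))
  list(n = n,
       pearson = list(r = r, p = cor_t_p(r)),
       spearman = list(rho = rho, p = cor_t_p(rho)),
       degenerate = FALSE)
}

#' HU firing-status distribution per origin class
#'
#' Tallies HU-resistant (`HUr_WT`) versus HU-sensitive (`HUr_rad53`)
#' origins per class (`unknown` excluded) and, for each class, tests the
#' difference from the pooled distribution of all *other* origins with a
#' two-tailed Fisher's exact test on the 2x2 table.
#'
#' @param classes Data frame `origin`, `call`.
#' @param hu Data frame `origin`, `hu_status` in
#'   `{HUr_WT, HUr_rad53, unknown}`.
#' @return List with `counts` (class x status matrix) and `tests`
#'   (per-class two-tailed Fisher P vs the rest).
#' @export
contingency_distribution <- function(classes, hu) {
  df <- merge(classes[c("origin", "call")], hu[c("origin", "hu_status")],
              by = "origin")
  df <- df[df$hu_status %in% c("HUr_WT", "HUr_rad53"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no origins with known HU status")
  counts <- table(factor(df$call),
                  factor(df$hu_status, levels = c("HUr_WT", "HUr_rad53")))
  counts <- unclass(counts)
  tests <- lapply(rownames(counts), function(cls) {
    if (sum(counts[cls, ]) == 0L) stop("empty group: ", cls)
    rest <- colSums(counts[rownames(counts) != cls, , drop = FALSE])
    tab <- rbind(group = counts[cls, ], rest = rest)
    p <- if (sum(rest) == 0L) NA_real_ else {
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(group = cls, hur_wt = counts[cls, "HUr_WT"],
               hur_rad53 = counts[cls, "HUr_rad53"], p_value = p,
               stringsAsFactors = FALSE)
  })
  list(counts = counts, tests = do.call(rbind, tests))
}

#' Hypergeometric over-representation of a set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' intersection between two sets drawn from a common universe.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector of all eligible elements.
#' @return Upper-tail P-value for `|A intersect B|`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}
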