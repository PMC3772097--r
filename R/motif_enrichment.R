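# PWM scoring against a k-th order Markov background estimated from the
# genome.  A window score is
#     sum_j log2( f_j(b_j) / q(b_j | preceding k bases) )
# where f_j are pseudocounted column frequencies and q the smoothed
# conditional probabilities of the background model.  LOD percentages
# normalize scores to the motif's context-free score range (computed
# against the background's stationary base frequencies).

DNA_BASES <- c("A", "C", "G", "T")

seq_codes <- function(seq_string) {
  codes <- match(strsplit(toupper(seq_string), "")[[1]], DNA_BASES)
  codes   # NA for N and anything else
}

#' Estimate a k-th order Markov background model from a genome
#'
#' Conditional probabilities `q(b | context)` are estimated from the
#' forward-strand (k+1)-mer counts of the genome with add-one smoothing.
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param order Markov order k (default 4).
#' @return An object of class `markov_background` with the smoothed
#'   conditional table and stationary base frequencies.
#' @export
markov_background <- function(genome, order = 4) {
  genome <- validate_genome(genome)
  stopifnot(order >= 0)
  counts1 <- colSums(Biostrings::oligonucleotideFrequency(genome, width = 1))
  counts1 <- counts1[DNA_BASES]
  base_freq <- (counts1 + 1) / (sum(counts1) + 4)
  if (order == 0) {
    cond <- matrix(base_freq, nrow = 1,
                   dimnames = list(NULL, DNA_BASES))
  } else {
    counts <- colSums(Biostrings::oligonucleotideFrequency(
      genome, width = order + 1))
    # (k+1)-mers are lexicographic with the last base fastest, so the
    # counts vector reshapes into a (4^k contexts) x (4 bases) table
    cond <- matrix(counts, ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, DNA_BASES))
    cond <- (cond + 1) / (rowSums(cond) + 4)
  }
  structure(list(order = order, cond = cond, log2cond = log2(cond),
                 base_freq = base_freq),
            class = "markov_background")
}

#' Build a position-weight-matrix motif model
#'
#' Column frequencies are computed from an aligned set of fixed-width
#' binding-site sequences with a pseudocount; scoring is done against a
#' Markov background (see [markov_background()]).  `max_score` /
#' `min_score` delimit the motif's score range against the background's
#' stationary base frequencies and anchor the LOD percentage scale.
#'
#' @param sequences Character vector (or `DNAStringSet`) of aligned sites,
#'   all the same width, ACGT only.
#' @param genome Genome used to estimate the background (ignored when
#'   `background` is given).
#' @param order Background Markov order (default 4).
#' @param pseudocount Added to every cell of the count matrix (default 1).
#' @param background Optional pre-built [markov_background()].
#' @return An object of class `motif_model`.
#' @export
build_motif <- function(sequences, genome = NULL, order = 4,
                        pseudocount = 1, background = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("no sequences supplied")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) stop("sequences must all have the same width")
  width <- widths[1]
  codes <- vapply(sequences, seq_codes, integer(width))
  codes <- matrix(codes, nrow = width)
  if (anyNA(codes)) stop("motif sequences must contain only A, C, G, T")
  counts <- vapply(seq_len(width), function(j) {
    tabulate(codes[j, ], nbins = 4)
  }, numeric(4))                       # 4 x width
  freq <- (counts + pseudocount) /
    (length(sequences) + 4 * pseudocount)
  rownames(freq) <- DNA_BASES
  if (is.null(background)) {
    if (is.null(genome)) stop("either genome or background must be given")
    background <- markov_background(genome, order)
  }
  # zero-frequency cells (pseudocount 0) score -Inf; the LOD range floor
  # uses a tiny frequency so the percentage scale stays finite
  odds <- log2(pmax(freq, 1e-12)) - log2(background$base_freq)
  structure(list(width = width, freq = freq, log2freq = log2(freq),
                 background = background,
                 max_score = sum(apply(odds, 2, max)),
                 min_score = sum(apply(odds, 2, min))),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width ", x$width, " bp, background order ",
      x$background$order, ", score range [",
      format(x$min_score, digits = 4), ", ",
      format(x$max_score, digits = 4), "] bits\n", sep = "")
  invisible(x)
}

#' Bipartite motif: two parts separated by a fixed degenerate spacer
#'
#' Models composite ORC binding sites such as the extended ACS plus the
#' WTW element of B1, 13 degenerate nucleotides downstream.  The combined
#' score of a placement is the sum of the two part scores; the spacer is
#' unscored.
#'
#' @param part_a,part_b [build_motif()] models.
#' @param gap Spacer length in bp (default 13).
#' @return An object of class `bipartite_motif`.
#' @export
bipartite_motif <- function(part_a, part_b, gap = 13) {
  stopifnot(inherits(part_a, "motif_model"), inherits(part_b, "motif_model"),
            gap >= 0)
  structure(list(part_a = part_a, part_b = part_b, gap = gap,
                 width = part_a$width + gap + part_b$width,
                 max_score = part_a$max_score + part_b$max_score,
                 min_score = part_a$min_score + part_b$min_score),
            class = "bipartite_motif")
}

# Per-position log2 background probability of the observed base given its
# k preceding bases; NA where the context is incomplete or contains N.
position_log2q <- function(codes, background) {
  k <- background$order
  L <- length(codes)
  if (k == 0) {
    return(log2(background$base_freq)[codes])
  }
  ctx <- rep(0, L)
  for (d in seq_len(k)) {
    shifted <- c(rep(NA_integer_, d), codes)[seq_len(L)]
    ctx <- ctx + (shifted - 1L) * 4^(d - 1)
  }
  background$log2cond[cbind(ctx + 1, codes)]
}

# Score every window start of one oriented sequence; NA where the window
# (or any background context in it) is unusable.
motif_window_scores <- function(codes, motif) {
  w <- motif$width
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_win <- L - w + 1L
  logq <- position_log2q(codes, motif$background)
  bad <- is.na(logq)          # covers N bases and the first k positions
  csq <- cumsum(ifelse(bad, 0, logq))
  csb <- cumsum(bad)
  starts <- seq_len(n_win)
  q_sum <- csq[starts + w - 1L] - c(0, csq)[starts]
  n_bad <- csb[starts + w - 1L] - c(0, csb)[starts]
  mot <- rep(0, n_win)
  for (j in seq_len(w)) {
    mot <- mot + motif$log2freq[cbind(codes[starts + j - 1L], j)]
  }
  score <- unname(mot - q_sum)
  score[n_bad > 0] <- NA
  score
}

bipartite_window_scores <- function(codes, motif) {
  sa <- motif_window_scores(codes, motif$part_a)
  sb <- motif_window_scores(codes, motif$part_b)
  off <- motif$part_a$width + motif$gap
  n_win <- length(codes) - motif$width + 1L
  if (n_win < 1L) return(numeric(0))
  idx <- seq_len(n_win)
  sa[idx] + sb[idx + off]
}

#' Scan a genome for motif matches above an LOD cutoff
#'
#' Both strands are scanned; windows containing N, or whose Markov
#' background context is incomplete (within `order` bp of a contig start
#' in the scanned orientation), are skipped.  Overlapping matches are all
#' reported.  The LOD percentage of a match is
#' `100 * (score - min_score) / (max_score - min_score)`.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param motif A [build_motif()] or [bipartite_motif()] model.
#' @param lod_cutoff_pct Report matches with LOD percent at or above this
#'   cutoff (default 70).
#' @return Data frame `chrom`, `pos` (0-based match start on the forward
#'   strand), `strand`, `score`, `lod_pct`.
#' @export
scan_motif <- function(genome, motif, lod_cutoff_pct = 70) {
  genome <- validate_genome(genome)
  scorer <- if (inherits(motif, "bipartite_motif")) {
    bipartite_window_scores
  } else {
    motif_window_scores
  }
  res <- list()
  for (chrom in names(genome)) {
    fwd <- as.character(genome[[chrom]])
    L <- nchar(fwd)
    rev <- as.character(Biostrings::reverseComplement(genome[[chrom]]))
    for (strand in c("+", "-")) {
      s <- scorer(seq_codes(if (strand == "+") fwd else rev), motif)
      if (length(s) == 0L) next
      lod <- 100 * (s - motif$min_score) / (motif$max_score - motif$min_score)
      hit <- which(!is.na(lod) & lod >= lod_cutoff_pct)
      if (length(hit) == 0L) next
      pos0 <- hit - 1L
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom,
        pos = if (strand == "+") pos0 else L - pos0 - motif$width,
        strand = strand, score = s[hit], lod_pct = lod[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), score = numeric(),
                      lod_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of scannable window positions in a genome
#'
#' Counts the windows (both strands) a motif scan actually evaluates,
#' which is the position basis used in enrichment contingency tables.
#'
#' @inheritParams scan_motif
#' @return Integer count of valid windows over both strands.
#' @export
scan_positions <- function(genome, motif) {
  genome <- validate_genome(genome)
  scorer <- if (inherits(motif, "bipartite_motif")) {
    bipartite_window_scores
  } else {
    motif_window_scores
  }
  total <- 0L
  for (chrom in names(genome)) {
    fwd <- as.character(genome[[chrom]])
    rev <- as.character(Biostrings::reverseComplement(genome[[chrom]]))
    total <- total + sum(!is.na(scorer(seq_codes(fwd), motif))) +
      sum(!is.na(scorer(seq_codes(rev), motif)))
  }
  total
}

#' Motif density fold of a region set over the genome
#'
#' `(matches_set / set_bp) / (matches_genome / genome_bp)`: the factor by
#' which the per-bp motif match frequency in a region set exceeds the
#' genome-wide frequency.
#'
#' @param matches_set,matches_genome Match counts.
#' @param set_bp,genome_bp Region sizes in bp.
#' @return Unitless fold.
#' @export
density_fold <- function(matches_set, set_bp, matches_genome, genome_bp) {
  stopifnot(set_bp > 0, genome_bp > 0, matches_set >= 0)
  if (matches_genome <= 0) stop("no genome matches; fold undefined")
  (matches_set / set_bp) / (matches_genome / genome_bp)
}

#' One-tailed Fisher's exact test for motif over-representation
#'
#' Tests whether matches are over-represented among the scanned positions
#' of a region set relative to the genome-wide control, using the 2x2
#' table (match / non-match positions) x (set / genome).
#'
#' @param matches_set,positions_set Match count and scanned-position count
#'   in the region set.
#' @param matches_genome,positions_genome Same for the genome control.
#' @return One-tailed (over-representation) P-value.
#' @export
fisher_enrichment <- function(matches_set, positions_set,
                              matches_genome, positions_genome) {
  if (matches_set > positions_set || matches_genome > positions_genome ||
      any(c(matches_set, positions_set, matches_genome,
            positions_genome) < 0)) {
    stop("invalid contingency table")
  }
  tab <- matrix(c(matches_set, positions_set - matches_set,
                  matches_genome, positions_genome - matches_genome),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
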