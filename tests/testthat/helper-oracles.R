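# Independent brute-force oracles used to cross-check the vectorized
# implementations.  These are deliberately written in the most direct way
# possible and share no code with the package internals.

# Exhaustive log-spaced grid search for the one-site hyperbola Kd.
oracle_grid_kd <- function(conc, fraction, n_grid = 10000,
                           lo = 0.1, hi = 1000) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  sse <- vapply(grid, function(kd) {
    sum((fraction - conc / (conc + kd))^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Direct per-window peak caller: enumerate every window, compute the
# Gaussian tail probability, Bonferroni-correct, merge significant
# windows, and sum probe values.
oracle_call_peaks <- function(track, cfg, sigma) {
  all_windows <- list()
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    if (nrow(ch) == 0) next
    for (s in seq(0, max(ch$mid), by = cfg$step)) {
      in_w <- ch$mid >= s & ch$mid < s + cfg$window
      if (sum(in_w) < cfg$min_probes) next
      m <- mean(ch$value[in_w])
      p <- if (sigma <= 0) {
        if (m > 0) 0 else 1
      } else {
        pnorm(m, mean = 0, sd = sigma / sqrt(sum(in_w)), lower.tail = FALSE)
      }
      all_windows[[length(all_windows) + 1]] <-
        data.frame(chrom = chrom, start = s, end = s + cfg$window, p = p)
    }
  }
  if (length(all_windows) == 0) return(NULL)
  w <- do.call(rbind, all_windows)
  w$p_corr <- pmin(1, w$p * nrow(w))
  w <- w[w$p_corr <= cfg$p_cutoff, , drop = FALSE]
  if (nrow(w) == 0) return(NULL)
  peaks <- list()
  for (chrom in unique(w$chrom)) {
    sub <- w[w$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    cur_start <- sub$start[1]; cur_end <- sub$end[1]; cur_p <- sub$p_corr[1]
    flush <- function(start, end, p) {
      ch <- track$chroms[[chrom]]
      sel <- ch$mid >= start & ch$mid < end
      data.frame(chrom = chrom, start = start, end = end,
                 area = sum(ch$value[sel]), p_value = p,
                 n_probes = sum(sel))
    }
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] <= cur_end) {
          cur_end <- max(cur_end, sub$end[i])
          cur_p <- min(cur_p, sub$p_corr[i])
        } else {
          peaks[[length(peaks) + 1]] <- flush(cur_start, cur_end, cur_p)
          cur_start <- sub$start[i]; cur_end <- sub$end[i]
          cur_p <- sub$p_corr[i]
        }
      }
    }
    peaks[[length(peaks) + 1]] <- flush(cur_start, cur_end, cur_p)
  }
  out <- do.call(rbind, peaks)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-position motif rescoring straight from the sequence string.
oracle_scan_scores <- function(seq_string, motif) {
  bases <- strsplit(toupper(seq_string), "")[[1]]
  k <- motif$background$order
  w <- motif$width
  L <- length(bases)
  base_idx <- function(b) match(b, c("A", "C", "G", "T"))
  scores <- rep(NA_real_, L - w + 1)
  for (p in seq_len(L - w + 1)) {
    if (p <= k) next
    win <- bases[p:(p + w - 1)]
    ok <- TRUE
    sc <- 0
    for (j in seq_len(w)) {
      b <- base_idx(win[j])
      ctx <- bases[(p + j - 1 - k):(p + j - 2)]
      if (is.na(b) || anyNA(base_idx(ctx))) { ok <- FALSE; break }
      if (k == 0) {
        q <- motif$background$base_freq[b]
      } else {
        ctx_i <- sum((base_idx(ctx) - 1) * 4^((k - 1):0))
        q <- motif$background$cond[ctx_i + 1, b]
      }
      sc <- sc + log2(motif$freq[b, j]) - log2(q)
    }
    if (ok) scores[p] <- sc
  }
  scores
}

# Run-length NDR scanner working directly on the binned signal.
oracle_ndr_width <- function(signal, bins, threshold, search = 600) {
  bin <- bins[2] - bins[1]
  above <- !is.na(signal) & signal >= threshold
  plus1 <- NA; minus1 <- NA
  i <- 1
  n <- length(signal)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      run_start <- bins[i]; run_end <- bins[j] + bin
      if (run_end > -search && run_start < search) {
        if (run_start >= 0 && is.na(plus1)) plus1 <- run_start
        if (run_end <= 0) minus1 <- run_end
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (is.na(plus1) || is.na(minus1)) return(NA_real_)
  plus1 - minus1
}

# Exhaustive best k-means SSE over every assignment of n points to at
# most k non-empty clusters.
oracle_best_sse <- function(mat, k) {
  n <- nrow(mat)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    assign <- integer(n)
    c0 <- code
    for (i in seq_len(n)) { assign[i] <- c0 %% k; c0 <- c0 %/% k }
    sse <- 0
    for (cl in unique(assign)) {
      rows <- mat[assign == cl, , drop = FALSE]
      ctr <- colMeans(rows)
      sse <- sse + sum(sweep(rows, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Two-tailed Fisher probability by direct summation over the
# hypergeometric support (sum of all tables at most as probable as the
# observed one, R's convention).
oracle_fisher_two_tail <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation.
oracle_hyper_upper <- function(k, size_a, size_b, size_u) {
  support <- k:min(size_a, size_b)
  sum(dhyper(support, size_a, size_u - size_a, size_b))
}

random_test_track <- function(n_probes = 400, spacing = 25, noise = 0.2,
                              peaks = 0, condition = "t") {
  mids <- seq(spacing %/% 2, by = spacing, length.out = n_probes)
  value <- rnorm(n_probes, 0, noise)
  if (peaks > 0) {
    for (i in seq_len(peaks)) {
      ctr <- sample(mids, 1)
      sel <- abs(mids - ctr) <= 120
      value[sel] <- value[sel] + runif(1, 1, 3)
    }
  }
  probe_track(list(chrT = data.frame(mid = mids, value = value)),
              condition = condition)
}

random_genome <- function(len, seed = NULL, name = "chrR",
                          probs = c(0.3, 0.2, 0.2, 0.3)) {
  if (!is.null(seed)) set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = probs), collapse = "")
  stats::setNames(s, name)
}
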