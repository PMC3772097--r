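balanced_genome <- function() {
  # equal base frequencies so the order-0 background is uniform
  stats::setNames(paste(rep("ACGT", 2500), collapse = ""), "chrB")
}

test_that("consensus-only motifs score exactly max_score under an order-0 background", {
  motif <- build_motif(rep("TTTTACGT", 10), genome = balanced_genome(),
                       order = 0, pseudocount = 0)
  sc <- oriclass:::motif_window_scores(oriclass:::seq_codes("TTTTACGT"), motif)
  expect_equal(sc[1], motif$max_score, tolerance = 1e-9)
  # order-0 equal-frequency background: score is sum of log2(4 * f_i(b))
  f <- motif$freq
  expect_equal(motif$max_score,
               sum(log2(4 * apply(f, 2, max))), tolerance = 1e-6)
  expect_error(build_motif(c("ACGT", "ACG"), balanced_genome()), "width")
  expect_error(build_motif("ACNG", balanced_genome()), "A, C, G, T")
})

test_that("uniform-random alignments carry near-zero information content", {
  set.seed(31)
  seqs <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
  }, character(1))
  motif <- build_motif(seqs, genome = balanced_genome(), order = 0)
  ic_per_col <- 2 + colSums(motif$freq * log2(motif$freq))
  expect_true(all(ic_per_col < 0.05))
})

test_that("planted consensus sites are found at 100% LOD and a 100% cutoff is exact", {
  set.seed(32)
  g <- random_genome(4000, name = "chrP", probs = rep(0.25, 4))
  site <- "TTTTACGTTTT"
  substr(g, 1001, 1011) <- site
  motif <- build_motif(site, genome = balanced_genome(), order = 0,
                       pseudocount = 0)
  hits <- scan_motif(g, motif, lod_cutoff_pct = 100 - 1e-6)
  fwd <- hits[hits$strand == "+", ]
  expect_true(1000 %in% fwd$pos)          # 0-based planted position
  expect_equal(fwd$lod_pct[fwd$pos == 1000], 100)
  # every 100%-LOD hit is an exact consensus occurrence
  for (p in fwd$pos) expect_equal(unname(substr(g, p + 1, p + 11)), site)
})

test_that("scanning matches a per-position rescoring oracle with a 4th-order background", {
  set.seed(33)
  g <- random_genome(5000, name = "chrO")
  bg_genome <- random_genome(20000, name = "chrBG")
  motif <- build_motif(c("TTTTATGTTTA", "TTTTATGTTTT", "TTTAATGTTTA"),
                       genome = bg_genome, order = 4)
  hits <- scan_motif(g, motif, lod_cutoff_pct = -Inf)
  fwd <- hits[hits$strand == "+", ]
  oracle <- oracle_scan_scores(g, motif)
  expect_equal(fwd$pos, which(!is.na(oracle)) - 1L)
  expect_equal(fwd$score, oracle[!is.na(oracle)], tolerance = 1e-9)

  # minus-strand scores equal the oracle on the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  oracle_rc <- oracle_scan_scores(rc, motif)
  rev_hits <- hits[hits$strand == "-", ]
  L <- nchar(g)
  expect_equal(sort(rev_hits$pos),
               sort(L - (which(!is.na(oracle_rc)) - 1L) - motif$width))
})

test_that("match sets are strand-symmetric under genome reverse complement", {
  set.seed(34)
  g <- random_genome(3000, name = "chrS")
  bg <- random_genome(20000, name = "chrBG")
  motif <- build_motif(c("TTTTATGTTTA", "TTTCATGTTTA"), genome = bg, order = 2)
  h1 <- scan_motif(g, motif, lod_cutoff_pct = 60)
  grc <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g))), "chrS")
  h2 <- scan_motif(grc, motif, lod_cutoff_pct = 60)
  L <- nchar(g)
  mirrored <- data.frame(pos = L - h2$pos - motif$width,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  o1 <- h1[order(h1$pos, h1$strand), ]
  o2 <- mirrored[order(mirrored$pos, mirrored$strand), ]
  expect_equal(o1$pos, o2$pos)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score, tolerance = 1e-9)
})

test_that("bipartite motifs score both parts across a fixed degenerate spacer", {
  bg <- balanced_genome()
  eacs <- build_motif("TTTTATGTTTAGTTTAT", genome = bg, order = 0,
                      pseudocount = 0)
  wtw <- build_motif("TAT", genome = bg, order = 0, pseudocount = 0)
  bip <- bipartite_motif(eacs, wtw, gap = 13)
  expect_equal(bip$width, 17 + 13 + 3)
  set.seed(35)
  g <- random_genome(2000, name = "chrB2", probs = rep(0.25, 4))
  planted <- paste0("TTTTATGTTTAGTTTAT",
                    paste(sample(c("A", "C", "G", "T"), 13, TRUE),
                          collapse = ""), "TAT")
  substr(g, 501, 500 + nchar(planted)) <- planted
  hits <- scan_motif(g, bip, lod_cutoff_pct = 100 - 1e-6)
  expect_true(500 %in% hits$pos[hits$strand == "+"])
})

test_that("density folds reproduce the printed desk arithmetic", {
  expect_equal(density_fold(875, 1.9e6, 4300, 12.1e6), 1.296, tolerance = 1e-3)
  expect_equal(density_fold(1038, 1.8e6, 4300, 12.1e6), 1.62, tolerance = 5e-3)
  expect_equal(density_fold(10, 100, 100, 1000), 1.0)
  expect_error(density_fold(5, 100, 0, 1000), "fold undefined")
})

test_that("Fisher enrichment matches the hypergeometric tail and is monotone", {
  p <- fisher_enrichment(8, 10, 2, 10)
  expect_equal(p, oracle_hyper_upper(8, 10, 10, 20), tolerance = 1e-10)
  # no enrichment at identical proportions
  expect_gte(fisher_enrichment(50, 1000, 500, 10000), 0.4)
  # increasing set matches at fixed margins never increases P
  ps <- vapply(3:9, function(a) fisher_enrichment(a, 10, 12 - a, 10),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(fisher_enrichment(11, 10, 5, 100), "invalid")
})
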