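small_cfg <- function(..., n = 8, seed = 13L) {
  simulation_config(
    n_per_class = c(chromatin_dependent = n, dna_dependent = n, weak = n),
    seed = seed, ...)
}

test_that("expected depletion ratios follow the occupancy arithmetic", {
  cfg <- simulation_config()
  # kd_eff = C/100: theta(C/10)/theta(C) = (10/11)/(100/101)
  expect_equal(simulate_in_vivo_ratio(0.3, 1, cfg),
               (10 / 11) / (100 / 101), tolerance = 1e-12)
  expect_equal(simulate_in_vivo_ratio(30, 1, cfg),
               (3 / 33) / 0.5, tolerance = 1e-12)
  # infinite chromatin boost drives the ratio to 1
  expect_equal(simulate_in_vivo_ratio(100, 1e12, cfg), 1, tolerance = 1e-6)
  # ratios are bounded in (0, 1]
  expect_true(all(simulate_in_vivo_ratio(runif(50, 1, 500),
                                         runif(50, 1, 100), cfg) <= 1))
})

test_that("seeded generation is deterministic", {
  s1 <- generate_study(small_cfg())
  s2 <- generate_study(small_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tracks$ORC2$chroms, s2$tracks$ORC2$chroms)
  expect_identical(s1$titrations, s2$titrations)
  s3 <- generate_study(small_cfg(seed = 14L))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("planted classes satisfy the noise-free ratio band invariants", {
  st <- generate_study(small_cfg(n = 20))
  tr <- st$truth
  expect_true(all(tr$expected_ratio[tr$true_class == "chromatin_dependent"]
                  >= 0.8))
  expect_true(all(tr$expected_ratio[tr$true_class == "dna_dependent"] >= 0.8))
  expect_true(all(tr$expected_ratio[tr$true_class == "weak"] <= 0.3))
  expect_true(all(tr$chromatin_boost[tr$true_class == "chromatin_dependent"]
                  >= 10))
  expect_true(all(tr$kd_dna > 0))
})

test_that("gEMSA signal reflects naked DNA: independent of the in-vivo boost", {
  cfg_a <- small_cfg(noise_sd = 0)
  cfg_b <- small_cfg(noise_sd = 0,
                     kd_vivo_ranges = list(chromatin_dependent = c(1, 2),
                                           dna_dependent = c(1, 2),
                                           weak = c(1, 2),
                                           complex = c(1, 2)))
  sa <- generate_study(cfg_a)
  sb <- generate_study(cfg_b)
  expect_identical(sa$truth$kd_dna, sb$truth$kd_dna)
  expect_false(identical(sa$truth$kd_vivo, sb$truth$kd_vivo))
  for (cc in names(sa$tracks$gemsa)) {
    expect_equal(sa$tracks$gemsa[[cc]]$chroms$chrS$value,
                 sb$tracks$gemsa[[cc]]$chroms$chrS$value, tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(sa$tracks$ORC2$chroms$chrS$value,
                                sb$tracks$ORC2$chroms$chrS$value)))
})

test_that("a noise-free study is classified perfectly end to end", {
  cfg <- small_cfg(noise_sd = 0, titration_noise_sd = 0, nuc_noise_sd = 0)
  st <- generate_study(cfg)
  res <- classify_study(st, restarts = 300, seed = 2L)
  expect_equal(classification_accuracy(res$classification, st$truth), 1)
})

test_that("planted ACS instances are rediscovered by the motif scanner", {
  st <- generate_study(small_cfg(n = 10))
  # anchor coordinates -> leftmost coordinate of each planted 11-mer
  left <- ifelse(st$origins$acs_strand == "+", st$origins$acs_pos,
                 st$origins$acs_pos - 10L)
  instances <- substring(as.character(st$genome[[1]]), left + 1, left + 11)
  rc <- st$origins$acs_strand == "-"
  instances[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(instances[rc])))
  expect_true(all(instances == instances[1]))  # the planted consensus
  motif <- build_motif(instances, genome = st$genome, order = 4)
  hits <- scan_motif(st$genome, motif, lod_cutoff_pct = 70)
  ok <- vapply(seq_len(nrow(st$origins)), function(i) {
    any(hits$pos == left[i] & hits$strand == st$origins$acs_strand[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("titrations, timing and nucleosome outputs carry the planted structure", {
  st <- generate_study(small_cfg(n = 12, seed = 21L))
  # titration fits recover the intrinsic Kd ordering: chromatin-dependent
  # origins bind naked DNA far more weakly than dna-dependent ones
  fits <- fit_titration_table(st$titrations)
  kd_of <- function(o) {
    e <- fits[[o]]
    if (e$censored) Inf else e$kd
  }
  tr <- st$truth
  dna_kds <- vapply(tr$origin[tr$true_class == "dna_dependent"], kd_of,
                    numeric(1))
  chr_kds <- vapply(tr$origin[tr$true_class == "chromatin_dependent"], kd_of,
                    numeric(1))
  expect_lt(max(dna_kds), min(chr_kds))
  # the reference titration fits near its configured Kd
  expect_equal(fits$REF$kd, st$config$reference_kd, tolerance = 0.8)

  # NDR deltas: ORC loss encroaches strongly at dna/weak, weakly at
  # chromatin-dependent origins
  wt <- ndr_measurements(st$nucleosome$wt, st$origins)
  mut <- ndr_measurements(st$nucleosome$orc_minus, st$origins)
  groups <- data.frame(origin = tr$origin, group = tr$true_class)
  res <- delta_ndr(wt, mut, groups)
  dd <- res$group_means[["dna_dependent"]] -
    res$group_means[["chromatin_dependent"]]
  expect_equal(dd, 100, tolerance = 10)

  # Trep means: chromatin-dependent origins replicate earlier
  tt <- group_trep_test(st$timing,
                        data.frame(origin = tr$origin, call = tr$true_class),
                        pairs = list(c("chromatin_dependent",
                                       "dna_dependent")))
  expect_lt(tt$tests$mean_a, tt$tests$mean_b)
})
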