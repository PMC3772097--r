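two_origin_setup <- function(orc21_scale = 1) {
  mids <- seq(5, 3995, by = 10)
  val <- ifelse(mids >= 900 & mids < 1100, 2,
                ifelse(mids >= 2900 & mids < 3100, 1, 0))
  orc2 <- probe_track(list(c1 = data.frame(mid = mids, value = val)), "ORC2")
  orc21 <- probe_track(list(c1 = data.frame(mid = mids,
                                            value = val * orc21_scale)),
                       "orc2-1")
  origins <- data.frame(name = c("A", "B"), chrom = "c1",
                        start = c(800, 2800), end = c(1200, 3200),
                        status = "confirmed", acs_pos = NA_integer_,
                        acs_strand = NA_character_,
                        telomeric_core_x = FALSE)
  peaks <- data.frame(chrom = "c1", start = c(880, 2880),
                      end = c(1120, 3120), area = c(40, 20),
                      p_value = 0, n_probes = 24)
  list(orc2 = orc2, orc21 = orc21, origins = origins, peaks = peaks)
}

test_that("ratio classes use inclusive 0.3 / 0.8 boundaries", {
  expect_equal(ratio_class(c(0.3, 0.8, 0.31, 0.79, -0.1, 1.2)),
               c("sensitive", "resistant", "moderate", "moderate",
                 "sensitive", "resistant"))
})

test_that("in-vivo ratios are measured over the wild-type peak coordinates", {
  s <- two_origin_setup(orc21_scale = 1)
  aff <- in_vivo_ratio(s$orc2, s$orc21, s$peaks, s$origins)
  expect_setequal(aff$origin, c("A", "B"))
  expect_equal(aff$ratio, c(1, 1))
  expect_equal(aff$ratio_class, c("resistant", "resistant"))

  s0 <- two_origin_setup(orc21_scale = 0)
  aff0 <- in_vivo_ratio(s0$orc2, s0$orc21, s0$peaks, s0$origins)
  expect_equal(aff0$ratio, c(0, 0))
  expect_equal(aff0$ratio_class, c("sensitive", "sensitive"))
})

test_that("total gEMSA signal sums the three concentrations per mode", {
  s <- two_origin_setup()
  tracks <- list("0.3" = s$orc2, "3" = s$orc2, "30" = s$orc2)
  prof <- total_gemsa_signal(tracks, s$origins, mode = "chip_coordinates",
                             orc2_peaks = s$peaks)
  a_area <- as.numeric(peak_area_over(s$orc2, "c1", 880, 1120))
  expect_equal(prof$total[prof$origin == "A"], 3 * a_area)
  expect_equal(prof$total, prof$signal_0.3 + prof$signal_3 + prof$signal_30)

  # called-peaks mode: a flat gEMSA track has no peaks, so signals are 0
  flat <- probe_track(list(c1 = data.frame(mid = seq(5, 3995, by = 10),
                                           value = 0)), "flat")
  prof0 <- total_gemsa_signal(list("0.3" = flat, "3" = flat, "30" = flat),
                              s$origins, mode = "called_peaks",
                              orc2_peaks = NULL)
  expect_equal(prof0$total, c(0, 0))

  # chip-coordinates mode admits negative totals
  neg <- probe_track(list(c1 = data.frame(mid = seq(5, 3995, by = 10),
                                          value = -0.1)), "neg")
  profn <- total_gemsa_signal(list("0.3" = neg, "3" = neg, "30" = neg),
                              s$origins, mode = "chip_coordinates",
                              orc2_peaks = s$peaks)
  expect_true(all(profn$total < 0))
})

test_that("k-means recovers separated blobs and matches the exhaustive oracle", {
  set.seed(99)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 3, 0, 0.05), n, 3), 2, center, `+`)
  }
  mat <- rbind(blob(c(0, 0, 0), 15), blob(c(5, 5, 5), 15),
               blob(c(10, 10, 10), 15))
  cl <- cluster_gemsa(mat, k = 3, restarts = 100, seed = 4L)
  expect_equal(cl$cluster, rep(c("Weak", "Moderate", "Strong"), each = 15))

  small <- matrix(runif(18), 6, 3)
  cl6 <- cluster_gemsa(small, k = 3, restarts = 500, seed = 4L)
  expect_equal(cl6$tot_withinss, oracle_best_sse(small, 3),
               tolerance = 1e-10)
})

test_that("clustering is deterministic and label-stable under input permutation", {
  set.seed(12)
  mat <- rbind(matrix(rnorm(60, 0, 0.4), 20, 3),
               matrix(rnorm(60, 6, 0.4), 20, 3),
               matrix(rnorm(60, 12, 0.4), 20, 3))
  rownames(mat) <- sprintf("o%02d", 1:60)
  cl1 <- cluster_gemsa(mat, restarts = 300, seed = 8L)
  perm <- sample(60)
  cl2 <- cluster_gemsa(mat[perm, ], restarts = 300, seed = 8L)
  m1 <- stats::setNames(cl1$cluster, rownames(mat))
  m2 <- stats::setNames(cl2$cluster, rownames(mat)[perm])
  expect_equal(m1[rownames(mat)], m2[rownames(mat)])
  # best SSE is non-increasing in the number of restarts
  sse_few <- cluster_gemsa(mat, restarts = 2, seed = 8L)$tot_withinss
  sse_many <- cluster_gemsa(mat, restarts = 300, seed = 8L)$tot_withinss
  expect_lte(sse_many, sse_few)
  expect_error(cluster_gemsa(mat[1:2, ], k = 3), "at least k")
})

test_that("the joint gEMSA-route rules classify ratio x cluster combinations", {
  aff <- data.frame(origin = c("r_weak", "r_strong", "m_weak", "s_weak",
                               "r_mod", "tel"),
                    ratio_class = c("resistant", "resistant", "moderate",
                                    "sensitive", "resistant", "resistant"))
  prof <- data.frame(origin = aff$origin,
                     cluster = c("Weak", "Strong", "Weak", "Weak",
                                 "Moderate", "Weak"))
  cls <- classify_joint(aff, prof, exclude = "tel")
  got <- stats::setNames(cls$call, cls$origin)
  expect_equal(unname(got["r_weak"]), "chromatin_dependent")
  expect_equal(unname(got["r_strong"]), "dna_dependent")
  expect_equal(unname(got["r_mod"]), "dna_dependent")
  expect_equal(unname(got["m_weak"]), "unclassified")
  expect_equal(unname(got["s_weak"]), "weak")
  expect_false("tel" %in% cls$origin)
  # partition: exactly one call per non-excluded origin
  expect_equal(sort(cls$origin), sort(setdiff(aff$origin, "tel")))
})

test_that("the EMSA-threshold route reproduces the published example origins", {
  survey <- emsa_origin_survey()
  ref <- survey$kd[survey$origin == "ARS317"]
  folds <- stats::setNames(ifelse(is.na(survey$kd), Inf, survey$kd / ref),
                           survey$origin)
  aff <- data.frame(origin = survey$origin,
                    ratio_class = ratio_class(survey$ratio))
  cls <- classify_by_emsa(aff, folds)
  got <- stats::setNames(cls$call, cls$origin)
  expect_equal(unname(got["ARS317"]), "dna_dependent")
  expect_equal(unname(got["ARS1528"]), "chromatin_dependent")
  expect_equal(unname(got["ARS1332"]), "complex")
  expect_equal(unname(got["ARS416"]), "unclassified")   # moderate band
  expect_equal(unname(got["ARS1413"]), "weak")
  expect_equal(nrow(cls), nrow(survey))                 # partition holds
})

test_that("the EMSA-threshold and gEMSA-cluster routes agree on resistant origins", {
  agree <- total <- 0L
  for (s in 1:10) {
    st <- generate_study(simulation_config(
      n_per_class = c(chromatin_dependent = 12, dna_dependent = 12,
                      weak = 12), seed = 600L + s))
    res <- classify_study(st, restarts = 300, seed = 1L)
    fits <- fit_titration_table(st$titrations)
    folds <- vapply(names(fits), function(o) {
      normalize_kd(fits[[o]], fits$REF)
    }, numeric(1))
    emsa <- classify_by_emsa(res$affinities, folds)
    joint <- merge(res$classification, emsa, by = "origin",
                   suffixes = c("_gemsa", "_emsa"))
    joint <- merge(joint, res$affinities[c("origin", "ratio_class")],
                   by = "origin")
    resist <- joint[joint$ratio_class == "resistant", ]
    total <- total + nrow(resist)
    agree <- agree + sum(resist$call_gemsa == resist$call_emsa)
  }
  expect_gte(agree / total, 0.85)
})
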