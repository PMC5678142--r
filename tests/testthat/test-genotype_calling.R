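test_that("normalization subtracts the NTC baseline and yields polar geometry", {
  ntc_mean <- 60
  p <- toy_panel(clones = tibble::tibble(
    sample_id = c("at_ntc", "pure_wt", "het"),
    rfu_mut = ntc_mean + c(0, 0, 1000),
    rfu_wt = ntc_mean + c(0, 500, 1000)))
  norm <- normalize_readings(p)
  r <- norm$readings
  expect_equal(norm$ntc$mean_wt, ntc_mean)
  expect_equal(norm$ntc$mean_mut, ntc_mean)
  at_ntc <- r[r$sample_id == "at_ntc", ]
  expect_equal(at_ntc$magnitude, 0)
  expect_true(is.na(at_ntc$angle))
  pure_wt <- r[r$sample_id == "pure_wt", ]
  expect_equal(pure_wt$angle, 0)
  expect_equal(pure_wt$magnitude, 500)
  het <- r[r$sample_id == "het", ]
  expect_equal(het$angle, 45, tolerance = 1e-6)

  no_ntc <- plate_panel(p$readings[p$readings$role != "ntc", ])
  expect_error(normalize_readings(no_ntc), class = "kaspcall_config_error")
})

test_that("control clusters sit at closed-form centroids, including gain asymmetry", {
  norm <- normalize_readings(toy_panel())
  model <- fit_control_clusters(norm)
  expect_equal(model$classes$centroid_angle, c(0, 45, 90), tolerance = 1e-9)
  expect_equal(model$classes$angle_sd, rep(0.75, 3))
  expect_equal(model$amp_threshold, 120)  # raw NTC magnitude mean, sd 0

  # mutant-channel gain x2: het controls move to atan2(1, 0.5) = 63.435 deg
  sim <- simulate_clone_screen(4, params = noise_free_params(channel_efficiency = 2),
                               seed = 1)
  m2 <- fit_control_clusters(normalize_readings(sim$panel))
  expect_equal(m2$classes$centroid_angle, c(0, atan2(1, 0.5) * 180 / pi, 90),
               tolerance = 1e-9)
})

test_that("mislabeled controls violate the centroid ordering and error", {
  p <- toy_panel()
  r <- p$readings
  swap <- r$role == "control_wt_mut"
  r$role[r$role == "control_mut_mut"] <- "control_wt_mut"
  r$role[swap] <- "control_mut_mut"
  expect_error(fit_control_clusters(normalize_readings(plate_panel(r))),
               "ordered", class = "kaspcall_validation_error")
  # too few controls in a class
  r2 <- p$readings[p$readings$sample_id != "mm2", ]
  expect_error(fit_control_clusters(normalize_readings(plate_panel(r2))),
               "mut_mut", class = "kaspcall_config_error")
})

test_that("noise-free calls are 100% concordant with truth, NHEJ compounds included", {
  sim <- simulate_clone_screen(400, cells_per_well = 1, p_hdr_allele = 0.3,
                               p_nhej_allele = 0.3,
                               params = noise_free_params(), seed = 42)
  norm <- normalize_readings(sim$panel)
  model <- fit_control_clusters(norm)
  calls <- call_genotypes(norm, model)
  j <- merge(calls, sim$truth, by = "sample_id")
  expect_equal(nrow(j), 400)
  expect_true(all(c("NO_AMP", "WT_WT", "WT_MUT", "MUT_MUT") %in% j$call))
  expect_identical(j$call, j$true_class)
  # half-signal flag raised exactly for amplifying clones with an NHEJ allele
  classed <- j$call %in% c("WT_WT", "WT_MUT", "MUT_MUT")
  expect_identical(j$half_signal_flag, j$half_signal & classed)
  # NO_AMP wells carry no nearest class
  expect_true(all(is.na(j$nearest_class[j$call == "NO_AMP"])))
})

test_that("a 5% mutant-fraction multi-cell well is INTERMEDIATE and ranked by HDR-likeness", {
  clones <- tibble::tibble(
    sample_id = c("multi05", "multi10", "plain_wt"),
    rfu_mut = 60 + 2000 * c(0.05, 0.10, 0),
    rfu_wt = 60 + 2000 * c(0.95, 0.90, 1))
  norm <- normalize_readings(toy_panel(clones = clones))
  model <- fit_control_clusters(norm)
  calls <- call_genotypes(norm, model)
  expect_equal(calls$call[calls$sample_id == "multi05"], "INTERMEDIATE")
  expect_equal(calls$call[calls$sample_id == "multi10"], "INTERMEDIATE")
  expect_equal(calls$call[calls$sample_id == "plain_wt"], "WT_WT")
  expect_equal(calls$nearest_class[calls$sample_id == "multi05"], "wt_wt")
  cand <- detect_intermediate_wells(calls, model)
  # larger mutant fraction is closer to the heterozygous centroid: first
  expect_equal(cand$sample_id, c("multi10", "multi05"))
  # no intermediates -> empty
  none <- calls[calls$call != "INTERMEDIATE", ]
  expect_equal(nrow(detect_intermediate_wells(none, model)), 0)
})

test_that("a multi-cell screen flags exactly the HDR-containing wells", {
  # 53 ten-cell wells, 2 of which carry one heterozygous HDR cell
  frac <- rep(0, 53)
  frac[c(17, 40)] <- multiwell_mut_fraction(10, 1, 0) / 100
  clones <- tibble::tibble(
    sample_id = sprintf("multi_%02d", 1:53),
    rfu_mut = 60 + 2000 * frac,
    rfu_wt = 60 + 2000 * (1 - frac))
  norm <- normalize_readings(toy_panel(clones = clones))
  model <- fit_control_clusters(norm)
  cand <- detect_intermediate_wells(call_genotypes(norm, model), model)
  expect_setequal(cand$sample_id, c("multi_17", "multi_40"))
})

test_that("calls are invariant to a common gain and monotone in the mutant channel", {
  sim <- simulate_clone_screen(120, p_hdr_allele = 0.25, p_nhej_allele = 0.25,
                               seed = 9)
  norm <- normalize_readings(sim$panel)
  model <- fit_control_clusters(norm)
  calls <- call_genotypes(norm, model)

  scaled <- sim$panel$readings
  scaled$rfu_mut <- scaled$rfu_mut * 3.7
  scaled$rfu_wt <- scaled$rfu_wt * 3.7
  norm2 <- normalize_readings(plate_panel(scaled))
  calls2 <- call_genotypes(norm2, fit_control_clusters(norm2))
  expect_identical(calls$call, calls2$call)
  expect_identical(calls$half_signal_flag, calls2$half_signal_flag)

  # monotonicity: with a fixed model, raising the mutant channel never moves
  # the call from a more-mutant class to a less-mutant one (INTERMEDIATE is
  # not a class; it fills the gaps between adjacent class windows)
  rank <- c(WT_WT = 1, WT_MUT = 2, MUT_MUT = 3)
  base <- toy_panel(clones = tibble::tibble(
    sample_id = "sweep", rfu_mut = 60, rfu_wt = 60 + 1800))
  model_b <- fit_control_clusters(normalize_readings(base))
  labs <- vapply(sort(c(seq(0, 4000, by = 50), seq(6000, 60000, by = 2000))),
                 function(y) {
    r <- base$readings
    r$rfu_mut[r$sample_id == "sweep"] <- 60 + y
    cl <- call_genotypes(normalize_readings(plate_panel(r)), model_b)
    cl$call[cl$sample_id == "sweep"]
  }, character(1))
  classed <- rank[labs[labs %in% names(rank)]]
  expect_true(!is.unsorted(classed))
  expect_true(all(c("WT_WT", "WT_MUT", "MUT_MUT") %in% labs))
  expect_true("INTERMEDIATE" %in% labs)
})

test_that("pure-NTC wells are never called amplified under default NTC noise", {
  sim <- simulate_clone_screen(2000, p_hdr_allele = 0, p_nhej_allele = 1,
                               seed = 31)  # every allele NHEJ: NTC-like wells
  norm <- normalize_readings(sim$panel)
  calls <- call_genotypes(norm, fit_control_clusters(norm))
  expect_true(mean(calls$call == "NO_AMP") >= 1 - 1e-3)
})
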