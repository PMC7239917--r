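test_that("generate_scenario is reproducible and well-shaped", {
  sc <- generate_scenario(5, 45, seed = 1)
  expect_s3_class(sc, "bnm_scenario")
  expect_length(sc$lakes, 5)
  expect_equal(nrow(sc$drivers_data), 5 * 45)
  expect_equal(as.integer(table(sc$drivers_data$lake_id)), rep(45L, 5))
  sc2 <- generate_scenario(5, 45, seed = 1)
  expect_identical(sc, sc2)
  expect_error(generate_scenario(0, 45, 1), "n_lakes")
  expect_error(generate_scenario(5, 5, 1), "n_years")
})

test_that("AT -> WT slope is positive in every lake by default and PE maps
           linearly to AT with positive slope", {
  sc <- generate_scenario(31, 45, seed = 2)
  slopes <- vapply(sc$lakes, function(l) l$coef$WT[["AT"]], numeric(1))
  expect_true(all(slopes > 0))
  for (lk in sc$lakes) expect_gt(lk$drivers$PE_b, 0)
  d <- sc$drivers_data[sc$drivers_data$lake_id == "L01", ]
  dr <- sc$lakes$L01$drivers
  expect_equal(d$PE, dr$PE_a + dr$PE_b * d$AT)
})

test_that("noiseless simulation reproduces the exact means", {
  sc <- generate_scenario(2, 20, seed = 3, sigma_frac = 0)
  panel <- forward_simulate(sc, seed = 4)
  for (id in names(sc$lakes)) {
    sub <- panel[panel$lake_id == id, ]
    co <- sc$lakes[[id]]$coef
    expect_equal(sub$WT, unname(co$WT["Intercept"] + co$WT["AT"] * sub$AT))
    mu <- predicted_means(co, sub, sc$lakes[[id]]$stocking)
    expect_equal(log(sub$CATCH), mu$muCATCH)
    expect_equal(log(sub$CHL), mu$muCHL)
  }
})

test_that("simulated CHL, CATCH, EFF are strictly positive", {
  sc <- generate_scenario(8, 45, seed = 5, sigma_frac = 0.3)
  panel <- forward_simulate(sc, seed = 6)
  expect_true(all(panel$CHL > 0))
  expect_true(all(panel$CATCH > 0))
  expect_true(all(panel$EFF > 0))
})

test_that("WT residuals match the stated normal law (Monte-Carlo)", {
  sc <- generate_scenario(1, 10000, seed = 7)
  panel <- forward_simulate(sc, seed = 8)
  co <- sc$lakes$L01$coef
  res <- panel$WT - (co$WT[["Intercept"]] + co$WT[["AT"]] * panel$AT)
  se <- sc$sigma[["WT"]] / sqrt(nrow(panel))
  expect_lt(abs(mean(res)), 3 * se)
  expect_lt(abs(sd(res) - sc$sigma[["WT"]]) / sc$sigma[["WT"]], 0.05)
})

test_that("apply_missingness respects the 9-year floor", {
  sc <- generate_scenario(2, 45, seed = 9)
  panel <- forward_simulate(sc, seed = 10)
  gappy <- apply_missingness(panel, c(CHL = 0.8), seed = 11)
  counts <- validate_panel(gappy)$counts
  expect_equal(unname(counts[, "CHL"]), c(9L, 9L))
  expect_true(validate_panel(gappy)$ok)
  # fraction 0: untouched; same seed: same gaps
  expect_identical(apply_missingness(panel, 0, seed = 1), panel)
  expect_identical(apply_missingness(panel, 0.2, seed = 3),
                   apply_missingness(panel, 0.2, seed = 3))
  expect_error(apply_missingness(panel, c(WT = 0.9), seed = 1),
               "observed years")
})

test_that("characteristics: circle SDI identity and planted-correlation
           behaviour", {
  sc <- generate_scenario(31, 45, seed = 12)
  ch <- generate_characteristics(sc, planted_r = 0, seed = 13)
  expect_equal(ch$SDI, sdi(ch$shoreline_length_km, ch$lake_area_km2))
  expect_true(all(ch$access_clean_water >= 0 & ch$access_clean_water <= 1))
  expect_true(all(ch$SDI >= 1))
  # r = 0: sample correlation within the n=31 Fisher-z 95% band
  r0 <- cor(ch$access_clean_water, true_vulnerability(sc))
  expect_lt(abs(r0), 0.35)
  expect_error(generate_characteristics(sc, planted_r = 1.2, seed = 1),
               "planted_r")
  # circle lakes: SL = 2 pi r, A = pi r^2 -> SDI exactly 1
  r <- c(0.5, 2, 10)
  expect_equal(sdi(2 * pi * r, pi * r^2), rep(1, 3))
})
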