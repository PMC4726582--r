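test_that("mirror measurement is exactly antisymmetric on noise-free phantoms", {
  clean <- render_phantom(cfg128(), tpl128)
  r <- measure_regions(clean$slice, tpl128)
  expect_true(all(r$difference == 0))
  expect_equal(r$difference, r$mean_hu - r$contralateral_mean_hu)

  les <- render_phantom(cfg128(), tpl128,
                        list(lesion_spec("insula", "left", 3, 1, 0)))
  r2 <- measure_regions(les$slice, tpl128)
  expect_equal(r2$difference[r2$name == "insula" & r2$side == "left"], -3)
  expect_equal(r2$difference[r2$name == "insula" & r2$side == "right"], 3)
})

test_that("null mirror differences are centred on zero under noise", {
  diffs <- vapply(1:200, function(s) {
    ph <- render_phantom(cfg128(noise_sd = 4, seed = 2000 + s), tpl128)
    r <- measure_regions(ph$slice, tpl128)
    r$difference[r$name == "insula" & r$side == "right"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("reading a mirrored image swaps sides and preserves |difference|", {
  ph <- render_phantom(cfg128(noise_sd = 4, seed = 31), tpl128,
                       list(lesion_spec("lentiform", "left", 3, 0.6)))
  r <- measure_regions(ph$slice, tpl128)
  flipped <- ct_slice(ph$slice$pixels[, ncol(ph$slice$pixels):1],
                      spacing = ph$slice$spacing)
  rf <- measure_regions(flipped, tpl128)
  swap <- ifelse(r$side == "left", "right", "left")
  for (i in seq_len(nrow(r))) {
    j <- which(rf$region == r$region[i] & rf$side == swap[i])
    expect_equal(rf$difference[j], r$difference[i])
    expect_equal(rf$mean_hu[j], r$mean_hu[i])
  }
})

test_that("detection is thresholded and monotone in the threshold", {
  clean <- render_phantom(cfg128(), tpl128)
  r <- measure_regions(clean$slice, tpl128)
  expect_identical(nrow(detect_regions(r, 1.5)), 0L)

  les <- render_phantom(cfg128(), tpl128,
                        list(lesion_spec("caudate", "right", 3, 1, 0)))
  rl <- measure_regions(les$slice, tpl128)
  det <- detect_regions(rl, 1.5)
  expect_identical(det$name, "caudate")
  expect_identical(det$side, "right")

  noisy <- render_phantom(cfg128(noise_sd = 4, seed = 9), tpl128,
                          list(lesion_spec("insula", "left", 2, 0.5)))
  rn <- measure_regions(noisy$slice, tpl128)
  thresholds <- c(0.5, 1, 1.5, 2.5, 4)
  counts <- vapply(thresholds, function(t) nrow(detect_regions(rn, t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_regions(rn, 0), "threshold")
})

test_that("ASPECTS scores complement the detected-region count", {
  expect_identical(aspects_score(integer(0)), 10L)
  expect_identical(aspects_score(1:10), 0L)
  expect_identical(aspects_score(c(2, 3)), 8L)
  expect_error(aspects_score(c(1, 11)), "region")
  set.seed(33)
  for (i in 1:20) {
    det <- sample(1:10, sample(0:10, 1))
    expect_identical(aspects_score(det) + length(unique(det)), 10L)
  }
})

test_that("lesion area recovers a disc of known size and tracks ground truth", {
  tpl <- aspects_template("ganglionic", shape = c(256, 256))
  sp <- tpl$spacing
  # noise-free, nothing flagged
  clean <- render_phantom(phantom_config(shape = c(256, 256), noise_sd = 0,
                                         seed = 1), tpl)
  expect_equal(lesion_area(clean$slice, tpl, threshold_hu = 1.5), 0)

  # synthetic 10 mm disc of -8 HU: area should be ~ pi cm^2
  px <- clean$slice$pixels
  yy <- (row(px) - 128) * sp[1]
  xx <- (col(px) - 180) * sp[2]
  disc <- sqrt(yy^2 + xx^2) <= 10
  s <- ct_slice(px - 8 * disc, spacing = sp)
  a <- lesion_area(s, tpl, threshold_hu = 4)
  expect_equal(a, pi, tolerance = 0.05)

  # 50 random seeded lesions at noise_sd 2: mean relative error <= 10%
  set.seed(44)
  regions <- c("lentiform", "insula", "M1", "M2", "M3")
  rel_err <- vapply(1:50, function(i) {
    les <- lesion_spec(sample(regions, 1), sample(c("left", "right"), 1),
                       delta_hu = 8,
                       coverage = runif(1, 0.6, 1), edge_sigma_mm = 0)
    cfg <- phantom_config(shape = c(256, 256), noise_sd = 2,
                          seed = 5000 + i)
    ph <- render_phantom(cfg, tpl, list(les))
    truth_px <- sum(fsnlb:::lesion_mask(tpl, les))
    # mask sampling is seeded identically inside render_phantom
    truth_cm2 <- truth_px * prod(sp) / 100
    est <- lesion_area(ph$slice, tpl, threshold_hu = 4)
    abs(est - truth_cm2) / truth_cm2
  }, numeric(1))
  expect_lte(mean(rel_err), 0.10)
})

test_that("CNR follows its definition and BC raises lesion CNR", {
  # equal means with spread in the mirror: CNR exactly 0
  px <- matrix(0, 8, 8)
  lesion <- matrix(FALSE, 8, 8); lesion[1, 1:3] <- TRUE
  mirror <- matrix(FALSE, 8, 8); mirror[8, 1:3] <- TRUE
  px[1, 1:3] <- 30
  px[8, 1:3] <- c(27, 33, 30)
  expect_equal(cnr(px, lesion, mirror), 0)
  # means 27 vs 30, sd 3 -> CNR 1
  px[1, 1:3] <- 27
  expect_equal(cnr(px, lesion, mirror), 1)
  px[8, 1:3] <- 30
  expect_error(cnr(px, lesion, mirror), "undefined")
  expect_error(cnr(px, lesion, lesion), "disjoint")

  colidx <- col(tpl128$labels)
  lmask <- tpl128$labels == 2 & colidx < tpl128$midline_col
  rmask <- tpl128$labels == 2 & colidx > tpl128$midline_col
  ratios <- vapply(1:100, function(s) {
    ph <- render_phantom(cfg128(noise_sd = 4, seed = 7000 + s), tpl128,
                         list(lesion_spec("insula", "left", 3, 1, 0)))
    bc <- apply_bc(ph$slice)
    cnr(bc, lmask, rmask) / cnr(ph$slice, lmask, rmask)
  }, numeric(1))
  expect_gt(median(ratios), 1)
})

test_that("experiment scoring handles null and saturated cohorts", {
  # all-negative cohort: no sensitivity denominator, specificity defined
  neg <- make_cohort(10, prevalence = 0, seed = 11, config = cfg128(4, 1),
                     template = tpl128)
  exn <- run_experiment(neg)
  expect_identical(exn$confusion$nect$tp + exn$confusion$nect$fn, 0L)
  expect_false(exn$accuracy$nect$metrics$defined[1])
  expect_true(exn$accuracy$nect$metrics$defined[2])

  # strong lesions, low noise: both methods saturate at sensitivity 1
  sat <- make_cohort(10, prevalence = 1, seed = 12,
                     config = cfg128(noise_sd = 2, seed = 1),
                     template = tpl128, delta_range = c(10, 10),
                     coverage_range = c(0.9, 1))
  exs <- run_experiment(sat)
  expect_equal(exs$accuracy$nect$metrics$estimate[1], 1)
  expect_equal(exs$accuracy$bc$metrics$estimate[1], 1)
})

test_that("experiment sensitivity is monotone in the reading threshold", {
  co <- make_cohort(30, seed = 13, config = cfg128(4, 1),
                    template = tpl128)
  lo <- run_experiment(co, threshold_hu = 1.0)
  hi <- run_experiment(co, threshold_hu = 2.5)
  for (m in c("nect", "bc"))
    expect_gte(lo$accuracy[[m]]$metrics$estimate[1],
               hi$accuracy[[m]]$metrics$estimate[1])
  # miss tallies only count true lesions
  expect_true(all(lo$misses$nect_missed <= lo$misses$n_lesions))
  expect_true(all(lo$misses$bc_missed <= lo$misses$n_lesions))
})
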