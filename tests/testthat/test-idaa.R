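test_that("peak detection applies the RFU floor, half-width and area rules", {
  # flat noisy trace below threshold: no peaks
  set.seed(1)
  flat <- tibble::tibble(migration = 1:500, rfu = abs(rnorm(500, 0, 10)))
  expect_equal(nrow(detect_peaks(flat)), 0)

  # single Gaussian: apex within 1 sample, area within 2% of closed form
  tr <- gauss_trace(centers = 300, heights = 500, sigma = 2.5)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$apex_migration - 300), 1)
  expect_lt(abs(pk$area - 500 * 2.5 * sqrt(2 * pi)) / (500 * 2.5 * sqrt(2 * pi)),
            0.02)

  # threshold is inclusive: 99 dropped, 101 kept, 100 kept
  tr2 <- gauss_trace(centers = c(150, 450), heights = c(99, 101), sigma = 2.5)
  pk2 <- detect_peaks(tr2, height_threshold = 100)
  expect_equal(nrow(pk2), 1)
  expect_lt(abs(pk2$apex_migration - 450), 1)
  tr3 <- gauss_trace(centers = 300, heights = 100, sigma = 2.5)
  expect_equal(nrow(detect_peaks(tr3, height_threshold = 100)), 1)

  expect_error(detect_peaks(tibble::tibble(migration = numeric(), rfu = numeric())),
               "empty")
})

test_that("Local Southern sizing is exact at standards and accurate between them", {
  aff <- migration_model(convexity = 0)
  std <- tibble::tibble(size = c(50, 75, 100, 139, 150, 200),
                        migration = aff(c(50, 75, 100, 139, 150, 200)))

  # unknown exactly at a standard's migration
  at_std <- tibble::tibble(apex_migration = aff(139), height = 500, area = 1)
  expect_equal(call_sizes_local_southern(at_std, std)$size, 139, tolerance = 1e-9)

  # affine migration, true size 120: within 0.5 bp (oracle: invert the
  # affine map analytically)
  unk <- tibble::tibble(apex_migration = aff(120), height = 500, area = 1)
  called <- call_sizes_local_southern(unk, std)
  expect_lt(abs(called$size - 120), 0.5)
  expect_false(called$size_fallback)

  # near the ladder ends the single-fit fallback is flagged
  low <- tibble::tibble(apex_migration = aff(55), height = 500, area = 1)
  expect_true(call_sizes_local_southern(low, std)$size_fallback)

  expect_error(call_sizes_local_southern(unk, std[1:3, ]), "at least 4")
})

test_that("size calling is strictly monotone in apex migration", {
  for (sd in 1:5) {
    set.seed(sd)
    offs <- sort(sample(seq(-24, 24, 4), 5))
    sim <- simulate_trace(mix = data.frame(offset = offs,
                                           fraction = rep(0.2, 5)),
                          noise_sd = 3, seed = sd)
    res <- idaa_pipeline(sim, wt_size = 300)
    sized <- dplyr::arrange(res$peaks, apex_migration)
    expect_false(is.unsorted(sized$size, strictly = TRUE))
  }
})

test_that("classification follows the retention window and outcome rules", {
  offs <- -40:40
  pk <- tibble::tibble(apex_migration = seq_along(offs), height = 500,
                       area = 1, size = 300 + offs)
  cls <- filter_and_classify(pk, wt_size = 300)
  expected <- ifelse(abs(offs) > 25, "EXCLUDED",
                     ifelse(offs == 0, "WT",
                            ifelse(offs == 8, "HDR", "NHEJ")))
  expect_equal(as.character(cls$class), expected)
  # boundary values from the rule table
  expect_equal(as.character(cls$class[offs == 25]), "NHEJ")
  expect_equal(as.character(cls$class[offs == 26]), "EXCLUDED")
  expect_equal(as.character(cls$class[offs == -3]), "NHEJ")
})

test_that("outcome quantification is area arithmetic over retained peaks", {
  pk <- tibble::tibble(area = c(600, 300, 100, 999),
                       class = factor(c("WT", "HDR", "NHEJ", "EXCLUDED"),
                                      levels = c("WT", "HDR", "NHEJ", "EXCLUDED")))
  out <- quantify_outcomes(pk)
  expect_equal(out$total_editing, 0.40)
  expect_equal(out$frac_hdr, 0.30)
  expect_equal(out$hdr_nhej_ratio, 3.0)
  expect_equal(out$frac_wt + out$total_editing, 1)

  single <- tibble::tibble(area = 100, class = factor("WT", levels = levels(pk$class)))
  out1 <- quantify_outcomes(single)
  expect_equal(out1$total_editing, 0)
  expect_true(is.na(out1$hdr_nhej_ratio))
  expect_false(out1$ratio_defined)

  all_out <- tibble::tibble(area = 1, class = factor("EXCLUDED", levels = levels(pk$class)))
  expect_error(quantify_outcomes(all_out), "excluded")
})

test_that("end-to-end recovery of outcome fractions is within 0.02", {
  maxerr <- 0
  for (sd in 1:20) {
    set.seed(3000 + sd)
    k <- sample(2:4, 1)
    offs <- c(0, sample(c(seq(-20, -4, 4), seq(4, 20, 4)), k - 1))
    fr <- runif(k, 0.1, 1); fr <- fr / sum(fr)
    sim <- simulate_trace(mix = data.frame(offset = offs, fraction = fr),
                          noise_sd = 5, seed = sd)
    res <- idaa_pipeline(sim, wt_size = 300)
    tru_wt <- sum(fr[offs == 0]); tru_hdr <- sum(fr[offs == 8])
    err <- max(abs(res$outcome$frac_wt - tru_wt),
               abs(res$outcome$frac_hdr - tru_hdr),
               abs(res$outcome$frac_nhej - (1 - tru_wt - tru_hdr)))
    maxerr <- max(maxerr, err)
  }
  expect_lte(maxerr, 0.02)
})

test_that("outcome fractions are invariant to a global RFU rescale", {
  sim <- simulate_trace(mix = data.frame(offset = c(0, 8, -6),
                                         fraction = c(0.5, 0.2, 0.3)),
                        noise_sd = 2, seed = 7)
  res1 <- idaa_pipeline(sim, wt_size = 300)
  k <- 3.7
  scaled <- sim
  scaled$trace$rfu <- scaled$trace$rfu * k
  scaled$ladder_trace$rfu <- scaled$ladder_trace$rfu * k
  res2 <- idaa_pipeline(scaled, wt_size = 300,
                        height_threshold = 100 * k, ladder_threshold = 100 * k)
  expect_equal(res2$outcome$frac_wt, res1$outcome$frac_wt, tolerance = 1e-6)
  expect_equal(res2$outcome$frac_hdr, res1$outcome$frac_hdr, tolerance = 1e-6)

  # classified HDR peak is the +8 product
  hdr_peak <- dplyr::filter(tidy(res1), class == "HDR")
  expect_equal(hdr_peak$offset, 8, tolerance = 0.2)
})
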