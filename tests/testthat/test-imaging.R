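test_that("background subtraction removes the non-signal level", {
  expect_true(all(subtract_background(matrix(7, 20, 20)) == 0))

  # planted spots of amplitude A over background B
  set.seed(1)
  img <- matrix(50 + rnorm(100 * 100, 0, 1), 100, 100)
  img <- add_disk(img, 30, 30, 5, 200)
  img <- add_disk(img, 70, 70, 5, 200)
  corr <- subtract_background(img)
  spot_peak <- max(corr)
  expect_lt(abs(spot_peak - 200) / 200, 0.05)

  # idempotence: second application changes < 1% of dynamic range
  twice <- subtract_background(corr)
  expect_lt(max(abs(twice - corr)) / diff(range(corr)), 0.01)
})

test_that("nucleus segmentation finds, splits and excludes correctly", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))$nuclei), 0)

  # 12 nuclei, 2 planted on the border: all 12 found, 10 analysed
  centers <- cbind(c(5, 40, 40, 80, 80, 120, 120, 160, 160, 200, 200, 250),
                   c(128, 40, 120, 200, 60, 140, 230, 40, 120, 200, 60, 128))
  f <- simulate_image_field(shape = c(256, 256), n_nuclei = 12,
                            centers = centers, seed = 5)
  seg <- segment_nuclei(subtract_background(f$channels$dapi))
  expect_equal(nrow(seg$nuclei), 12)
  expect_equal(sum(seg$nuclei$touches_border), 2)

  # two touching ellipses split by the watershed
  img <- matrix(0, 80, 80)
  img <- add_disk(img, 40, 30, 12, 100)
  img <- add_disk(img, 40, 52, 12, 100)
  seg2 <- segment_nuclei(img)
  expect_equal(nrow(seg2$nuclei), 2)

  # labels partition: no pixel in two nuclei (labels are single-valued)
  expect_true(all(sort(unique(as.vector(seg$labels))) %in% 0:12))
})

test_that("per-nucleus intensities are exact on constructed masks", {
  labels <- matrix(0L, 20, 20)
  labels[5:8, 5:8] <- 1L
  labels[12:15, 12:16] <- 2L
  ch <- matrix(0, 20, 20)
  ch[labels == 1L] <- 3
  ch[labels == 2L] <- 7
  nuc <- tibble::tibble(label = c(1L, 2L))
  out <- nuclear_intensities(nuc, labels, ch, prefix = "m")
  expect_equal(out$m_mean, c(3, 7))
  expect_equal(out$m_integrated, c(3 * 16, 7 * 20))
  # linearity: halving the channel halves the integrated value
  out2 <- nuclear_intensities(nuc, labels, ch / 2, prefix = "m")
  expect_equal(out2$m_integrated, out$m_integrated / 2)
})

test_that("cell-cycle assignment recovers phases and handles degeneracy", {
  rec <- simulate_nucleus_records(2000, seed = 11)
  out <- assign_cell_cycle(rec)
  est <- prop.table(table(factor(out$phase, c("G1", "S", "G2M"))))
  tru <- prop.table(table(factor(rec$phase, c("G1", "S", "G2M"))))
  expect_lt(max(abs(est - tru)), 0.02)

  # rule definitions: clear EdU-positive is S; EdU-negative at 2N is G1
  thr <- attr(out, "thresholds")
  expect_true(all(out$phase[rec$edu_mean > 10 * thr$edu] == "S"))
  near_2n <- !is.na(out$phase) & out$phase != "S" &
    abs(rec$dapi_integrated - 2e4) < 1e3
  expect_true(all(out$phase[near_2n] == "G1"))

  # unimodal DAPI demands an explicit anchor
  uni <- tibble::tibble(label = 1:200, edu_mean = exp(rnorm(200, 0, 0.2)),
                        dapi_integrated = rnorm(200, 2e4, 300),
                        touches_border = FALSE)
  expect_error(assign_cell_cycle(uni), "2N anchor")
  ok <- assign_cell_cycle(uni, dapi_2n = 2e4)
  expect_true(all(ok$phase %in% c("G1", "S", "G2M")))

  # too few nuclei without explicit thresholds
  expect_error(assign_cell_cycle(uni[1:5, ]), "supply")
})

test_that("phase fractions sum to one over analysed nuclei", {
  rec <- simulate_nucleus_records(500, phase_fractions = c(0.5, 0.3, 0.2),
                                  seed = 3)
  out <- assign_cell_cycle(rec)
  p <- prop.table(table(out$phase[!is.na(out$phase)]))
  expect_equal(sum(p), 1)
})

test_that("three-class Otsu matches the brute-force oracle on 64-level images", {
  for (sd in 1:5) {
    set.seed(sd)
    x <- c(rnorm(400, 10, 2), rnorm(300, 30, 3), rnorm(100, 55, 2))
    x <- pmin(pmax(round(x), 0), 63)
    mine <- otsu3_thresholds(x, levels = 64)
    orc <- oracle_otsu3(x, levels = 64)
    expect_equal(unname(mine), unname(orc), tolerance = 1e-12)
  }
})

test_that("focus counting keeps only the top intensity class", {
  # flat nucleus: zero foci
  labels <- matrix(0L, 64, 64); labels[20:44, 20:44] <- 1L
  nuc <- tibble::tibble(label = 1L, area = sum(labels == 1L))
  expect_equal(detect_foci(nuc, labels, matrix(5, 64, 64))$foci_count, 0L)

  # five well-separated planted foci recovered exactly
  f <- simulate_image_field(n_nuclei = 1, foci_per_nucleus = 5, seed = 21)
  seg <- segment_nuclei(subtract_background(f$channels$dapi))
  fo <- detect_foci(seg$nuclei, seg$labels, subtract_background(f$channels$marker))
  expect_equal(fo$foci_count, 5L)

  # tri-modal nucleus: haze (middle class) contributes no foci
  img <- matrix(0, 64, 64)
  img[25:39, 25:39] <- 30                       # haze plateau inside nucleus
  img <- add_disk(img, 28, 28, 1.2, 200)        # two true spots
  img <- add_disk(img, 36, 36, 1.2, 200)
  labels <- matrix(0L, 64, 64); labels[18:46, 18:46] <- 1L
  nuc <- tibble::tibble(label = 1L, area = sum(labels == 1L))
  fo3 <- detect_foci(nuc, labels, img, radius = 3)
  expect_equal(fo3$foci_count, 2L)

  # nucleus smaller than the structuring element: 0 with warning
  tiny_lab <- matrix(0L, 32, 32); tiny_lab[16:17, 16:17] <- 1L
  tiny <- tibble::tibble(label = 1L, area = 4)
  expect_warning(res <- detect_foci(tiny, tiny_lab, matrix(1, 32, 32)),
                 "smaller")
  expect_equal(res$foci_count, 0L)
})

test_that("damage classification sits at the control 95th percentile", {
  set.seed(31)
  control <- tibble::tibble(marker_mean = rlnorm(1000, 3, 0.4))
  self <- classify_damaged(control, control)
  expect_equal(sum(self$damaged), 50)

  shifted <- dplyr::mutate(control,
                           marker_mean = marker_mean + 10 * sd(marker_mean))
  expect_true(all(classify_damaged(shifted, control)$damaged))

  expect_error(classify_damaged(control, control[0, ]), "empty control")
})

test_that("Pearson colocalization matches hand arithmetic and affine invariance", {
  labels <- matrix(0L, 10, 10); labels[2:4, 2:4] <- 1L
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  bv <- c(2, 1, 4, 3, 6, 5, 8, 7, 9)
  a[labels == 1L] <- vals; b[labels == 1L] <- bv
  nuc <- tibble::tibble(label = 1L)
  r <- pearson_colocalization(nuc, labels, a, b)$pearson_r
  hand <- sum((vals - mean(vals)) * (bv - mean(bv))) /
    sqrt(sum((vals - mean(vals))^2) * sum((bv - mean(bv))^2))
  expect_equal(r, hand, tolerance = 1e-12)

  expect_equal(pearson_colocalization(nuc, labels, a, a)$pearson_r, 1)
  expect_equal(pearson_colocalization(nuc, labels, a, max(a) - a)$pearson_r, -1)

  # affine rescaling with positive gain leaves r unchanged
  r2 <- pearson_colocalization(nuc, labels, 3 * a + 7, b)$pearson_r
  expect_equal(r2, r, tolerance = 1e-12)

  # constant channel flagged undefined
  const <- pearson_colocalization(nuc, labels, a, matrix(5, 10, 10))
  expect_true(is.na(const$pearson_r))
  expect_false(const$r_defined)
})

test_that("micronucleus scoring assigns satellites to their parents", {
  # 10 hand-placed nuclei (r = 10), satellites (r = 2) next to three of them
  img <- matrix(0, 240, 240)
  centers <- rbind(expand.grid(row = c(40, 110, 180), col = c(40, 110, 180)),
                   data.frame(row = 40, col = 215))
  for (i in seq_len(10)) img <- add_disk(img, centers$row[i], centers$col[i], 10, 100)
  for (i in 1:3) img <- add_disk(img, centers$row[i] + 14, centers$col[i], 2, 100)
  img <- add_disk(img, 100, 10, 2, 100) # orphan satellite, far from everything
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$nuclei), 10)
  mn <- detect_micronuclei(img, seg)
  expect_equal(mn$fraction, 0.3)
  expect_equal(sum(mn$nuclei$micronuclei), 3L)
  expect_equal(sum(is.na(mn$satellites$parent)), 1)

  # generated fields: fraction recovered exactly
  f <- simulate_image_field(shape = c(300, 300), n_nuclei = 10,
                            micronucleus_prob = 0.4, seed = 8)
  seg2 <- segment_nuclei(subtract_background(f$channels$dapi))
  mn2 <- detect_micronuclei(subtract_background(f$channels$dapi), seg2)
  expect_equal(mn2$fraction, mean(f$truth$n_micronuclei >= 1))
})

test_that("wound closure is monotone, bounded and tracks the truth", {
  w <- simulate_wound_series(seed = 13)
  ws <- wound_closure_series(w$frames, w$times)
  expect_false(is.unsorted(ws$closure))
  expect_true(all(ws$closure >= 0 & ws$closure <= 100))
  expect_equal(ws$closure[ws$t == 0], 0)
  expect_lt(max(abs(ws$closure - w$truth$closure[match(ws$t, w$truth$t)])), 2)
  # fully covered frame reads 100%
  expect_equal(ws$closure[ws$t == 24], 100)

  # a frame identical to 0 h closes 0%
  w0 <- simulate_wound_series(times = c(0, 4),
                              closure_fn = function(t) 0 * t, seed = 14)
  ws0 <- wound_closure_series(w0$frames, w0$times)
  expect_lt(max(abs(ws0$closure)), 2)
})
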