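test_that("lvef computes the ejection fraction and guards its domain", {
  expect_equal(lvef(100, 50), 50)
  expect_equal(lvef(120, 40), 100 * 80 / 120)
  expect_error(lvef(100, 100), "exceed")
  expect_error(lvef(100, -5), "> 0")
  # scale invariance
  for (k in c(0.5, 2, 13)) {
    expect_equal(lvef(k * 120, k * 40), lvef(120, 40))
  }
})

ellipsoid_discs <- function(n, D1 = 4, D2 = 3, L = 8) {
  z <- (seq_len(n) - 0.5) * L / n
  shrink <- sqrt(pmax(0, 1 - ((z - L / 2) / (L / 2))^2))
  data.frame(index = seq_len(n), d4ch_cm = D1 * shrink,
             d2ch_cm = D2 * shrink)
}

test_that("simpson biplane volume is exact on a cylinder", {
  d <- data.frame(d4ch_cm = rep(3, 10), d2ch_cm = rep(3, 10))
  expect_equal(simpson_biplane_volume(d, long_axis_cm = 5),
               (pi / 4) * 9 * 5)
})

test_that("simpson biplane volume approaches the ellipsoid closed form", {
  closed <- (pi / 6) * 4 * 3 * 8  # 50.27 mL
  v20 <- simpson_biplane_volume(ellipsoid_discs(20), long_axis_cm = 8)
  expect_lt(abs(v20 - closed) / closed, 0.01)
  # midpoint-rule refinement: error shrinks monotonically with n
  errs <- vapply(c(4, 8, 16, 32, 64, 400), function(n) {
    abs(simpson_biplane_volume(ellipsoid_discs(n), long_axis_cm = 8) - closed)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("simpson input validation catches malformed discs", {
  d <- ellipsoid_discs(8)
  expect_error(simpson_biplane_volume(d[, -2], long_axis_cm = 8), "d4ch_cm")
  expect_error(simpson_biplane_volume(d, long_axis_cm = -1), "positive")
  expect_error(simpson_biplane_volume(d[1:3, ], long_axis_cm = 8),
               "at least 4")
  d$d2ch_cm[2] <- -1
  expect_error(simpson_biplane_volume(d, long_axis_cm = 8), "positive")
})

test_that("mean filling rate recovers a constant slope exactly", {
  for (n in c(5, 17, 64)) {
    t <- seq(0, 0.5, length.out = n)
    vtc <- data.frame(time_s = t, volume_ml = 40 + 100 * t)
    expect_equal(as.numeric(mean_filling_rate(vtc, es_index = 1,
                                              ed_index = n)), 100)
  }
})

test_that("mean filling rate matches the analytic sinusoidal mean slope", {
  t <- seq(0, 1, length.out = 64)
  vtc <- data.frame(time_s = t, volume_ml = 70 - 30 * cos(2 * pi * t))
  mfr <- mean_filling_rate(vtc)
  # filling from V_ES = 40 to V_ED = 100 over half a period: 120 mL/s
  expect_lt(abs(as.numeric(mfr) - 120) / 120, 0.02)
  cyc <- attr(mfr, "cycles")
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$es_index, 1L)
})

test_that("a two-sample diastolic segment reduces to the two-point slope", {
  vtc <- data.frame(time_s = c(0, 0.1, 0.2, 0.3),
                    volume_ml = c(80, 40, 90, 85))
  mfr <- mean_filling_rate(vtc, es_index = 2, ed_index = 3)
  expect_equal(as.numeric(mfr), (90 - 40) / 0.1)
})

test_that("multi-cycle curves average the per-cycle filling rates", {
  t <- seq(0, 2, length.out = 257)
  vtc <- data.frame(time_s = t, volume_ml = 70 - 30 * cos(2 * pi * t))
  mfr <- mean_filling_rate(vtc)
  expect_equal(nrow(attr(mfr, "cycles")), 2L)
  expect_lt(abs(as.numeric(mfr) - 120) / 120, 0.02)
})

test_that("filling-rate properties hold on monotone segments", {
  set.seed(4)
  t <- sort(runif(30, 0, 1))
  v <- cumsum(runif(30, 0.5, 3)) + 40
  vtc <- data.frame(time_s = t, volume_ml = v)
  mfr <- as.numeric(mean_filling_rate(vtc, es_index = 1, ed_index = 30))
  slopes <- diff(v) / diff(t)
  expect_gt(mfr, 0)
  expect_lte(mfr, max(slopes) + 1e-9)
})

test_that("volume-time curves are validated", {
  expect_error(mean_filling_rate(data.frame(time_s = c(0, 1, 1, 2),
                                            volume_ml = c(1, 2, 3, 4))),
               "strictly increasing")
  expect_error(mean_filling_rate(data.frame(time_s = 0:3,
                                            volume_ml = c(1, -2, 3, 4))),
               "positive")
  # no filling segment: monotonically decreasing curve
  expect_error(mean_filling_rate(data.frame(time_s = 0:4,
                                            volume_ml = c(90, 80, 70, 60, 50))),
               "segment")
})

test_that("ratio metrics compute E/A and E/E'", {
  out <- ratio_metrics(data.frame(e_peak = 80, a_peak = 60, e_prime = 10))
  expect_equal(out$e_over_a, 80 / 60)
  expect_equal(out$e_over_eprime, 8)
  eq <- ratio_metrics(data.frame(e_peak = 70, a_peak = 70, e_prime = 70))
  expect_equal(eq$e_over_a, 1)
  expect_equal(eq$e_over_eprime, 1)
  expect_error(ratio_metrics(data.frame(e_peak = 80, a_peak = 0,
                                        e_prime = 10)), "positive")
})

test_that("qt dispersion is max minus min and permutation invariant", {
  qts <- c(380, 395, 402, 410, 441)
  df <- data.frame(lead = c("I", "II", "V1", "V5", "V6"), qt_ms = qts)
  expect_equal(qt_dispersion(df), 61)
  set.seed(1)
  shuffled <- df[sample(nrow(df)), ]
  expect_equal(qt_dispersion(shuffled), 61)
  # translation invariance
  df2 <- df; df2$qt_ms <- df2$qt_ms + 37
  expect_equal(qt_dispersion(df2), 61)
  # identical intervals
  same <- data.frame(lead = paste0("L", 1:12), qt_ms = rep(400, 12))
  expect_equal(qt_dispersion(same), 0)
  expect_error(qt_dispersion(df[1, , drop = FALSE]), "at least 2")
  expect_warning(qt_dispersion(data.frame(lead = c("a", "b"),
                                          qt_ms = c(150, 400))),
                 "plausibility")
})

test_that("ptfv1 multiplies amplitude by duration with the sign convention", {
  expect_equal(ptfv1(-1.0, 0.04), -0.04)
  expect_equal(ptfv1(0, 0.12), 0)
  expect_equal(ptfv1(-0.5, 0.06), -0.03)
  expect_error(ptfv1(0.5, 0.04), "negative")
  expect_error(ptfv1(-0.5, -0.01), ">= 0")
})

test_that("cardiac CSV readers round-trip and validate headers", {
  tmp <- withr::local_tempdir()
  vtc_path <- file.path(tmp, "vtc.csv")
  t <- seq(0, 1, length.out = 16)
  readr::write_csv(data.frame(time_s = t,
                              volume_ml = 70 - 30 * cos(2 * pi * t)),
                   vtc_path)
  vtc <- read_vtc(vtc_path)
  expect_s3_class(vtc, "tbl_df")
  expect_equal(nrow(vtc), 16)

  bad <- file.path(tmp, "bad.csv")
  readr::write_csv(data.frame(time_s = t, volume = t), bad)
  expect_error(read_vtc(bad), "volume_ml")

  qt_path <- file.path(tmp, "qt.csv")
  readr::write_csv(data.frame(lead = c("I", "II"), qt_ms = c(380, 420)),
                   qt_path)
  ptf_path <- file.path(tmp, "ptf.csv")
  readr::write_csv(data.frame(v1_ptf_amplitude_mm = -0.5,
                              v1_ptf_duration_s = 0.06), ptf_path)
  ann <- read_ecg_annotations(qt_path, ptf_path)
  expect_equal(qt_dispersion(ann), 40)
  expect_equal(attr(ann, "ptf")$amplitude_mm, -0.5)

  discs_path <- file.path(tmp, "discs.csv")
  writeLines(c("# long_axis_cm: 8", "index,d4ch_cm,d2ch_cm",
               paste(1:8, rep(3, 8), rep(3, 8), sep = ",")), discs_path)
  discs <- read_biplane_discs(discs_path)
  expect_equal(attr(discs, "long_axis_cm"), 8)
  expect_equal(simpson_biplane_volume(discs), (pi / 4) * 9 * 8)

  nohdr <- file.path(tmp, "nohdr.csv")
  writeLines(c("index,d4ch_cm,d2ch_cm", "1,3,3"), nohdr)
  expect_error(read_biplane_discs(nohdr), "long_axis_cm")
})
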