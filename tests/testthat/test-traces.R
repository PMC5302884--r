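# A two-bump unit-area test trace with a known peak and a known minimum,
# built from Gaussians so landmarks are smooth and unambiguous.
two_bump_trace <- function(peak_at = 0.19, min_at = 1.33, grid = NULL) {
  if (is.null(grid)) grid <- seq(-0.6, 2.4, length.out = 900)
  # equal flanking Gaussians put the valley minimum exactly at min_at
  y <- dnorm(grid, peak_at, 0.05) + 0.5 * dnorm(grid, min_at + 0.45, 0.16) +
    0.5 * dnorm(grid, min_at - 0.45, 0.16)
  new_trace(grid, y / trapz(grid, y))
}

test_that("normalisation yields unit area, is idempotent, and rejects empty lanes", {
  tr <- two_bump_trace()
  doubled <- new_trace(tr$position, tr$intensity * 2)
  norm <- normalize_trace(doubled)
  expect_equal(trapz(norm$position, norm$intensity), 1, tolerance = 1e-9)
  again <- normalize_trace(norm)
  expect_equal(again$intensity, norm$intensity, tolerance = 1e-12)
  zero <- new_trace(1:10, rep(0, 10))
  expect_error(normalize_trace(zero), "zero total intensity")
})

test_that("alignment applies the two-point affine map from detected landmarks", {
  tr <- two_bump_trace(peak_at = 0.25, min_at = 1.2)
  al <- align_trace(normalize_trace(tr))
  lm <- attr(al, "landmarks")
  expect_within(lm$peak_4x_raw, 0.25, 0.01)
  expect_within(lm$min_720_raw, 1.2, 0.02)
  # the affine map sends the detected landmarks to exactly 0 and 1
  mapped <- (c(lm$peak_4x_raw, lm$min_720_raw) - lm$peak_4x_raw) /
    (lm$min_720_raw - lm$peak_4x_raw)
  expect_equal(mapped, c(0, 1))
  expect_equal(al$position,
               (tr$position - lm$peak_4x_raw) / (lm$min_720_raw - lm$peak_4x_raw))
  expect_identical(al$intensity, tr$intensity / trapz(tr$position, tr$intensity))
})

test_that("aligning an aligned trace is the identity", {
  al <- align_trace(normalize_trace(two_bump_trace()))
  al2 <- align_trace(al)
  expect_equal(al2$position, al$position, tolerance = 1e-6)
  expect_equal(al2$intensity, al$intensity)
})

test_that("alignment failure names the missing landmark", {
  # monotone trace: no local extrema anywhere
  flat <- new_trace(seq(-0.5, 2, length.out = 300),
                    seq(1, 2, length.out = 300))
  expect_error(align_trace(flat), "4x peak")
  # peak present, but nothing resembling a minimum in the 720 window
  grid <- seq(-0.6, 2.4, length.out = 900)
  y <- dnorm(grid, 0.19, 0.05) + exp(grid) * 0.01
  expect_error(align_trace(new_trace(grid, y / trapz(grid, y))),
               "720 kDa minimum")
})

test_that("averaging identical traces returns the trace with zero spread", {
  al <- align_trace(normalize_trace(two_bump_trace()))
  avg <- average_traces(list(al, al, al, al, al))
  ref <- approx(al$position, al$intensity, avg$position)$y
  expect_equal(avg$intensity, ref, tolerance = 1e-9)
  expect_true(all(avg$sd < 1e-12))
  expect_equal(attr(avg, "n_traces"), 5L)
})

test_that("averaging requires aligned traces and a common support", {
  raw <- normalize_trace(two_bump_trace())
  expect_error(average_traces(list(raw)), "aligned")
  a <- new_trace(seq(0, 1, length.out = 50), rep(1, 50), aligned = TRUE)
  b <- new_trace(seq(2, 3, length.out = 50), rep(1, 50), aligned = TRUE)
  expect_error(average_traces(list(a, b)), "common support")
})

test_that("trace distance is a metric and separates disjoint unit bumps", {
  al <- align_trace(normalize_trace(two_bump_trace()))
  expect_equal(trace_distance(al, al), 0)
  al2 <- align_trace(normalize_trace(two_bump_trace(peak_at = 0.22)))
  expect_equal(trace_distance(al, al2), trace_distance(al2, al))
  expect_gt(trace_distance(al, al2), 0)
  g1 <- seq(0, 1, length.out = 400)
  bump1 <- new_trace(g1, dnorm(g1, 0.5, 0.05), aligned = TRUE)
  g2 <- seq(4, 5, length.out = 400)
  bump2 <- new_trace(g2, dnorm(g2, 4.5, 0.05), aligned = TRUE)
  expect_equal(trace_distance(bump1, bump2, n_grid = 5000), 2, tolerance = 0.01)
  expect_error(trace_distance(normalize_trace(two_bump_trace()), al), "aligned")
})

test_that("traces survive a CSV round trip with their metadata sidecar", {
  dir <- withr::local_tempdir()
  al <- align_trace(normalize_trace(two_bump_trace()))
  path <- file.path(dir, "lane.csv")
  write_trace_csv(al, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "lane.meta.json")))
  back <- read_trace_csv(path)
  expect_equal(back$position, al$position)
  expect_equal(back$intensity, al$intensity)
  expect_true(attr(back, "aligned"))
  write.csv(data.frame(a = 1:3, b = 4:6), file.path(dir, "bad.csv"),
            row.names = FALSE)
  expect_error(read_trace_csv(file.path(dir, "bad.csv")), "position")
})

test_that("cropping restricts the axis interval and keeps flags", {
  al <- align_trace(normalize_trace(two_bump_trace()))
  cropped <- crop_trace(al, 0, 1)
  expect_true(all(cropped$position >= 0 & cropped$position <= 1))
  expect_true(attr(cropped, "aligned"))
  expect_error(crop_trace(al, 10, 11), "fewer than 2")
})
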