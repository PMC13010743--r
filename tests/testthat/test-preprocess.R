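scr <- screen_geometry()

test_that("pixel-to-degree conversion is the signed per-axis arctangent", {
  d <- px_to_deg(960, 540, scr)
  expect_equal(d$x_deg, 0); expect_equal(d$y_deg, 0)
  # 100 px right of center at 0.02767 cm/px pitch, 60 cm viewing distance
  d2 <- px_to_deg(1060, 540, scr)
  expect_equal(d2$x_deg, atan(100 * scr$pitch_x / 60) * 180 / pi)
  expect_equal(d2$x_deg, 2.64, tolerance = 0.01)
  # left screen edge
  d3 <- px_to_deg(0, 540, scr)
  expect_equal(d3$x_deg, -atan(26.56 / 60) * 180 / pi, tolerance = 0.01)
  expect_equal(d3$x_deg, -23.9, tolerance = 0.05)
  expect_error(px_to_deg(1, 1, screen_geometry(distance_cm = -5)), "distance")
})

mk_rec <- function(lx, ly, lv, rx, ry, rv) {
  # degree-valued eye positions packed into the pixel raster frame
  to_px <- function(x, y) {
    list(px = scr$width_px / 2 + tan(x * pi / 180) * 60 / scr$pitch_x,
         py = scr$height_px / 2 - tan(y * pi / 180) * 60 / scr$pitch_y)
  }
  L <- to_px(lx, ly); R <- to_px(rx, ry)
  data.frame(t_s = (seq_along(lx) - 1) / 30,
             lx_px = L$px, ly_px = L$py, l_valid = lv,
             rx_px = R$px, ry_px = R$py, r_valid = rv)
}

test_that("cyclopean stream averages valid eyes and falls back to one eye", {
  rec <- mk_rec(lx = c(1, NA, NA), ly = c(2, NA, NA), lv = c(1, 0, 0),
                rx = c(3, 3, NA), ry = c(4, 4, NA), rv = c(1, 1, 0))
  st <- build_stream(rec, "cyclopean", screen = scr)
  expect_equal(st$x[1], 2, tolerance = 1e-6)
  expect_equal(st$y[1], 3, tolerance = 1e-6)
  expect_equal(st$x[2], 3, tolerance = 1e-6)   # only right eye valid
  expect_true(is.na(st$x[3]))                  # neither eye valid
  both <- build_stream(rec, "both_valid_only", screen = scr)
  expect_false(both$valid[2])
  expect_error(build_stream(rec, "amblyopic_eye", screen = scr), "amblyopic_side")
  amb <- build_stream(rec, "amblyopic_eye", amblyopic_side = "right", screen = scr)
  expect_equal(amb$x[2], 3, tolerance = 1e-6)
})

test_that("validity flagging catches speed, display bounds and margin", {
  n <- 20
  x <- rep(0, n); x[10] <- 40       # 40 deg in one frame: 1200 deg/s
  st <- data.frame(t_s = (seq_len(n) - 1) / 30, x = x, y = rep(0, n),
                   valid = TRUE)
  bad0 <- flag_invalid(st, scr, margin = 0)
  expect_true(bad0[9] && bad0[10] && bad0[11])  # both bounding samples of both intervals
  expect_false(any(bad0[c(1:7, 14:20)]))
  bad1 <- flag_invalid(st, scr, margin = 1)
  expect_true(bad1[8] && bad1[12])              # +-1 frame margin
  st2 <- st; st2$x <- rep(0, n); st2$x[5] <- -30  # beyond the display half-width
  expect_true(flag_invalid(st2, scr, margin = 0)[5])
})

test_that("gap interpolation bridges short interior gaps only", {
  x <- c(1, rep(NA, 6), 2); y <- c(0, rep(NA, 6), 0)
  g <- interpolate_gaps(x, y)
  expect_equal(g$x, c(1, 1 + (1:6) / 7, 2))
  expect_false(any(g$missing))
  # 7-sample gap untouched
  x7 <- c(1, rep(NA, 7), 2)
  g7 <- interpolate_gaps(x7, rep(0, 9))
  expect_true(all(is.na(g7$x[2:8])))
  # 1-sample gap between equal values
  g1 <- interpolate_gaps(c(5, NA, 5), c(0, NA, 0))
  expect_equal(g1$x[2], 5)
  # edge gaps have no flanking anchor
  ge <- interpolate_gaps(c(NA, 1, 2), c(NA, 0, 0))
  expect_true(is.na(ge$x[1]))
  # originally valid samples are never altered
  set.seed(3)
  x <- rnorm(50); x[sample(2:49, 8)] <- NA
  g <- interpolate_gaps(x, rnorm(50))
  expect_equal(g$x[!is.na(x)], x[!is.na(x)])
})

test_that("trial QC applies the strict more-than-30-percent rule", {
  expect_false(qc_trial(rep(c(TRUE, FALSE), c(31, 69)))$retained)
  expect_true(qc_trial(rep(c(TRUE, FALSE), c(30, 70)))$retained)
  expect_true(qc_trial(rep(FALSE, 50))$retained)
  expect_false(qc_trial(logical(0))$retained)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and yields central-difference velocity", {
  n <- 30; dt <- 1 / 30
  t <- (seq_len(n) - 1) * dt
  sm0 <- smooth_and_differentiate(rep(2, n), rep(-1, n), dt)
  expect_equal(sm0$xs, rep(2, n))
  expect_equal(sm0$vx[3:(n - 2)], rep(0, n - 4), tolerance = 1e-10)
  # an order-2 filter reproduces quadratics exactly on interior samples
  xq <- 3 + 2 * t + 5 * t^2
  smq <- smooth_and_differentiate(xq, xq, dt)
  expect_equal(smq$xs[3:(n - 2)], xq[3:(n - 2)], tolerance = 1e-9)
  # linear ramp of 0.1 deg per frame -> speed 3.0 deg/s
  xr <- 0.1 * (seq_len(n) - 1)
  smr <- smooth_and_differentiate(xr, rep(0, n), dt)
  expect_equal(smr$speed[5:(n - 4)], rep(3, n - 8), tolerance = 1e-9)
  expect_error(smooth_and_differentiate(xr, xr, dt, window = 5, polyorder = 5),
               "polyorder")
  # runs shorter than the window pass through unsmoothed
  xs <- c(1, 2, 3, NA, rep(0, 10))
  sms <- smooth_and_differentiate(xs, xs, dt)
  expect_equal(sms$xs[1:3], c(1, 2, 3))
})

test_that("flag-interpolate-qc is idempotent", {
  set.seed(11)
  n <- 120
  x <- cumsum(rnorm(n, 0, 0.2)); y <- cumsum(rnorm(n, 0, 0.2))
  x[30:33] <- NA; y[30:33] <- NA
  x[70] <- 60                        # glitch
  st <- data.frame(t_s = (seq_len(n) - 1) / 30, x = x, y = y,
                   valid = is.finite(x))
  pass1 <- flag_invalid(st, scr)
  g1 <- interpolate_gaps(replace(x, pass1, NA), replace(y, pass1, NA))
  st2 <- data.frame(t_s = st$t_s, x = g1$x, y = g1$y, valid = !g1$missing)
  pass2 <- flag_invalid(st2, scr)
  g2 <- interpolate_gaps(replace(g1$x, pass2, NA), replace(g1$y, pass2, NA))
  expect_equal(g2$x, g1$x)
  expect_equal(mean(g2$missing), mean(g1$missing))
})
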