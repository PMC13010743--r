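scr <- screen_geometry()
dt <- 1 / 30

mk_fix <- function(cx, cy, dur = 300) {
  n <- length(cx)
  data.frame(start = seq_len(n) * 20, end = seq_len(n) * 20 + 8,
             t_start = seq_len(n), t_end = seq_len(n) + 0.3,
             duration_ms = rep(dur, n), cx = cx, cy = cy,
             rms = rep(0.1, n), cell = gazescreen:::gs_cell_of(cx, cy, scr))
}

test_that("scan-path features: entropy, regressions, refixations", {
  # single fixation: transition features missing, counts zero
  f1 <- task1_features(mk_fix(0, 0))
  expect_true(is.na(f1["t1_entropy"]))
  expect_equal(unname(f1["t1_regressions"]), 0)
  expect_equal(unname(f1["t1_refixations"]), 0)
  # 4 equiprobable distinct transitions -> 2 bits (cells far apart, 2 visits each)
  cx <- rep(c(-18, -6, 6, 18), 2); cy <- rep(0, 8)
  f2 <- task1_features(mk_fix(cx, cy))
  # transitions: (1,2),(2,3),(3,4),(4,1) each observed; the wrap transition
  # appears once and the rest twice except... construct exactly equal counts:
  cxe <- c(-18, -6, 6, 18, -18, -6, 6, 18, -18)  # 8 transitions, 4 types x 2
  f2 <- task1_features(mk_fix(cxe, rep(0, 9)))
  expect_equal(unname(f2["t1_entropy"]), 2)
  # left-to-right scan of 6 fixations with 2 leftward steps
  cx3 <- c(0, 3, 6, 4, 9, 7); f3 <- task1_features(mk_fix(cx3, rep(0, 6)))
  expect_equal(unname(f3["t1_regressions"]), 2)
  expect_equal(unname(f3["t1_saccade_amp"]), mean(abs(diff(cx3))))
  # refixation: return within 1 deg of a non-adjacent earlier fixation
  f4 <- task1_features(mk_fix(c(0, 5, 0.4), rep(0, 3)))
  expect_equal(unname(f4["t1_refixations"]), 1)
})

test_that("entropy is translation-invariant within cells and properly bounded", {
  set.seed(4)
  for (rep in 1:10) {
    cx <- runif(8, -20, 20); cy <- runif(8, -10, 10)
    f <- task1_features(mk_fix(cx, cy))
    cells <- gazescreen:::gs_cell_of(cx, cy, scr)
    n_types <- length(unique(paste(head(cells, -1), tail(cells, -1))))
    expect_lte(f[["t1_entropy"]], log2(n_types) + 1e-9)
    expect_gte(f[["t1_entropy"]], 0)
    shift <- runif(2, -0.3, 0.3)
    cells2 <- gazescreen:::gs_cell_of(cx + shift[1], cy + shift[2], scr)
    if (identical(cells, cells2)) {   # translation stayed within the same cells
      f2 <- task1_features(mk_fix(cx + shift[1], cy + shift[2]))
      expect_equal(f2[["t1_entropy"]], f[["t1_entropy"]])
    }
  }
})

mk_seg <- function(x, y) {
  n <- length(x)
  sm <- smooth_and_differentiate(x, y, dt)
  structure(list(t_s = (seq_len(n) - 1) * dt, x = x, y = y,
                 xs = sm$xs, ys = sm$ys, vx = sm$vx, vy = sm$vy,
                 speed = sm$speed, missing = !is.finite(x),
                 invalid_fraction = 0, retained = TRUE, dt = dt),
            class = "trial_segment")
}
no_events <- data.frame(onset = integer(), offset = integer(),
                        amplitude = numeric(), peak_speed = numeric(),
                        class = character())

test_that("grating-trial features: drift projection, hull area, latency", {
  # gaze pinned to the stimulus center
  seg0 <- mk_seg(rep(0, 60), rep(0, 60))
  fx0 <- idt_fixations(seg0$t_s, seg0$xs, seg0$ys, screen = scr)
  f0 <- task2_features(seg0, fx0, no_events, orientation = 0)
  expect_equal(unname(f0["t2_drift_deg"]), 0)
  expect_equal(unname(f0["t2_hull_area"]), 0)
  expect_equal(unname(f0["t2_latency_ms"]), 0)
  # net displacement (0.5, 0): drift 0.5 at orientation 0, 0 at orientation 90
  x <- seq(0, 0.5, length.out = 60)
  segd <- mk_seg(x, rep(0, 60))
  fxd <- idt_fixations(segd$t_s, segd$xs, segd$ys, screen = scr)
  fd0 <- task2_features(segd, fxd, no_events, orientation = 0)
  fd90 <- task2_features(segd, fxd, no_events, orientation = 90)
  expect_equal(unname(fd0["t2_drift_deg"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(fd90["t2_drift_deg"]), 0, tolerance = 1e-6)
  # hull of the corners of a 1x1 deg square is 1 deg^2 (shoelace oracle)
  sq <- mk_seg(c(rep(c(0, 0, 1, 1), 15)), c(rep(c(0, 1, 1, 0), 15)))
  fs <- task2_features(sq, fx0, no_events, orientation = 0)
  expect_equal(unname(fs["t2_hull_area"]),
               oracle_shoelace(c(0, 0, 1, 1), c(0, 1, 1, 0)))
  # corrective rate normalizes by trial duration in minutes
  ev <- data.frame(onset = c(5L, 20L), offset = c(7L, 22L),
                   amplitude = c(0.5, 0.8), peak_speed = c(70, 70),
                   class = c("small_corrective", "small_corrective"))
  fr <- task2_features(seg0, fx0, ev, orientation = 0)
  expect_equal(unname(fr["t2_corrective_rate"]), 2 / (60 * dt / 60))
})

test_that("pursuit features: tracking error, gain, degenerate cases", {
  tr <- make_pursuit_trajectory(4, 30, phases = c(0.4, 1.0))
  target <- data.frame(x = tr$x, y = tr$y, vx = tr$vx, vy = tr$vy)
  # gaze identical to target
  seg <- mk_seg(tr$x, tr$y)
  f <- task3_features(seg, target, no_events)
  expect_equal(unname(f["t3_tracking_error"]), 0, tolerance = 1e-8)
  expect_equal(unname(f["t3_pursuit_gain"]), 1, tolerance = 0.01)
  # gaze scaled toward center by 0.8
  seg8 <- mk_seg(0.8 * tr$x, 0.8 * tr$y)
  f8 <- task3_features(seg8, target, no_events)
  expect_equal(unname(f8["t3_pursuit_gain"]), 0.8, tolerance = 0.01)
  # stationary gaze: gain 0
  segs <- mk_seg(rep(0, length(tr$x)), rep(0, length(tr$x)))
  fs <- task3_features(segs, target, no_events)
  expect_equal(unname(fs["t3_pursuit_gain"]), 0, tolerance = 1e-8)
  expect_error(task3_features(seg, target[1:10, ], no_events), "frame-aligned")
  # tracking error is invariant under joint rigid translation
  seg_t <- mk_seg(0.8 * tr$x + 2, 0.8 * tr$y - 1)
  target_t <- target; target_t$x <- target$x + 2; target_t$y <- target$y - 1
  ft <- task3_features(seg_t, target_t, no_events)
  expect_equal(unname(ft["t3_tracking_error"]),
               unname(f8["t3_tracking_error"]), tolerance = 1e-8)
})

test_that("subject aggregation is a per-task median with orientation averaging", {
  base <- data.frame(subject_id = "S01", group = "control", task_id = 1L,
                     trial_id = 1:3, orientation = NA_real_, contrast = NA_real_,
                     invalid_fraction = 0, retained = TRUE)
  ft <- cbind(base, as.data.frame(matrix(NA_real_, 3, 15,
              dimnames = list(NULL, gazescreen:::gs_feature_names))))
  ft$t1_entropy <- c(1, 2, 100)
  agg <- aggregate_subject(ft)
  expect_equal(agg$t1_entropy, 2)      # robust to the outlier trial
  # identical trials aggregate to the trial value
  ft$t1_entropy <- rep(1.7, 3)
  expect_equal(aggregate_subject(ft)$t1_entropy, 1.7)
  # orientation-then-average for task 2: hand-built 2x2 grid
  b2 <- data.frame(subject_id = "S01", group = "control", task_id = 2L,
                   trial_id = 1:4, orientation = c(0, 0, 90, 90),
                   contrast = 0.4, invalid_fraction = 0, retained = TRUE)
  f2 <- cbind(b2, as.data.frame(matrix(NA_real_, 4, 15,
              dimnames = list(NULL, gazescreen:::gs_feature_names))))
  f2$t2_drift_deg <- c(1, 3, 10, 30)
  agg2 <- aggregate_subject(f2)
  expect_equal(agg2$t2_drift_deg, mean(c(median(c(1, 3)), median(c(10, 30)))))
  # permutation invariance over trial order
  f2p <- f2[c(3, 1, 4, 2), ]
  expect_equal(aggregate_subject(f2p)$t2_drift_deg, agg2$t2_drift_deg)
  # zero retained trials leave the task features missing
  f2$retained <- FALSE
  expect_true(is.na(aggregate_subject(f2)$t2_drift_deg))
})
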