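# Euclidean-distance identity assignment with bounded history and expiry

gate_big <- bt_polygon(c(-1e4, 1e4, 1e4, -1e4), c(-1e4, -1e4, 1e4, 1e4))

step_once <- function(state, det, params = tracker_params(), gate = NULL) {
  tracker_step(state, det, params, gate)
}

test_that("sub-radius detections keep their identity, others found new ones", {
  st <- tracker_state()
  r1 <- step_once(st, make_frame_det(0, 100, 100))
  expect_equal(r1$assignments$track_id, 1L)

  # distance 10 < 20: identity retained
  r2 <- step_once(r1$state, make_frame_det(1, 110, 100))
  expect_equal(r2$assignments$track_id, 1L)

  # distance 25 > 20: a new identity
  r3 <- step_once(r2$state, make_frame_det(2, 135, 100))
  expect_equal(r3$assignments$track_id, 2L)

  # distance exactly 20 is NOT a match (strictly less than)
  st <- tracker_state()
  r1 <- step_once(st, make_frame_det(0, 100, 100))
  r2 <- step_once(r1$state, make_frame_det(1, 120, 100))
  expect_equal(r2$assignments$track_id, 2L)
})

test_that("unique sub-radius pairing associates each track to its detection", {
  st <- tracker_state()
  r1 <- step_once(st, make_frame_det(0, c(0, 30), 0))
  r2 <- step_once(r1$state, make_frame_det(1, c(29, 1), 0))
  # detection at 29 belongs to the track founded at 30, detection at 1 to 0
  expect_equal(r2$assignments$track_id, c(2L, 1L))
})

test_that("greedy resolves conflicts nearest-first with one-to-one use", {
  # one track, two detections both in radius: nearest wins, other is new
  st <- tracker_state()
  r1 <- step_once(st, make_frame_det(0, 100, 100))
  r2 <- step_once(r1$state, make_frame_det(1, c(108, 103), 100))
  expect_equal(r2$assignments$track_id, c(2L, 1L))
})

test_that("missed-frame expiry removes a track after max_missed empty frames", {
  p <- tracker_params()
  st <- tracker_state()
  r <- step_once(st, make_frame_det(0, 100, 100), p)
  empty <- make_frame_det(0, numeric(0), numeric(0))
  for (f in 1:10) {
    r <- step_once(r$state, empty, p)
    if (f < 10) expect_length(r$state$tracks, 1)
  }
  expect_length(r$state$tracks, 0)
  # a detection at the old spot now founds a fresh identity
  d <- make_frame_det(11, 100, 100)
  r2 <- step_once(r$state, d, p)
  expect_equal(r2$assignments$track_id, 2L)
})

test_that("gap survival: identity preserved iff gap < max_missed", {
  run_gap <- function(gap) {
    det <- rbind(make_frame_det(0, 100, 100),
                 make_frame_det(gap + 1L, 105, 100))
    run_tracker(det, tracker_params(), n_frames = gap + 2L)
  }
  expect_equal(unique(run_gap(9)$track_id), 1L)   # 9 missed frames: survives
  expect_equal(run_gap(10)$track_id, c(1L, 2L))    # 10 missed frames: new id

  # short gap but reappearance beyond the radius: still a new identity
  far <- rbind(make_frame_det(0, 100, 100), make_frame_det(3L, 130, 100))
  expect_equal(run_tracker(far, tracker_params(), n_frames = 4L)$track_id,
               c(1L, 2L))
})

test_that("association is invariant to detection input order", {
  set.seed(55)
  p <- tracker_params(min_confidence = 0)
  for (rep in 1:50) {
    nt <- sample(1:5, 1); nd <- sample(1:5, 1)
    txy <- matrix(runif(2 * nt, 0, 60), ncol = 2)
    dxy <- matrix(runif(2 * nd, 0, 60), ncol = 2)
    st0 <- tracker_step(tracker_state(),
                        make_frame_det(0, txy[, 1], txy[, 2]), p)$state
    perm <- sample(nd)
    a1 <- tracker_step(st0, make_frame_det(1, dxy[, 1], dxy[, 2]),
                       p)$assignments
    a2 <- tracker_step(st0, make_frame_det(1, dxy[perm, 1], dxy[perm, 2]),
                       p)$assignments
    # with distinct distances, the (identity, position) matching is the same
    m1 <- a1[a1$track_id <= nt, c("track_id", "cx", "cy")]
    m2 <- a2[a2$track_id <= nt, c("track_id", "cx", "cy")]
    expect_equal(m1[order(m1$track_id), ], m2[order(m2$track_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("frame bookkeeping is strict", {
  st <- tracker_state()
  expect_error(tracker_step(st, make_frame_det(3, 0, 0)), "expects frame")
  r <- step_once(st, make_frame_det(0, 0, 0))
  expect_error(tracker_step(r$state, make_frame_det(0, 0, 0)),
               "expects frame")
  mixed <- rbind(make_frame_det(1, 0, 0), make_frame_det(2, 5, 5))
  expect_error(tracker_step(r$state, mixed), "mixed frame")
})

test_that("low-confidence and out-of-gate detections are discarded", {
  gate <- bt_polygon(c(0, 200, 200, 0), c(0, 0, 200, 200))
  det <- rbind(make_frame_det(0, 50, 50, conf = 0.9),
               make_frame_det(0, 60, 60, conf = 0.3),     # below cutoff
               make_frame_det(0, 300, 300, conf = 0.9))   # outside gate
  r <- tracker_step(tracker_state(), det, tracker_params(), gate)
  expect_equal(nrow(r$assignments), 1)
  expect_equal(r$assignments$cx, 50)
})

test_that("history is bounded and frames strictly increase", {
  det <- do.call(rbind, lapply(0:24, function(f)
    make_frame_det(f, 100 + f * 2, 100)))
  st <- tracker_state()
  for (f in 0:24) {
    r <- tracker_step(st, det[det$frame == f, ], tracker_params())
    st <- r$state
  }
  h <- st$tracks[[1]]$history
  expect_equal(nrow(h), 10)
  expect_equal(h$frame, 15:24)
  expect_true(all(diff(h$frame) > 0))
})

test_that("single-frame association equals the brute-force oracle", {
  set.seed(123)
  p <- tracker_params(min_confidence = 0)
  for (rep in 1:300) {
    nt <- sample(0:5, 1); nd <- sample(0:5, 1)
    txy <- matrix(runif(2 * nt, 0, 80), ncol = 2)
    dxy <- matrix(runif(2 * nd, 0, 80), ncol = 2)
    # seed the state with nt tracks at known positions
    st <- tracker_state()
    if (nt > 0) {
      r <- tracker_step(st, make_frame_det(0, txy[, 1], txy[, 2]), p)
      st <- r$state
    } else {
      st$frame <- 0L
    }
    det <- if (nd > 0) make_frame_det(1, dxy[, 1], dxy[, 2]) else
      make_frame_det(1, numeric(0), numeric(0))
    r <- tracker_step(st, det, p)
    want <- oracle_greedy_match(txy, dxy, p$match_radius)
    got <- r$assignments$track_id[want$det]
    expect_equal(got, want$track, # nolint
                 info = sprintf("rep %d", rep))
    # detections the oracle leaves unmatched must carry fresh ids (> nt)
    fresh <- setdiff(seq_len(nd), want$det)
    if (length(fresh))
      expect_true(all(r$assignments$track_id[fresh] > nt))
  }
})

test_that("per-frame assignment is one-to-one and ids never reused", {
  set.seed(77)
  det <- do.call(rbind, lapply(0:49, function(f)
    make_frame_det(f, runif(4, 0, 300), runif(4, 0, 300))))
  out <- run_tracker(det, tracker_params(min_confidence = 0))
  for (f in unique(out$frame)) {
    ids <- out$track_id[out$frame == f]
    expect_equal(length(ids), length(unique(ids)))
  }
  # first appearance order of ids is monotone in frame
  first <- tapply(out$frame, out$track_id, min)
  expect_true(all(diff(first[order(as.integer(names(first)))]) >= 0))
})

test_that("run_tracker recovers clean trajectories without switches", {
  # one bird moving 5 px/frame for 50 frames
  det <- make_frame_det(0:49, 100 + 5 * (0:49), 200)
  out <- run_tracker(det, tracker_params())
  expect_equal(unique(out$track_id), 1L)
  expect_equal(nrow(out), 50)

  # two parallel trajectories 100 px apart
  det2 <- rbind(make_frame_det(0:49, 100 + 5 * (0:49), 100),
                make_frame_det(0:49, 100 + 5 * (0:49), 200))
  det2 <- det2[order(det2$frame), ]
  out2 <- run_tracker(det2, tracker_params())
  expect_equal(sort(unique(out2$track_id)), c(1L, 2L))
  # each identity stays on one y-line: zero switches
  expect_equal(length(unique(out2$y[out2$track_id == 1L])), 1L)
  expect_equal(length(unique(out2$y[out2$track_id == 2L])), 1L)
})

test_that("empty input yields empty output", {
  expect_equal(nrow(run_tracker(make_frame_det(0, numeric(0), numeric(0)))),
               0)
})
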