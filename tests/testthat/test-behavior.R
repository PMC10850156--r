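test_that("velocity recovers constant-speed motion and the smoothing limit", {
  fr <- 30
  n <- 300
  traj <- trajectory(seq_len(n) - 1L, (seq_len(n) - 1) / fr,
                     seq(2, by = 10 / fr, length.out = n), rep(5, n),
                     rep(5, n), fr, c(200, 200))
  v <- velocity(traj)
  interior <- 40:260
  expect_equal(v$speed[interior], rep(10, length(interior)),
               tolerance = 0.02)

  # stationary track: all zeros
  traj0 <- trajectory(1:50, (1:50) / fr, rep(3, 50), rep(3, 50),
                      rep(0, 50), fr, c(50, 50))
  expect_equal(velocity(traj0)$speed, rep(0, 50))

  # zero window degenerates to the raw finite difference
  vraw <- velocity(traj, smooth_window = 0)
  expect_equal(vraw$speed, rep(10, n))
})

test_that("immobility needs both criteria and strictly more than 15 frames", {
  cfg <- default_config()
  pad <- rep(20, 30) # non-qualifying flanks
  mk <- function(n_quiet, speed_quiet = 0, motion_quiet = 0) {
    speed <- c(pad, rep(speed_quiet, n_quiet), pad)
    motion <- c(rep(5, 30), rep(motion_quiet, n_quiet), rep(5, 30))
    make_traj_with_speed(speed, motion)
  }
  x <- mk(20)
  expect_equal(nrow(detect_immobility(x$traj, cfg, x$vel)), 1)
  expect_equal(detect_immobility(x$traj, cfg, x$vel)$stop -
                 detect_immobility(x$traj, cfg, x$vel)$start,
               20 / 30)

  # exactly 15 qualifying frames: "over 15" is strict
  x15 <- mk(15)
  expect_equal(nrow(detect_immobility(x15$traj, cfg, x15$vel)), 0)
  x16 <- mk(16)
  expect_equal(nrow(detect_immobility(x16$traj, cfg, x16$vel)), 1)

  # slow but visibly moving (motion 2%) is not immobility
  xm <- mk(20, speed_quiet = 5, motion_quiet = 2)
  expect_equal(nrow(detect_immobility(xm$traj, cfg, xm$vel)), 0)
  # exactly at the 6 cm/s threshold is not immobility (strict <)
  xs <- mk(20, speed_quiet = 6, motion_quiet = 0)
  expect_equal(nrow(detect_immobility(xs$traj, cfg, xs$vel)), 0)
})

test_that("locomotion bouts apply the 6 cm/s and 10 cm rules", {
  cfg <- default_config()
  fr <- 30
  # one continuous 10-s run at 10 cm/s: one bout of ~100 cm
  x <- make_traj_with_speed(c(rep(0, 30), rep(10, 300), rep(0, 30)),
                            frame_rate = fr, arena = c(200, 200))
  out <- detect_locomotion(x$traj, cfg, x$vel)
  expect_equal(nrow(out$bouts), 1)
  expect_equal(out$distance, 100, tolerance = 0.02)

  # a run covering ~9 cm at 7 cm/s is discarded by the 100 mm rule
  x9 <- make_traj_with_speed(c(rep(0, 30), rep(7, round(9 / 7 * fr)),
                               rep(0, 30)), frame_rate = fr,
                             arena = c(200, 200))
  out9 <- detect_locomotion(x9$traj, cfg, x9$vel)
  expect_equal(nrow(out9$bouts), 0)
  expect_equal(out9$distance, 0)

  # stationary: nothing
  x0 <- make_traj_with_speed(rep(0, 100))
  expect_equal(nrow(detect_locomotion(x0$traj, cfg, x0$vel)$bouts), 0)
  # exactly 6 cm/s is not locomotion (strict >)
  x6 <- make_traj_with_speed(rep(6, 400), frame_rate = fr,
                             arena = c(200, 200))
  expect_equal(nrow(detect_locomotion(x6$traj, cfg, x6$vel)$bouts), 0)
})

test_that("pauses need < 3 cm/s for at least 1 s; initiations at pause end", {
  cfg <- default_config()
  fr <- 30
  # 2 s stationary then movement
  x <- make_traj_with_speed(c(rep(0, 60), rep(10, 120)), frame_rate = fr)
  out <- detect_pauses(x$traj, cfg, x$vel)
  expect_equal(nrow(out$pauses), 1)
  expect_equal(out$initiations, 2.0)

  # 0.9 s below threshold: no pause
  x2 <- make_traj_with_speed(c(rep(10, 30), rep(2, 27), rep(10, 30)),
                             frame_rate = fr)
  expect_equal(nrow(detect_pauses(x2$traj, cfg, x2$vel)$pauses), 0)
  # exactly 1 s qualifies
  x3 <- make_traj_with_speed(c(rep(10, 30), rep(2, 30), rep(10, 30)),
                             frame_rate = fr)
  expect_equal(nrow(detect_pauses(x3$traj, cfg, x3$vel)$pauses), 1)

  # constant 10 cm/s: none
  x4 <- make_traj_with_speed(rep(10, 200), frame_rate = fr,
                             arena = c(200, 200))
  expect_equal(nrow(detect_pauses(x4$traj, cfg, x4$vel)$pauses), 0)
})

test_that("zone metrics partition time exactly and match per-frame classification", {
  cfg <- default_config(frame_rate = 30)
  # diagonal crossing of a square arena
  n <- 600
  traj <- trajectory(seq_len(n) - 1L, (seq_len(n) - 1) / 30,
                     seq(0.5, 49.5, length.out = n),
                     seq(0.5, 49.5, length.out = n),
                     rep(5, n), 30, c(50, 50))
  zm <- zone_metrics(traj, cfg)
  expect_equal(zm$center_time + zm$thigmo_time, n / 30)
  # brute-force per-frame classification: band width 12.5% of the side
  band <- 0.125 * 50
  ctr <- traj$x >= band & traj$x <= 50 - band &
    traj$y >= band & traj$y <= 50 - band
  expect_equal(zm$center_time, sum(ctr) / 30)
  expect_equal(zm$thigmo_time, sum(!ctr) / 30)

  # wall-hugging path: no center time; central path: no thigmotaxis
  wall <- trajectory(1:100, (1:100) / 30, rep(1, 100),
                     seq(1, 40, length.out = 100), rep(5, 100), 30,
                     c(50, 50))
  expect_equal(zone_metrics(wall, cfg)$center_time, 0)
  ctr_traj <- trajectory(1:100, (1:100) / 30,
                         seq(20, 30, length.out = 100), rep(25, 100),
                         rep(5, 100), 30, c(50, 50))
  expect_equal(zone_metrics(ctr_traj, cfg)$thigmo_time, 0)
})

test_that("focused exploration chains successive dips within 5 s", {
  dip <- function(start, stop) data.frame(behavior = "head_dip",
                                          start = start, stop = stop)
  # gap of 3 s chains
  d <- rbind(dip(0, 1), dip(4, 5))
  fe <- detect_focused_exploration(d)
  expect_equal(nrow(fe$episodes), 1)
  expect_equal(fe$episodes$start, 0)
  expect_equal(fe$episodes$stop, 5)
  # 6 s apart: two isolated dips
  d2 <- rbind(dip(0, 1), dip(7, 8))
  fe2 <- detect_focused_exploration(d2)
  expect_equal(nrow(fe2$episodes), 0)
  expect_equal(nrow(fe2$isolated), 2)
  # transitive chaining across three dips with 4-s gaps
  d3 <- rbind(dip(0, 0.5), dip(4.5, 5), dip(9, 9.5))
  fe3 <- detect_focused_exploration(d3)
  expect_equal(nrow(fe3$episodes), 1)
  expect_equal(fe3$episodes$n_dips, 3)
  # a gap of exactly 5 s still chains ("within 5 s")
  d5 <- rbind(dip(0, 1), dip(6, 7))
  expect_equal(nrow(detect_focused_exploration(d5)$episodes), 1)
  # every dip lands in exactly one category
  set.seed(6)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    st <- sort(runif(n, 0, 40))
    d <- dip(st, st + 0.5)
    fe <- detect_focused_exploration(d)
    expect_equal(sum(fe$episodes$n_dips) + nrow(fe$isolated), n)
  }
})

test_that("ethogram precedence is manual > immobility > locomotion > surveying", {
  cfg <- default_config(frame_rate = 30)
  script <- data.frame(
    label = c("locomotion", "immobility", "surveying"),
    duration = c(20, 20, 10), speed = c(10, 0, 0),
    zone = "wall")
  g <- gen_tracking(cfg, seed = 1, script = script)
  etho <- build_ethogram(g$trajectory, NULL, cfg)
  lab <- attr(etho, "frame_labels")
  expect_setequal(unique(etho$behavior),
                  c("locomotion", "immobility", "surveying"))
  # manual rearing overrides moving frames
  manual <- event_table(data.frame(behavior = "rearing", start = 5,
                                   stop = 8))
  etho2 <- build_ethogram(g$trajectory, manual, cfg)
  lab2 <- attr(etho2, "frame_labels")
  sel <- g$trajectory$time >= 5 & g$trajectory$time < 8
  expect_true(all(lab2[sel] == "rearing"))
  expect_equal(lab2[!sel], lab[!sel])
})

test_that("detectors are invariant to uniform time translation", {
  cfg <- default_config(frame_rate = 30)
  g <- gen_tracking(cfg, seed = 3)
  tr <- g$trajectory
  tr2 <- tr
  tr2$time <- tr$time + 137.5
  for (fn in list(detect_immobility,
                  function(a, b) detect_locomotion(a, b)$bouts,
                  function(a, b) detect_pauses(a, b)$pauses)) {
    a <- fn(tr, cfg)
    b <- fn(tr2, cfg)
    expect_equal(b$start, a$start + 137.5)
    expect_equal(b$stop, a$stop + 137.5)
  }
})

test_that("epoch metrics average repetitions and normalize to Pre", {
  cfg <- default_config(frame_rate = 30, epoch_length = 30,
                        epoch_design = c("Pre", "ON", "OFF", "ON", "OFF"))
  # identical 30-s behavior blocks in every epoch
  block <- data.frame(label = c("locomotion", "immobility"),
                      duration = c(15, 15), speed = c(10, 0),
                      zone = "wall")
  script <- do.call(rbind, replicate(5, block, simplify = FALSE))
  g <- gen_tracking(cfg, seed = 1, script = script)
  etho <- build_ethogram(g$trajectory, NULL, cfg)
  em <- epoch_metrics(etho, g$trajectory, NULL, cfg)
  num <- vapply(em$normalized[-1], function(v) max(abs(v)), numeric(1))
  # residual boundary-frame effects only: fractions of a second / of a cm
  # against epoch totals of 15 s and ~150 cm
  expect_lt(max(num), 2.5)

  # head-dips only in ON epochs: Pre-normalized ON count equals raw count
  dips <- event_table(data.frame(behavior = rep("head_dip", 4),
                                 start = c(35, 40, 100, 110),
                                 stop = c(36, 41, 101, 111)))
  em2 <- epoch_metrics(etho, g$trajectory, dips, cfg)
  on_raw <- em2$by_label$headdip_count[em2$by_label$label == "ON"]
  on_norm <- em2$normalized$headdip_count[em2$normalized$label == "ON"]
  expect_equal(on_norm, on_raw)
  expect_equal(on_raw, 2) # (2 + 2) dips over 2 ON repetitions

  # design longer than the session is an error
  cfg_long <- default_config(frame_rate = 30, epoch_length = 500)
  expect_error(epoch_metrics(etho, g$trajectory, NULL, cfg_long),
               class = "ek_parameter_error")
})
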