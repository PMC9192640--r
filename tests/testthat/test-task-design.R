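# Trial schedule, motion timing, trigger codes and behavioural scoring.

test_that("schedule counterbalances all design cells exactly", {
  sched <- buildTrialSchedule(8, 20, seed = 1)
  expect_equal(nrow(sched), 160)
  cells <- table(sched$distractor, sched$cued_colour, sched$pairing)
  expect_true(all(cells == 20))
  # deterministic under a fixed seed
  expect_identical(sched, buildTrialSchedule(8, 20, seed = 1))
  # different seed reorders
  expect_false(identical(sched$cued_colour,
                         buildTrialSchedule(8, 20, seed = 2)$cued_colour))
})

test_that("motion directions are counterbalanced within each stratum", {
  sched <- buildTrialSchedule(8, 20, seed = 3)
  dirs <- as.matrix(sched[, paste0("dir_", 1:5)])
  for (d in c("present", "absent"))
    for (p in c("black6_white7.5", "black7.5_white6")) {
      inS <- sched$distractor == d & sched$pairing == p
      expect_equal(as.integer(table(dirs[inS, ])), rep(50L, 4))
    }
})

test_that("non-divisible trial counts are a configuration error", {
  expect_error(buildTrialSchedule(3, 5), "divisible")
})

test_that("onset sampler always satisfies the timing constraints", {
  set.seed(42)
  for (i in 1:2000) {
    on <- sampleMotionOnsets()
    expect_true(on[1] > 1.0)
    expect_true(all(diff(on) >= 2.0))
    expect_true(on[5] <= 13.5)
  }
})

test_that("infeasible onset constraints error via the packing bound", {
  # 1.0 + 5*0.5 + 4*1.5 + 1.5 = 11.0 <= 15 is feasible
  expect_silent(sampleMotionOnsets(15, 5, 1.0, 1.5, 1.5, 0.5, seed = 1))
  expect_error(sampleMotionOnsets(15, 5, 1.0, 12.0, 1.5, 0.5, seed = 1),
               "infeasible")
})

test_that("trigger encode/decode is the identity on all condition tuples", {
  map <- canonicalTriggerMap()
  codes <- c(map$cue_onset, map$trial_onset, map$motion_onset, map$feedback)
  expect_equal(length(unique(codes)), 49)  # 8 + 8 + 32 + 1
  expect_true(all(codes >= 1 & codes <= 255))
  for (d in c("present", "absent"))
    for (co in c("black", "white"))
      for (p in c("black6_white7.5", "black7.5_white6")) {
        spec <- specRow(d, co, p)
        ev <- encodeTriggers(spec, map)
        expect_equal(nrow(ev), 8)
        expect_equal(ev$kind, c("cue_onset", "trial_onset",
                                rep("motion_onset", 5), "feedback"))
        expect_equal(ev$code[8], 222L)
        for (j in 1:7) {
          lab <- decodeTriggerCode(ev$code[j], map)
          expect_equal(lab$cued_colour, co)
          expect_equal(lab$distractor, d)
          expect_equal(lab$cued_freq, spec$cued_freq)
          if (lab$kind == "motion_onset")
            expect_equal(lab$direction, spec[[paste0("dir_", j - 2)]])
        }
      }
})

test_that("a colliding trigger map is rejected", {
  map <- canonicalTriggerMap()
  map$cue_onset[1] <- map$trial_onset[1]
  expect_error(encodeTriggers(specRow(), map), "colliding")
})

test_that("response scoring implements the first-press rule", {
  fr <- 120
  spec <- specRow(onsets = c(2, 5, 7.5, 10, 12.5),
                  dirs = c(0, 90, 180, 270, 0))
  blank <- integer(15 * fr)

  # no press anywhere: all misses, no RTs
  sc <- scoreResponses(blank, spec)
  expect_equal(sc$acc, rep(0L, 5))
  expect_true(all(is.na(sc$rt)))

  # correct press 0.6 s after the first (0 degree) target
  resp <- blank
  resp[round((2 + 0.6) * fr) + 1] <- 1L
  sc <- scoreResponses(resp, spec)
  expect_equal(sc$acc[1], 1L)
  expect_equal(sc$rt[1], 0.6)
  expect_equal(sc$acc[-1], rep(0L, 4))

  # wrong first press then right second press: scored incorrect, no RT
  resp <- blank
  resp[round((5 + 0.4) * fr) + 1] <- 4L   # wrong key for the 90-deg target
  resp[round((5 + 0.8) * fr) + 1] <- 2L   # right key, but too late
  sc <- scoreResponses(resp, spec)
  expect_equal(sc$acc[2], 2L)
  expect_true(is.na(sc$rt[2]))

  # presses outside every attribution window do not change the scores
  resp2 <- resp
  resp2[round(0.5 * fr) + 1] <- 3L        # before the first target
  expect_identical(scoreResponses(resp2, spec)$acc, sc$acc)

  # a window wider than the guaranteed spacing cannot attribute uniquely
  expect_error(scoreResponses(blank, spec, window = 2.5), "uniquely")
})
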