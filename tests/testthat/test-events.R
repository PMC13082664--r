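test_that("binarize_contact thresholds and validates", {
  expect_equal(binarize_contact(c(0.0, 0.2, 0.9, 1.0), 0.5), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_contact(c(0.1, 0.2, 0.3), 0.5), c(0L, 0L, 0L))
  expect_equal(binarize_contact(c(0, 1, 2), 0), c(1L, 1L, 1L))
  expect_error(binarize_contact(c(0, NA, 1), 0.5), "non-finite")
})

test_that("detect_events extracts rising/falling edges", {
  ev <- detect_events(c(0, 0, 1, 1, 1, 0, 0), fs = 100, min_gap = 0)
  expect_equal(ev$type, c("HS", "TO"))
  expect_equal(ev$index, c(2L, 5L))

  ev2 <- detect_events(c(1, 1, 0, 0), fs = 100, min_gap = 0)
  expect_equal(ev2$type, "TO")
  expect_equal(ev2$index, 2L)

  expect_equal(nrow(detect_events(integer(), fs = 100)), 0L)
  expect_error(detect_events(c(0, 2, 1), fs = 100), "binary")
})

test_that("debounce merging matches the run-enumeration oracle", {
  # single-sample dropout inside a long stance
  x <- c(rep(0, 10), rep(1, 50), 0, rep(1, 49), rep(0, 10))
  ev <- detect_events(x, fs = 100, min_gap = 0.05)
  clean <- c(rep(0, 10), rep(1, 100), rep(0, 10))
  ev_clean <- detect_events(clean, fs = 100, min_gap = 0)
  expect_equal(data.frame(ev), data.frame(ev_clean))

  set.seed(101)
  for (rep_i in 1:30) {
    n <- sample(50:200, 1)
    x <- as.integer(stats::runif(n) <
                      stats::filter(stats::runif(n), rep(1 / 5, 5), circular = TRUE))
    mg <- sample(c(0, 0.02, 0.05), 1)
    got <- detect_events(x, fs = 100, min_gap = mg)
    want <- oracle_detect(x, 100, mg)
    expect_equal(got$type, want$type)
    expect_equal(got$index, want$index)
  }
})

test_that("label_phases applies the four interval rules", {
  el <- gaitphase:::new_gait_events(c("TO", "HS"), c(10L, 50L), "left")
  er <- gaitphase:::new_gait_events(c("HS", "TO", "HS"), c(0L, 60L, 100L), "right")
  ph <- label_phases(el, er, 120L, reference_side = "right")
  r <- rle(as.integer(ph))
  expect_equal(r$values, c(0L, 1L, 2L, 3L, -1L))
  expect_equal(r$lengths, c(10L, 40L, 10L, 40L, 20L))
  # per-sample cross-check against an independent rule evaluator
  want <- vapply(0:119, oracle_phase_at, integer(1),
                 ref_hs = c(0, 100), ref_to = 60, con_hs = 50, con_to = 10)
  expect_equal(as.integer(ph), want)
})

test_that("periodic schedule yields the closed-form 20/80/20/80 partition", {
  p <- gait_sim_params(trial_duration = 10, fs = 200, cycle_mean = 1.0,
                       cycle_cv = 0, stance_fraction = 0.6,
                       contralateral_offset = 0.5, start_offset = 0.1)
  ev <- simulate_subject_cycles(p)
  ph <- label_phases(ev$left, ev$right, 2000L)
  r <- rle(as.integer(ph))
  core <- r$lengths[r$values >= 0]
  vals <- r$values[r$values >= 0]
  expect_equal(unique(core[vals == 0L]), 20L)
  expect_equal(unique(core[vals == 1L]), 80L)
  expect_equal(unique(core[vals == 2L]), 20L)
  expect_equal(unique(core[vals == 3L]), 80L)
  s <- phase_duration_summary(ph, 200)
  expect_equal(s$mean_s, c(0.10, 0.40, 0.10, 0.40))
  expect_equal(s$sd_s, rep(0, 4))
})

test_that("labeling errors name the offending situation", {
  # alternation violation
  bad <- gaitphase:::new_gait_events(c("HS", "HS"), c(0L, 10L), "right")
  expect_error(validate_events <- gaitphase:::validate_events(bad), "alternate")
  # mid-sequence interleaving: in the second cycle the chain's reference TO
  # lands beyond the next reference HS
  el <- gaitphase:::new_gait_events(c("TO", "HS", "TO", "HS"),
                                    c(10L, 50L, 130L, 180L), "left")
  er <- gaitphase:::new_gait_events(c("HS", "TO", "HS", "TO", "HS", "TO"),
                                    c(0L, 60L, 100L, 120L, 200L, 230L), "right")
  expect_error(label_phases(el, er, 260L), "labeling error")
})

test_that("phase_duration_summary edge cases", {
  expect_equal(nrow(phase_duration_summary(rep(-1L, 100), 100)), 0L)
  one <- c(rep(-1L, 5), rep(0L, 10), rep(1L, 20), rep(2L, 10), rep(3L, 20), rep(-1L, 5))
  s <- phase_duration_summary(one, 100)
  expect_equal(s$sd_s, rep(0, 4))
  expect_equal(s$n_runs, rep(1L, 4))
})

test_that("partition, order and side-symmetry hold on random schedules", {
  set.seed(7)
  for (i in 1:25) {
    p <- gait_sim_params(trial_duration = 10, fs = 200,
                         cycle_mean = stats::runif(1, 0.9, 1.3),
                         cycle_cv = stats::runif(1, 0, 0.05),
                         stance_fraction = stats::runif(1, 0.57, 0.65),
                         contralateral_offset = stats::runif(1, 0.46, 0.55))
    ev <- simulate_subject_cycles(p)
    ph <- label_phases(ev$left, ev$right, 2000L)
    r <- rle(as.integer(ph))
    vals <- r$values[r$values >= 0]
    # order: deduplicated labels cycle LR -> LS -> PSw -> Sw
    expect_equal(vals, rep(0:3, length.out = length(vals)))
    # partition: labeled samples between consecutive reference HS sum to
    # the cycle length
    rhs <- ev$right$index[ev$right$type == "HS"]
    lab <- as.integer(ph)
    for (k in seq_len(length(rhs) - 1L)) {
      seg <- lab[(rhs[k] + 1L):rhs[k + 1L]]
      if (all(seg >= 0L)) {
        expect_equal(length(seg), rhs[k + 1L] - rhs[k])
        expect_equal(sort(unique(seg)), 0:3)
      }
    }
    # symmetry: swapping sides and the reference leg gives the same label
    # multiset per complete cycle (durations are tied to the schedule)
    ph_l <- label_phases(ev$left, ev$right, 2000L, reference_side = "left")
    tab_r <- table(factor(lab[lab >= 0], levels = 0:3))
    tab_l <- table(factor(as.integer(ph_l)[as.integer(ph_l) >= 0], levels = 0:3))
    # same number of complete cycles may differ by one at the boundaries;
    # compare per-cycle run-length multisets instead
    rl_r <- rle(lab[lab >= 0])$lengths
    rl_l <- rle(as.integer(ph_l)[as.integer(ph_l) >= 0])$lengths
    expect_lt(abs(mean(rl_r) - mean(rl_l)), max(rl_r))
    expect_true(all(tab_l > 0) && all(tab_r > 0))
  }
})
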