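test_that("autofluorescence subtraction floors at zero with a warning", {
  expect_identical(correct_autofluorescence(c(500, 300), 0), c(500, 300))
  expect_identical(correct_autofluorescence(500, 120), 380)
  expect_warning(
    out <- correct_autofluorescence(c(100, 500), c(150, 120)),
    class = "ntx_floor_warning"
  )
  expect_identical(out, c(0, 380))
  expect_error(correct_autofluorescence(c(1, 2, 3), c(1, 2)),
               class = "ntx_alignment_error")
})

test_that("fold induction is the ratio of replicate means", {
  expect_equal(fold_induction(c(680, 720), c(195, 205)), 3.5)
  expect_equal(fold_induction(c(200, 200), c(200, 200)), 1)
  # scale invariance
  expect_equal(fold_induction(2 * c(680, 720), 2 * c(195, 205)), 3.5)
  expect_error(fold_induction(c(500), c(0, 0)),
               class = "ntx_degenerate_data_error")
})

test_that("fold_table corrects, averages and references the vehicle control", {
  screen <- fold_screen(doses = c(5, 10), folds = c(2, 3.5),
                        viability = c(80, 60), auto = 4)
  ft <- fold_table(screen)
  expect_equal(ft$fold[ft$dose_ug_ml == 0], 1)
  expect_equal(ft$fold[ft$dose_ug_ml == 10], 3.5, tolerance = 1e-12)
  expect_false(any(ft$gated_out))
  # autofluorescence inflating raw GFP must not inflate the fold
  raw_ratio <- screen$gfp_mean[screen$dose_ug_ml == 10] /
    screen$gfp_mean[screen$dose_ug_ml == 0]
  expect_gt(raw_ratio, 3.5)
})

test_that("verdicts follow the fold bands with the viability gate", {
  # folds > 2 at healthy viability: positive
  pos <- call_reporter(tibble::tibble(
    dose_ug_ml = c(5, 10, 20), fold = c(2.1, 3.3, 3.5),
    viability_pct = c(90, 75, 50)
  ))
  expect_identical(pos$verdict, "positive")
  expect_equal(pos$max_valid_fold, 3.5)
  expect_equal(pos$lowest_positive_dose, 5)

  # >2-fold reached only below the viability gate: not positive
  gated <- call_reporter(tibble::tibble(
    dose_ug_ml = c(5, 10, 20), fold = c(1.2, 1.4, 2.5),
    viability_pct = c(90, 60, 20)
  ))
  expect_identical(gated$verdict, "negative")
  expect_equal(gated$gated_doses, 20)

  # all folds at or below 1: negative
  neg <- call_reporter(tibble::tibble(
    dose_ug_ml = c(5, 10), fold = c(0.9, 1.0), viability_pct = c(95, 90)
  ))
  expect_identical(neg$verdict, "negative")

  # weak band (1.5, 2]: fold exactly 2 counts as weak positive
  weak <- call_reporter(tibble::tibble(
    dose_ug_ml = c(5, 10), fold = c(1.6, 2.0), viability_pct = c(95, 90)
  ))
  expect_identical(weak$verdict, "weak_positive")
  expect_true(is.na(weak$lowest_positive_dose))

  # every dose gated out: uninterpretable
  un <- call_reporter(tibble::tibble(
    dose_ug_ml = c(5, 10), fold = c(3, 4), viability_pct = c(20, 10)
  ))
  expect_identical(un$verdict, "uninterpretable")
  expect_match(un$explanation, "viability")
})

test_that("calls are monotone in thresholds and gating never creates positives", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    folds <- tibble::tibble(
      dose_ug_ml = sort(runif(n, 1, 100)),
      fold = runif(n, 0.5, 4),
      viability_pct = runif(n, 5, 100)
    )
    rank_of <- c(negative = 1, weak_positive = 2, positive = 3,
                 uninterpretable = 0)
    v_low <- call_reporter(folds, positive_threshold = 2)
    v_high <- call_reporter(folds, positive_threshold = 3)
    expect_lte(rank_of[v_high$verdict], rank_of[v_low$verdict])
    # a stricter gate can only lower the maximum valid fold
    g_strict <- call_reporter(folds, viability_gate = 50)
    if (!is.na(g_strict$max_valid_fold) && !is.na(v_low$max_valid_fold)) {
      expect_lte(g_strict$max_valid_fold, v_low$max_valid_fold)
    }
  }
})

test_that("synthetic panels with known activation are called correctly", {
  set.seed(77)
  n_runs <- 200
  correct <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    f_max <- sample(c(1.2, 4), 1) # clearly inactive vs clearly active
    cfg <- panel_config(
      list(particle_spec("NP", 20, 5)), reporters = "Srxn1",
      true_ld50s = 30,
      fold_curves = tibble::tibble(reporter = "Srxn1", fold_max = f_max,
                                   d_half = 5),
      noise_cv = 0.1, n_replicates = 3, seed = r
    )
    calls <- call_reporter_table(generate_screen(cfg))
    correct[r] <- (calls$verdict == "positive") == (f_max > 2)
  }
  expect_gte(mean(correct), 0.95)
})

test_that("dose selection implements the 50-75% cytotoxicity rule", {
  # 40 ug/mL gives 60% cytotoxicity: ladder 2.5 .. 40
  sc <- data.frame(dose = c(10, 20, 40, 80), viability = c(80, 65, 40, 15))
  expect_equal(select_doses(sc), c(2.5, 5, 10, 20, 40))

  # no cytotoxicity anywhere: tested up to the 100 ug/mL cap
  flat <- data.frame(dose = c(12.5, 25, 50, 100),
                     viability = c(99, 98, 98, 97))
  expect_equal(select_doses(flat), c(6.25, 12.5, 25, 50, 100))

  # 80% cytotoxicity at 20 and 55% at 10: top dose 10
  mid <- data.frame(dose = c(2.5, 5, 10, 20), viability = c(90, 70, 45, 20))
  expect_equal(select_doses(mid), c(0.625, 1.25, 2.5, 5, 10))

  # band jumped over entirely: fall back to the last dose under 50%
  jump <- data.frame(dose = c(5, 10, 20, 40), viability = c(95, 80, 60, 10))
  expect_equal(select_doses(jump), c(1.25, 2.5, 5, 10, 20))

  # everything too toxic
  toxic <- data.frame(dose = c(5, 10, 20, 40), viability = c(10, 8, 5, 2))
  expect_error(select_doses(toxic), class = "ntx_degenerate_data_error")

  expect_error(select_doses(data.frame(dose = c(1, 2), viability = c(9, 9))),
               class = "ntx_insufficient_data_error")
})
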