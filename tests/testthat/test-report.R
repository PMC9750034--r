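make_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_training_dataset(n_per_class = 20, seed = 300)
      cache <<- train_movement_classifier(ds, seed = 300)
    }
    cache
  }
})

test_that("a full synthetic patient yields 18 ASIs, 5 decisions and 10 grades", {
  cfg <- generator_config(seed = 71, severity = 0.4, affected_side = "left")
  sessions <- generate_patient(cfg, "pr")
  rep <- assess_patient(sessions, make_model())
  expect_s3_class(rep, "patient_report")
  expect_equal(sum(lengths(rep$asi$per_area)), 18)
  expect_length(rep$ability, 5)
  grades <- unlist(lapply(unclass(rep$grades),
                          function(g) c(g$left_grade, g$right_grade)))
  expect_length(grades, 10)
  expect_length(rep$missing, 0)
})

test_that("partial input yields a partial report with explicit missing markers", {
  rest_only <- list(make_rest(n = 4))
  rep <- assess_patient(rest_only)
  expect_length(rep$asi$per_area, 1)
  expect_null(rep$ability)
  expect_null(rep$grades)
  expect_true("block:grades" %in% rep$missing)
  expect_true(any(grepl("^block:ability", rep$missing)))
  expect_true("movement:smiling" %in% rep$missing)
  # renders without error, with dashes for absent entries
  txt <- render_report(rep, "text")
  expect_match(txt, "—")
})

test_that("conflicting patients, duplicate movements and absent rest error", {
  cfg <- generator_config(seed = 72)
  a <- generate_patient(cfg, "pa")
  b <- generate_patient(cfg, "pb")
  expect_error(assess_patient(c(a, b)), "patient ids")
  expect_error(assess_patient(c(a, a[1])), "duplicate")
  expect_error(assess_patient(a[-1]), "rest")
})

test_that("JSON rendering is schema-stable and matches the text view after rounding", {
  cfg <- generator_config(seed = 73, severity = 0.6, affected_side = "right")
  sessions <- generate_patient(cfg, "pj")
  rep <- assess_patient(sessions, make_model())
  doc <- render_report(rep, "json")
  parsed <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  expect_named(parsed, c("patient_id", "asi", "ability", "grades", "missing",
                         "metadata"))
  expect_length(parsed$asi, 6)
  expect_length(parsed$ability, 5)
  expect_length(parsed$grades, 5)
  # full precision in JSON; integer display rounding in text
  txt <- render_report(rep, "text")
  eyes_rest <- parsed$asi$rest$eyes
  expect_match(txt, sprintf("\\b%d\\b", as.integer(round(eyes_rest))))
  for (m in names(parsed$grades)) {
    expect_equal(parsed$grades[[m]]$left, rep$grades[[m]]$left_grade)
  }
  expect_error(render_report(rep, "xml"), "arg")
})

test_that("simulate -> assess -> render is byte-identical across runs", {
  run <- function() {
    cfg <- generator_config(seed = 74, severity = 0.3, affected_side = "left")
    sessions <- generate_patient(cfg, "pk")
    render_report(assess_patient(sessions, make_model()), "json")
  }
  expect_identical(run(), run())
})

test_that("severity sweep: affected grades fall, healthy grades hold, ASIs fall", {
  severities <- seq(0, 1, by = 0.1)
  affected <- list()
  healthy <- list()
  engaged_asi <- list()
  for (s in severities) {
    cfg <- generator_config(seed = 80, noise_sd = 0, severity = s,
                            affected_side = "left", rest_asymmetry_scale = 0)
    sessions <- generate_patient(cfg, "sweep")
    gr <- grade_report(sessions)
    ar <- asi_report(sessions)
    affected[[length(affected) + 1]] <-
      vapply(gr, function(g) g$left_grade, integer(1))
    healthy[[length(healthy) + 1]] <-
      vapply(gr, function(g) g$right_grade, integer(1))
    engaged_asi[[length(engaged_asi) + 1]] <- c(
      smiling = unname(ar$per_area$smiling[["mouth"]]),
      eye_closure = unname(ar$per_area$eye_closure[["eyes"]]),
      raising_eyebrows = unname(ar$per_area$raising_eyebrows[["eyebrows"]]),
      blowing_cheeks = unname(ar$per_area$blowing_cheeks[["mouth"]]),
      whistling = unname(ar$per_area$whistling[["mouth"]])
    )
  }
  affected <- do.call(rbind, affected)
  healthy <- do.call(rbind, healthy)
  engaged_asi <- do.call(rbind, engaged_asi)
  # affected side: non-increasing in severity for every movement, reaching 0
  expect_true(all(apply(affected, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(affected[1, ] > 0))
  expect_true(all(affected[nrow(affected), ] == 0))
  # healthy side: constant for the four lateralised movements; whistling
  # shares the midline pucker term, so it may only decrease
  lateral <- setdiff(colnames(healthy), "whistling")
  expect_true(all(apply(healthy[, lateral], 2,
                        function(col) length(unique(col)) == 1)))
  expect_true(all(diff(healthy[, "whistling"]) <= 0))
  # engaged-area dynamic ASIs: non-increasing in severity
  expect_true(all(apply(engaged_asi, 2, function(col) all(diff(col) <= 1e-9))))
})

test_that("with mild noise, averaged grades keep the severity ordering", {
  severities <- c(0, 0.5, 1)
  mean_affected <- matrix(0, length(severities), 5)
  mean_healthy <- matrix(0, length(severities), 4)
  n_seeds <- 20
  for (si in seq_along(severities)) {
    acc_a <- matrix(0, n_seeds, 5)
    acc_h <- matrix(0, n_seeds, 4)
    for (k in seq_len(n_seeds)) {
      cfg <- generator_config(seed = 9000 + k, noise_sd = 0.02,
                              severity = severities[si],
                              affected_side = "left",
                              rest_asymmetry_scale = 0)
      gr <- grade_report(generate_patient(cfg, "noisy"))
      acc_a[k, ] <- vapply(gr, function(g) g$left_grade, integer(1))
      lateral <- setdiff(names(gr), "whistling")
      acc_h[k, ] <- vapply(gr[lateral], function(g) g$right_grade, integer(1))
    }
    mean_affected[si, ] <- colMeans(acc_a)
    mean_healthy[si, ] <- colMeans(acc_h)
  }
  expect_true(all(apply(mean_affected, 2, function(col) all(diff(col) <= 0))))
  # healthy-side means stay within half a grade point of their noise-free value
  expect_true(all(apply(mean_healthy, 2,
                        function(col) max(col) - min(col) <= 0.5)))
})
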