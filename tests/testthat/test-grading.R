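test_that("index bands reproduce the published criteria with half-open bounds", {
  crit <- grade_criteria()
  expect_equal(classify_index(2.0, crit$rdhp), 1L)
  expect_equal(classify_index(2.6, crit$rlds), 3L)
  expect_equal(classify_index(1.5, crit$rdhp), 1L)   # boundary: [lo, hi)
  expect_equal(classify_index(1.5, crit$rlds), 2L)
  expect_equal(classify_index(2.5, crit$rlds), 3L)
  expect_true(is.na(classify_index(2.5, crit$rdhp))) # above the RDHP top
  expect_equal(classify_index(0.2, crit$rdhp), 3L)
})

test_that("invalid criteria are rejected", {
  expect_error(
    grade_criteria(rdhp = list(`1` = c(1.4, 2.5), `2` = c(1.0, 1.5),
                               `3` = c(0, 1.0))),
    class = "mushgrade_invalid_criteria"
  )
  expect_error(
    grade_criteria(rlds = list(`1` = c(0, 1.5), `2` = c(1.5, 2.5),
                               `3` = c(2.5, 3.5))),
    class = "mushgrade_invalid_criteria"
  )
  expect_error(
    grade_criteria(rdhp = list(`1` = c(1.5, 2.5), `2` = c(1.0, 1.5),
                               `3` = c(0.2, 1.0))),
    class = "mushgrade_invalid_criteria"
  )
})

test_that("grade assignment lets RLDS prevail on every conflict", {
  g <- assign_grade(2.0, 1.0)
  expect_equal(g$grade, 1L)
  expect_false(g$conflict)

  g2 <- assign_grade(2.0, 3.0)
  expect_equal(g2$grade, 3L)
  expect_true(g2$conflict)

  g3 <- assign_grade(0.5, 2.0)      # RDHP says 3, RLDS says 2
  expect_equal(g3$grade, 2L)
  expect_true(g3$conflict)

  g4 <- assign_grade(3.0, 1.0)      # RDHP none -> automatic conflict
  expect_true(is.na(g4$rdhp_grade))
  expect_equal(g4$grade, 1L)
  expect_true(g4$conflict)
})

test_that("every positive ratio pair gets exactly one grade and RLDS dominates", {
  set.seed(1)
  n <- 10000
  rdhp <- exp(runif(n, log(0.05), log(20)))
  rlds <- exp(runif(n, log(0.05), log(20)))
  g <- assign_grade(rdhp, rlds)
  expect_true(all(g$grade %in% 1:3))                 # totality
  expect_true(all(!is.na(g$rlds_grade)))
  disagree <- is.na(g$rdhp_grade) | g$rdhp_grade != g$rlds_grade
  expect_identical(g$conflict, disagree)
  expect_true(all(g$grade[disagree] == g$rlds_grade[disagree]))
  expect_true(all(g$grade[!disagree] == g$rdhp_grade[!disagree]))
})

test_that("criteria survive a YAML config round trip with identical decisions", {
  crit <- grade_criteria()
  cfg <- pipeline_config(criteria = crit)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, tf)
  crit2 <- read_pipeline_config(tf)$criteria

  grid <- expand.grid(
    rdhp = seq(0.05, 5, length.out = 100),
    rlds = seq(0.05, 5, length.out = 100)
  )
  g1 <- assign_grade(grid$rdhp, grid$rlds, crit)
  g2 <- assign_grade(grid$rdhp, grid$rlds, crit2)
  expect_identical(g1, g2)
})

test_that("broken specimens are detected with the right reason", {
  intact <- demo_mask()
  expect_false(detect_broken(intact)$broken)

  no_cap <- render_mushroom(fixture_spec(
    D1 = 60, H = 30, L = 40, D2 = 20, broken_mode = "no_cap",
    canvas = c(192, 192)
  ))$mask
  b <- detect_broken(no_cap)
  expect_true(b$broken)
  expect_equal(b$reason, "cap absent")

  no_stalk <- render_mushroom(fixture_spec(
    D1 = 60, H = 30, L = 40, D2 = 20, broken_mode = "no_stalk",
    canvas = c(192, 192)
  ))$mask
  expect_equal(detect_broken(no_stalk)$reason, "stalk absent")

  # cap split into two comparable fragments
  m <- matrix(0L, 80, 80)
  m[10:29, 10:35] <- 1L   # 45-ish %
  m[10:29, 40:69] <- 1L   # 55-ish %
  m[30:60, 35:44] <- 2L
  b2 <- detect_broken(label_mask(m))
  expect_true(b2$broken)
  expect_equal(b2$reason, "cap fragmented")

  # speckle below the fragment threshold is not "broken"
  m2 <- matrix(0L, 80, 80)
  m2[10:29, 10:49] <- 1L
  m2[30:60, 25:34] <- 2L
  m2[70, 70] <- 1L        # 1 px speck, far below 10%
  expect_false(detect_broken(label_mask(m2))$broken)
})
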