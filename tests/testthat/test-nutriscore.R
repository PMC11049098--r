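test_that("negative-nutrient points follow the strict threshold bands", {
  expect_equal(unlist(negative_points(0, 0, 0, 0)),
               c(energy_pts = 0, sugars_pts = 0, sfa_pts = 0, sodium_pts = 0))
  p <- negative_points(1500, 20, 5, 400)
  expect_equal(unlist(p),
               c(energy_pts = 4, sugars_pts = 4, sfa_pts = 4, sodium_pts = 4))
  expect_equal(negative_points(4000, 0, 0, 0)$energy_pts, 10L)
  # thresholds are strict: a value exactly on a threshold stays below
  expect_equal(negative_points(335, 4.5, 1, 90)$energy_pts, 0L)
  expect_equal(negative_points(335.1, 4.6, 1.1, 90.1)$energy_pts, 1L)
})

test_that("positive-nutrient points and zero-imputation for missing values", {
  p <- positive_points(8, 2, 0)
  expect_equal(unlist(p), c(protein_pts = 4, fiber_pts = 2, fv_pts = 0))
  expect_equal(positive_points(0, 0, 90)$fv_pts, 5L)
  expect_equal(unlist(positive_points(NA, NA, NA)),
               c(protein_pts = 0, fiber_pts = 0, fv_pts = 0))
  # FV bands are coarse: 0/1/2/5
  expect_equal(positive_points(0, 0, c(30, 50, 70, 90))$fv_pts,
               c(0L, 1L, 2L, 5L))
})

test_that("the score is the negative total minus the positive total", {
  pts <- function(e, s, f, na, p, fi, fv) {
    tibble::tibble(energy_pts = e, sugars_pts = s, sfa_pts = f,
                   sodium_pts = na, protein_pts = p, fiber_pts = fi,
                   fv_pts = fv)
  }
  expect_equal(fsam_nps(pts(0, 0, 0, 0, 0, 0, 0)), 0L)
  expect_equal(fsam_nps(pts(4, 4, 4, 4, 4, 2, 0)), 10L)
  expect_equal(fsam_nps(pts(10, 10, 10, 10, 5, 5, 5)), 25L)
  # full model: protein dropped when negatives reach 11 without max FV
  expect_equal(fsam_nps(pts(5, 5, 1, 0, 5, 0, 0), preset = "fsam2017_full"),
               11L)
  expect_equal(fsam_nps(pts(5, 5, 1, 0, 5, 0, 5), preset = "fsam2017_full"),
               1L)
  expect_equal(fsam_nps(pts(5, 5, 1, 0, 5, 0, 0), preset = "fsam2017_full",
                        is_cheese = TRUE), 6L)
})

test_that("grade bands match the published cut points", {
  expect_equal(as.character(assign_grade(-5, "solid")), "A")
  expect_equal(as.character(assign_grade(0, "solid")), "B")
  expect_equal(as.character(assign_grade(2, "beverage")), "C")
  expect_equal(as.character(assign_grade(19, "solid")), "E")
  expect_equal(as.character(assign_grade(c(-15, 30), "water")), c("A", "A"))
  expect_equal(as.character(assign_grade(c(-15, 1, 6, 10), "beverage")),
               c("B", "B", "D", "E"))
  expect_error(assign_grade(41, "solid"), "range")
})

test_that("grade bands partition the whole score range for every state", {
  for (state in c("solid", "beverage", "water")) {
    g <- assign_grade(-15:40, state)
    expect_false(any(is.na(g)))
    # contiguous: each grade occupies one unbroken block of scores
    expect_equal(g, sort(g))
  }
  # beverages never reach A; waters are always A
  expect_false(any(assign_grade(-15:40, "beverage") == "A"))
  expect_true(all(assign_grade(-15:40, "water") == "A"))
})

test_that("records missing a negative nutrient are excluded, missing positives imputed", {
  foods <- make_food_table(c("a", "b", "c"))
  foods$sodium_mg[1] <- NA
  foods$fiber_g[2] <- NA
  res <- score_table(foods)
  expect_equal(res$status,
               c("excluded_missing_negative", "scored", "scored"))
  expect_true(is.na(res$fsam_nps[1]))
  expect_true(is.na(res$grade[1]))
  expect_setequal(res$imputed_positives[[2]], c("fiber_g", "fv_percent"))
  expect_setequal(res$imputed_positives[[3]], "fv_percent")
})

test_that("every scored record stays within [-15, 40] and responds monotonically", {
  n <- 400
  panels <- random_panels(n, seed = 42)
  s0 <- score_panel(panels)
  expect_true(all(s0 >= -15 & s0 <= 40))

  withr::with_seed(43, {
    for (v in c("energy_kj", "sugars_g", "sfa_g", "sodium_mg")) {
      up <- panels
      up[[v]] <- up[[v]] * runif(n, 1, 2) + 1
      expect_true(all(score_panel(up) >= s0), info = v)
    }
    for (v in c("protein_g", "fiber_g")) {
      up <- panels
      up[[v]] <- up[[v]] * runif(n, 1, 2) + 0.5
      expect_true(all(score_panel(up) <= s0), info = v)
    }
    up <- panels
    up$fv_percent <- pmin(100, up$fv_percent + runif(n, 0, 50))
    expect_true(all(score_panel(up) <= s0), info = "fv_percent")
  })
})

test_that("full-model beverages use the stricter energy and sugar scales", {
  # 200 kJ, 8 g sugars: trivial for a solid, substantial for a beverage
  solid <- negative_points(200, 8, 0, 0, preset = "fsam2017_full",
                           physical_state = "solid")
  bev <- negative_points(200, 8, 0, 0, preset = "fsam2017_full",
                         physical_state = "beverage")
  expect_equal(unlist(solid[c("energy_pts", "sugars_pts")]),
               c(energy_pts = 0, sugars_pts = 1))
  expect_equal(unlist(bev[c("energy_pts", "sugars_pts")]),
               c(energy_pts = 7, sugars_pts = 6))
  # the paper preset applies food scales everywhere
  paper_bev <- negative_points(200, 8, 0, 0, preset = "paper",
                               physical_state = "beverage")
  expect_equal(unlist(paper_bev), unlist(solid))
})
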