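test_that("densities divide pooled intake by energy in units of 1000 kcal", {
  # 2000 kcal of filler-like food plus 320 g of a raw vegetable
  db <- food_database(rbind(
    food_row("veg", "VO010", energy = 0),  # pure component, no energy
    food_row("fuel", "X", energy = 400),
    food_row("sugar", "X", energy = 400, sugars = 100)
  ))
  intake <- intake_table(data.frame(
    subject_id = "s1", day = 1,
    food_id = c("veg", "fuel", "sugar"),
    grams = c(320, 467.5, 32.5)
  ))
  d <- component_densities(intake, db)
  expect_equal(d$energy_kcal, 2000)
  expect_equal(d$components[["total_vegetables"]], 160)
  # 32.5 g added sugars at 4 kcal/g out of 2000 kcal = 6.5 % of energy
  expect_equal(d$components[["added_sugars"]], 6.5)
})

test_that("densities are invariant to scaling every consumed amount", {
  db <- make_food_db(seed = 3)
  cohort <- make_cohort(cohort_spec(n_subjects = 1, seed = 9), db)
  intake <- cohort$intake
  d1 <- component_densities(intake, db)
  intake2 <- intake
  intake2$grams <- intake2$grams * 2.7
  d2 <- component_densities(intake2, db)
  expect_equal(d1$components, d2$components, tolerance = 1e-12)
})

test_that("multi-day records pool intake and energy", {
  db <- make_food_db(seed = 3)
  co2 <- make_cohort(cohort_spec(n_subjects = 1, seed = 9, days = 2), db)
  d <- component_densities(co2$intake, db)
  gt <- co2$ground_truth
  expect_equal(unname(d$components[mhei_component_names()]),
               unname(unlist(gt[1, mhei_component_names()])),
               tolerance = 1e-9)
})

test_that("zero-energy intake is flagged and scores zero", {
  db <- tiny_db()
  intake <- intake_table(data.frame(subject_id = "s", day = 1,
                                    food_id = "water", grams = 500))
  d <- component_densities(intake, db)
  expect_true(d$zero_energy)
  sc <- total_score(d)
  expect_equal(sc$total, 0)
  expect_true(all(sc$components == 0))
})

test_that("adequacy scoring is linear up to the standard then capped", {
  expect_equal(score_adequacy(141, 141, 5), 5)
  expect_equal(score_adequacy(0, 141, 5), 0)
  expect_equal(score_adequacy(70.5, 141, 5), 2.5)
  expect_equal(score_adequacy(500, 141, 5), 5)
})

test_that("moderation scoring is a descending ramp between its standards", {
  expect_equal(score_moderation(32, 32, 76, 10), 10)
  expect_equal(score_moderation(76, 32, 76, 10), 0)
  expect_equal(score_moderation(54, 32, 76, 10), 5)
  expect_equal(score_moderation(10, 32, 76, 10), 10)
  expect_equal(score_moderation(100, 32, 76, 10), 0)
})

test_that("fatty-acid scoring handles thresholds and degenerate diets", {
  expect_equal(score_fatty_acids(2.5), 10)
  expect_equal(score_fatty_acids(1.2), 0)
  expect_equal(score_fatty_acids(1.85), 5)
  expect_equal(score_fatty_acids(Inf), 10)   # unsaturated fat, no SFA
  expect_equal(score_fatty_acids(NaN), 0)    # no fat at all
})

test_that("a profile at every metric standard scores exactly 100", {
  for (std in list(mhei2015_standards(), hei2015_standards())) {
    sc <- total_score(densities_at_max(std), std)
    expect_equal(sc$total, 100)
    expect_equal(unname(sc$components), std$table$max_points)
  }
})

test_that("component failure is additive in the total", {
  std <- mhei2015_standards()
  d <- densities_at_max(std)
  d$components[["total_fruits"]] <- 0  # one 5-point component to zero
  expect_equal(total_score(d, std)$total, 95)
})

test_that("scores are bounded and monotone in density", {
  std <- mhei2015_standards()
  set.seed(123)
  for (i in 1:25) {
    tab <- std$table
    vals <- stats::runif(13, 0, 3) * tab$standard_for_max
    names(vals) <- tab$component
    sc <- total_score(as_component_densities(vals), std)
    expect_true(all(sc$components >= 0 & sc$components <= tab$max_points))
    expect_gte(sc$total, 0)
    expect_lte(sc$total, 100)
  }
  # monotone: adequacy nondecreasing, moderation nonincreasing
  grid <- seq(0, 200, by = 10)
  adeq <- vapply(grid, score_adequacy, numeric(1),
                 standard_for_max = 141, max_points = 5)
  expect_true(all(diff(adeq) >= 0))
  mod <- vapply(grid, score_moderation, numeric(1),
                standard_for_max = 32, standard_for_min = 76,
                max_points = 10)
  expect_true(all(diff(mod) <= 0))
})

test_that("percent of standard caps at 100 and mirrors moderation scores", {
  std <- mhei2015_standards()
  at_max <- densities_at_max(std)
  expect_true(all(percent_of_standard(at_max, std) == 100))
  zero <- as_component_densities(
    stats::setNames(rep(0, 13), mhei_component_names())
  )
  pct <- percent_of_standard(zero, std)
  reg <- mhei_components()
  expect_true(all(pct[reg$component[reg$kind == "moderation"]] == 100))
  expect_true(all(pct[reg$component[reg$kind == "adequacy"]] == 0))
  half <- zero
  half$components[["total_fruits"]] <- 141 / 2
  expect_equal(percent_of_standard(half, std)[["total_fruits"]], 50)
})

test_that("score_cohort returns one row per subject with all components", {
  db <- make_food_db(seed = 3)
  cohort <- make_cohort(cohort_spec(n_subjects = 4, seed = 10), db)
  sc <- score_cohort(cohort$intake, db)
  expect_identical(nrow(sc), 4L)
  expect_true(all(mhei_component_names() %in% names(sc)))
  expect_equal(rowSums(sc[mhei_component_names()]), sc$total)
  expect_identical(unique(sc$standards_id), "mhei2015")
})

test_that("metric and imperial scorers share structure, only standards differ", {
  # a density vector scaled component-wise from metric to imperial units
  m <- mhei2015_standards()$table
  h <- hei2015_standards()$table
  set.seed(99)
  frac <- stats::setNames(stats::runif(13, 0, 1.4), m$component)
  dm <- as_component_densities(stats::setNames(frac * m$standard_for_max,
                                               m$component))
  dh <- as_component_densities(stats::setNames(frac * h$standard_for_max,
                                               h$component))
  sm <- total_score(dm, mhei2015_standards())
  sh <- total_score(dh, hei2015_standards())
  # adequacy + refined-grains fractions translate exactly; nutrient
  # moderation ramps have identical thresholds anyway
  adeq <- m$component[mhei_components()$kind == "adequacy"]
  expect_equal(sm$components[adeq], sh$components[adeq], tolerance = 1e-12)
  expect_equal(sm$components[["refined_grains"]] > 0,
               sh$components[["refined_grains"]] > 0)
})
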