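test_that("raw foods have factor one and processed foods the energy-density ratio", {
  db <- tiny_db()
  raw <- db_record(db, "apple_raw")
  dried <- db_record(db, "apple_dried")
  expect_equal(processing_factor(raw, raw)$factor, 1)
  expect_identical(processing_factor(raw, raw)$basis, "raw_unity")
  f <- processing_factor(dried, raw)
  expect_equal(f$factor, 290 / 58)  # = 5
  expect_identical(f$basis, "energy_density_ratio")
})

test_that("legumes use the cooked form as the unity reference", {
  db <- tiny_db()
  cooked <- db_record(db, "lentils_cooked")
  dry <- db_record(db, "lentils_dry")
  expect_equal(processing_factor(cooked, cooked)$factor, 1)
  f <- processing_factor(dry, cooked)
  expect_equal(f$factor, 345 / 115)
  expect_gt(f$factor, 1)
})

test_that("a zero-energy reference makes the factor undefined", {
  zero_raw <- food_row("zero", "FO020", energy = 0)
  proc <- food_row("proc", "FO021", energy = 100)
  db <- food_database(rbind(zero_raw, proc))
  expect_error(processing_factor(db_record(db, "proc"), db_record(db, "zero")),
               class = "mhei_factor_undefined_error")
})

test_that("gram equivalents credit amount x factor to the mapped components", {
  db <- tiny_db()
  geq <- gram_equivalents(150, db_record(db, "strawberry"), db)
  expect_equal(geq[["total_fruits"]], 150)
  expect_equal(geq[["whole_fruits"]], 150)
  expect_equal(sum(geq), 300)
  expect_equal(sum(gram_equivalents(0, db_record(db, "strawberry"), db)), 0)
  # processed: amount x factor
  geq_dried <- gram_equivalents(100, db_record(db, "apple_dried"), db)
  expect_equal(geq_dried[["total_fruits"]], 500)
})

test_that("a processed food with no reference falls back to factor 1 with a warning", {
  db <- food_database(food_row("orphan", "GR011", energy = 140))
  expect_warning(
    geq <- gram_equivalents(100, db_record(db, "orphan"), db),
    "factor 1"
  )
  expect_equal(geq[["refined_grains"]], 100)
})

test_that("equivalents are linear in the consumed amount", {
  db <- make_food_db(seed = 11)
  set.seed(42)
  ids <- sample(db$records$food_id, 15)
  for (id in ids) {
    rec <- db_record(db, id)
    a <- stats::runif(1, 0, 300)
    b <- stats::runif(1, 0, 300)
    both <- suppressWarnings(food_contributions(a + b, rec, db))
    parts <- add_contributions(
      suppressWarnings(food_contributions(a, rec, db)),
      suppressWarnings(food_contributions(b, rec, db))
    )
    expect_equal(both$components, parts$components, tolerance = 1e-12)
    expect_equal(both$energy_kcal, parts$energy_kcal, tolerance = 1e-12)
  }
})

test_that("nutrient equivalents use protein and calcium content directly", {
  db <- tiny_db()
  ne <- nutrient_equivalents(100, db_record(db, "cod"))
  expect_equal(ne[["total_protein_foods"]], 20)
  expect_equal(ne[["seafood_plant_proteins"]], 20)
  milk <- nutrient_equivalents(250, db_record(db, "milk"))
  expect_equal(milk[["dairy"]], 300)
  zero_p <- nutrient_equivalents(100, food_row("gelatin", "PM", protein = 0))
  expect_equal(sum(zero_p), 0)
  expect_error(nutrient_equivalents(100, db_record(db, "apple_raw")),
               class = "mhei_equivalents_type_error")
})

test_that("ingredient mass fractions come from cup-equivalent quotients", {
  expect_equal(ingredient_fraction_from_cup_equivalents(0.03, 0.69),
               0.03 / 0.69)
  expect_equal(ingredient_fraction_from_cup_equivalents(0, 0.69), 0)
  expect_equal(ingredient_fraction_from_cup_equivalents(0.69, 0.69), 1)
  expect_error(ingredient_fraction_from_cup_equivalents(0.1, 0),
               class = "mhei_fraction_undefined_error")
})

test_that("the strawberry-yogurt decomposition yields 4.3 g berry equivalents", {
  db <- tiny_db()
  frac <- ingredient_fraction_from_cup_equivalents(0.03, 0.69)
  rec <- recipe_table(data.frame(menu_id = "strawberry_yogurt",
                                 food_id = "strawberry",
                                 mass_fraction = frac))
  prof <- menu_equivalents(rec, "strawberry_yogurt", db)
  expect_equal(round(prof$components[["whole_fruits"]], 1), 4.3)
  expect_equal(round(prof$components[["total_fruits"]], 1), 4.3)
})

test_that("a single-ingredient recipe with fraction 1 matches the food's own profile", {
  db <- make_food_db(seed = 5)
  set.seed(7)
  singles <- db$records$food_id[db$records$processing_state %in% c(0L, NA)]
  for (id in sample(singles, 8)) {
    rec <- recipe_table(data.frame(menu_id = "m", food_id = id,
                                   mass_fraction = 1))
    menu <- menu_equivalents(rec, "m", db)
    own <- food_contributions(100, db_record(db, id), db)
    expect_equal(menu$components, own$components, tolerance = 1e-12)
    expect_equal(menu$energy_kcal, own$energy_kcal, tolerance = 1e-12)
  }
})

test_that("an empty recipe profiles to all-zero, a dangling ingredient errors", {
  db <- tiny_db()
  empty <- recipe_table(data.frame(menu_id = character(0),
                                   food_id = character(0),
                                   mass_fraction = numeric(0)))
  prof <- menu_equivalents(empty, "ghost", db)
  expect_equal(sum(prof$components), 0)
  expect_equal(prof$energy_kcal, 0)
  dangling <- recipe_table(data.frame(menu_id = "m", food_id = "nope",
                                      mass_fraction = 0.5))
  err <- expect_error(menu_equivalents(dangling, "m", db),
                      class = "mhei_recipe_dangling_error")
  expect_match(conditionMessage(err), "m")
  expect_match(conditionMessage(err), "nope")
})

test_that("recipe mass fractions must sum to at most one", {
  expect_error(
    recipe_table(data.frame(menu_id = "m", food_id = c("a", "b"),
                            mass_fraction = c(0.7, 0.5))),
    class = "mhei_recipe_fraction_error"
  )
})

test_that("the 50/50 lettuce recipe reproduces the published blend and flags the declared profile", {
  # declared menu-level profile vs the profile recomputed from its recipe
  declared <- c(dark_green = 0.00, other_veg = 0.91)
  iceberg <- c(dark_green = 0.00, other_veg = 0.91)
  green_leaf <- c(dark_green = 1.43, other_veg = 0.00)
  recomputed <- 0.5 * iceberg + 0.5 * green_leaf
  expect_equal(round(recomputed[["dark_green"]], 2), 0.72)
  expect_equal(round(recomputed[["other_veg"]], 2), 0.46)
  report <- detect_recipe_discrepancies(declared, recomputed)
  expect_setequal(report$component, c("dark_green", "other_veg"))
})

test_that("discrepancy detection is strict and tolerance-bounded", {
  a <- c(x = 1.00, y = 2.00)
  expect_identical(nrow(detect_recipe_discrepancies(a, a)), 0L)
  at_tol <- c(x = 1.005, y = 2.00)
  expect_identical(nrow(detect_recipe_discrepancies(a, at_tol)), 0L)
  over <- c(x = 1.0051, y = 2.00)
  expect_identical(detect_recipe_discrepancies(a, over)$component, "x")
})

test_that("recipes reconstruct from paired cup-equivalent tables", {
  df <- data.frame(menu_id = "yog", ingredient_food_id = "strawberry",
                   component = "whole_fruits",
                   menu_cupeq_per_100g = 0.03,
                   ingredient_cupeq_per_100g = 0.69)
  rec <- recipes_from_cup_equivalents(df)
  expect_s3_class(rec, "recipe_table")
  expect_equal(rec$mass_fraction, 0.03 / 0.69)
})

test_that("the equivalents table covers foods and menus per 100 g", {
  db <- tiny_db()
  rec <- recipe_table(data.frame(menu_id = "m", food_id = "strawberry",
                                 mass_fraction = 0.5))
  tab <- equivalents_table(db, rec)
  expect_identical(nrow(tab), nrow(db$records) + 1L)
  m <- tab[tab$id == "m", ]
  expect_equal(m$total_fruits, 50)
  expect_equal(m$energy_kcal, 16)
})
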