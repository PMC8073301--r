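test_that("CACFP rule table worked examples classify as specified", {
  # age 10: 8 fl oz unflavored skim, 0.6 oz eq fruit, 1.0 oz eq grain
  d <- make_breakfast(age_years = 10L, milk_oz = 8, milk_fat = "skim",
                      fruit_oz = 0.6, grain_oz = 1.0)
  expect_true(classify_cacfp(d)$cacfp_compliant)
  # age 4: 6 fl oz unflavored 1%, 0.5 / 0.5 oz eq
  d <- make_breakfast(age_years = 4L, milk_oz = 6, milk_fat = "lowfat_1pct",
                      fruit_oz = 0.5, grain_oz = 0.5)
  expect_true(classify_cacfp(d)$cacfp_compliant)
  # whole milk only compliant at age 1
  d <- make_breakfast(age_years = 10L, milk_oz = 8, milk_fat = "whole",
                      fruit_oz = 0.6, grain_oz = 1.0)
  expect_false(classify_cacfp(d)$cacfp_compliant)
  d <- make_breakfast(age_years = 1L, milk_oz = 4, milk_fat = "whole",
                      fruit_oz = 0.3, grain_oz = 0.5)
  expect_true(classify_cacfp(d)$cacfp_compliant)
  # flavored skim allowed only at ages 6-18
  d <- make_breakfast(age_years = 4L, milk_oz = 6, milk_fat = "skim",
                      milk_flavored = TRUE, fruit_oz = 0.5, grain_oz = 0.5)
  expect_false(classify_cacfp(d)$cacfp_compliant)
  d <- make_breakfast(age_years = 12L, milk_oz = 8, milk_fat = "skim",
                      milk_flavored = TRUE, fruit_oz = 0.6, grain_oz = 1.0)
  expect_true(classify_cacfp(d)$cacfp_compliant)
  # 2% milk non-compliant at every age
  for (a in c(1L, 2L, 4L, 10L)) {
    d <- make_breakfast(age_years = a, milk_oz = 8, milk_fat = "reduced_2pct",
                        fruit_oz = 1, grain_oz = 2)
    expect_false(classify_cacfp(d)$cacfp_compliant)
  }
  # no breakfast occasion -> non-compliant
  d <- make_item(occasion_code = "other")
  expect_false(classify_cacfp(d)$cacfp_compliant)
})

test_that("amounts sum across same-category items within the breakfast", {
  d <- make_recalls(
    make_item(age_years = 10L, food_code = "m1", category = "milk", amount = 5,
              milk_fat_level = "skim", milk_flavored = FALSE),
    make_item(age_years = 10L, food_code = "m2", category = "milk", amount = 3,
              milk_fat_level = "skim", milk_flavored = FALSE),
    make_item(age_years = 10L, food_code = "f", category = "fruit_vegetable",
              amount = 0.6),
    make_item(age_years = 10L, food_code = "g", category = "grain", amount = 1)
  )
  expect_true(classify_cacfp(d)$cacfp_compliant)
  # disallowed milk rows do not count toward the minimum
  d$milk_fat_level[d$food_code == "m2"] <- "whole"
  expect_false(classify_cacfp(d)$cacfp_compliant)
})

test_that("compliance is monotone in component amounts", {
  set.seed(42)
  for (i in 1:60) {
    age <- sample(1:18, 1)
    fat <- sample(c("whole", "reduced_2pct", "lowfat_1pct", "skim"), 1)
    base <- c(milk = runif(1, 0, 10), fruit = runif(1, 0, 1.5),
              grain = runif(1, 0, 2))
    d0 <- make_breakfast(age_years = age, milk_oz = base["milk"], milk_fat = fat,
                         fruit_oz = base["fruit"], grain_oz = base["grain"])
    d1 <- make_breakfast(age_years = age, milk_oz = base["milk"] + runif(1, 0, 4),
                         milk_fat = fat, fruit_oz = base["fruit"] + runif(1, 0, 1),
                         grain_oz = base["grain"] + runif(1, 0, 1))
    if (classify_cacfp(d0)$cacfp_compliant) {
      expect_true(classify_cacfp(d1)$cacfp_compliant)
    }
  }
})

test_that("egg detection fires only on true egg items at breakfast", {
  egg_day <- make_recalls(
    make_item(food_code = "boiled_egg", category = "egg"),
    make_item(food_code = "toast", category = "grain", amount = 1)
  )
  expect_true(detect_egg_at_breakfast(egg_day)$egg_at_breakfast)
  for (cat in c("egg_substitute", "other_poultry_egg", "egg_mixed_dish")) {
    d <- make_item(food_code = cat, category = cat)
    expect_false(detect_egg_at_breakfast(d)$egg_at_breakfast)
  }
  # egg outside breakfast does not count; no breakfast at all is FALSE
  d <- make_item(occasion_code = "other", category = "egg")
  expect_false(detect_egg_at_breakfast(d)$egg_at_breakfast)
  # invariant to non-egg items added alongside
  more <- make_recalls(egg_day,
                       make_item(food_code = "milk9", category = "milk", amount = 4))
  expect_true(detect_egg_at_breakfast(more)$egg_at_breakfast)
})

test_that("person_status aggregates days per the any-day / day-1 rules", {
  # eggs on day 2 only -> egg consumer
  d <- make_recalls(
    make_item(day_index = 1L, food_code = "toast", category = "grain"),
    make_item(day_index = 2L, food_code = "egg", category = "egg")
  )
  st <- person_status(d)
  expect_true(st$egg_at_breakfast)
  expect_true(st$has_breakfast)

  # compliant day-1 breakfast -> cacfp_compliant
  st <- person_status(make_recalls(
    make_breakfast(age_years = 10L),
    make_item(day_index = 2L, occasion_code = "other", food_code = "x")
  ))
  expect_true(st$cacfp_compliant)

  # compliant day-2 breakfast does not qualify (day-1 rule)
  st <- person_status(make_recalls(
    make_item(day_index = 1L, occasion_code = "other", food_code = "x"),
    make_breakfast(age_years = 10L, day_index = 2L)
  ))
  expect_false(st$cacfp_compliant)
  expect_false(st$has_breakfast)

  # breakfast skipper on both days -> all FALSE
  st <- person_status(make_recalls(
    make_item(day_index = 1L, occasion_code = "other", food_code = "x"),
    make_item(day_index = 2L, occasion_code = "other", food_code = "y")
  ))
  expect_false(any(unlist(st[, -1])))

  expect_error(person_status(make_item()[0, ]), class = "dietshift_validation")
})
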