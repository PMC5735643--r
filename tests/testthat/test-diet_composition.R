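# Printed diet-composition surface of the two-piranha survey: FO and VF
# columns per species x season, used across diet/niche tests.
table1 <- list(
  gibbus_flood = list(
    fo = c(fish = 65.517, crustacean = 10.345, insect = 20.689,
           plant = 3.448, microcrustacean = 3.448),
    vf = c(fish = 22.014, crustacean = 2.510, insect = 1.089,
           plant = 0.138, microcrustacean = 0.055),
    ifi = c(fish = 0.9671, crustacean = 0.0174, insect = 0.0151,
            plant = 0.0003, microcrustacean = 0.0001)),
  gibbus_dry = list(
    fo = c(fish = 96.429, crustacean = 10.714, insect = 14.286,
           plant = 25.000, microcrustacean = 3.571),
    vf = c(fish = 37.118, crustacean = 3.857, insect = 0.843,
           plant = 4.007, microcrustacean = 0.075),
    ifi = c(fish = 0.9588, crustacean = 0.0111, insect = 0.0032,
            plant = 0.0268, microcrustacean = 0.0001)),
  rhombeus_flood = list(
    fo = c(fish = 80, crustacean = 20, insect = 20, microcrustacean = 20),
    vf = c(fish = 0.906, crustacean = 0.089, insect = 0.004,
           microcrustacean = 0.001),
    ifi = c(fish = 0.9747, crustacean = 0.0239, insect = 0.0011,
            microcrustacean = 0.0003)),
  rhombeus_dry = list(
    fo = c(fish = 100),
    vf = c(fish = 1.000),
    ifi = c(fish = 1.000)))

test_that("frequency of occurrence counts stomachs, not item rows", {
  sp <- tiny_specimens()
  it <- tiny_items(sp)
  fo <- frequency_of_occurrence(it, sp, group_key("S. gibbus"))
  # 3 content stomachs; fish in a1 and a2, insect in a1, plant in a3
  expect_equal(fo[["fish"]], 100 * 2 / 3)
  expect_equal(fo[["insect"]], 100 * 1 / 3)
  expect_equal(fo[["plant"]], 100 * 1 / 3)
  expect_equal(fo[["crustacean"]], 0)
  # duplicate item rows of one category in one stomach do not change FO
  it2 <- rbind(it, data.frame(specimen_id = "a1", category = "fish",
                              volume = 0.2))
  fo2 <- frequency_of_occurrence(it2, sp, group_key("S. gibbus"))
  expect_equal(fo2[["fish"]], fo[["fish"]])
  # the 19-of-29 configuration recovered from the printed flood column
  expect_equal(19 * 100 / 29, 65.517, tolerance = 1e-5)
  expect_error(frequency_of_occurrence(it, sp, group_key("S. rhombeus", "dry")),
               "no content-bearing stomachs")
})

test_that("volumetric frequency pools volumes across the group's stomachs", {
  sp <- tiny_specimens()
  it <- tiny_items(sp)
  vf <- volumetric_frequency(it, sp, group_key("S. gibbus"))
  expect_equal(sum(vf), 100)
  expect_equal(vf[["fish"]], 100 * 5 / 6.5)
  vf_r <- volumetric_frequency(it, sp, group_key("S. rhombeus"))
  expect_equal(vf_r[["fish"]], 100 * 10 / 10.4)
  # single category present -> 100
  one <- data.frame(specimen_id = "b1", category = "fish", volume = 2)
  expect_equal(volumetric_frequency(one, sp,
                                    group_key("S. rhombeus"))[["fish"]], 100)
  # equal totals -> 50/50
  two <- data.frame(specimen_id = c("a1", "a2"),
                    category = c("fish", "insect"), volume = c(3, 3))
  vf2 <- volumetric_frequency(two, sp, group_key("S. gibbus"))
  expect_equal(unname(vf2[c("fish", "insect")]), c(50, 50))
  zero <- data.frame(specimen_id = "a1", category = "fish", volume = 0)
  expect_error(volumetric_frequency(zero, sp, group_key("S. gibbus")),
               "volumes are zero")
})

test_that("feeding importance reproduces the printed index from printed FO/VF", {
  for (block in table1) {
    ifi <- feeding_importance(block$fo, block$vf)
    expect_equal(sum(ifi), 1)
    expect_true(all(abs(ifi[names(block$ifi)] - block$ifi) <= 1e-4))
  }
  # scale invariance in the volumes
  b <- table1$gibbus_flood
  expect_equal(feeding_importance(b$fo, b$vf * 37.2),
               feeding_importance(b$fo, b$vf))
  # single nonzero category
  expect_equal(feeding_importance(c(a = 50, b = 0), c(a = 10, b = 0)),
               c(a = 1, b = 0))
  expect_error(feeding_importance(c(a = 1), c(b = 1)), "same category names")
})

test_that("diet_table assembles FO/VF/IF with a shared denominator", {
  sp <- tiny_specimens()
  it <- tiny_items(sp)
  tab <- diet_table(it, sp, group_key("S. gibbus"))
  expect_equal(tab$category, food_categories)
  expect_true(all(tab$N == 3))
  expect_equal(sum(tab$ifi), 1)
  expect_equal(sum(tab$vf_pct), 100)
  expect_equal(tab$fo_pct, 100 * tab$n / tab$N)
  # categories consumed by nobody are all-zero rows
  expect_equal(tab$fo_pct[tab$category == "other"], 0)
  expect_equal(tab$ifi[tab$category == "other"], 0)
  # one stomach, one item
  one <- validate_stomach_items(
    data.frame(specimen_id = "b1", category = "fish", volume = 2), sp)
  t1 <- diet_table(one, sp, group_key("S. rhombeus"))
  expect_equal(t1$fo_pct[t1$category == "fish"], 100)
  expect_equal(t1$vf_pct[t1$category == "fish"], 100)
  expect_equal(t1$ifi[t1$category == "fish"], 1)
})

test_that("removing an unused category leaves the other index values unchanged", {
  b <- table1$gibbus_flood
  fo6 <- c(b$fo, other = 0)
  vf6 <- c(b$vf, other = 0)
  ifi6 <- feeding_importance(fo6, vf6)
  ifi5 <- feeding_importance(b$fo, b$vf)
  expect_equal(ifi6[names(ifi5)], ifi5)
  expect_equal(ifi6[["other"]], 0)
})

test_that("repletion profiles count classes and their relative frequencies", {
  sp <- tiny_specimens()
  pr <- repletion_profile(sp, group_key("S. rhombeus"))
  expect_equal(unname(pr$counts), c(1, 0, 1))
  expect_equal(unname(pr$rel_freq), c(0.5, 0, 0.5))
  expect_equal(sum(pr$rel_freq), 1)
  all_void <- sp[sp$specimen_id == "b2", ]
  pv <- repletion_profile(all_void, group_key("S. rhombeus"))
  expect_equal(unname(pv$rel_freq), c(1, 0, 0))
  expect_error(repletion_profile(sp[0, ], group_key()), "empty group")
  by_iv <- repletion_by_interval(sp, group_key("S. gibbus"))
  expect_length(by_iv, 8)
  expect_named(by_iv, net_checks)
})
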