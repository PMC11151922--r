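test_that("duplicate keys are summed and reported, not rejected", {
  df <- flowers_df(list(2020, 1, "A", 1, "cistus", 3),
                   list(2020, 1, "A", 1, "cistus", 4),
                   list(2020, 1, "A", 2, "lavandula", 5))
  expect_message(tab <- as_survey_table(df, "flowers"), "1 duplicate")
  expect_s3_class(tab, "survey_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$count[tab$plant == "cistus"], 7)
})

test_that("schema and validation errors name the problem", {
  df <- flowers_df(list(2020, 1, "A", 1, "cistus", 3))
  expect_error(as_survey_table(df[setdiff(names(df), "count")], "flowers"),
               "missing required column.*count")
  df_neg <- df; df_neg$count <- -1
  expect_error(as_survey_table(df_neg, "flowers"), "negative count at row 1")

  fs <- data.frame(year = 2020, site = "A", plant = "cistus", individual = "i1",
                   flowers_marked = 10, fruits = 12)
  expect_error(as_survey_table(fs, "fruitset"), "fruits > flowers_marked at row 1")
  fs$fruits <- 5; fs$flowers_marked <- 0
  expect_error(as_survey_table(fs, "fruitset"), "flowers_marked must be >= 1")
})

test_that("a well-formed visits CSV round-trips through read_survey_table", {
  df <- data.frame(year = rep(c(2020, 2021), each = 3), round = 1:3,
                   site = "A", subplot = 1:6,
                   plant = "cistus", pollinator = c("apis", "bombus", "apis",
                                                    "bombus", "apis", "bombus"),
                   visits = 1:6)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  tab <- read_survey_table(path, "visits")
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$visits), sum(df$visits))
  expect_identical(survey_kind(tab), "visits")

  out <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(tab, out)
  expect_equal(nrow(read_survey_table(out, "visits")), 6)
})

test_that("build_tensor aggregates rounds/subplots and zero-fills absences", {
  df <- flowers_df(list(2020, 1, "A", 1, "cistus", 3),
                   list(2020, 2, "A", 2, "cistus", 4),
                   list(2021, 1, "A", 1, "lavandula", 5),
                   list(2020, 1, "B", 1, "cistus", 2),
                   list(2021, 1, "B", 1, "cistus", 6))
  tab <- as_survey_table(df, "flowers")
  tn <- build_tensor(tab, "flower_availability")
  expect_equal(dim(tn), c(2, 2, 2))
  expect_equal(tn["cistus", "A", "2020"], 7)       # rounds + subplots summed
  expect_equal(tn["cistus", "A", "2021"], 0)       # true zero for unseen year
  expect_equal(tn["lavandula", "B", "2020"], 0)    # unit universe is global
  expect_equal(tn["lavandula", "A", "2021"], 5)
  expect_equal(sum(tn), sum(df$count))             # conservation under sum

  # mean annualization divides by the global round universe (2 rounds here)
  tn_mean <- build_tensor(tab, "flower_availability", annualize = "mean")
  expect_equal(tn_mean["cistus", "A", "2020"], 7 / 2)

  # row order must not matter
  tn_perm <- build_tensor(as_survey_table(df[sample(nrow(df)), ], "flowers"),
                          "flower_availability")
  expect_equal(unclass(tn_perm), unclass(tn))

  expect_error(build_tensor(as_survey_table(df[df$year == 2020, ], "flowers"),
                            "flower_availability"),
               "temporal dimension < 2")
  expect_error(build_tensor(tab, "visitation_rate"), "needs a 'visits' table")
})

test_that("visits tensors: pollinator units sum over plants, pair units enumerate pairs", {
  df <- data.frame(year = rep(c(2020, 2021), each = 4), round = 1,
                   site = "A", subplot = 1,
                   plant = rep(c("p1", "p1", "p2", "p2"), 2),
                   pollinator = rep(c("x", "y"), 4),
                   visits = c(3, 1, 5, 2, 1, 1, 1, 1))
  tab <- as_survey_table(df, "visits")
  vis <- build_tensor(tab, "visitation_rate")
  expect_equal(dimnames(vis)$unit, c("x", "y"))
  expect_equal(vis["x", "A", "2020"], 8)            # 3 on p1 + 5 on p2

  inter <- build_tensor(tab, "interaction_frequency")
  expect_equal(dim(inter)[1], 4)                    # all 4 observed pairs
  expect_setequal(dimnames(inter)$unit, c("p1:x", "p1:y", "p2:x", "p2:y"))
  # collapsing pairs over plants reproduces the visitation tensor
  poll <- sub("^.*:", "", dimnames(inter)$unit)
  expect_equal(apply(unclass(inter), c(2, 3), function(s) tapply(s, poll, sum)),
               unclass(vis), ignore_attr = TRUE)
})

test_that("aggregate_fruitset: pooled vs individual-mean, bounds, missingness", {
  fs <- data.frame(year = rep(c(2020, 2021), each = 2), site = "A",
                   plant = "cistus", individual = paste0("i", 1:4),
                   flowers_marked = c(20, 5, 10, 10), fruits = c(10, 1, 4, 6))
  tab <- as_survey_table(fs, "fruitset")
  pooled <- aggregate_fruitset(tab)
  expect_equal(pooled["cistus", "A", "2020"], 11 / 25)   # 0.44
  ind <- aggregate_fruitset(tab, "individual_mean")
  expect_equal(ind["cistus", "A", "2020"], (0.5 + 0.2) / 2)

  one <- data.frame(year = c(2020, 2021), site = "A", plant = "cistus",
                    individual = "i1", flowers_marked = 10, fruits = c(10, 0))
  tn <- aggregate_fruitset(as_survey_table(one, "fruitset"))
  expect_equal(tn["cistus", "A", "2020"], 1)             # upper bound

  # an unmeasured plant-site-year is NA, never zero
  two_sp <- rbind(fs, data.frame(year = 2020, site = "A", plant = "halimium",
                                 individual = "j1", flowers_marked = 8, fruits = 2))
  tn2 <- aggregate_fruitset(as_survey_table(two_sp, "fruitset"))
  expect_true(is.na(tn2["halimium", "A", "2021"]))
  vals <- tn2[!is.na(tn2)]
  expect_true(all(vals >= 0 & vals <= 1))

  expect_error(aggregate_fruitset(as_survey_table(fs[0, ], "fruitset")), "empty")
})

test_that("as_tibble on a tensor is tidy and drops missing cells", {
  tb <- as_tibble(micro_tensor())
  expect_named(tb, c("unit", "patch", "time", "value"))
  expect_equal(nrow(tb), 12)
  expect_equal(sum(tb$value), sum(unclass(micro_tensor())))
})
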