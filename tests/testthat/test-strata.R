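test_that("CCM groups same-weekday days of a month into one stratum, sizes 4-5", {
  # the five Saturdays of November 2019 share <2019 : November : Saturday>
  sat <- as.Date(c("2019-11-02", "2019-11-09", "2019-11-16", "2019-11-23",
                   "2019-11-30"))
  year <- daily_series(as.Date("2019-01-01") + 0:364, rpois(365, 3),
                       rnorm(365), family = "poisson")
  ds <- assign_strata(year, stratum_scheme("CCM"))
  ids <- unique(ds$stratum[ds$date %in% sat])
  expect_length(ids, 1L)
  expect_identical(as.character(ids), "2019:11:Sat")
  # every full-month stratum holds the case day plus 3 or 4 controls
  expect_true(all(table(ds$stratum) %in% c(4L, 5L)))
})

test_that("CC2D pairs consecutive days within a year and gives 183 strata per 365-day year", {
  s <- daily_series(as.Date("2001-01-01") + 0:364, rnorm(365), rnorm(365))
  ds <- assign_strata(s, stratum_scheme("CC2D", "fixed365"))
  expect_identical(attr(ds, "n_strata"), 183L)
  by_day <- ds$stratum[order(ds$day)]
  expect_identical(by_day[1], by_day[2])    # days 1,2 share a stratum
  expect_false(by_day[2] == by_day[3])      # days 2,3 do not
  expect_true(all(table(ds$stratum) %in% 1:2))
  expect_equal(sum(table(ds$stratum) == 1L), 1L)  # the trailing day 365

  # ten 365-day years: 183 strata in each
  s10 <- daily_series(as.Date("2001-01-01") + 0:3649, rnorm(3650), rnorm(3650))
  ds10 <- assign_strata(s10, stratum_scheme("CC2D", "fixed365"))
  expect_identical(attr(ds10, "n_strata"), 1830L)
})

test_that("fixed365 year rule rejects incompatible spans unless permitted", {
  s <- daily_series(as.Date("2001-01-01") + 0:399, rnorm(400), rnorm(400))
  expect_error(assign_strata(s, stratum_scheme("CC2D", "fixed365")),
               "divisible by 365")
  ds <- assign_strata(s, stratum_scheme("CC2D", "fixed365", allow_partial_year = TRUE))
  expect_identical(attr(ds, "n_strata"), 183L + 18L)  # 35 trailing days -> 18 blocks
})

test_that("non-chained schemes partition the retained days; chained duplicates interior weeks", {
  set.seed(31)
  s <- daily_series(as.Date("2003-01-01") + 0:729, rnorm(730), rnorm(730))
  for (nm in c("CC2D", "CC3D", "CC2W", "CCM")) {
    ds <- assign_strata(s, stratum_scheme(nm, "calendar"))
    expect_identical(sort(unique(ds$day)), 0:729)
    expect_true(all(attr(ds, "duplication") == 1L), label = nm)
    sizes <- table(ds$stratum)
    lim <- switch(nm, CC2D = 2L, CC3D = 3L, CC2W = 2L, CCM = 5L)
    expect_true(all(sizes <= lim), label = nm)
  }
  ds <- assign_strata(s, stratum_scheme("CC2CW", "calendar"))
  expect_true(all(attr(ds, "duplication") %in% 1:2))
})

test_that("CC2CW membership counts match an independent enumeration of the chained construction", {
  # 52-week year: weeks 2..51 contribute to exactly 2 strata, weeks 1 and 52 to 1
  n <- 364
  s <- daily_series(as.Date("2001-01-01") + seq_len(n) - 1L, rnorm(n), rnorm(n))
  ds <- assign_strata(s, stratum_scheme("CC2CW", "fixed365", allow_partial_year = TRUE))
  # oracle: enumerate chained week pairs (w, w+1) and count day memberships
  week <- (seq_len(n) - 1L) %/% 7L + 1L
  expected <- integer(n)
  for (w in seq_len(max(week) - 1L)) {
    members <- which(week %in% c(w, w + 1L))
    expected[members] <- expected[members] + 1L
  }
  got <- as.integer(attr(ds, "duplication")[as.character(seq_len(n) - 1L)])
  expect_identical(got, expected)
  expect_true(all(got[week %in% 2:51] == 2L))
  expect_true(all(got[week %in% c(1L, 52L)] == 1L))
  # each chained stratum pairs at most two same-weekday days
  expect_true(all(table(ds$stratum) <= 2L))
})

test_that("informative_strata removes singletons, flat exposure and (poisson) all-zero strata", {
  x <- c(1, 2, 10, 10, 0, 1, 3, 4)
  y <- c(2, 3, 1, 4, 0, 0, 1, 2)
  g <- factor(c(1, 1, 2, 2, 3, 3, 4, 4))
  ds <- make_stratified(c(x, 5), c(y, 1), factor(c(as.character(g), "5")))  # add singleton
  fp <- informative_strata(ds, "poisson")
  expect_identical(sort(as.character(unique(fp$stratum))), c("1", "4"))
  expect_equal(attr(fp, "removed"),
               list(too_small = 1L, constant_exposure = 1L, zero_outcome = 1L))
  # gaussian keeps the all-zero-outcome pair
  fg <- informative_strata(ds, "gaussian")
  expect_identical(sort(as.character(unique(fg$stratum))), c("1", "3", "4"))
  # filtering is idempotent
  expect_identical(as.data.frame(informative_strata(fp, "poisson")), as.data.frame(fp))
})

test_that("rows with missing outcome or exposure are excluded at stratification", {
  s <- daily_series(as.Date("2001-01-01") + 0:9,
                    outcome = c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10),
                    exposure = c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10))
  ds <- assign_strata(s, stratum_scheme("CC2D", "calendar"))
  expect_identical(sort(unique(ds$day)), c(0L, 3:9))
})

test_that("stratified datasets export to CSV for audit", {
  s <- daily_series(as.Date("2001-01-01") + 0:9, rnorm(10), rnorm(10))
  ds <- assign_strata(s, stratum_scheme("CC2D", "calendar"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_strata_csv(ds, p)
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(ds))
  expect_identical(back$stratum, as.character(ds$stratum))
})
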