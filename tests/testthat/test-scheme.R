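test_that("categorization reproduces the expert breakpoints at interval boundaries", {
  sch <- default_scheme()
  cases <- list(
    # factor, raw value, expected code
    list("age", 29.9, 0L), list("age", 30, 1L), list("age", 39.9, 1L),
    list("age", 40, 2L), list("age", 45, 2L), list("age", 50, 3L),
    list("age", 60, 4L), list("age", 69.9, 4L), list("age", 70, 5L),
    list("age", 88, 5L),
    list("mmsetotal", 30, 0L), list("mmsetotal", 26, 0L),
    list("mmsetotal", 25, 0L), list("mmsetotal", 24, 1L),
    list("mmsetotal", 20, 1L), list("mmsetotal", 19, 2L),
    list("mmsetotal", 10, 2L), list("mmsetotal", 9, 3L),
    list("mmsetotal", 0, 3L),
    list("indepscl", 0, 0L), list("indepscl", 40, 0L),
    list("indepscl", 41, 1L), list("indepscl", 80, 1L),
    list("indepscl", 81, 2L), list("indepscl", 95, 2L),
    list("indepscl", 96, 3L), list("indepscl", 100, 3L),
    list("fiscore", 0, 0L), list("fiscore", 5, 0L), list("fiscore", 6, 1L),
    list("fiscore", 10, 1L), list("fiscore", 11, 2L), list("fiscore", 15, 2L),
    list("fiscore", 16, 3L), list("fiscore", 20, 3L), list("fiscore", 21, 4L),
    list("tfcscore", 0, 0L), list("tfcscore", 5, 0L), list("tfcscore", 6, 1L),
    list("tfcscore", 8, 1L), list("tfcscore", 9, 2L), list("tfcscore", 12, 2L),
    list("tfcscore", 13, 3L),
    list("motscore", 0, 0L), list("motscore", 1, 1L), list("motscore", 31, 1L),
    list("motscore", 32, 2L), list("motscore", 62, 2L),
    list("motscore", 63, 3L), list("motscore", 93, 3L),
    list("motscore", 94, 4L),
    list("exfscore", 0, 0L), list("exfscore", 1, 1L), list("exfscore", 4, 1L),
    list("exfscore", 5, 2L), list("exfscore", 8, 2L), list("exfscore", 9, 3L),
    list("exfscore", 12, 3L), list("exfscore", 13, 4L),
    list("irascore", 0, 0L), list("irascore", 4, 1L), list("irascore", 7, 2L),
    list("irascore", 8, 2L), list("irascore", 9, 3L), list("irascore", 13, 4L),
    list("depscore", 0, 0L), list("depscore", 2, 1L), list("depscore", 6, 2L),
    list("depscore", 12, 3L), list("depscore", 14, 4L),
    list("psyscore", 0, 0L), list("psyscore", 3, 1L), list("psyscore", 11, 3L),
    list("aptscore", 0, 0L), list("aptscore", 5, 2L), list("aptscore", 9, 3L),
    list("sdmt1", 50, 0L), list("sdmt1", 43, 0L), list("sdmt1", 42, 1L),
    list("sdmt1", 35, 1L), list("sdmt1", 34, 2L), list("sdmt1", 27, 2L),
    list("sdmt1", 26, 3L), list("sdmt1", 25, 3L), list("sdmt1", 0, 3L)
  )
  for (cs in cases) {
    expect_identical(hdwtrules:::categorize_value(sch, cs[[1]], cs[[2]]),
                     cs[[3]],
                     info = sprintf("%s = %s", cs[[1]], cs[[2]]))
  }
})

test_that("weight-change categories follow the symmetric magnitude scheme", {
  expect_identical(weight_category(c(-25, -20.001, -20)), c(-3L, -3L, -3L))
  expect_identical(weight_category(c(-19.9, -15, -10)), c(-2L, -2L, -2L))
  expect_identical(weight_category(c(-9.9, -5)), c(-1L, -1L))
  expect_identical(weight_category(c(-4.9, 0, 4.9)), c(0L, 0L, 0L))
  expect_identical(weight_category(c(5, 9.9)), c(1L, 1L))
  expect_identical(weight_category(c(12, 19.9)), c(2L, 2L))
  expect_identical(weight_category(c(20, 30)), c(3L, 3L))
  expect_error(weight_category(NA_real_), "finite")
})

test_that("every value in the declared range maps to exactly one code and severity is monotone", {
  sch <- default_scheme()
  reverse_scored <- c("mmsetotal", "sdmt1")
  for (f in hd_factor_names) {
    iv <- sch[[f]]
    lo <- min(iv$lo)
    hi <- max(iv$lo) + 10
    grid <- seq(lo, hi, by = 0.25)
    codes <- hdwtrules:::categorize_value(sch, f, grid)
    expect_false(anyNA(codes))
    # monotone in the declared direction
    d <- diff(codes)
    if (f %in% reverse_scored) expect_true(all(d <= 0)) else
      expect_true(all(d >= 0))
    # each code covers a contiguous block (exactly one interval per code)
    expect_identical(sort(unique(codes)), sort(iv$code))
  }
})

test_that("values jittered within a category's raw interval keep their code", {
  sch <- default_scheme()
  set.seed(42)
  for (f in hd_factor_names) {
    for (code in sch[[f]]$code) {
      iv <- hdwtrules:::scheme_interval(sch, f, code)
      x <- runif(25, iv["lo"], max(iv["hi"] - 1e-9, iv["lo"]))
      expect_true(all(hdwtrules:::categorize_value(sch, f, x) == code),
                  info = sprintf("%s code %d", f, code))
    }
  }
})

test_that("categorize converts records and rejects out-of-range or missing values", {
  tab <- make_subject("S1", c(100, 95, 85),
                      factors = list(irascore = 7, depscore = 12))
  rec <- compute_weight_change(tab)
  kb <- categorize(rec)
  expect_identical(kb$wtCat, -2L)       # -15% loss is severe
  expect_identical(kb$irascore, 2L)
  expect_identical(kb$depscore, 3L)
  rec_bad <- rec
  rec_bad$age <- 10                      # below the declared range
  expect_error(categorize(rec_bad), "age")
  rec_na <- rec
  rec_na$sdmt1 <- NA
  expect_error(categorize(rec_na), "missing")
})

test_that("category densities count per group and sum to one", {
  kb <- data.frame(subjid = sprintf("S%d", 1:4), group = "pMan",
                   wtCat = c(-3L, -3L, 0L, 2L),
                   irascore = c(0L, 0L, 1L, 2L), stringsAsFactors = FALSE)
  dens <- category_density(kb, "irascore")
  expect_equal(dens$frequency, c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(sum(dens$frequency), 1)
  dens_w <- category_density(kb, "wtCat")
  expect_equal(dens_w$frequency[dens_w$category == -3], 0.5)
  expect_error(category_density(kb[0, ], "irascore"), "empty")
  expect_error(category_density(kb, "nosuch"), "unknown")
})

test_that("scheme survives a JSON round-trip", {
  sch <- default_scheme()
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(sch, path)
  back <- read_scheme(path)
  for (f in hd_factor_names) expect_equal(back[[f]], sch[[f]], info = f)
  expect_equal(back$wtCat$magnitude_breaks, sch$wtCat$magnitude_breaks)
})
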