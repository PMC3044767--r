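test_that("minimal config loads with defaults filled and recorded", {
  f <- tempfile(fileext = ".yaml")
  writeLines("model: rate", f)
  cfg <- load_config(f)
  expect_equal(cfg$populations$E$N, 100)
  expect_equal(cfg$solver$dt, 1)
  expect_true(length(attr(cfg, "defaults_filled")) > 0)
  m <- rate_model_from_config(cfg)
  expect_s3_class(m$conn, "ring_connectivity")
})

test_that("invalid configs are rejected with a list of violations", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("model: rate", "connectivity:", "  J_II: -2"), f)
  expect_error(load_config(f), class = "ringcrf_config_error")
  writeLines(c("model: quantum"), f)
  expect_error(load_config(f), class = "ringcrf_config_error")
  writeLines(c("nonsense_section:", "  a: 1"), f)
  expect_error(load_config(f), class = "ringcrf_config_error")
  expect_error(load_config(tempfile()), class = "ringcrf_config_error")
})

test_that("configs round-trip losslessly", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("model: rate", "drive:", "  nu0: 2.5"), f)
  cfg <- load_config(f)
  g <- tempfile(fileext = ".yaml")
  write_config(cfg, g)
  cfg2 <- load_config(g)
  attr(cfg, "defaults_filled") <- NULL
  attr(cfg2, "defaults_filled") <- NULL
  expect_equal(unclass(cfg), unclass(cfg2))
})

test_that("fixtures are deterministic and carry recoverable truth", {
  a <- generate_fixture("crf", noise_sd = 1, seed = 10)
  b <- generate_fixture("crf", noise_sd = 1, seed = 10)
  expect_identical(a$data, b$data)
  f <- fit_hratio(a$data)
  expect_true(f$good)
  expect_equal(f$C50, a$truth$C50, tolerance = 0.2)
})

test_that("run records are written atomically with version and warnings", {
  f <- tempfile(fileext = ".json")
  write_run_record(f, config = list(x = 1), timings = c(total = 0.5),
                   warnings = "used default widths")
  rec <- jsonlite::read_json(f)
  expect_equal(rec$package, "ringcrf")
  expect_equal(rec$config$x, 1)
  expect_equal(rec$warnings, "used default widths")
  expect_false(file.exists(paste0(f, ".tmp")))
})
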