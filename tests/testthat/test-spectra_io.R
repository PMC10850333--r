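test_that("write/read round trip is exact and preserves header order", {
  set.seed(101)
  s <- spectra_set(matrix(runif(50), 5, 10), sort(runif(10, 950, 1650)),
                   runif(5, 0.03, 0.2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, f)
  r <- read_spectra(f)
  expect_identical(r$reflectance, s$reflectance)
  expect_identical(r$wavelengths, s$wavelengths)
  expect_identical(r$target, s$target)
  expect_identical(r$sample_ids, s$sample_ids)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(r, f2)
  expect_identical(strsplit(readLines(f, n = 1), ",")[[1]],
                   strsplit(readLines(f2, n = 1), ",")[[1]])
})

test_that("a full-size table reads back with n = 230, p = 125", {
  ds <- generate_dataset(synthetic_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, f)
  r <- read_spectra(f)
  expect_identical(dim(r), c(230L, 125L))
  expect_identical(r$reflectance, ds$reflectance)
})

test_that("malformed input fails with a located diagnostic", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,impurity,950,960",
               "a,0.1,0.5,0.6",
               "b,0.2,0.7"), f)
  expect_error(read_spectra(f), "row 3")

  writeLines(c("sample_id,impurity,950,960",
               "a,0.1,0.5,0.6",
               "b,0.2,oops,0.7"), f)
  expect_error(read_spectra(f), "row 2.*'950'|'950'.*row 2")

  writeLines(c("sample_id,impurity,950,960",
               "a,0.1,0.5,0.6",
               "a,0.2,0.6,0.7"), f)
  expect_error(read_spectra(f), "duplicate sample ID")

  writeLines(c("sample_id,950,960",
               "a,0.5,0.6"), f)
  expect_error(read_spectra(f), "missing target column 'impurity'")
})

test_that("writing requires a valid target and container", {
  s <- spectra_set(matrix(runif(8), 2, 4), 1:4 * 100 + 900, c(0.1, 0.2))
  s$target <- numeric(0)
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_spectra(s, f), "target")
})

test_that("validation rejects non-finite reflectance and bad shapes", {
  wl <- seq(950, 1650, length.out = 4)
  expect_error(spectra_set(matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 2, 4), wl,
                           c(0.1, 0.2)), "missing or non-finite")
  expect_error(spectra_set(matrix(c(1, Inf, 3, 4, 5, 6, 7, 8), 2, 4), wl,
                           c(0.1, 0.2)), "missing or non-finite")
  expect_error(spectra_set(matrix(1:8 / 8, 2, 4), rev(wl), c(0.1, 0.2)),
               "strictly increasing")
  expect_error(spectra_set(matrix(1:8 / 8, 2, 4), wl, c(0.1)), "target length")
  expect_error(spectra_set(matrix(1:8 / 8, 2, 4), wl, c(0.1, 0.2),
                           c("a", "a")), "duplicate")
})

test_that("split and selection JSON artifacts round trip and validate", {
  sp <- split_indices(c(1, 3, 4), c(2, 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_split(sp, f)
  r <- read_split(f)
  expect_identical(r$train, sp$train)
  expect_identical(r$test, sp$test)
  expect_error(split_indices(c(1, 2), c(2, 3)), "overlap")
  expect_error(split_indices(c(1, 2), integer(0)), "non-empty")
  expect_error(split_indices(c(1, 2), c(5, 6)), "partition")

  sel <- selection_result(c(7, 2, 9), scores = runif(10), method = "frog",
                          p = 10)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, f2, wavelengths = seq(950, 1650, length.out = 10))
  r2 <- read_selection(f2)
  expect_identical(r2$selected, sel$selected)
  expect_identical(r2$method, "frog")
  expect_error(selection_result(c(1, 1), method = "spa"), "unique")
  expect_error(selection_result(c(1, 11), method = "spa", p = 10), "exceed")
})
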