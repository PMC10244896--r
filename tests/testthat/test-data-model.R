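test_that("encounter histories define recruitment at the first sighting", {
  h <- encounter_histories(matrix(c(0L, 1L, 0L, 1L), 1), 2002:2005, "F1")
  expect_equal(h$recruit, 2L)
  expect_equal(ncol(h$sightings), 4L)
  expect_true(is.na(h$sightings[1, 1])) # pre-recruitment is structurally absent
})

test_that("invalid encounter rows are rejected", {
  expect_error(encounter_histories(matrix(c(0L, 0L, 0L), 1), 2002:2004, "F1"),
               "never sighted")
  expect_error(encounter_histories(matrix(c(1L, NA, 0L), 1), 2002:2004, "F1"),
               "after first sighting")
  expect_error(encounter_histories(matrix(c(1L, 2L, 0L), 1), 2002:2004, "F1"),
               "non-binary")
  expect_error(encounter_histories(rbind(c(1L, 0L), c(1L, 1L)), 2002:2003,
                                   c("F1", "F1")), "duplicate")
})

test_that("encounter matrix round-trips through CSV losslessly", {
  h <- toy_histories()
  path <- withr::local_tempfile(fileext = ".csv")
  write_encounter_matrix(h, path)
  h2 <- read_encounter_matrix(path)
  expect_identical(h2$sightings, h$sightings)
  expect_identical(h2$recruit, h$recruit)
  expect_identical(h2$female_id, h$female_id)
  expect_identical(h2$years, h$years)
})

test_that("single-season filter keeps >=2 sightings, logs removals, idempotent", {
  m <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(NA, 1L, 1L))
  h <- encounter_histories(m, 2002:2004, c("A", "B", "C"))
  f <- filter_single_season(h, quiet = TRUE)
  expect_setequal(f$female_id, c("B", "C"))
  expect_equal(attr(f, "n_removed"), 1L)
  f2 <- filter_single_season(f, quiet = TRUE)
  expect_equal(attr(f2, "n_removed"), 0L)
  expect_identical(f2$sightings, f$sightings)
})

test_that("filter count matches a direct scan on simulated histories", {
  col <- simulate_colony(small_config(n_females = 100L, seed = 3L))
  k <- sum(rowSums(col$encounters$sightings == 1L, na.rm = TRUE) < 2L)
  f <- filter_single_season(col$encounters, quiet = TRUE)
  expect_equal(length(f$female_id), 100L - k)
})

test_that("parity groups follow cumulative birth order", {
  pups <- data.frame(female_id = "A", year = c(2005, 2003, 2006, 2009))
  expect_equal(as.character(derive_parity(pups)), c("2", "1", "3+", "3+"))
  expect_equal(as.character(derive_parity(data.frame(female_id = "Z",
                                                     year = 2004))), "1")
  expect_error(derive_parity(data.frame(female_id = c("A", "A"),
                                        year = c(2004, 2004))),
               "same female and occasion")
})

test_that("derive_parity equals a cumulative-count oracle on random tables", {
  set.seed(42)
  for (rep in 1:1000) {
    nfem <- sample(1:6, 1)
    tab <- do.call(rbind, lapply(seq_len(nfem), function(i) {
      yrs <- sample(2002:2015, sample(1:8, 1))
      data.frame(female_id = paste0("F", i), year = yrs)
    }))
    tab <- tab[sample(nrow(tab)), , drop = FALSE] # shuffle row order
    got <- as.character(derive_parity(tab))
    want <- vapply(seq_len(nrow(tab)), function(j) {
      cnt <- sum(tab$female_id == tab$female_id[j] & tab$year <= tab$year[j])
      if (cnt >= 3) "3+" else as.character(cnt)
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("standardizer centres, scales, inverts and rejects degenerate input", {
  s <- fit_standardizer(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(std_transform(s, c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  s2 <- fit_standardizer(x)
  z <- std_transform(s2, x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(std_inverse(s2, z), x, tolerance = 1e-10)
  expect_error(fit_standardizer(rep(5, 10)), "distinct")
})

test_that("standardizer recovers the weaning-length moments it was fit to", {
  set.seed(7)
  lw <- rnorm(4000, 112.7, 4.28)
  s <- fit_standardizer(lw)
  expect_equal(s$mean, 112.7, tolerance = 3 * 4.28 / sqrt(4000) / 112.7)
  expect_equal(s$sd, 4.28, tolerance = 0.05)
})

test_that("female and pup tables round-trip and validate", {
  fem <- data.frame(female_id = c("A", "B"), cohort = c(1998L, 2002L),
                    weaning_length_cm = c(110.5, 120))
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_female_table(fem, fpath)
  expect_equal(read_female_table(fpath), fem)
  fem$weaning_length_cm[1] <- 85
  write_female_table(fem, fpath)
  expect_warning(read_female_table(fpath), "90-132")

  pup <- data.frame(female_id = "A", year = 2005L, pup_sex = "female",
                    weaning_mass_kg = 48.5, maternal_age_yr = 7L)
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_pup_table(pup, ppath)
  expect_equal(read_pup_table(ppath), pup)
  pup$weaning_mass_kg <- -1
  write_pup_table(pup, ppath)
  expect_error(read_pup_table(ppath), "positive")
})

test_that("manifest round-trips as key-value text", {
  mf <- list(seed = 42L, note = "abc", value = 1.25)
  path <- withr::local_tempfile(fileext = ".txt")
  write_manifest(mf, path)
  got <- read_manifest(path)
  expect_equal(names(got), names(mf))
  expect_equal(as.numeric(got$seed), 42)
  expect_equal(got$note, "abc")
})
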