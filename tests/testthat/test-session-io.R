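# Session HDF5 and registration CSV readers/writers, and the
# repeatedly-identified neuron set.

test_that("session write/read round-trips bit-exactly, with and without compression", {
  s <- small_session()$session
  for (level in c(0, 4)) {
    f <- tempfile(fileext = ".h5")
    write_session(s, f, compress = level)
    s2 <- read_session(f)
    expect_identical(s2$calcium$values, s$calcium$values)
    expect_identical(s2$calcium$transients, s$calcium$transients)
    expect_identical(s2$calcium$neuron_ids, s$calcium$neuron_ids)
    expect_identical(s2$behavior$context, s$behavior$context)
    expect_identical(s2$behavior$coping, s$behavior$coping)
    expect_identical(s2$behavior$speed_parts, s$behavior$speed_parts)
    expect_identical(s2$behavior$speed_mean, s$behavior$speed_mean)
    expect_identical(s2$animal_id, s$animal_id)
    expect_identical(s2$day, s$day)
    unlink(f)
  }
})

test_that("overwrite is refused without the force flag", {
  s <- small_session()$session
  f <- tempfile(fileext = ".h5")
  write_session(s, f)
  expect_error(write_session(s, f), "file exists")
  expect_silent(write_session(s, f, overwrite = TRUE))
  unlink(f)
})

test_that("a file lacking a required dataset raises a format error naming it", {
  s <- small_session()$session
  f <- tempfile(fileext = ".h5")
  write_session(s, f)
  rhdf5::h5delete(f, "behavior/context")
  expect_error(read_session(f), "/behavior/context")
  unlink(f)
})

test_that("registration CSV round-trips and rejects duplicated local indices", {
  m <- registration_map(c(5L, 2L, 9L), day1 = c(0L, 1L, -1L),
                        day3 = c(2L, 0L, 1L), day9 = c(-1L, 0L, 1L))
  f <- tempfile(fileext = ".csv")
  write_registration(m, f)
  m2 <- read_registration(f)
  expect_identical(as.data.frame(m2), as.data.frame(m))
  expect_identical(attr(m2, "days"), c(1L, 3L, 9L))
  unlink(f)
  expect_error(registration_map(1:2, day1 = c(0L, 0L)), "duplicated local")
  expect_error(registration_map(c(1L, 1L), day1 = c(0L, 1L)), "duplicate global_id")
})

test_that("repeatedly_identified returns exactly the all-day neurons, ascending", {
  m <- registration_map(c(3L, 1L, 2L), day1 = c(0L, 1L, 2L),
                        day3 = c(1L, 0L, -1L))
  expect_identical(repeatedly_identified(m), c(1L, 3L))
  # neuron with one absent cell is excluded
  expect_false(2L %in% repeatedly_identified(m))
  # all present on all days -> all ids
  m_all <- registration_map(1:4, day1 = 0:3, day3 = c(2L, 0L, 3L, 1L))
  expect_identical(repeatedly_identified(m_all), 1:4)
  # empty intersection
  m_none <- registration_map(1:2, day1 = c(0L, -1L), day3 = c(-1L, 0L))
  expect_identical(repeatedly_identified(m_none), integer(0))
  expect_error(repeatedly_identified(m, days = 7), "unknown day")
  # monotonicity: more days can only shrink the set
  expect_true(all(repeatedly_identified(m, c(1, 3)) %in%
                    repeatedly_identified(m, 1)))
})

test_that("independent per-day presence yields the closed-form all-day fraction", {
  # p = 0.74 over 3 days -> expected fraction p^3 = 0.405
  p <- generator_params(n_neurons = 1000L, n_frames_baseline = 200L,
                        n_frames_ts = 400L)
  md <- generate_multiday(p, days = c(1, 3, 9), seed = 4)
  frac <- length(repeatedly_identified(md$map)) / 1000
  expected <- 0.74^3
  ci <- 1.96 * sqrt(expected * (1 - expected) / 1000)
  expect_within(frac, expected, ci + 0.01)
  # the emitted map reflects presence exactly
  expect_identical(unname(colSums(as.data.frame(md$map)[-1] >= 0)),
                   unname(colSums(md$truth$presence)))
})
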