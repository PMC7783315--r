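write_cm <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("contact map loading validates, normalises and counts entries", {
  f <- write_cm(c("# comment", "1 5 0.9"))
  m <- load_contact_map(f)
  expect_identical(nrow(m$entries), 1L)
  expect_identical(c(m$entries$i, m$entries$j), c(1L, 5L))

  # reversed pair is normalised to the upper triangle
  m2 <- load_contact_map(write_cm("5 1 0.9"))
  expect_identical(c(m2$entries$i, m2$entries$j), c(1L, 5L))

  expect_error(load_contact_map(write_cm(c("1 5 0.9", "2 2 0.5"))), "line 2")
  expect_error(load_contact_map(write_cm("1 5 1.7")), "outside")
  expect_warning(load_contact_map(write_cm(c("1 5 0.4", "5 1 0.9"))), "duplicate")

  # entry count equals an independent line count minus comments
  set.seed(2)
  body <- sprintf("%d %d %.2f", 1:100, 101:200, runif(100))
  f3 <- write_cm(c("# hdr", body, "# tail"))
  n_expected <- sum(!startsWith(readLines(f3), "#"))
  expect_identical(nrow(load_contact_map(f3)$entries), n_expected)
})

test_that("stitching one full-length segment is the identity with coverage 1", {
  fx <- make_segmented_contact_fixture(300L, segment_scheme = list(c(1L, 300L)),
                                       noise_frac = 0, seed = 1)
  comp <- stitch(fx$segments, 300L)
  expect_identical(comp$entries[, c("i", "j", "p")],
                   data.frame(i = fx$segments[[1]]$entries$i,
                              j = fx$segments[[1]]$entries$j,
                              p = fx$segments[[1]]$entries$p))
  expect_true(all(comp$entries$coverage == 1L))
})

test_that("overlap merging follows the merge rule (hand-computed)", {
  s1 <- segment_contact_map(1L, 50L, data.frame(i = 10L, j = 20L, p = 0.4))
  s2 <- segment_contact_map(6L, 50L, data.frame(i = 5L, j = 15L, p = 0.8))
  for (rule in c("mean", "max", "min")) {
    comp <- stitch(list(s1, s2), 60L, rule)
    expect_identical(nrow(comp$entries), 1L)
    expect_identical(comp$entries$coverage, 2L)
    expect_equal(comp$entries$p,
                 switch(rule, mean = 0.6, max = 0.8, min = 0.4))
  }
  # disjoint segments do not merge
  s3 <- segment_contact_map(40L, 20L, data.frame(i = 1L, j = 5L, p = 0.7))
  comp <- stitch(list(s1, s3), 60L)
  expect_identical(nrow(comp$entries), 2L)
  expect_true(all(comp$entries$coverage == 1L))
  expect_error(stitch(list(s1), 40L), "exceeds")
})

test_that("the four-window PrtP segmentation covers the full mature length", {
  scheme <- list(c(1L, 799L), c(301L, 799L), c(501L, 799L), c(926L, 800L))
  fx <- make_segmented_contact_fixture(1725L, boundaries = 520L,
                                       segment_scheme = scheme, seed = 13)
  spans <- t(vapply(fx$segments, function(s) c(s$offset, s$offset + s$length - 1L),
                    integer(2)))
  expect_identical(spans[, 1], c(1L, 301L, 501L, 926L))
  expect_identical(spans[, 2], c(799L, 1099L, 1299L, 1725L))
  comp <- stitch(fx$segments, 1725L)
  covered <- sort(unique(c(comp$entries$i, comp$entries$j)))
  expect_identical(range(covered), c(1L, 1725L))
  expect_gte(max(comp$entries$coverage), 2L)
})

test_that("stitching is idempotent and permutation-invariant", {
  fx <- make_segmented_contact_fixture(
    500L, boundaries = 250L,
    segment_scheme = list(c(1L, 300L), c(201L, 300L)), seed = 4)
  comp <- stitch(fx$segments, 500L)
  # restitch the composite as a single full-length segment
  again <- stitch(segment_contact_map(1L, 500L, comp$entries[, c("i", "j", "p")]),
                  500L)
  expect_equal(again$entries[, c("i", "j", "p")], comp$entries[, c("i", "j", "p")])
  for (rule in c("mean", "max", "min")) {
    a <- stitch(fx$segments, 500L, rule)
    b <- stitch(rev(fx$segments), 500L, rule)
    expect_equal(a$entries, b$entries)
  }
})

test_that("the tilted diagonal band places entries at (position, separation)", {
  comp <- stitch(segment_contact_map(1L, 100L,
                                     data.frame(i = 10L, j = 60L, p = 0.9)), 100L)
  band <- render_diagonal_band(comp, 200L)
  expect_identical(dim(band), c(100L, 200L))
  expect_equal(unname(band[10, 50]), 0.9)
  expect_equal(sum(band), 0.9)
  # separation beyond the band is clipped
  expect_equal(sum(render_diagonal_band(comp, 40L)), 0)
  # empty map -> zero matrix
  empty <- stitch(segment_contact_map(1L, 50L,
                                      data.frame(i = integer(0), j = integer(0),
                                                 p = numeric(0))), 50L)
  expect_equal(sum(render_diagonal_band(empty, 10L)), 0)
})

test_that("planted domain boundaries are recovered and uniform maps stay whole", {
  two <- make_segmented_contact_fixture(500L, boundaries = 250L,
                                        segment_scheme = list(c(1L, 500L)),
                                        noise_frac = 0, seed = 5)
  seg <- detect_domain_boundaries(stitch(two$segments, 500L))
  expect_identical(length(seg$boundaries), 1L)
  expect_lte(abs(seg$boundaries - 250L), 2L)

  three <- make_segmented_contact_fixture(750L, boundaries = c(250L, 500L),
                                          segment_scheme = list(c(1L, 750L)),
                                          seed = 6)
  seg3 <- detect_domain_boundaries(stitch(three$segments, 750L))
  expect_identical(length(seg3$boundaries), 2L)
  expect_true(all(abs(seg3$boundaries - c(250L, 500L)) <= 3L))

  uniform <- make_segmented_contact_fixture(600L,
                                            segment_scheme = list(c(1L, 600L)),
                                            seed = 7)
  expect_identical(
    length(detect_domain_boundaries(stitch(uniform$segments, 600L))$boundaries), 0L)
  expect_error(detect_domain_boundaries(stitch(uniform$segments, 600L),
                                        min_domain = 400L), "shorter")
})

test_that("boundary recovery is robust to 10% uniform contact noise", {
  for (s in 1:3) {
    fx <- make_segmented_contact_fixture(700L, boundaries = 350L,
                                         segment_scheme = list(c(1L, 700L)),
                                         noise_frac = 0.1, seed = s)
    seg <- detect_domain_boundaries(stitch(fx$segments, 700L))
    expect_identical(length(seg$boundaries), 1L)
    expect_lte(abs(seg$boundaries - 350L), 3L)
  }
})

test_that("planted repeat periods are recovered with unit counts", {
  fr <- make_segmented_contact_fixture(
    1725L, repeat_spec = list(region = c(500L, 1400L), period = 100L),
    segment_scheme = list(c(1L, 1725L)), seed = 5)
  rs <- detect_repeat_period(stitch(fr$segments, 1725L), c(500L, 1400L), 150L)
  expect_lte(abs(rs$period - 100L), 2L)
  expect_identical(rs$n_units, 9L)
  expect_false(rs$weak)

  # 60-residue W-like units
  fw <- make_segmented_contact_fixture(
    900L, repeat_spec = list(region = c(100L, 800L), period = 60L),
    segment_scheme = list(c(1L, 900L)), seed = 6)
  rw <- detect_repeat_period(stitch(fw$segments, 900L), c(100L, 800L), 90L)
  expect_lte(abs(rw$period - 60L), 2L)

  # featureless region: weak signal
  fn <- make_segmented_contact_fixture(600L, segment_scheme = list(c(1L, 600L)),
                                       seed = 7)
  rn <- detect_repeat_period(stitch(fn$segments, 600L), c(1L, 600L), 150L)
  expect_true(rn$weak)
  expect_lt(rn$strength, 0.2)
  expect_error(detect_repeat_period(stitch(fn$segments, 600L), c(1L, 100L), 150L),
               "too short")
})

test_that("composite maps round-trip through the 3-column text format", {
  fx <- make_segmented_contact_fixture(200L, segment_scheme = list(c(1L, 200L)),
                                       seed = 8)
  comp <- stitch(fx$segments, 200L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_contact_map(comp, f)
  tab <- read.table(f)
  expect_identical(nrow(tab), nrow(comp$entries))
  expect_equal(tab$V3, comp$entries$p)
})
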