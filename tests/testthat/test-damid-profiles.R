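test_that("bedGraph loading re-bins by proportional allocation", {
  map <- uniform_map(10, L = 100)
  bg <- tempfile(fileext = ".bedgraph")

  ## interval exactly equal to fragment 7 ([600, 700))
  writeLines("chr1\t600\t700\t12", bg)
  p <- load_fragment_signal(bg, map, sample_meta("s1"))
  expect_equal(p$values[7], 12)
  expect_equal(sum(p$values), 12)

  ## 100 bp interval of value 10 split 30/70 across the fragment boundary
  writeLines("chr1\t170\t270\t10", bg)
  p <- load_fragment_signal(bg, map, sample_meta("s1"))
  expect_equal(p$values[2], 3)
  expect_equal(p$values[3], 7)

  ## mass conservation on random non-overlapping intervals
  set.seed(11)
  starts <- sort(sample(seq(0, 980, 20), 15))
  widths <- pmin(sample(5:40, 15, replace = TRUE), diff(c(starts, 1000)))
  vals <- round(runif(15, 0, 50), 3)
  writeLines(sprintf("chr1\t%d\t%d\t%g", starts, starts + widths, vals), bg)
  p <- load_fragment_signal(bg, map, sample_meta("s1"))
  expect_equal(sum(p$values), sum(vals), tolerance = 1e-9)
})

test_that("bedGraph loading rejects bad input", {
  map <- uniform_map(5, L = 100)
  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr9\t0\t10\t5", bg)
  expect_error(load_fragment_signal(bg, map, sample_meta("s")), "unknown chromosome")
  writeLines(c("chr1\t0\t50\t5", "chr1\t40\t90\t5"), bg)
  expect_error(load_fragment_signal(bg, map, sample_meta("s")), "overlapping")
  writeLines("chr1\t0\t50\t-2", bg)
  expect_error(load_fragment_signal(bg, map, sample_meta("s")), "negative")
})

test_that("fragment TSV loads verbatim with zeros elsewhere", {
  map <- uniform_map(6, L = 100)
  tf <- tempfile(fileext = ".tsv")
  writeLines("1\t42.5", tf)
  p <- load_fragment_signal(tf, map, sample_meta("s"))
  expect_equal(p$values, c(42.5, 0, 0, 0, 0, 0))
  writeLines(c("2\t1", "2\t2"), tf)
  expect_error(load_fragment_signal(tf, map, sample_meta("s")), "duplicated")
  writeLines("99\t1", tf)
  expect_error(load_fragment_signal(tf, map, sample_meta("s")), "out of range")
})

test_that("RPM normalisation", {
  map <- uniform_map(3, L = 100)
  p <- profile_on(c(5, 0, 15), map, unit = "count")
  r <- rpm_normalize(p)
  expect_equal(r$values, c(250000, 0, 750000))
  expect_equal(r$unit, "rpm")

  p <- profile_on(rep(7, 3), map, unit = "count")
  expect_equal(rpm_normalize(p)$values, rep(1e6 / 3, 3))

  expect_error(rpm_normalize(profile_on(c(0, 0, 0), map, unit = "count")),
               "all-zero")

  ## conservation property on random counts
  set.seed(3)
  for (i in 1:10) {
    v <- rpois(3, 50)
    if (sum(v) == 0) next
    expect_equal(sum(rpm_normalize(profile_on(v, map, unit = "count"))$values),
                 1e6, tolerance = 1e-9)
  }
})

test_that("log2 ratio arithmetic, antisymmetry, and errors", {
  map <- uniform_map(4, L = 100)
  fus <- profile_on(c(3, 1, 5, 0), map, unit = "rpm")
  dam <- profile_on(c(1, 1, 5, 0), map, unit = "rpm")
  lr <- log2_ratio(fus, dam, pseudocount = 1)
  expect_equal(lr$values[1], 1)          # log2((3+1)/(1+1))
  expect_equal(lr$values[2], 0)
  expect_equal(lr$values[4], 0)
  expect_equal(lr$unit, "log2_ratio")

  ## identity and exact antisymmetry
  expect_equal(log2_ratio(dam, dam)$values, rep(0, 4))
  set.seed(5)
  a <- profile_on(runif(4, 0, 100), map, unit = "rpm")
  b <- profile_on(runif(4, 0, 100), map, unit = "rpm")
  expect_identical(log2_ratio(a, b)$values, -log2_ratio(b, a)$values)

  expect_error(log2_ratio(fus, dam, pseudocount = 0), "pseudocount")
  other <- uniform_map(5, L = 100)
  expect_error(log2_ratio(fus, profile_on(rep(1, 5), other, unit = "rpm")),
               "different maps")
})

test_that("median centering", {
  map <- uniform_map(5, L = 100)
  cst <- profile_on(rep(2.5, 5), map)
  expect_equal(median_center(cst)$values, rep(0, 5))
  set.seed(9)
  p <- profile_on(rnorm(5), map)
  centred <- median_center(p)
  expect_equal(median(centred$values), 0)
  expect_equal(median_center(centred)$values, centred$values)
})

test_that("profile constructor validates", {
  map <- uniform_map(3, L = 100)
  expect_error(fragment_profile(1:2, map, sample_meta("s"), "count"),
               "3 fragments")
  expect_error(fragment_profile(c(-1, 0, 0), map, sample_meta("s"), "count"),
               "non-negative")
  expect_error(sample_meta("s", channel = "dam_only", fusion_name = "PolII"),
               "empty fusion_name")
})
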