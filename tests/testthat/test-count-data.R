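test_that("independence filter applies the anchored rule", {
  expect_equal(nrow(filter_independent_captures(make_records(numeric(0)))), 0)

  one <- filter_independent_captures(make_records(0))
  expect_equal(nrow(one), 1)

  # 10 suppressed by the 0-anchor; 40 kept because 40 - 0 >= 30
  r <- filter_independent_captures(make_records(c(0, 10, 40)))
  expect_equal(as.numeric(r$timestamp - r$timestamp[1], units = "mins"),
               c(0, 40))

  # a tie at exactly the window is kept ("at least" 30 min apart)
  r <- filter_independent_captures(make_records(c(0, 30)))
  expect_equal(nrow(r), 2)

  # anchored, not sliding: 0, 20, 40 keeps 0 and 40 (20 is suppressed and
  # does not reset the anchor)
  r <- filter_independent_captures(make_records(c(0, 20, 40)))
  expect_equal(as.numeric(r$timestamp - r$timestamp[1], units = "mins"),
               c(0, 40))

  # streams are independent per species and unit
  recs <- rbind(make_records(c(0, 10), species = "tiger"),
                make_records(c(0, 10), species = "muntjac"),
                make_records(c(5, 15), unit = "u2"))
  expect_equal(nrow(filter_independent_captures(recs)), 3)
})

test_that("independence filter is idempotent on random streams", {
  set.seed(99)
  for (rep in 1:20) {
    recs <- make_records(sort(sample(0:500, 40)),
                         species = sample(c("a", "b"), 40, TRUE),
                         unit = sample(c("u1", "u2"), 40, TRUE))
    once <- filter_independent_captures(recs)
    twice <- filter_independent_captures(once)
    expect_identical(once$timestamp, twice$timestamp)
    # retained records are pairwise >= 30 min apart within each stream
    for (grp in split(once, paste(once$species, once$unit))) {
      if (nrow(grp) > 1) {
        expect_true(all(diff(as.numeric(grp$timestamp) / 60) >= 30))
      }
    }
  }
})

test_that("record validation catches bad input", {
  bad <- make_records(c(0, 10))
  bad$timestamp <- c("2020-01-01 00:00", "not-a-time")
  expect_error(validate_detection_records(bad), "unparseable timestamp")

  neg <- make_records(0); neg$count <- 0
  expect_error(validate_detection_records(neg), "counts must be integers >= 1")

  two <- rbind(make_records(0, landscape = "A"),
               make_records(60, landscape = "B"))
  expect_error(validate_detection_records(two), "more than one landscape")
})

test_that("aggregation pools cameras into units", {
  recs <- rbind(make_records(c(0, 60), unit = "cam1", count = 1),
                make_records(30, unit = "cam2", count = 2))
  assign <- data.frame(camera = c("cam1", "cam2"), unit = "u1",
                       landscape = "A")
  covs <- data.frame(camera = c("cam1", "cam2"), FLII = c(0.2, 0.4))
  daily <- aggregate_to_units(recs, assign, covs)
  expect_equal(unname(daily$covariates["u1", "FLII"]), 0.3)
  # 1 + 1 + 2 captures on the same day sum to 4
  expect_equal(sum(daily$counts["tiger", "u1", ]), 4)
  expect_equal(unname(daily$trap_nights["u1"]), 2)  # two cameras, one day

  # a sampled day without records is an observed zero, not missing
  act <- data.frame(camera = c("cam1", "cam2"),
                    start = "2020-01-01", end = "2020-01-02")
  daily2 <- aggregate_to_units(recs, assign, covs, camera_activity = act)
  expect_true(all(daily2$sampled["u1", ]))
  expect_equal(unname(daily2$counts["tiger", "u1", 2]), 0)

  expect_error(aggregate_to_units(recs, data.frame(camera = "cam1",
                                                   unit = "u1")),
               "cam2")
})

test_that("occasion binning sums daily blocks and keeps partials", {
  dd <- c(1, 0, 0, 2, 0, 0, 0, 0, 0, 1, 3, 0)
  recs <- make_records((which(dd > 0) - 1) * 24 * 60,
                       count = dd[dd > 0])
  act <- data.frame(camera = "u1", start = "2020-01-01", end = "2020-01-12")
  daily <- aggregate_to_units(recs, camera_activity = act)
  hist <- bin_occasions(daily, occasion_days = 5)
  expect_equal(as.numeric(hist$counts["tiger", "u1", ]), c(3, 1, 3))
  expect_true(all(hist$mask))            # trailing 2-day block retained
  expect_equal(hist$effort[["u1"]], 12)  # sampled days carry the effort

  # no mass lost in binning, any block size
  set.seed(3)
  for (od in c(1, 3, 5, 7)) {
    dd <- rpois(17, 1)
    recs <- make_records((seq_along(dd) - 1) * 24 * 60, count = pmax(dd, 1))
    recs <- recs[dd > 0, ]
    act <- data.frame(camera = "u1", start = "2020-01-01",
                      end = "2020-01-17")
    h <- bin_occasions(aggregate_to_units(recs, camera_activity = act), od)
    expect_equal(sum(h$counts), sum(dd[dd > 0]))
  }
})

test_that("group capping clamps daily counts at one and is idempotent", {
  recs <- make_records(c(0, 24 * 60, 2 * 24 * 60), count = c(2, 5, 1))
  act <- data.frame(camera = "u1", start = "2020-01-01", end = "2020-01-04")
  daily <- aggregate_to_units(recs, camera_activity = act)
  capped <- cap_group_counts(daily, "tiger")
  expect_equal(as.numeric(capped$counts["tiger", "u1", ]), c(1, 1, 1, 0))
  expect_identical(cap_group_counts(capped, "tiger")$counts, capped$counts)
  expect_error(cap_group_counts(daily, "sambar"), "unknown species")
  # a 5-day occasion for a capped species can still reach 5
  h <- bin_occasions(capped, 5)
  expect_equal(as.numeric(h$counts["tiger", "u1", 1]), 3)
})

test_that("covariate standardization centers, scales, and screens", {
  z <- standardize_covariates(cbind(a = c(1, 2, 3), b = c(0, 5, 1)))
  expect_equal(as.numeric(z$values[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z$values))), 1e-8)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-8)

  expect_error(standardize_covariates(cbind(a = 1:3, b = 1:3)),
               "collinearity: \\|r\\(a, b\\)\\| = 1.000")
  expect_error(standardize_covariates(cbind(a = c(5, 5))), "zero-variance")

  set.seed(11)
  for (rep in 1:10) {
    x <- matrix(rnorm(60), 20, 3)
    z <- standardize_covariates(x)
    expect_lt(max(abs(colMeans(z$values))), 1e-8)
    expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-8)
  }
})

test_that("zero informant follows detections and corroborated flags", {
  counts <- array(0L, c(2, 4, 3))
  counts[1, 1, 1] <- 2L  # dominant detected in landscape A only
  counts[2, , ] <- 1L    # subordinate everywhere
  hist <- count_history(counts, landscape = c("A", "A", "B", "B"),
                        species = c("dom", "sub"))
  z <- build_zero_informant(hist, extirpation_flags = data.frame(
    species = "dom", landscape = "B"))
  expect_equal(unname(z$Z["dom", ]), c(1, 1, 0, 0))
  expect_equal(unname(z$Z["sub", ]), c(1, 1, 1, 1))

  # no flags: Z identically 1
  z0 <- build_zero_informant(hist)
  expect_true(all(z0$Z == 1))

  # flag contradicting a detection is an error
  expect_error(build_zero_informant(hist, extirpation_flags = data.frame(
    species = "dom", landscape = "A")), "contradicts")

  # property: never Z = 0 where the species was detected
  set.seed(21)
  for (rep in 1:15) {
    cc <- array(rbinom(2 * 6 * 4, 1, 0.2), c(2, 6, 4))
    land <- sample(c("A", "B", "C"), 6, TRUE)
    h <- count_history(cc, landscape = land, species = c("dom", "sub"))
    empty <- outer(1:2, unique(land),
                   function(i, l) vapply(seq_along(l), function(q) {
                     sum(cc[i[q], land == l[q], ]) == 0
                   }, logical(1)))
    flags <- NULL
    for (i in 1:2) for (lq in seq_along(unique(land))) {
      if (empty[i, lq]) {
        flags <- rbind(flags, data.frame(species = c("dom", "sub")[i],
                                         landscape = unique(land)[lq]))
      }
    }
    z <- build_zero_informant(h, extirpation_flags = flags)
    det <- apply(cc, c(1, 2), sum) > 0
    expect_false(any(z$Z == 0 & det))
  }
})

test_that("count history and data bundle validate their invariants", {
  expect_error(count_history(array(-1L, c(2, 2, 2))), ">= 0")
  expect_error(count_history(array(0L, c(2, 2, 2)), occasion_days = 0),
               "occasion_days")

  # bundling rejects an informant that zeroes a unit with detections
  counts <- array(1L, c(2, 3, 2))
  Zbad <- matrix(1L, 2, 3); Zbad[1, 2] <- 0L
  expect_error(make_tiny_data(J = 3, O = 2, counts = counts, Z = Zbad),
               "contradicts detections")
})
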