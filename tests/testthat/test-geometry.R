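# Independent oracle: the speaker positions written out longhand from the
# physical description of the rig, and the class-membership rules applied by
# brute-force enumeration over those positions.
oracle_positions <- function() {
  rbind(
    data.frame(az = 0, el = 90),
    data.frame(az = c(0, -90, 90, 180), el = 45),
    data.frame(az = c(0, -45, 45, -90, 90, -135, 135, 180), el = 0),
    data.frame(az = c(0, -90, 90), el = -45)
  )
}

test_that("the canonical array matches the rig description", {
  arr <- speaker_array_fixture()
  expect_equal(nrow(arr), 16)
  expect_equal(anyDuplicated(arr[, c("azimuth_deg", "elevation_deg")]), 0)
  counts <- table(arr$elevation_deg)
  expect_equal(as.integer(counts[c("-45", "0", "45", "90")]), c(3, 8, 4, 1))
  expect_true(all(arr$radius_cm == 80))
  expect_true(all(arr$azimuth_deg > -180 & arr$azimuth_deg <= 180))
  # same multiset of positions as the longhand oracle
  o <- oracle_positions()
  expect_setequal(paste(arr$azimuth_deg, arr$elevation_deg),
                  paste(o$az, o$el))
  # deterministic and id-stable
  expect_identical(arr, build_speaker_array())
  expect_equal(arr$location_id, 0:15)
})

test_that("spherical/cartesian conversions follow the stated frame", {
  expect_equal(drop(spherical_to_cartesian(0, 0, 80)), c(x_cm = 80, y_cm = 0, z_cm = 0))
  expect_equal(drop(spherical_to_cartesian(0, 90, 80)),
               c(x_cm = 0, y_cm = 0, z_cm = 80), tolerance = 1e-12)
  expect_equal(drop(spherical_to_cartesian(-90, 0, 80)),
               c(x_cm = 0, y_cm = -80, z_cm = 0), tolerance = 1e-12)
  # round trip over the whole array (pole excluded: azimuth degenerate there)
  arr <- speaker_array_fixture()
  nonpole <- arr[arr$elevation_deg < 90, ]
  xyz <- spherical_to_cartesian(nonpole$azimuth_deg, nonpole$elevation_deg,
                                nonpole$radius_cm)
  back <- cartesian_to_spherical(xyz[, 1], xyz[, 2], xyz[, 3])
  expect_equal(back[, "azimuth_deg"], nonpole$azimuth_deg,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back[, "elevation_deg"], nonpole$elevation_deg,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back[, "radius_cm"], nonpole$radius_cm,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("hoop radii reproduce the rig dimensions", {
  expect_equal(round(hoop_radius(45, 80), 1), 56.6)
  expect_equal(round(hoop_radius(-45, 80), 1), 56.6)
  expect_equal(hoop_radius(0, 80), 80)
  expect_equal(hoop_radius(90, 80), 0, tolerance = 1e-12)
})

test_that("condition labelings partition the array with the derived sizes", {
  arr <- speaker_array_fixture()
  o <- oracle_positions()
  # brute-force membership rules applied to the oracle table
  oracle_sizes <- list(
    left_vs_right = c(sum(o$az < 0 & o$az > -180 & o$el < 90),
                      sum(o$az > 0 & o$az < 180 & o$el < 90)),
    up_vs_down = c(sum(o$el > 0), sum(o$el < 0)),
    front_vs_back = c(sum(abs(o$az) < 90 & o$el < 90), sum(abs(o$az) > 90))
  )
  expected <- list(left_vs_right = c(5, 5), up_vs_down = c(5, 3),
                   front_vs_back = c(5, 4))
  for (cond in names(expected)) {
    expect_equal(oracle_sizes[[cond]], expected[[cond]], label = cond)
    lab <- condition_labels(arr, cond)
    expect_equal(length(lab$class_a), expected[[cond]][1], label = cond)
    expect_equal(length(lab$class_b), expected[[cond]][2], label = cond)
    all_ids <- sort(c(lab$class_a, lab$class_b, lab$excluded))
    expect_equal(all_ids, 0:15, label = cond)
  }
  expect_equal(length(condition_labels(arr, "left_vs_right")$excluded), 6)
  expect_error(condition_labels(arr, "near_vs_far"))
})

test_that("negating azimuth mirrors left/right and fixes the other labelings", {
  arr <- speaker_array_fixture()
  mirrored <- arr
  mirrored$azimuth_deg <- -arr$azimuth_deg
  mirrored$azimuth_deg[mirrored$azimuth_deg == -180] <- 180
  lr <- condition_labels(arr, "left_vs_right")
  lr_m <- condition_labels(mirrored, "left_vs_right")
  expect_setequal(lr_m$class_a, lr$class_b)
  expect_setequal(lr_m$class_b, lr$class_a)
  for (cond in c("up_vs_down", "front_vs_back")) {
    expect_identical(condition_labels(mirrored, cond),
                     condition_labels(arr, cond), label = cond)
  }
})

test_that("behavioral labels follow the button mapping", {
  expect_equal(behavioral_label(-45, 0), "left")
  expect_equal(behavioral_label(0, 90), "middle")
  expect_equal(behavioral_label(90, 45), "right")
  expect_equal(behavioral_label(c(0, 180), c(0, 0)), c("middle", "middle"))
  arr <- speaker_array_fixture()
  labs <- behavioral_label(arr$azimuth_deg, arr$elevation_deg)
  expect_equal(as.integer(table(factor(labs, c("left", "middle", "right")))),
               c(5, 6, 5))
})

test_that("speaker array and labeling round-trip through disk", {
  arr <- speaker_array_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_speaker_array(arr, tsv)
  expect_equal(read_speaker_array(tsv), arr)
  js <- withr::local_tempfile(fileext = ".json")
  lab <- condition_labels(arr, "up_vs_down")
  write_condition_labels(lab, js)
  expect_equal(read_condition_labels(js), lab)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_speaker_array(bad), "lacks columns")
})
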