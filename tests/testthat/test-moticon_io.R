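test_that("filenames parse to keys and round-trip", {
  k <- parse_filename("0lbs_sitting.txt")
  expect_equal(k$carried_weight, 0)
  expect_equal(k$activity, "sitting")
  expect_equal(k$iteration, 1L)

  k <- parse_filename("11lbs_standing2.txt")
  expect_equal(unclass(k)[c("carried_weight", "activity", "iteration")],
               list(carried_weight = 11, activity = "standing",
                    iteration = 2L))
  expect_equal(parse_filename("5lbs_walking3.txt")$iteration, 3L)

  # grammar is a bijection on the valid key space
  for (w in c(0, 2, 5, 11, 13)) {
    for (act in c("sitting", "standing", "walking")) {
      for (it in 1:3) {
        key <- recording_key(w, act, it)
        expect_equal(parse_filename(format_filename(key)), key)
      }
    }
  }
  expect_equal(format_filename(recording_key(0, "sitting", 1L)),
               "0lbs_sitting.txt")
})

test_that("malformed filenames fail naming the offending field", {
  expect_error(parse_filename("sitting_0lbs.txt"), "malformed")
  expect_error(parse_filename("5kg_standing.txt"), "malformed")
  expect_error(parse_filename("5lbs_running2.txt"), "activity")
  expect_error(parse_filename("5lbs_standing0.txt"), "iteration")
})

test_that("recordings round-trip through the text export", {
  spec <- synthetic_participant_spec("T01", 150, weight_class = c(0, 5),
                                     n_iterations = 2, duration = 0.2,
                                     seed = 11)
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  p <- file.path(d, "T01", "standing", "5lbs_standing2.txt")
  rec <- load_recording(p, participant_id = "T01")
  expect_s3_class(rec, "insole_recording")
  expect_identical(names(rec), insole_channels())
  expect_equal(nrow(rec), 10)
  expect_equal(attr(rec, "sampling_rate"), 50)
  expect_equal(attr(rec, "key")$carried_weight, 5)

  # write-then-read is value-exact
  p2 <- file.path(d, "copy.txt")
  write_recording(rec, p2)
  rec2 <- load_recording(p2, key = attr(rec, "key"), participant_id = "T01")
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("schema violations are rejected with informative errors", {
  d <- withr::local_tempdir()
  ok <- matrix(0, 3, 51)
  p <- file.path(d, "0lbs_standing.txt")

  write.table(ok[, 1:50], p, row.names = FALSE, col.names = FALSE)
  expect_error(load_recording(p), "expected 51 columns, found 50")

  bad <- as.data.frame(ok)
  bad[2, 7] <- "x"
  write.table(bad, p, row.names = FALSE, col.names = FALSE)
  expect_error(suppressWarnings(load_recording(p)), "parse|non-numeric")

  neg <- ok
  neg[1, 2] <- -1
  write.table(neg, p, row.names = FALSE, col.names = FALSE)
  expect_error(load_recording(p), "negative")
})

test_that("a header permits arbitrary column order", {
  spec <- synthetic_participant_spec("T01", 150, weight_class = c(0, 5),
                                     duration = 0.1, seed = 3)
  d <- withr::local_tempdir()
  generate_participant(spec, d)
  p <- file.path(d, "T01", "standing", "0lbs_standing.txt")
  rec <- load_recording(p)
  shuffled <- as.data.frame(rec)[, sample(51)]
  p2 <- file.path(d, "shuf.txt")
  data.table::fwrite(shuffled, p2, sep = "\t")
  rec2 <- load_recording(p2, key = attr(rec, "key"))
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("scan_dataset inventories a generated cohort and flags problems", {
  d <- withr::local_tempdir()
  generate_cohort(2, 0, out_dir = d, seed = 5,
                  base_spec = list(weight_class = c(0, 2), duration = 0.1,
                                   n_iterations = 2))
  inv <- scan_dataset(d)
  expect_s3_class(inv, "insole_inventory")
  expect_equal(nrow(inv$manifest), 2 * 2 * 2)
  expect_setequal(unique(inv$manifest$participant_id), c("P01", "P02"))
  expect_equal(sort(unique(inv$manifest$iteration)), 1:2)
  expect_equal(nrow(inv$ground_truth), 2)

  # unknown activity folders are warned about and skipped, not dropped
  dir.create(file.path(d, "P01", "jumping"))
  file.create(file.path(d, "P01", "jumping", "0lbs_standing.txt"))
  expect_warning(inv2 <- scan_dataset(d), "unknown activity")
  expect_equal(nrow(inv2$manifest), nrow(inv$manifest))

  # scan -> write -> scan is idempotent on the manifest
  expect_equal(suppressWarnings(scan_dataset(d))$manifest, inv2$manifest)
})

test_that("select_participants enforces complete iterations", {
  manifest <- expand.grid(participant_id = c("A", "B", "C"),
                          activity = "standing", carried_weight = c(0, 5, 9),
                          iteration = 1:2, stringsAsFactors = FALSE)
  manifest$path <- ""
  # B is missing the 5 lbs file in iteration 2; C has only one iteration
  manifest <- manifest[!(manifest$participant_id == "B" &
                           manifest$iteration == 2 &
                           manifest$carried_weight == 5), ]
  manifest <- manifest[!(manifest$participant_id == "C" &
                           manifest$iteration == 2), ]
  expect_equal(select_participants(manifest, 2L), "A")

  # with three complete iterations everyone qualifies at min 2
  m3 <- expand.grid(participant_id = c("A", "B"), activity = "standing",
                    carried_weight = c(0, 2), iteration = 1:3,
                    stringsAsFactors = FALSE)
  m3$path <- ""
  expect_equal(select_participants(m3, 2L), c("A", "B"))
  expect_error(select_participants(m3, 1L))
})
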