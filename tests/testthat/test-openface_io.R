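test_that("frame tables round-trip through write/read, padded headers and all", {
  clip <- make_clip(10, aus = list(AU20_r = seq(0, 4.5, length.out = 10),
                                   AU20_c = rep(c(0, 1), 5),
                                   AU05_c = rep(1, 10)))  # presence-only AU
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_table(clip, path)
  back <- read_frame_table(path, "P01", "truth")
  expect_equal(back$frames, clip$frames, tolerance = 1e-12)
  expect_equal(back$frames$AU05_r, rep(0, 10))  # zeros preserved

  # upstream dialect pads headers with spaces
  lines <- readLines(path)
  lines[1] <- gsub(",", ", ", lines[1])
  writeLines(lines, path)
  padded <- read_frame_table(path, "P01", "truth")
  expect_equal(padded$frames, clip$frames, tolerance = 1e-12)
})

test_that("reader enforces the column and row contracts", {
  clip <- make_clip(3)
  path <- withr::local_tempfile(fileext = ".csv")

  drop_col <- clip$frames[setdiff(names(clip$frames), "AU20_c")]
  data.table::fwrite(drop_col, path)
  expect_error(read_frame_table(path, "P01", "truth"), class = "MissingColumn")
  expect_error(read_frame_table(path, "P01", "truth"), "AU20_c")

  bad <- clip$frames
  bad$AU02_r <- c("0.1", "oops", "0.3")
  data.table::fwrite(bad, path)
  expect_error(read_frame_table(path, "P01", "truth"), class = "MalformedRow")

  data.table::fwrite(clip$frames[0, ], path)
  expect_error(read_frame_table(path, "P01", "truth"), class = "EmptyTable")
})

test_that("construction validates invariants", {
  f <- make_frames(3)
  f$AU01_r <- c(0, 6, 0)  # out of [0, 5]
  expect_error(clip_timeseries(f, "P01", "truth"), class = "MalformedRow")
  f <- make_frames(3)
  f$AU01_c <- c(0, 0.5, 1)  # non-binary presence
  expect_error(clip_timeseries(f, "P01", "truth"), class = "MalformedRow")
  f <- make_frames(3)
  f$frame <- c(1, 3, 2)  # not increasing
  expect_error(clip_timeseries(f, "P01", "truth"), class = "MalformedRow")
  expect_error(clip_timeseries(make_frames(3)[0, ], "P01", "truth"),
               class = "EmptyTable")
})

test_that("merge_clips concatenates, renumbers, and is additive/associative", {
  a <- make_clip(100, aus = list(AU20_r = rep(1, 100), AU20_c = rep(1, 100)))
  b <- make_clip(50)
  m <- merge_clips(list(a, b))
  expect_equal(nrow(m$frames), 150)
  expect_equal(m$frames$frame, 1:150)

  one <- merge_clips(list(a))
  expect_equal(one$frames, a$frames)

  c3 <- make_clip(20)
  left <- merge_clips(list(merge_clips(list(a, b)), c3))
  right <- merge_clips(list(a, merge_clips(list(b, c3))))
  expect_equal(left$frames, right$frames)

  lie <- make_clip(10, condition = "lie")
  expect_error(merge_clips(list(a, lie)), class = "MixedIdentity")
  other_rate <- make_clip(10, frame_rate = 25)
  expect_error(merge_clips(list(a, other_rate)), class = "MixedIdentity")
})

test_that("manifest reading assembles and merges clips", {
  dir <- withr::local_tempdir()
  clips <- list(make_clip(30, "P01", "truth"), make_clip(20, "P01", "truth"),
                make_clip(25, "P01", "lie"))
  # two truth files for P01 must merge into one clip
  for (i in seq_along(clips))
    write_frame_table(clips[[i]], file.path(dir, sprintf("c%d.csv", i)))
  man <- data.frame(path = sprintf("c%d.csv", 1:3),
                    participant_id = "P01",
                    condition = c("truth", "truth", "lie"), frame_rate = 30)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  got <- read_manifest(file.path(dir, "manifest.csv"))
  expect_length(got, 2)
  sizes <- sort(vapply(got, length, 0L))
  expect_equal(sizes, c(25L, 50L))
})
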