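test_that("segment and curve constructors enforce their invariants", {
  expect_error(segment("approach", c(1, 2), c(0, 0), 100),
               "strictly decreasing")
  expect_error(segment("retract", c(2, 1), c(0, 0), 100),
               "strictly increasing")
  expect_error(segment("approach", c(2, 1), c(0), 100), "equal length")
  expect_error(segment("approach", c(2, 1), c(0, NA), 100), "finite")
  expect_error(segment("approach", 2, 0, 100), "at least 2")
  s <- segment("approach", c(10, 5), c(0, 1), 4096)
  expect_error(force_curve(list(s), spring_constant = -1, velocity = 1,
                           temperature = 300, mode = "indentation",
                           curve_id = "x"),
               "spring_constant")
  expect_error(force_curve(list(s), 120, 5000, 300, "indentation", ""),
               "curve_id")
  p <- segment("pause", c(0, 0, 0), c(1, 1, 1), 100)
  expect_error(force_curve(list(p), 120, 5000, 300, "indentation", "x"),
               "approach or retract")
  fc <- force_curve(list(s), 120, 5000, 310, "indentation", "c1")
  expect_s3_class(fc, "force_curve")
  expect_identical(get_segment(fc, "approach")$kind, "approach")
  expect_null(get_segment(fc, "retract"))
})

test_that("a minimal two-point file round-trips and validation catches bad headers", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "min.fdc.tsv")
  writeLines(c("# curve_id = tiny", "# mode = indentation",
               "# spring_constant_pN_per_nm = 120",
               "# velocity_nm_per_s = 5000", "# temperature_K = 310",
               "# sampling_rate_Hz = 4096",
               "segment\theight_nm\tforce_pN",
               "approach\t10\t0", "approach\t5\t1"), f)
  cur <- read_curve(f)
  expect_length(cur$segments, 1L)
  expect_length(cur$segments[[1]]$height, 2L)

  bad <- file.path(dir, "bad.fdc.tsv")
  writeLines(c("# curve_id = tiny", "# mode = indentation",
               "# spring_constant_pN_per_nm = -3",
               "# velocity_nm_per_s = 5000", "# temperature_K = 310",
               "# sampling_rate_Hz = 4096",
               "segment\theight_nm\tforce_pN",
               "approach\t10\t0", "approach\t5\t1"), bad)
  expect_error(read_curve(bad), "spring_constant")

  ragged <- file.path(dir, "ragged.fdc.tsv")
  writeLines(c("# curve_id = tiny", "# mode = indentation",
               "# spring_constant_pN_per_nm = 120",
               "# velocity_nm_per_s = 5000", "# temperature_K = 310",
               "# sampling_rate_Hz = 4096",
               "segment\theight_nm\tforce_pN",
               "approach\t10\t0", "approach\t5"), ragged)
  expect_error(read_curve(ragged), "line 9")

  nonnum <- file.path(dir, "nonfinite.fdc.tsv")
  writeLines(c("# curve_id = tiny", "# mode = indentation",
               "# spring_constant_pN_per_nm = 120",
               "# velocity_nm_per_s = 5000", "# temperature_K = 310",
               "# sampling_rate_Hz = 4096",
               "segment\theight_nm\tforce_pN",
               "approach\t10\tNaN", "approach\t5\t1"), nonnum)
  expect_error(read_curve(nonnum), "line 8")
})

test_that("write -> read is the identity on 100 random curves, exactly", {
  dir <- withr::local_tempdir()
  set.seed(101)
  for (i in 1:100) {
    cur <- random_curve(sprintf("rt%03d", i))
    p <- file.path(dir, paste0(cur$curve_id, ".fdc.tsv"))
    write_curve(cur, p)
    back <- read_curve(p)
    expect_identical(back$curve_id, cur$curve_id)
    expect_identical(back$mode, cur$mode)
    expect_identical(back$spring_constant, cur$spring_constant)
    expect_identical(back$velocity, cur$velocity)
    expect_identical(back$temperature, cur$temperature)
    expect_identical(back$cell_id, cur$cell_id)
    expect_identical(back$group_label, cur$group_label)
    expect_length(back$segments, length(cur$segments))
    for (j in seq_along(cur$segments)) {
      expect_identical(back$segments[[j]]$kind, cur$segments[[j]]$kind)
      expect_identical(back$segments[[j]]$height, cur$segments[[j]]$height)
      expect_identical(back$segments[[j]]$force, cur$segments[[j]]$force)
      expect_identical(back$segments[[j]]$sampling_rate,
                       cur$segments[[j]]$sampling_rate)
    }
    expect_equal(back$annotations$true_E_kPa, cur$annotations$true_E_kPa)
    expect_identical(back$annotations$note, cur$annotations$note)
  }
})

test_that("segment blocks keep their order and count through serialization", {
  dir <- withr::local_tempdir()
  segs <- list(segment("approach", c(10, 5, 1), c(0, 0, 1), 4096),
               segment("pause", c(1, 1), c(1, 1), 4096),
               segment("retract", c(1, 5, 10), c(1, 0, 0), 2048))
  cur <- force_curve(segs, 120, 5000, 310, "adhesion", "threeseg")
  p <- file.path(dir, "threeseg.fdc.tsv")
  write_curve(cur, p)
  txt <- readLines(p)
  expect_true(any(grepl("^# curve_id = threeseg$", txt)))
  # all metadata fields appear in the header
  for (key in c("mode", "spring_constant_pN_per_nm", "velocity_nm_per_s",
                "temperature_K", "sampling_rate_Hz"))
    expect_true(any(startsWith(txt, paste0("# ", key))))
  back <- read_curve(p)
  expect_identical(vapply(back$segments, `[[`, character(1), "kind"),
                   c("approach", "pause", "retract"))
  # differing per-segment sampling rates survive
  expect_identical(back$segments[[3]]$sampling_rate, 2048)
})

test_that("manifests parse, reject duplicates, and defer missing files", {
  dir <- withr::local_tempdir()
  c1 <- random_curve("m1"); c2 <- random_curve("m2")
  write_curve(c1, file.path(dir, "m1.fdc.tsv"))
  write_curve(c2, file.path(dir, "m2.fdc.tsv"))
  mf <- file.path(dir, "manifest.csv")
  df <- data.frame(path = c("m1.fdc.tsv", "m2.fdc.tsv", "gone.fdc.tsv"),
                   group_label = c("Q", "R", "Q"),
                   cell_id = c("a", "b", "c"),
                   mode = c1$mode)
  write.csv(df, mf, row.names = FALSE)
  man <- read_manifest(mf)
  expect_equal(nrow(man), 3L)
  loaded <- load_manifest_curves(man, base_dir = dir)
  expect_length(loaded$curves, 2L)
  expect_equal(nrow(loaded$errors), 1L)
  expect_match(loaded$errors$path, "gone")
  # group labels come from the manifest
  expect_identical(loaded$curves[[1]]$group_label, "Q")

  empty <- file.path(dir, "empty.csv")
  write.csv(df[0, ], empty, row.names = FALSE)
  expect_error(read_manifest(empty), "no entries")

  dup <- file.path(dir, "dup.csv")
  write.csv(df[c(1, 1), ], dup, row.names = FALSE)
  expect_error(read_manifest(dup), "duplicate")
})
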