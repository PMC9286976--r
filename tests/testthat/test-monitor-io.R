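test_that("multibeam fixture parses to heights via h = 3p", {
  p <- write_multibeam_fixture(c("0\t1\t1", "1\t1\t2", "2\t1\t2"))
  trajs <- read_monitor_file(p, "multibeam_tsv")
  expect_length(trajs, 1)
  expect_equal(trajs[[1]]$heights_mm, c(3, 6, 6))
  expect_false(trajs[[1]]$flagged)
})

test_that("multibeam validation errors name the offending line", {
  p <- write_multibeam_fixture(c("0\t1\t1", "1\t1\t18"))
  expect_error(read_monitor_file(p, "multibeam_tsv"), "line 3.*position index 18")
  p2 <- write_multibeam_fixture(c("0\t1\t1", "1\t1"))
  expect_error(read_monitor_file(p2, "multibeam_tsv"), "line 3.*3 tab-delimited")
  p3 <- write_multibeam_fixture(c("0\t1\t1", "1\t1\tx"))
  expect_error(read_monitor_file(p3, "multibeam_tsv"), "line 3")
  p4 <- write_multibeam_fixture(c("2\t1\t1", "1\t1\t2"))
  expect_error(read_monitor_file(p4, "multibeam_tsv"), "non-monotone")
})

test_that("gap policy holds the last position and flags long gaps", {
  # missing second 2 inherits position 2; 1 s gap is not flagged
  p <- write_multibeam_fixture(c("0\t1\t1", "1\t1\t2", "3\t1\t4"))
  tr <- read_monitor_file(p, "multibeam_tsv")[[1]]
  expect_equal(tr$heights_mm, c(3, 6, 6, 12))
  expect_false(tr$flagged)
  # 6 s gap exceeds the 5 s policy and flags the fly
  p2 <- write_multibeam_fixture(c("0\t1\t1", "7\t1\t4"))
  tr2 <- read_monitor_file(p2, "multibeam_tsv")[[1]]
  expect_equal(tr2$heights_mm, c(3, 3, 3, 3, 3, 3, 3, 12))
  expect_true(tr2$flagged)
  # NA position rows are gaps too
  p3 <- write_multibeam_fixture(c("0\t1\t1", "1\t1\tNA", "2\t1\t3"))
  expect_equal(read_monitor_file(p3, "multibeam_tsv")[[1]]$heights_mm, c(3, 3, 9))
})

test_that("manifest metadata is joined onto tubes", {
  p <- write_multibeam_fixture(c("0\t1\t1", "1\t1\t2", "0\t2\t17", "1\t2\t13"))
  mf <- system.file("extdata", "manifest_example.dcf", package = "flyclimb")
  trajs <- read_monitor_file(p, "multibeam_tsv", manifest = mf)
  expect_setequal(names(trajs), c("ctrl_A", "park_B"))
  expect_equal(trajs$park_B$genotype, "park25")
  expect_equal(trajs$park_B$dose_ug_per_ml, 9)
  expect_equal(trajs$park_B$heights_mm, c(51, 39))
})

test_that("canonical round-trip is the identity on valid trajectories", {
  set.seed(7)
  for (rep in 1:10) {
    trajs <- lapply(seq_len(sample(1:4, 1)), function(i)
      random_trajectory(sample(5:80, 1), id = paste0("fly", i)))
    names(trajs) <- vapply(trajs, function(x) x$fly_id, character(1))
    path <- tempfile(fileext = ".tsv")
    write_canonical(trajs, path)
    back <- read_monitor_file(path, "canonical_table")
    expect_equal(length(back), length(trajs))
    for (id in names(trajs)) {
      expect_equal(back[[id]]$heights_mm, trajs[[id]]$heights_mm)
      expect_equal(back[[id]]$genotype, trajs[[id]]$genotype)
      expect_equal(back[[id]]$age_days, trajs[[id]]$age_days)
      expect_equal(back[[id]]$dose_ug_per_ml, trajs[[id]]$dose_ug_per_ml)
      expect_equal(back[[id]]$start_day, trajs[[id]]$start_day)
    }
  }
})

test_that("write_canonical on an empty set yields a header-only file", {
  path <- tempfile(fileext = ".tsv")
  write_canonical(list(), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^fly_id\tt_s\theight_mm")
  expect_length(read_monitor_file(path, "canonical_table"), 0)
})

test_that("one 3-sample trajectory writes 3 data rows", {
  path <- tempfile(fileext = ".tsv")
  write_canonical(trajectory("f1", c(3, 6, 9)), path)
  expect_length(readLines(path), 4)  # header + 3
})

test_that("canonical reader enforces its schema and grid", {
  path <- tempfile(fileext = ".tsv")
  writeLines("fly_id\tt_s", path)
  expect_error(read_monitor_file(path, "canonical_table"), "missing columns")
  df <- as.data.frame(trajectory("f1", c(3, 6)))
  df$height_mm[2] <- 7
  path2 <- tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_monitor_file(path2, "canonical_table"), "grid")
})

test_that("flight tables parse strict booleans", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("fly_id\tgenotype\tdose_ug_per_ml\tstart_day\tflew",
               "a\tcontrol\t0\tNA\tyes",
               "b\tpark25\t9\t0\tno"), path)
  fl <- read_flight_table(path)
  expect_equal(fl$flew, c(TRUE, FALSE))
  expect_equal(fl$genotype, c("control", "park25"))

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("fly_id\tgenotype\tdose_ug_per_ml\tstart_day\tflew",
               "a\tcontrol\t0\tNA\tmaybe"), path2)
  expect_error(read_flight_table(path2), "ambiguous.*maybe")

  path3 <- tempfile(fileext = ".tsv")
  writeLines("fly_id\tgenotype\tdose_ug_per_ml\tstart_day\tflew", path3)
  expect_identical(nrow(read_flight_table(path3)), 0L)
})

test_that("flight table round-trips through write_flight_table", {
  fl <- simulate_flight(0.5, 20, seed = 3, genotype = "park25",
                        dose_ug_per_ml = 4.5, start_day = 2L)
  path <- tempfile(fileext = ".csv")
  write_flight_table(fl, path)
  back <- read_flight_table(path)
  expect_equal(back$flew, fl$flew)
  expect_equal(back$start_day, fl$start_day)
})
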