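test_that("load_depth_windows computes per-window arithmetic means", {
  # constant depth 10 over 15 kb -> three windows of mean 10
  prof <- load_depth_windows(depth_table(0, 15000, 10), survey = c(1, 15000),
                             window_size = 5000)
  expect_equal(nrow(prof$windows), 3)
  expect_equal(prof$windows$mean_depth, rep(10, 3))
  expect_equal(prof$windows$start, c(1, 5001, 10001))

  # depth 10 over first half of one window, absent bases count as 0
  prof2 <- load_depth_windows(depth_table(0, 2500, 10), survey = c(1, 5000),
                              window_size = 5000)
  expect_equal(prof2$windows$mean_depth, 5.0)

  # per-base Poisson depths: mean equals independent sum/5000
  set.seed(42)
  d <- rpois(5000, 8)
  perbase <- data.frame(chrom = "Y", pos = 1:5000, depth = d)
  prof3 <- load_depth_windows(perbase, survey = c(1, 5000), window_size = 5000)
  expect_equal(prof3$windows$mean_depth, sum(d) / 5000)

  # rows spanning several windows distribute mass by overlap
  prof4 <- load_depth_windows(depth_table(2000, 12000, 6), survey = c(1, 15000),
                              window_size = 5000)
  expect_equal(prof4$windows$mean_depth, c(6 * 3000, 6 * 5000, 6 * 2000) / 5000)
})

test_that("load_depth_windows rejects malformed and empty sources", {
  expect_error(load_depth_windows(data.frame()[0, ]), "empty")
  bad <- data.frame(chrom = "Y", start = c(0, 5000), end = c(5000, "oops"),
                    depth = c(3, 3))
  expect_error(load_depth_windows(bad, survey = c(1, 10000)), "line 2")
  expect_error(load_depth_windows(depth_table(0, 100, 5), survey = c(1, 100),
                                  window_size = 0), "window_size")
})

test_that("region_depth_ratio matches constructed factors and errors cleanly", {
  rs <- toy_regions()
  uniform <- load_depth_windows(depth_table(0, 100000, 12), survey = rs$survey_interval)
  r1 <- region_depth_ratio(uniform, rs)
  expect_equal(unname(r1$per_region_ratio), rep(1, 4))
  expect_equal(r1$combined_ratio, 1.0)

  # depth 2d inside all four regions (window-aligned), d elsewhere
  rows <- rbind(depth_table(0, 100000, 10),
                do.call(rbind, lapply(rs$regions, function(iv)
                  depth_table(iv[1] - 1, iv[2], 10))))
  doubled <- load_depth_windows(rows, survey = rs$survey_interval, window_size = 1000)
  r2 <- region_depth_ratio(doubled, rs)
  expect_equal(r2$combined_ratio, 2.0, tolerance = 1e-12)

  # uninformative sample: zero reference depth
  zero_ref <- load_depth_windows(depth_table(0, 70000, 10),
                                 survey = rs$survey_interval)
  expect_error(region_depth_ratio(zero_ref, rs), "uninformative")

  # region outside the profile span is named in the error
  narrow <- region_set(regions = list(far = c(5e6, 6e6)),
                       reference_interval = c(1e6, 2e6),
                       survey_interval = c(1, 1e7))
  prof <- load_depth_windows(depth_table(0, 3e6, 10), survey = c(1, 3e6))
  expect_error(region_depth_ratio(prof, narrow), "far")
})

test_that("region ratios equal brute-force per-base recomputation", {
  rs <- toy_regions()
  set.seed(7)
  # random per-window depths on a 1 kb grid (<= 100 windows, window-aligned)
  starts <- seq(0, 99000, by = 1000)
  tab <- data.frame(chrom = "Y", start = starts, end = starts + 1000,
                    depth = runif(100, 5, 20))
  prof <- load_depth_windows(tab, survey = rs$survey_interval, window_size = 1000)
  got <- region_depth_ratio(prof, rs)

  # oracle: expand to per-base depth, average bases directly
  perbase <- rep(tab$depth, each = 1000)
  base_mean <- function(iv) mean(perbase[iv[1]:iv[2]])
  ref <- base_mean(rs$reference_interval)
  for (nm in names(rs$regions)) {
    expect_equal(unname(got$per_region_ratio[nm]),
                 base_mean(rs$regions[[nm]]) / ref, tolerance = 1e-12)
  }
  all_bases <- unlist(lapply(rs$regions, function(iv) iv[1]:iv[2]))
  expect_equal(got$combined_ratio, mean(perbase[all_bases]) / ref,
               tolerance = 1e-12)
})

test_that("combined ratio is invariant to uniform depth scaling", {
  rs <- toy_regions()
  set.seed(11)
  starts <- seq(0, 99000, by = 5000)
  tab <- data.frame(chrom = "Y", start = starts, end = starts + 5000,
                    depth = runif(20, 1, 30))
  for (c_scale in c(0.1, 3, 250)) {
    tab2 <- tab; tab2$depth <- tab$depth * c_scale
    a <- region_depth_ratio(load_depth_windows(tab, survey = rs$survey_interval), rs)
    b <- region_depth_ratio(load_depth_windows(tab2, survey = rs$survey_interval), rs)
    expect_equal(a$combined_ratio, b$combined_ratio, tolerance = 1e-12)
    expect_equal(a$per_region_ratio, b$per_region_ratio, tolerance = 1e-12)
  }
})

test_that("rough_copy_number applies the 7-copy-equivalent rule", {
  expect_equal(rough_copy_number(1.0), 6)    # reference structure
  expect_equal(rough_copy_number(0.62), 3)   # low end of observed ratios
  expect_equal(rough_copy_number(1.89), 12)  # high end
  expect_equal(rough_copy_number(2.0), 13)   # 2 x 7 - 1
  expect_equal(rough_copy_number(0), 0)
  expect_error(rough_copy_number(-0.1), ">= 0")
  # custom model
  expect_equal(rough_copy_number(1.5, copy_model(10, 2)), 13)
})

test_that("flag_curated detects flank deviations", {
  rs <- toy_regions()
  flat <- load_depth_windows(depth_table(0, 100000, 10),
                             survey = rs$survey_interval, window_size = 1000)
  expect_true(flag_curated(flat, rs, flank_bp = 10000)$pass)

  # one flank window at 2x median
  bump <- flat
  i <- which(bump$windows$start == 13001)  # inside the left flank of region 1
  bump$windows$mean_depth[i] <- 20
  res <- flag_curated(bump, rs, flank_bp = 10000, max_rel_dev = 0.25)
  expect_false(res$pass)
  expect_equal(res$offending$start, 13001)

  # profile confined to the region block -> no flank windows -> error
  tiny <- load_depth_windows(depth_table(20000, 67000, 10),
                             survey = c(20001, 67000), window_size = 1000)
  expect_error(flag_curated(tiny, rs, flank_bp = 10000), "flank")
})

test_that("flag_curated recovers exactly the samples with planted flank duplications", {
  rs <- toy_regions()
  truth <- rep(FALSE, 100); truth[c(3, 12, 27, 31, 44, 58, 66, 71, 89, 97)] <- TRUE
  flank_lo <- c(10001, 20000)  # inside the left flank
  got <- vapply(seq_len(100), function(i) {
    prof <- emulate_depth(c(r = 8), base_depth = 10, noise = "none",
                          regions = rs, window_size = 1000,
                          sample_id = sprintf("s%03d", i))
    if (truth[i]) {
      sel <- prof$windows$start >= flank_lo[1] & prof$windows$end <= flank_lo[2]
      prof$windows$mean_depth[sel] <- prof$windows$mean_depth[sel] * 2
    }
    !flag_curated(prof, rs, flank_bp = 15000)$pass
  }, logical(1))
  expect_identical(got, truth)
})

test_that("BED round trip is bit-exact and validates structure", {
  rs <- region_set()
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  write_regions_bed(rs, path)
  rs2 <- read_regions_bed(path)
  expect_identical(rs2$regions, rs$regions)
  expect_identical(rs2$reference_interval, rs$reference_interval)

  expect_error(region_set(regions = list(a = c(10, 100), b = c(50, 200)),
                          reference_interval = c(300, 400),
                          survey_interval = c(1, 1000)), "overlap")
  expect_error(region_set(regions = list(a = c(10, 100)),
                          reference_interval = c(50, 400),
                          survey_interval = c(1, 1000)), "overlap")
})
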