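test_that("an empty config yields background-only channels and no ground truth", {
  cfg <- fdl_sim_config(0.5, n_cells = 0, noise_sd = 0,
                        image_height_px = 64, image_width_px = 64)
  sim <- generate_fdl_image(cfg)
  expect_equal(nrow(sim$ground_truth), 0)
  expect_true(all(sim$image$red == cfg$background_level))
  expect_true(all(sim$image$green == cfg$background_level))
})

test_that("a pure-red config leaves the green channel at background inside cells", {
  cfg <- fdl_sim_config(1.0, red_fraction_sd = 0, noise_sd = 0,
                        n_cells = 5, image_height_px = 128,
                        image_width_px = 128,
                        cell_radius_px_range = c(8, 10))
  sim <- generate_fdl_image(cfg)
  expect_true(all(sim$image$green == cfg$background_level))
  expect_true(any(sim$image$red > cfg$background_level))
  expect_true(all(sim$ground_truth$true_red_fraction == 1))
})

test_that("ground-truth red fractions center on the configured group mean", {
  cfg <- fdl_sim_config(0.946, red_fraction_sd = 0.087, n_cells = 50,
                        image_height_px = 640, image_width_px = 640,
                        seed = 7)
  sim <- generate_fdl_image(cfg)
  f <- sim$ground_truth$true_red_fraction
  expect_equal(length(f), 50)
  expect_lt(abs(mean(f) - 0.946), 3 * sd(f) / sqrt(50))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("identical config and seed reproduce the image bitwise", {
  cfg <- fdl_sim_config(0.4, n_cells = 8, image_height_px = 128,
                        image_width_px = 128,
                        cell_radius_px_range = c(6, 9), seed = 11)
  a <- generate_fdl_image(cfg)
  b <- generate_fdl_image(cfg)
  expect_identical(a$image$red, b$image$red)
  expect_identical(a$image$green, b$image$green)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("noiseless in-disk fractions match ground truth within quantization", {
  cfg <- fdl_sim_config(0.349, red_fraction_sd = 0.233, noise_sd = 0,
                        n_cells = 10, image_height_px = 256,
                        image_width_px = 256,
                        cell_radius_px_range = c(8, 12), seed = 3)
  sim <- generate_fdl_image(cfg)
  gt <- sim$ground_truth
  bg <- cfg$background_level
  for (i in seq_len(nrow(gt))) {
    # probe the disk center pixel block (well inside the cell)
    r <- gt$center_row[i]; c <- gt$center_col[i]
    red <- sim$image$red[r, c] - bg
    green <- sim$image$green[r, c] - bg
    expect_lt(abs(red / (red + green) - gt$true_red_fraction[i]), 1 / 255)
  }
})

test_that("sample mean of true fractions converges with cell count", {
  dev_at_n <- function(n_cells, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- fdl_sim_config(0.349, red_fraction_sd = 0.233,
                            n_cells = n_cells, image_height_px = 512,
                            image_width_px = 512,
                            cell_radius_px_range = c(3, 4),
                            min_gap_px = 1, seed = s)
      abs(mean(generate_fdl_image(cfg)$ground_truth$true_red_fraction) -
            0.349)
    }, numeric(1)))
  }
  expect_lt(dev_at_n(400, 1:6), dev_at_n(25, 1:6))
})

test_that("an overcrowded config fails with an explicit error", {
  cfg <- fdl_sim_config(0.5, n_cells = 40, image_height_px = 64,
                        image_width_px = 64,
                        cell_radius_px_range = c(10, 12))
  expect_error(generate_fdl_image(cfg), "image too crowded")
})

test_that("config invariants are enforced", {
  expect_error(fdl_sim_config(1.2), "mean_red_fraction")
  expect_error(fdl_sim_config(0.5, cell_radius_px_range = c(0, 3)),
               "cell_radius_px_range")
  expect_error(fdl_sim_config(0.5, red_fraction_sd = -1), "red_fraction_sd")
  expect_error(fdl_sim_config(0.5, image_height_px = 16,
                              cell_radius_px_range = c(10, 12)),
               "does not fit")
})

test_that("group set writes TIFF pairs, ground truth and a manifest", {
  out <- withr::local_tempdir()
  cfgs <- tiny_fdl_configs(seed = 2)
  man <- generate_fdl_group_set(cfgs, out, cases_per_group = 1,
                                images_per_case = 2)
  expect_equal(nrow(man), 8)
  expect_equal(length(list.files(out, pattern = "\\.tif$")), 16)
  expect_setequal(unique(man$group), group_levels())
  gt <- read_table(file.path(out, "ground_truth.csv"))
  expect_equal(nrow(gt), 8 * 6)

  # same seed again -> byte-identical files
  out2 <- withr::local_tempdir()
  generate_fdl_group_set(tiny_fdl_configs(seed = 2), out2,
                         cases_per_group = 1, images_per_case = 2)
  for (f in list.files(out, pattern = "\\.tif$")) {
    expect_identical(readBin(file.path(out, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
})

test_that("chromogenic cohorts follow the configured score distribution", {
  all0 <- generate_chr_cohort(chr_sim_config(2, 50, c(1, 0, 0, 0)))
  expect_true(all(all0$score == 0))
  all3 <- generate_chr_cohort(chr_sim_config(1, 50, c(0, 0, 0, 1)))
  expect_equal(case_mean_score(all3), 3.0)

  # pooled neuron counts 82/538/418/177 -> expectation 1905/1215
  probs <- c(82, 538, 418, 177) / 1215
  expected <- sum(0:3 * probs)
  big <- generate_chr_cohort(chr_sim_config(1, 100000, probs, seed = 9))
  se <- sd(big$score) / sqrt(nrow(big))
  expect_lt(abs(mean(big$score) - expected), 3 * se)

  same <- generate_chr_cohort(chr_sim_config(3, 40, probs, seed = 5))
  again <- generate_chr_cohort(chr_sim_config(3, 40, probs, seed = 5))
  expect_identical(same, again)
})

test_that("invalid score probability vectors are rejected", {
  expect_error(chr_sim_config(1, 10, c(0.5, 0.5)), "length-4")
  expect_error(chr_sim_config(1, 10, c(0.7, 0.5, -0.2, 0)), "nonnegative")
  expect_error(chr_sim_config(1, 10, c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
})

test_that("range-spanning cohorts put case means inside their group range", {
  sim <- generate_chr_group_cohort(seed = 21)
  cm <- case_mean_scores(sim$scores)
  cm <- merge(cm, sim$cases, by = "case_id")
  rng <- chr_group_ranges()
  for (g in rng$group) {
    m <- cm$mean_score[cm$group == g]
    lo <- rng$lo[rng$group == g]; hi <- rng$hi[rng$group == g]
    # neuron-level sampling noise around the target: allow 4 SE slack
    slack <- 4 * 0.5 / sqrt(300)
    expect_true(all(m > lo - slack & m < hi + slack))
    expect_gt(diff(range(m)), (hi - lo) * 0.3)  # spans the range
  }
  expect_identical(sim, generate_chr_group_cohort(seed = 21))
})
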