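test_that("degenerate noise yields identical cells at the configured baselines", {
  cfg <- small_config(n_strains = 5, n_events = 50, sigma_strain = 0,
                      sigma_cell = 0)
  scr <- generate_screen(cfg)
  expect_true(all(scr$events$fsc == cfg$baseline_size))
  expect_true(all(scr$events$mvenus == cfg$baseline_fluor))
  expect_true(all(scr$events$mcherry == cfg$baseline_fluor))
})

test_that("identical config and seed reproduce the screen bit-for-bit", {
  cfg <- small_config(n_strains = 20, n_events = 100, seed = 7,
                      effect_classes = scaled_effect_classes(20))
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_screen(s1, d1)
  write_screen(s2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("adding strains does not perturb earlier strains' events", {
  a <- generate_screen(small_config(n_strains = 10, n_events = 60, seed = 3))
  b <- generate_screen(small_config(n_strains = 30, n_events = 60, seed = 3))
  first <- a$events[a$events$strain_id == "ko0005", ]
  second <- b$events[b$events$strain_id == "ko0005", ]
  expect_equal(first$fsc, second$fsc)
  expect_equal(first$mvenus, second$mvenus)
})

test_that("per-strain channel means follow the lognormal closed form", {
  # log fluorescence variance is (1 + gamma^2) * sigma_cell^2: the channel
  # inherits the cell's own size noise through the coupling exponent and
  # adds its independent channel noise
  sigma <- 0.2
  cfg <- small_config(n_strains = 6, n_events = 2000, seed = 11,
                      sigma_strain = 0, sigma_cell = sigma)
  scr <- generate_screen(cfg)
  expected <- cfg$baseline_fluor *
    exp((1 + cfg$coupling_exponent^2) * sigma^2 / 2)
  for (id in unique(scr$events$strain_id)) {
    x <- scr$events$mvenus[scr$events$strain_id == id]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected), 3 * se)
  }
})

test_that("with gamma = 1 and no gene-specific effect the channels have equal means", {
  cfg <- small_config(n_strains = 8, n_events = 2000, seed = 5)
  scr <- generate_screen(cfg)
  for (id in unique(scr$events$strain_id)) {
    v <- scr$events$mvenus[scr$events$strain_id == id]
    c_ <- scr$events$mcherry[scr$events$strain_id == id]
    se <- sqrt(var(v) / length(v) + var(c_) / length(c_))
    expect_lt(abs(mean(v) - mean(c_)), 4 * se)
  }
})

test_that("seeded effects shift strains monotonically", {
  make <- function(dS, dG) {
    ec <- list(list(system = "DB", n = 3L, dS = dS, dE = 0, dG = dG))
    scr <- generate_screen(small_config(n_strains = 10, n_events = 400,
                                        seed = 9, effect_classes = ec,
                                        clustered_layout = TRUE))
    ev <- scr$events[scr$events$strain_id == "ko0001", ]
    list(fsc = mean(ev$fsc), ratio = mean(ev$mvenus) / mean(ev$mcherry))
  }
  base <- make(0, 0); up <- make(0.4, 0); more <- make(0.8, 0)
  expect_lt(base$fsc, up$fsc)
  expect_lt(up$fsc, more$fsc)
  g0 <- make(0, 0); g1 <- make(0, 0.3); g2 <- make(0, 0.6)
  expect_lt(g0$ratio, g1$ratio)
  expect_lt(g1$ratio, g2$ratio)
})

test_that("null strains are exchangeable under label permutation", {
  cfg <- small_config(n_strains = 120, n_events = 300, seed = 21)
  scr <- generate_screen(cfg)
  ss <- summarize_screen(scr$events, min_events = 100)
  ss <- ss[!startsWith(ss$strain_id, "WT"), ]
  set.seed(31)
  fake <- sample(rep(c("A", "B"), length.out = nrow(ss)))
  obs <- abs(mean(ss$S[fake == "A"]) - mean(ss$S[fake == "B"]))
  null <- replicate(999, {
    p <- sample(fake)
    abs(mean(ss$S[p == "A"]) - mean(ss$S[p == "B"]))
  })
  p <- (1 + sum(null >= obs)) / 1000
  expect_gt(p, 0.01)
})

test_that("replicate sets are keyed by strain and day with day-level shifts", {
  cfg <- small_config(n_strains = 30, n_events = 150, seed = 13)
  subset <- sprintf("ko%04d", 1:12)
  reps <- generate_replicate_set(cfg, subset, n_days = 4)
  expect_equal(nrow(unique(reps[, c("strain_id", "day")])), 48L)
  expect_setequal(unique(reps$strain_id), subset)

  # with no replicate or cell noise, days are identical by construction
  cfg0 <- small_config(n_strains = 6, n_events = 50, seed = 13,
                       sigma_cell = 0, sigma_replicate = 0)
  r0 <- generate_replicate_set(cfg0, "ko0002", n_days = 3)
  by_day <- split(r0$fsc, r0$day)
  expect_equal(by_day[[1]], by_day[[2]])
  expect_equal(by_day[[2]], by_day[[3]])

  expect_error(generate_replicate_set(cfg, character(0), 2), "empty")
  expect_error(generate_replicate_set(cfg, "ko0001", 1), "n_days")
  expect_error(generate_replicate_set(cfg, "nope", 2), "unknown strain")
})

test_that("invalid configurations are rejected", {
  expect_error(screen_config(n_strains = 10,
                             effect_classes = default_effect_classes()),
               "exceed")
  expect_error(screen_config(sigma_cell = -1), "SDs")
  expect_error(screen_config(n_strains = 0), "positive")
})

test_that("layout has one row per strain plus controls, filled row-major", {
  cfg <- small_config(n_strains = 200, n_events = 10, n_wt_controls = 2)
  scr <- generate_screen(cfg)
  expect_equal(nrow(scr$layout), 202L)
  expect_equal(scr$layout$plate[1:96], rep(1L, 96))
  expect_equal(scr$layout$well[1:3], c("A01", "A02", "A03"))
  expect_equal(scr$layout$well[13], "B01")
  expect_equal(sum(scr$layout$is_control), 2L)
})

test_that("delimited round trip preserves summaries and metadata", {
  cfg <- small_config(n_strains = 4, n_events = 250, seed = 17)
  scr <- generate_screen(cfg)
  dir <- withr::local_tempdir()
  files <- write_screen(scr, dir, format = "delimited")
  layout <- data.table::fread(file.path(dir, "layout.tsv"))
  expect_equal(nrow(layout), 6L)
  back <- data.table::rbindlist(lapply(files, read_events, layout = layout))
  orig <- summarize_screen(scr$events, min_events = 100)
  rt <- summarize_screen(back, min_events = 100)
  rt <- rt[match(orig$strain_id, rt$strain_id), ]
  expect_equal(rt$S, orig$S, tolerance = 1e-9)
  expect_equal(rt$mV, orig$mV, tolerance = 1e-9)
})

test_that("fcs output parses as FCS 3.x with the three named channels", {
  cfg <- small_config(n_strains = 3, n_events = 120, seed = 23)
  scr <- generate_screen(cfg)
  dir <- withr::local_tempdir()
  files <- write_screen(scr, dir, format = "fcs")
  m <- read_fcs(files[1])
  expect_equal(colnames(m), c("FSC-H", "mVenus", "mCherry"))
  ev <- read_events(files[1])
  first <- scr$events[scr$events$plate == 1 & scr$events$well == "A01", ]
  expect_equal(ev$fsc, first$fsc, tolerance = 1e-6)
  expect_equal(ev$mcherry, first$mcherry, tolerance = 1e-6)
  expect_error(write_screen(scr, dir, format = "parquet"))
})

test_that("configurations round-trip through the key/value file", {
  cfg <- small_config(n_strains = 50, n_events = 77, seed = 3,
                      effect_classes = scaled_effect_classes(50))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_screen_config(cfg, path)
  back <- read_screen_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
})
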