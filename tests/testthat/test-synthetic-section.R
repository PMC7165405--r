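test_that("coverage extremes render exactly: full rings and empty rings", {
  spec <- section_spec(n_fibres = 6, primary_coverage_fractions = c(1, 1, 1, 0, 0, 0),
                       noise_sd = 0, seed = 3)
  sec <- generate_section(spec)
  expect_equal(sec$truth$true_coverage_fraction, c(1, 1, 1, 0, 0, 0))
  mask <- get_channel(sec$stack, "mask")
  prim <- get_channel(sec$stack, "primary")
  for (i in 1:3) {   # full coverage: every ring pixel carries the arc intensity
    ring <- sec$labels == i & mask == spec$mask_ring_intensity
    expect_true(all(prim[ring] == spec$primary_arc_intensity))
  }
  for (i in 4:6) {   # zero coverage: ring stays at background in the primary
    ring <- sec$labels == i & mask == spec$mask_ring_intensity
    expect_true(all(prim[ring] == spec$sarcoplasm_background))
  }
})

test_that("zero-noise sarcoplasm pixels equal the background exactly", {
  spec <- section_spec(n_fibres = 4, primary_coverage_fractions = 0.5,
                       sarcoplasm_background = 8000, noise_sd = 0, seed = 5)
  sec <- generate_section(spec)
  mask <- get_channel(sec$stack, "mask")
  prim <- get_channel(sec$stack, "primary")
  sarco <- sec$labels > 0 & mask == spec$sarcoplasm_background
  expect_gt(sum(sarco), 1000)
  expect_true(all(prim[sarco] == 8000))
})

test_that("noisy sarcoplasm sample mean is within 3 SE of the background", {
  spec <- section_spec(n_fibres = 1, primary_coverage_fractions = 0.5,
                       sarcoplasm_background = 8000, noise_sd = 500, seed = 8)
  sec <- generate_section(spec)
  # locate the sarcoplasm from the noise-free render of the same spec
  spec0 <- spec; spec0$noise_sd <- 0
  sec0 <- generate_section(spec0)
  mask0 <- get_channel(sec0$stack, "mask")
  sarco <- sec0$labels == 1 & mask0 == spec$sarcoplasm_background
  v <- get_channel(sec$stack, "primary")[sarco]
  se <- 500 / sqrt(length(v))
  expect_lt(abs(mean(v) - 8000), 3 * se)
})

test_that("no emitted pixel is negative or above full scale", {
  spec <- section_spec(n_fibres = 4, primary_coverage_fractions = 1,
                       primary_arc_intensity = 65000, noise_sd = 3000, seed = 2)
  sec <- generate_section(spec)
  expect_gte(min(sec$stack$pixels), 0)
  expect_lte(max(sec$stack$pixels), 65535)
})

test_that("identical seeds give bit-identical sections", {
  spec <- section_spec(n_fibres = 6, seed = 77)
  a <- generate_section(spec)
  b <- generate_section(spec)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$labels, b$labels)
  expect_equal(a$truth$true_coverage_fraction, b$truth$true_coverage_fraction)
})

test_that("impossible placement fails naming the first offending fibre", {
  spec <- section_spec(n_fibres = 9, canvas_size = c(60, 60), seed = 1)
  expect_error(generate_section(spec), "fibre 1")
})

test_that("rendered ring area matches the analytic annulus-arc area within 5%", {
  fx <- fixture_small()
  spec0 <- fx$spec; spec0$noise_sd <- 0
  sec <- generate_section(spec0)
  mask <- get_channel(sec$stack, "mask")
  for (i in c(1, 7, 13, 19, 25)) {
    rendered <- sum(sec$labels == i & mask == spec0$mask_ring_intensity)
    t_px <- sec$truth$ring_thickness_um[i] / spec0$pixel_size
    analytic <- analytic_ring_area_px(sec$truth$polygon[[i]],
                                      c(sec$truth$centroid_y[i], sec$truth$centroid_x[i]),
                                      t_px)
    expect_lt(abs(rendered - analytic) / analytic, 0.05)
  }
})

test_that("painted arc subtends the recorded coverage of the ring mid-line", {
  fx <- fixture_noisefree_grid()
  sec <- fx$sec
  prim <- get_channel(sec$stack, "primary")
  for (i in seq_len(nrow(sec$truth))) {
    orac <- sweep_coverage_oracle(sec, i, prim, sec$spec$sarcoplasm_background)
    expect_lt(abs(orac - sec$truth$true_coverage_fraction[i] * 100), 2)
  }
})

test_that("control panel draws negative-baseline replicates deterministically", {
  spec <- section_spec(n_fibres = 9, tertiary_mode = "sarcoplasmic",
                       myosin_positive_fraction = 0,
                       primary_coverage_fractions = 1, seed = 50)
  panel <- generate_control_panel(spec, 5)
  expect_length(panel, 5)
  expect_true(all(vapply(panel, function(s) !any(s$truth$true_myosin_positive),
                         logical(1))))
  panel2 <- generate_control_panel(spec, 5)
  for (j in 1:5)
    expect_identical(panel[[j]]$stack$pixels, panel2[[j]]$stack$pixels)
  # replicates differ from one another but only by sampling noise/placement
  means <- vapply(panel, function(s) {
    mask <- get_channel(s$stack, "mask")
    sarco <- s$labels > 0 & mask < 19000
    mean(get_channel(s$stack, "tertiary")[sarco])
  }, numeric(1))
  expect_gt(stats::sd(means), 0)
  expect_lt(stats::sd(means), 20)   # consistent with noise_sd / sqrt(n_px)
  bad <- spec; bad$myosin_positive_fraction <- 0.2
  expect_error(generate_control_panel(bad, 2), "negative baseline")
})
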