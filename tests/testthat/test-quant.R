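test_that("the cytoplasm-referenced threshold behaves as mean + k*sd", {
  expect_equal(fibre_positive_threshold(rep(8000, 100), k = 3), 8000)
  set.seed(10)
  v <- rnorm(5000, 8000, 500)
  t3 <- fibre_positive_threshold(v, k = 3)
  se <- 500 * sqrt(1 / 5000 + 9 / (2 * 5000))   # se of mean + 3 sd
  expect_lt(abs(t3 - 9500), 3 * se)
  # affine equivariance is exact
  t_aff <- fibre_positive_threshold(2.5 * v + 300, k = 3)
  expect_equal(t_aff, 2.5 * t3 + 300, tolerance = 1e-9)
  # too few pixels: flagged unquantifiable
  out <- fibre_positive_threshold(rep(8000, 10))
  expect_true(is.na(out))
  expect_true(attr(out, "unquantifiable"))
})

test_that("positive objects and extents behave on constructed arcs", {
  # sub-threshold ring: no objects; full ring: one object spanning it all
  st0 <- make_circle_stack(r_px = 40, band_px = 3, arcs = list())
  seg0 <- segment_fibres(st0, detect_tissue(st0))
  f0 <- partition_fibres(seg0, st0)$fibres[[1]]
  prim0 <- get_channel(st0, "primary")
  expect_length(find_positive_objects(f0, prim0, 9500), 0L)
  expect_equal(circumference_positivity(list(), f0), 0)

  st1 <- make_circle_stack(r_px = 40, band_px = 3, arcs = list(c(0, 2 * pi)))
  seg1 <- segment_fibres(st1, detect_tissue(st1))
  f1 <- partition_fibres(seg1, st1)$fibres[[1]]
  objs1 <- find_positive_objects(f1, get_channel(st1, "primary"), 9500)
  expect_length(objs1, 1L)
  expect_equal(objs1[[1]]$circumferential_extent, f1$circumference_px)
  expect_equal(circumference_positivity(objs1, f1), 100)

  # quarter arc: extent/circumference = 0.25 +- 0.02
  st2 <- make_circle_stack(r_px = 40, band_px = 3, arcs = list(c(0.3, 0.3 + pi / 2)))
  seg2 <- segment_fibres(st2, detect_tissue(st2))
  f2 <- partition_fibres(seg2, st2)$fibres[[1]]
  objs2 <- find_positive_objects(f2, get_channel(st2, "primary"), 9500)
  expect_length(objs2, 1L)
  expect_lt(abs(objs2[[1]]$circumferential_extent / f2$circumference_px - 0.25), 0.02)

  # two disjoint 60-degree arcs: ~33.3% and estimator agreement within 3
  st3 <- make_circle_stack(r_px = 40, band_px = 3,
                           arcs = list(c(0, pi / 3), c(pi, pi + pi / 3)))
  seg3 <- segment_fibres(st3, detect_tissue(st3))
  f3 <- partition_fibres(seg3, st3)$fibres[[1]]
  objs3 <- find_positive_objects(f3, get_channel(st3, "primary"), 9500)
  expect_length(objs3, 2L)
  cp_p <- circumference_positivity(objs3, f3, "projection")
  cp_l <- circumference_positivity(objs3, f3, "literal")
  expect_lt(abs(cp_p - 100 / 3), 2)
  expect_lt(abs(cp_p - cp_l), 3)
})

test_that("coverage classes use left-closed negative and strict positivity", {
  cc <- classify_coverage(c(0, 25, 30, 50, 75, 100))
  expect_equal(as.character(cc$coverage_class),
               c("0-25", "0-25", "25-50", "25-50", "50-75", "75-100"))
  expect_equal(cc$is_positive, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_error(classify_coverage(-1), "\\[0, 100\\]")
  expect_error(classify_coverage(101), "\\[0, 100\\]")
})

test_that("sarcolemmal means are reported raw, without background subtraction", {
  st <- make_circle_stack(r_px = 40, band_px = 3, arcs = list(c(0, 2 * pi)),
                          bg = 8000, arc_int = 30000, ring_int = 30000)
  an <- analyse_section(st)
  expect_equal(an$records$primary_sarcolemma_mean, 30000, tolerance = 1e-9)
  expect_equal(an$records$primary_sarcoplasm_mean, 8000, tolerance = 1e-9)
  expect_equal(an$records$primary_circumference_positivity, 100)
})

test_that("affine transforms of a stain channel shift means and not calls", {
  fx <- fixture_noisefree_grid()
  sec <- fx$sec; an <- fx$an
  px <- sec$stack$pixels
  px[, , 2] <- 1.5 * px[, , 2] + 300          # primary channel only
  st2 <- channel_stack(px[, , 1], px[, , 2], px[, , 3],
                       tertiary_kind = sec$stack$tertiary_kind,
                       pixel_size = sec$stack$pixel_size)
  an2 <- analyse_section(st2)
  r1 <- an$records[order(an$records$label), ]
  r2 <- an2$records[order(an2$records$label), ]
  expect_equal(r2$primary_sarcolemma_mean, 1.5 * r1$primary_sarcolemma_mean + 300,
               tolerance = 1e-9)
  expect_equal(r2$primary_sarcoplasm_mean, 1.5 * r1$primary_sarcoplasm_mean + 300,
               tolerance = 1e-9)
  expect_identical(r2$primary_is_positive, r1$primary_is_positive)
  expect_identical(r2$primary_coverage_class, r1$primary_coverage_class)
  expect_equal(r2$primary_circumference_positivity,
               r1$primary_circumference_positivity, tolerance = 1e-6)
})

test_that("colocalisation flags empty subregions as missing, never zero", {
  fx <- fixture_noisefree_grid()
  rec <- fx$an$records
  mm <- match_records(fx$an, fx$sec)
  zero_cov <- mm$rec_idx[fx$sec$truth$true_coverage_fraction == 0]
  full_cov <- mm$rec_idx[fx$sec$truth$true_coverage_fraction == 1]
  expect_true(all(is.na(rec$tertiary_mean_in_primary_pos[zero_cov])))
  expect_true(all(is.finite(rec$tertiary_mean_in_primary_neg[zero_cov])))
  expect_true(all(is.na(rec$tertiary_mean_in_primary_neg[full_cov])))
  expect_true(all(is.finite(rec$tertiary_mean_in_primary_pos[full_cov])))
})

test_that("a doubled tertiary effect size is recovered in the coloc ratio", {
  spec <- section_spec(n_fibres = 36,
                       primary_coverage_fractions = rep(seq(0.2, 0.8, 0.1), length.out = 36),
                       seed = 5)   # defaults: tertiary pos 24000 = 2 x 12000
  sec <- generate_section(spec)
  an <- analyse_section(sec$stack)
  ratio <- an$summary$colocalisation_mean_in_pos / an$summary$colocalisation_mean_in_neg
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("editing one fibre's stain pixels leaves every other fibre untouched", {
  fx <- fixture_small()
  sec <- fx$sec
  px <- sec$stack$pixels
  victim <- 5L
  px[, , 2][sec$labels == victim] <- 8000      # erase fibre 5's primary signal
  st2 <- channel_stack(px[, , 1], px[, , 2], px[, , 3],
                       tertiary_kind = sec$stack$tertiary_kind,
                       pixel_size = sec$stack$pixel_size)
  an2 <- analyse_section(st2)
  mm <- match_labels(fx$an$labels, sec$labels)
  vic_lab <- mm$matched_label[victim]
  r1 <- fx$an$records[fx$an$records$label != vic_lab, ]
  r2 <- an2$records[an2$records$label != vic_lab, ]
  expect_equal(r2, r1, tolerance = 1e-12)
})

test_that("coverage is monotone in the painted arc fraction, noise-free", {
  fx <- fixture_noisefree_grid()
  mm <- match_records(fx$an, fx$sec)
  cp <- fx$an$records$primary_circumference_positivity[mm$rec_idx]
  tr <- fx$sec$truth$true_coverage_fraction
  o <- order(tr)
  expect_true(all(diff(cp[o]) >= -0.5))
})
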