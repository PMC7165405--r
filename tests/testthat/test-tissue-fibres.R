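test_that("blank and noise-only images yield no tissue", {
  z <- matrix(0, 64, 64)
  st <- channel_stack(z, z, z, pixel_size = 0.5)
  expect_error(detect_tissue(st), "no tissue")
  set.seed(1)
  n <- matrix(pmax(rnorm(64 * 64, 8000, 500), 0), 64, 64)
  stn <- channel_stack(n, n, n, pixel_size = 0.5)
  expect_error(detect_tissue(stn), "no tissue")
})

test_that("tissue mask covers the fibres and artefact exclusion is surgical", {
  fx <- fixture_small()
  tis <- detect_tissue(fx$sec$stack)
  fibre_px <- fx$sec$labels > 0
  expect_gt(mean(tis$tissue[fibre_px]), 0.99)
  # with no artefacts injected nothing is excluded
  tis2 <- exclude_artefacts(fx$sec$stack, tis)
  expect_false(any(tis2$excluded))
  # a fold streak is excluded nearly completely with negligible collateral
  aspec <- section_spec(n_fibres = 36, primary_coverage_fractions = 0.5,
                        artefact_spec = list(list(type = "fold", width_um = 5,
                                                  intensity = 65000)),
                        seed = 9)
  asec <- generate_section(aspec)
  atis <- exclude_artefacts(asec$stack, detect_tissue(asec$stack))
  streak <- asec$artefact_mask
  expect_gt(mean(atis$excluded[streak]), 0.90)
  expect_lt(mean(atis$excluded[asec$labels > 0 & !streak]), 0.01)
  expect_true(any(grepl("saturated", atis$provenance)))
})

test_that("a fully saturated image is excluded entirely and yields no fibres", {
  s <- matrix(65535, 64, 64)
  st <- channel_stack(s, s, s, pixel_size = 0.5)
  tis <- exclude_artefacts(st, detect_tissue(st))
  expect_true(all(tis$excluded))
  expect_false(any(tis$tissue))
  seg <- segment_fibres(st, tis)
  expect_equal(seg$n_fibres, 0L)
})

test_that("fibres are recovered with high overlap against truth labels", {
  fx <- fixture_small()
  mm <- match_labels(fx$an$labels, fx$sec$labels)
  expect_gte(sum(mm$jaccard >= 0.8), 24)  # at least 24/25
  # no analysed label overlaps the excluded mask
  expect_false(any(fx$an$labels$labels > 0 & fx$an$tissue$excluded))
})

test_that("undersized fibres are rejected with reason 'area'", {
  spec <- section_spec(n_fibres = 4, fibre_diameter_range = c(10, 12),
                       primary_coverage_fractions = 1, noise_sd = 0, seed = 4)
  sec <- generate_section(spec)
  tis <- detect_tissue(sec$stack)
  seg <- segment_fibres(sec$stack, tis)
  expect_equal(seg$n_fibres, 0L)
  expect_gt(nrow(seg$rejected), 0L)
  expect_true(all(seg$rejected$reason == "area"))
})

test_that("an elongated low-solidity profile is rejected with reason 'shape'", {
  size <- 161; ctr <- 81
  rr <- matrix(seq_len(size) - ctr, size, size)
  cc <- matrix(seq_len(size) - ctr, size, size, byrow = TRUE)
  dist <- sqrt(rr^2 + cc^2); ang <- atan2(cc, rr) %% (2 * pi)
  inner <- dist >= 40 & dist <= 52 & ang <= 1.5 * pi    # C-shaped profile
  # membrane band fully enclosing the C (including its angular end faces)
  band <- as.matrix(EBImage::dilate(EBImage::Image(inner * 1),
                                    EBImage::makeBrush(7, "disc"))) > 0 & !inner
  mask <- matrix(8000, size, size); mask[band] <- 30000
  st <- channel_stack(mask, matrix(8000, size, size), matrix(8000, size, size),
                      pixel_size = 0.5)
  seg <- segment_fibres(st, detect_tissue(st))
  expect_true("shape" %in% seg$rejected$reason)
  expect_equal(seg$n_fibres, 0L)
})

test_that("every accepted fibre is exactly tiled by ring and sarcoplasm", {
  fx <- fixture_small()
  for (f in fx$an$partition$fibres) {
    expect_false(any(f$ring & f$sarcoplasm))
    expect_identical(f$ring | f$sarcoplasm, f$region)
    expect_gte(f$circumference_px, 8)
  }
})

test_that("segmentation is deterministic and monotone in the area filter", {
  fx <- fixture_small()
  tis <- detect_tissue(fx$sec$stack)
  s1 <- segment_fibres(fx$sec$stack, tis)
  s2 <- segment_fibres(fx$sec$stack, tis)
  expect_identical(s1$labels, s2$labels)
  n_at <- vapply(c(150, 400, 900, 1400), function(a) {
    segment_fibres(fx$sec$stack, tis,
                   segmentation_params(min_fibre_area = a))$n_fibres
  }, integer(1))
  expect_true(all(diff(n_at) <= 0L))
})

test_that("fixed-band partition recovers the closed-form circle circumference", {
  st <- make_circle_stack(r_px = 40, band_px = 3)
  tis <- detect_tissue(st)
  seg <- segment_fibres(st, tis)
  expect_equal(seg$n_fibres, 1L)
  part <- partition_fibres(seg, st,
                           segmentation_params(ring_mode = "fixed-band",
                                               fixed_band_um = 1))
  circ_um <- part$fibres[[1]]$circumference_px * 0.5
  expect_lt(abs(circ_um - 2 * pi * 19.5) / (2 * pi * 19.5), 0.05)
})

test_that("laminin-band ring area tracks the analytic annulus within 15%", {
  fx <- fixture_small()
  spec0 <- fx$spec; spec0$noise_sd <- 0
  sec <- generate_section(spec0)
  an <- analyse_section(sec$stack)
  mm <- match_records(an, sec)
  for (i in c(2, 10, 18)) {
    f <- an$partition$fibres[[as.character(mm$matched_label[i])]]
    t_px <- sec$truth$ring_thickness_um[i] / spec0$pixel_size
    analytic <- analytic_ring_area_px(sec$truth$polygon[[i]],
                                      c(sec$truth$centroid_y[i], sec$truth$centroid_x[i]),
                                      t_px)
    expect_lt(abs(sum(f$ring) - analytic) / analytic, 0.15)
  }
})

test_that("ring-dominant candidates are dropped with a recorded reason", {
  size <- 41
  rr <- matrix(seq_len(size) - 21, size, size)
  cc <- matrix(seq_len(size) - 21, size, size, byrow = TRUE)
  disk <- rr^2 + cc^2 <= 15^2
  lab <- matrix(0L, size, size); lab[disk] <- 1L
  fake <- structure(list(labels = lab, n_fibres = 1L,
                         rejected = data.frame(candidate = integer(0),
                                               reason = character(0),
                                               area_um2 = numeric(0)),
                         band = disk, pixel_size = 0.5),
                    class = "fibre_label_map")
  st <- channel_stack(matrix(8000, size, size), matrix(8000, size, size),
                      matrix(8000, size, size), pixel_size = 0.5)
  part <- partition_fibres(fake, st)
  expect_length(part$fibres, 0L)
  expect_equal(part$dropped$reason, "ring-dominant")
})
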