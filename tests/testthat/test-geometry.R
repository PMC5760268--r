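# Channel geometry: centerline, tortuosity, curvature, Dean number and
# node classification.

test_that("cosine centerline evaluates correctly and rejects out-of-domain x", {
  A <- 25e-6; lam <- 104.17e-6
  expect_equal(centerline(0, A, lam), A)
  expect_equal(centerline(lam / 4, 13e-6, lam), 0, tolerance = 1e-12)
  expect_equal(centerline(lam, A, lam), A)          # period
  expect_equal(tortuosity_index(A, lam), 0.24, tolerance = 0.002)
  expect_error(centerline(2.5 * lam, A, lam), "outside")
  expect_error(centerline(-lam, A, lam), "outside")
  expect_error(centerline(1e-6, -1e-6, lam), "amplitude")
})

test_that("minimum radius of curvature matches closed form and brute force", {
  ## TI = 0.24 with A = D = 25 um: the reported ~11 um bend radius
  expect_equal(radius_of_curvature_min(25e-6, 104.17e-6), 11e-6,
               tolerance = 0.5e-6 / 11e-6)
  expect_identical(radius_of_curvature_min(0, 157e-6), Inf)
  ## direct evaluation, cross-checked against finite-difference curvature
  expect_equal(radius_of_curvature_min(12.56e-6, 157e-6), 49.7e-6,
               tolerance = 0.005)
  for (case in list(c(12.56e-6, 157e-6), c(25e-6, 104.17e-6),
                    c(37.68e-6, 157e-6))) {
    expect_equal(radius_of_curvature_min(case[1], case[2]),
                 brute_curvature_min(case[1], case[2]),
                 tolerance = 0.01)
  }
})

test_that("Dean numbers: limits, linearity, and all presets are O(0.1)", {
  expect_equal(dean_number(1030, 1e-3, 25e-6, 1.236e-3, Inf), 0)
  expect_error(dean_number(1030, 1e-3, 25e-6, 1.236e-3, -1), "positive")
  d1 <- dean_number(1030, 1e-3, 25e-6, 1.236e-3, 11e-6)
  expect_equal(dean_number(1030, 2e-3, 25e-6, 1.236e-3, 11e-6), 2 * d1)
  ## V = Q/D at the matched initial flow, sharpest bend
  V <- 5.394e-8 / 25e-6
  dn <- dean_number(1030, V, 25e-6, 1.236e-3, 11e-6)
  expect_equal(dn, 0.068, tolerance = 0.02)
  ## every tortuosity preset stays in the weak-secondary-flow regime
  for (TI in c(0.08, 0.16, 0.24)) {
    pr <- ti_preset(TI)
    rc <- radius_of_curvature_min(pr$A, pr$lambda)
    expect_lt(dean_number(1030, V, 25e-6, 1.236e-3, rc), 0.3)
  }
})

test_that("tortuosity presets: fixed-length and equal-arc conventions", {
  pr <- ti_preset(0.16)
  expect_equal(pr$lambda, 157e-6)
  expect_equal(pr$A, 0.16 * 157e-6)
  expect_equal(pr$L, 314e-6)
  pr2 <- ti_preset(0.16, mode = "equal-arc", arc_target = 380e-6)
  expect_equal(arc_length(pr2$A, pr2$lambda), 380e-6, tolerance = 1e-6)
  expect_equal(pr2$A / pr2$lambda, 0.16)
})

test_that("straight strip mask: uniform columns, height within one dx of D", {
  ch <- build_channel(A = 0, lambda = 157e-6, D = 25e-6, nx = 600)
  counts <- rowSums(ch$mask)
  expect_true(all(counts == counts[1]))            # identical columns
  expect_lt(abs(counts[1] * ch$dx - 25e-6), ch$dx)
  ## fluid band is contiguous in every column
  expect_true(all(apply(ch$mask, 1, function(col) {
    r <- rle(col)$values
    sum(r == 1L) == 1L
  })))
})

test_that("tortuous mask is periodic under a half-domain (lambda) shift", {
  pr <- ti_preset(0.16)
  ch <- build_channel(pr$A, pr$lambda, 25e-6, nx = 160)
  shift <- 160 / 2                                  # lambda = nx/2 columns
  expect_identical(ch$mask[, ], ch$mask[c((shift + 1):160, 1:shift), ])
})

test_that("fluid area matches a 10x-resolution integration oracle", {
  A <- 12.56e-6; lam <- 157e-6; D <- 25e-6
  ch <- build_channel(A, lam, D, nx = 160)
  ## oracle: classify a 10x finer node grid with the same rule and sum
  nfx <- 1600L
  dxf <- 2 * lam / nfx
  nfy <- ceiling((2 * A + D) / dxf) + 4L
  xs <- (seq_len(8 * nfx) - 0.5) * (2 * lam / (8 * nfx))
  ys_c <- A * cos(2 * pi * xs / lam) + A + D / 2
  xf <- (seq_len(nfx) - 0.5) * dxf
  yf <- (seq_len(nfy) - 0.5 - 2) * dxf
  nodes <- expand.grid(x = xf, y = yf)
  phif <- occlusim:::cpp_dist_to_curve(nodes$x, nodes$y, xs, ys_c, 2 * lam)
  area_fine <- sum(phif <= D / 2) * dxf^2
  expect_equal(ch$fluid_area, area_fine, tolerance = 0.02)
})

test_that("degenerate geometries are rejected", {
  expect_error(build_channel(A = 0, lambda = 157e-6, D = 2e-6, nx = 64),
               "thinner")
  expect_error(build_channel(A = 1e-6, lambda = 157e-6, D = 25e-6, nx = 4),
               "nx")
})

test_that("vertical wall rule bounds vertical distance; mask export round-trips", {
  pr <- ti_preset(0.16)
  ch <- build_channel(pr$A, pr$lambda, 25e-6, nx = 96,
                      wall_rule = "vertical")
  yc <- pr$A * cos(2 * pi * ch$x / pr$lambda) + pr$A + 12.5e-6
  vert <- abs(outer(-yc, ch$y, `+`))
  expect_true(all(vert[ch$mask == 1L] <= 12.5e-6 + 1e-12))
  tf <- tempfile(fileext = ".txt")
  write_mask(ch, tf)
  lines <- readLines(tf)
  expect_length(lines, ch$ny)
  expect_equal(sum(as.integer(unlist(strsplit(lines, "")))), sum(ch$mask))
})
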