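# Opening, stretching, probing and the inverse mapping.

test_that("contours open at azimuth pi with a lowest-index tie-break", {
  circ <- circle_points(120, 10, c(50, 50))
  op <- open_contour(circ, c(50, 50))
  expect_equal(nrow(op), round(2 * pi * 10))
  # leftmost point, within half an angular sampling step
  expect_lt(max(abs(op[1, ] - c(40, 50))), 0.6)
  az <- attr(op, "azimuth")
  expect_lt(ang_diff(az[1] * 180 / pi, 180), 180 / nrow(op) + 1e-6)

  # two vertices exactly equidistant from pi: the lower index wins;
  # a diamond at azimuths 45/135/225/315 ties between 135 and 225
  diamond <- circle_points(4, 10, c(0, 0), phase = pi / 4)
  op2 <- open_contour(diamond, c(0, 0), n = 4)
  expect_equal(op2[1, ], diamond[2, ], tolerance = 1e-9)  # azimuth 135

  # star-shaped contour: unwrapped azimuths increase monotonically and
  # agree with an angle-sorting oracle
  th <- 2 * pi * (0:199) / 200
  star <- cbind((20 + 4 * cos(6 * th)) * cos(th),
                (20 + 4 * cos(6 * th)) * sin(th))
  op3 <- open_contour(star, c(0, 0))
  az3 <- attr(op3, "azimuth")
  unwrapped <- az3 + 2 * pi * cumsum(c(0, diff(az3) < -pi))
  expect_true(all(diff(unwrapped) > 0))
  # angle-sorting oracle: sorting by azimuth from the opening point at pi
  # reproduces the opened sequence
  expect_equal(order((az3 - az3[1]) %% (2 * pi)), seq_len(nrow(op3)))

  expect_error(open_contour(circ, c(500, 50)), class = "cyclo_opening_error")
})

test_that("the longest contour sets the common cyclorama length", {
  fake <- structure(list(perimeters = cbind(c(100, 80), c(120, 99))),
                    class = "reslicing_set")
  expect_equal(reference_length(fake), 120L)
  fx <- fx_marker_unroll()
  L <- reference_length(fx$surfaces)
  expect_lt(abs(L - round(2 * pi * 90)), 2)  # outer radius 90 phantom
  expect_true(all(round(fx$surfaces$perimeters) <= L))
})

test_that("stretching resamples uniformly with a monotone index map", {
  sq <- normalize_contour(cbind(c(0, 25, 25, 0), c(0, 0, 25, 25)), 100)
  op <- open_contour(sq, c(12.5, 12.5), n = 100)
  st <- stretch_contour(op, 200)
  expect_equal(nrow(st), 200)
  seg <- sqrt(rowSums(diff(st)^2))
  expect_lt(max(abs(seg - contour_perimeter(op) / 200)), 0.05)
  im <- attr(st, "index_map")
  expect_true(all(diff(im) >= 0))
  expect_equal(im[1], 1)
  expect_equal(im[200], 100)

  # identity case: stretching to its own length changes nothing
  st2 <- stretch_contour(op, nrow(op))
  expect_lt(max(abs(st2 - op)), 1e-6)
})

test_that("probing fills the cyclorama from the right source voxels", {
  fx <- fx_marker_unroll()
  surf <- fx$surfaces

  # constant volume probes to a constant, in both interpolation modes
  vol7 <- array(7, dim(fx$phantom$volume))
  expect_true(all(probe_volume(vol7, surf)$values == 7))
  expect_true(all(probe_volume(vol7, surf, interp = "nearest")$values == 7))

  # longitudinal bright stripe at azimuths [170, 190] deg shows up in
  # the columns whose stored source azimuth lies in that range
  spec <- fx$spec
  xs <- matrix(seq_len(spec$cols), spec$rows, spec$cols, byrow = TRUE)
  ys <- matrix(seq_len(spec$rows), spec$rows, spec$cols)
  az <- (atan2(ys - spec$center[2], xs - spec$center[1]) * 180 / pi) %% 360
  rr <- sqrt((xs - spec$center[1])^2 + (ys - spec$center[2])^2)
  slice <- ifelse(az >= 170 & az <= 190 & rr >= 50 & rr <= 90, 255, 0)
  vol <- array(rep(slice, dim(fx$phantom$volume)[3]),
               dim(fx$phantom$volume))
  cy <- probe_volume(vol, surf)
  bright <- which(cy$values[, 11, 3] > 200)
  src_az <- (atan2(cy$sy[bright, 11, 3] - spec$center[2],
                   cy$sx[bright, 11, 3] - spec$center[1]) * 180 / pi) %% 360
  expect_true(all(src_az > 169 & src_az < 191))
  # the stripe is centred on the opening point, i.e. the first columns
  expect_lt(ang_diff((atan2(cy$sy[1, 11, 3] - spec$center[2],
                            cy$sx[1, 11, 3] - spec$center[1]) * 180 / pi) %% 360,
                     180), 1)

  # out-of-bounds probes are filled and counted
  tiny <- vol[1:40, 1:40, , drop = FALSE]
  expect_error(probe_volume(tiny[, , 1:3], surf),
               class = "cyclo_contract_error")
})

test_that("markers at 50% depth peak on the middle cyclorama slice", {
  mk <- data.frame(azimuth_deg = seq(0, 315, by = 45), depth = 0.5,
                   h_lo = 3L, h_hi = 7L, intensity = 255)
  spec <- phantom_spec(rows = 128, cols = 128, n_slices = 9,
                       inner_radius = 25, outer_radius = 45, markers = mk)
  ph <- make_tube(spec, key_interval = 4L)
  cfg <- run_config(n_points = 100, window = 10, m = 4L, n_levels = 5L)
  surf <- mesh_sections(ph$contours, 9, cfg)
  cy <- probe_volume(ph$volume, surf)
  means <- apply(cy$values[, 3:7, ], 3, mean)
  expect_equal(which.max(means), 3L)  # c = (C-1)/2 at odd C = 5
})

test_that("the inverse mapping recovers voxels and builds seed cubes", {
  fx <- fx_marker_unroll()
  cy <- fx$cyclo
  dims <- dim(cy$values)

  set.seed(3)
  cells <- cbind(sample(dims[1], 25), sample(dims[2], 25, replace = TRUE),
                 sample(dims[3], 25, replace = TRUE))
  mask <- inverse_map(cells, cy, cube = 1)
  expect_equal(dim(mask), cy$dim_volume)
  hits <- which(mask == 1, arr.ind = TRUE)
  # every forward-probed source voxel is recovered within 1 voxel (Chebyshev)
  for (k in seq_len(nrow(cells))) {
    src <- c(cy$sy[cells[k, , drop = FALSE]], cy$sx[cells[k, , drop = FALSE]],
             cells[k, 2])
    cheb <- min(apply(hits, 1, function(v) max(abs(v - src))))
    expect_lt(cheb, 1)
  }

  # a single seed dilated to a 5x5x5 cube, clipped at the stack border
  m5 <- inverse_map(matrix(c(10, 11, 3), 1), cy, cube = 5)
  expect_equal(sum(m5), 125)
  m5b <- inverse_map(matrix(c(10, 1, 3), 1), cy, cube = 5)  # slice border
  expect_equal(sum(m5b), 75)

  expect_true(all(inverse_map(matrix(0, 0, 3), cy, cube = 5) == 0))
  expect_error(inverse_map(cbind(1, 1), cy), class = "cyclo_contract_error")
})
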