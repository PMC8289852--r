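# Contour normalization, boundary pairing and annulus membership.

test_that("equidistant resampling fixes spacing, orientation and start point", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  out <- normalize_contour(sq, 8)
  spacing <- sqrt(rowSums(diff(rbind(out, out[1, ]))^2))
  expect_equal(spacing, rep(5, 8))  # perimeter 40 / 8
  expect_equal(out[1, ], c(0, 0))

  # circle polyline vs brute-force arc-length oracle (the equal-chord
  # fixed point deviates from the single-pass oracle only by corner cuts)
  circ <- circle_points(100, 10, c(50, 50))
  got <- normalize_contour(circ, 200)
  expect_lt(max(abs(got - oracle_resample(circ, 200))), 0.01)
  spacing <- sqrt(rowSums(diff(rbind(got, got[1, ]))^2))
  expect_lt(max(abs(spacing - mean(spacing))), 1e-6)
  expect_lt(abs(mean(spacing) - contour_perimeter(circ) / 200), 1e-3)

  # clockwise input is flipped to counter-clockwise (positive signed area)
  tri_cw <- cbind(c(0, 1, 2), c(0, 2, 0))
  expect_lt(signed_area(tri_cw), 0)
  expect_gt(signed_area(normalize_contour(tri_cw, 6)), 0)
})

test_that("normalization is idempotent and rejects degenerate input", {
  shapes <- list(circle_points(37, 12, c(3, -5)),
                 cbind(c(0, 8, 9, 4, -2), c(0, 1, 7, 9, 4)))
  for (xy in shapes) {
    once <- normalize_contour(xy, 50)
    twice <- normalize_contour(once, 50)
    expect_lt(max(abs(once - twice)), 1e-6)
  }
  expect_error(normalize_contour(cbind(c(0, 0), c(0, 1)), 8),
               class = "cyclo_invalid_contour")
  expect_error(normalize_contour(matrix(1, 5, 2), 8),
               class = "cyclo_invalid_contour")
  expect_error(normalize_contour(circle_points(10, 5), 2),
               class = "cyclo_parameter_error")
})

test_that("boundary pairing rotates the outer start to the nearest point", {
  ctr <- c(0, 0)
  inner <- normalize_contour(circle_points(100, 10, ctr), 100)
  outer <- normalize_contour(circle_points(100, 20, ctr, phase = 0.7), 100)

  # inner starts at (10, 0): paired outer start must be its radial partner
  expect_equal(inner[1, ], c(10, 0), tolerance = 1e-9)
  sec <- pair_boundaries(inner, outer)
  expect_lt(max(abs(sec$outer[1, ] - c(20, 0))), 0.7)  # within one sample step

  # start at (0, 10): same radial-symmetry argument
  inner2 <- normalize_contour(circle_points(100, 10, ctr, phase = pi / 2), 100)
  sec2 <- pair_boundaries(inner2, outer)
  expect_lt(max(abs(sec2$outer[1, ] - c(0, 20))), 0.7)

  # ellipse outer: start equals exhaustive arg-min over all outer points
  ell <- normalize_contour(cbind(30 * cos(2 * pi * (0:99) / 100),
                                 15 * sin(2 * pi * (0:99) / 100)), 100)
  sec3 <- pair_boundaries(inner, ell)
  d2 <- (ell[, 1] - inner[1, 1])^2 + (ell[, 2] - inner[1, 2])^2
  expect_equal(sec3$outer[1, ], ell[which.min(d2), ])

  # pairing never changes coordinates, only the cyclic start
  reord <- sec3$outer[order(sec3$outer[, 1], sec3$outer[, 2]), ]
  expect_equal(reord, ell[order(ell[, 1], ell[, 2]), ])

  expect_error(pair_boundaries(ell, inner), class = "cyclo_geometry_error")
  expect_error(pair_boundaries(inner[1:50, ], outer),
               class = "cyclo_contract_error")
})

test_that("annulus membership follows the even-odd rule with boundaries excluded", {
  sec <- concentric_section(200)
  ctr <- c(128, 128)
  expect_true(annulus_contains(ctr + c(30, 0), sec))   # mid-wall
  expect_false(annulus_contains(ctr + c(10, 0), sec))  # lumen
  expect_false(annulus_contains(ctr + c(55, 0), sec))  # outside

  # inner boundary vertices are excluded; the mid-wall ring is included
  expect_false(any(annulus_contains(sec$inner, sec)))
  mid <- (sec$inner + sec$outer) / 2
  expect_true(all(annulus_contains(mid, sec)))

  # 1000 random points vs the independent even-odd oracle on both polygons
  set.seed(42)
  pts <- cbind(runif(1000, 80, 176), runif(1000, 80, 176))
  want <- vapply(seq_len(1000), function(k) {
    oracle_point_in_polygon(pts[k, 1], pts[k, 2], sec$outer) &&
      !oracle_point_in_polygon(pts[k, 1], pts[k, 2], sec$inner)
  }, TRUE)
  expect_identical(unname(annulus_contains(pts, sec)), want)
})
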