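# Field-line tracing: windows, normals, field evaluation, statuses,
# thickness, and the geometric invariants of the construction.

test_that("charge windows are cyclic, contiguous and of size 2w+1", {
  expect_equal(window_indices(1, 2, 10), c(9, 10, 1, 2, 3))
  expect_equal(window_indices(10, 2, 10), c(8, 9, 10, 1, 2))
  set.seed(7)
  for (k in 1:20) {
    I <- sample(5:200, 1)
    w <- sample(seq_len((I - 1) %/% 2), 1)
    i <- sample(I, 1)
    J <- window_indices(i, w, I)
    expect_length(J, 2 * w + 1)
    expect_true(i %in% J)
    expect_length(unique(J), 2 * w + 1)
  }
})

test_that("the first step always lands inside the annulus", {
  sec <- concentric_section(200)
  # on the inner circle at angle 0, into the wall means +x (away from
  # the lumen); sampling skews it by at most a half angular step
  n0 <- inward_normal(sec, 1, 2)
  expect_gt(n0[1], 0)
  expect_lt(abs(atan2(n0[2], n0[1])), 2 * pi / 200 + 1e-9)

  # square annulus: edge midpoints get the axis-aligned outward normal
  sq_in <- normalize_contour(cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10)), 40)
  sq_out <- normalize_contour(cbind(c(-20, 20, 20, -20), c(-20, -20, 20, 20)), 40)
  sqsec <- pair_boundaries(sq_in, sq_out)
  mid <- which.min(rowSums((sqsec$inner - matrix(c(10, 0), 40, 2,
                                                 byrow = TRUE))^2))
  expect_equal(inward_normal(sqsec, mid, 2), c(1, 0), tolerance = 1e-9)

  # star-shaped section: the chosen sign always satisfies containment
  th <- 2 * pi * (0:63) / 64
  star_in <- normalize_contour(cbind((12 + 3 * cos(5 * th)) * cos(th),
                                     (12 + 3 * cos(5 * th)) * sin(th)), 64)
  star_out <- normalize_contour(cbind((30 + 4 * cos(3 * th)) * cos(th),
                                      (30 + 4 * cos(3 * th)) * sin(th)), 64)
  ssec <- pair_boundaries(star_in, star_out)
  for (i in seq_len(64)) {
    nv <- inward_normal(ssec, i, 1.5)
    expect_true(annulus_contains(ssec$inner[i, ] + 1.5 * nv, ssec))
  }
})

test_that("the windowed field points from the inner to the outer boundary", {
  sec <- concentric_section(200)
  fp <- field_params(200, 15, 2, 1, 75, 50)
  # on the symmetry axis of the window the field is purely radial outward
  E <- electric_field(c(128 + 30, 128), sec, 1, fp)
  expect_gt(E[1], 0)
  expect_lt(abs(E[2] / E[1]), 1e-9)

  # full window: direction radial within 1 degree, checked against a
  # plain-loop sum over all window charges
  fpF <- field_params(200, 99, 2, 1, 75, 50)
  for (i in c(1, 35, 117)) {
    p <- sec$inner[i, ] * 0.6 + sec$outer[i, ] * 0.4
    E <- electric_field(p, sec, i, fpF)
    oracle <- c(0, 0)
    for (j in window_indices(i, 99, 200)) {
      din <- p - sec$inner[j, ]; dout <- p - sec$outer[j, ]
      oracle <- oracle + din / sum(din^2)^1.5 - dout / sum(dout^2)^1.5
    }
    expect_equal(E, oracle, tolerance = 1e-12)
    radial <- p - c(128, 128)
    cosang <- sum(E * radial) / sqrt(sum(E^2) * sum(radial^2))
    expect_gt(cosang, cos(pi / 180))
  }

  # linearity in rigidity: E(rig = 2) = E_inner_part + 2 * E_outer_part
  p <- c(128 + 27, 128 + 4)
  fp2 <- field_params(200, 15, 2, 2, 75, 50)
  J <- window_indices(5, 15, 200)
  e_in <- colSums((matrix(p, length(J), 2, byrow = TRUE) - sec$inner[J, ]) /
                    rowSums(sweep(sec$inner[J, ], 2, p, "-")^2)^1.5)
  e_out <- colSums((matrix(p, length(J), 2, byrow = TRUE) - sec$outer[J, ]) /
                     rowSums(sweep(sec$outer[J, ], 2, p, "-")^2)^1.5)
  expect_equal(electric_field(p, sec, 5, fp2), e_in - 2 * e_out,
               tolerance = 1e-12)
  expect_error(electric_field(sec$inner[5, ], sec, 5, fp),
               class = "cyclo_singularity")
})

test_that("tracing classifies complete, stray and collapsed lines", {
  fx <- fx_concentric_lines()
  d <- vapply(fx$lines, `[[`, 0, "length")
  expect_length(fx$lines, 200)           # nothing removed
  expect_equal(attr(fx$lines, "n_stray"), 0)
  expect_equal(attr(fx$lines, "n_collapsed"), 0)
  expect_lt(max(abs(d - 20)), 0.5)       # wall thickness R_out - R_in

  # too few steps to cross a 20 px wall with 2 px segments
  stray <- trace_field_line(fx$section, 1, field_params(200, 15, 2, 1, 3, 50))
  expect_equal(stray$status, "stray")

  # a complete path whose scatter stays below v_min is still collapsed
  tight <- trace_field_line(fx$section, 1,
                            field_params(200, 15, 2, 1, 75, v_min = 1e6))
  expect_equal(tight$status, "collapsed")

  # delta exceeding the wall thickness fails at the very first step
  thin <- pair_boundaries(normalize_contour(circle_points(64, 20), 64),
                          normalize_contour(circle_points(64, 21.5), 64))
  fat <- trace_field_line(thin, 1, field_params(64, 5, delta = 3,
                                                k_max = 10, v_min = 0.5))
  expect_equal(fat$status, "collapsed")

  # the scatter variance matches its definition on a frozen path
  pts <- cbind(c(0, 1, 2, 3), c(0, 0.5, 0.2, 0.9))
  K <- 3
  ctr <- colSums(pts) / K
  expect_equal(cyclorama:::line_variance(pts),
               sum(sweep(pts, 2, ctr)^2) / K)
})

test_that("trace_all keeps complete lines in index order or fails loudly", {
  fx <- fx_concentric_lines()
  idx <- vapply(fx$lines, `[[`, 0L, "index")
  expect_true(all(diff(idx) > 0))
  expect_true(all(idx %in% 1:200))
  expect_error(trace_all(fx$section, field_params(200, 15, 2, 1, k_max = 1,
                                                  v_min = 50)),
               class = "cyclo_meshing_failure")
  expect_error(trace_all(fx$section, field_params(100, 15, 2, 1, 75, 50)),
               class = "cyclo_contract_error")
})

test_that("field lines start orthogonally, progress monotonically and never cross", {
  # small elliptical annulus for the pairwise crossing check
  th <- 2 * pi * (0:31) / 32
  inner <- normalize_contour(cbind(14 * cos(th), 9 * sin(th)), 32)
  outer <- normalize_contour(cbind(34 * cos(th), 24 * sin(th)), 32)
  sec <- pair_boundaries(inner, outer)
  lines <- trace_all(sec, field_params(32, 6, 1.5, 1, 80, 1))
  for (a in seq_along(lines)) {
    ln <- lines[[a]]
    # start orthogonality to the local tangent
    u <- sec$inner[ln$index %% 32 + 1, ] - sec$inner[ln$index, ]
    step1 <- ln$points[2, ] - ln$points[1, ]
    expect_lt(abs(sum(u * step1)) / sqrt(sum(u^2) * sum(step1^2)), 0.05)
    # monotone progress away from the inner boundary
    dmin <- apply(ln$points, 1, function(p)
      min(sqrt(rowSums(sweep(sec$inner, 2, p)^2))))
    expect_true(all(diff(dmin) > -1.5))
    if (a < length(lines))
      for (b in (a + 1):length(lines))
        expect_false(oracle_polylines_cross(ln$points, lines[[b]]$points))
  }
})

test_that("a concentric annulus unrolls symmetrically, whatever the rigidity", {
  fx <- fx_concentric_lines()
  d <- vapply(fx$lines, `[[`, 0, "length")
  expect_lt(diff(range(d)), 1e-3)
  # radial symmetry makes the full-window trace rigidity-invariant
  fp_soft <- field_params(200, 99, 2, rigidity = 0.5, 75, 50)
  fp_stiff <- field_params(200, 99, 2, rigidity = 4, 75, 50)
  for (i in c(1, 50)) {
    d_soft <- trace_field_line(fx$section, i, fp_soft)$length
    d_stiff <- trace_field_line(fx$section, i, fp_stiff)$length
    expect_lt(abs(d_soft - d_stiff), 1e-3)
  }
})
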