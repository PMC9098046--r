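tetra_mesh <- function() {
  ## boundary of a tetrahedron: 4 vertices, 6 edges, 4 faces, chi = 2
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  m <- build_mesh(structure_frame(v), r = 10)
  m$vertices <- v  # already inside the unit ball
  m
}

test_that("EC curve recovers the full-complex Euler characteristic", {
  m <- tetra_mesh()
  filt <- filtration_spec(15)
  cv <- ec_curve(m, c(0, 0, 1), filt)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(tail(cv$values, 1), 2)          # sphere topology
  expect_equal(tail(cv$values, 1), euler_characteristic(m))

  ## isolated vertices below the first threshold: constant curve
  pts <- structure_frame(matrix(runif(15, -0.1, 0.1), 5, 3))
  iso <- build_mesh(pts, r = 1e-6)
  iso$vertices <- iso$vertices / 10
  iso$vertices[, 3] <- -1            # at the floor: inside every sublevel
  cv2 <- ec_curve(iso, c(0, 0, 1), filtration_spec(8))
  expect_true(all(cv2$values == 5))
})

test_that("EC curves match the rebuild-from-scratch sublevel oracle", {
  set.seed(42)
  filt <- filtration_spec(25)
  for (rep in 1:6) {
    fr <- random_frame(25, box = 6, seed = 100 + rep)
    m <- normalize_meshes(list(build_mesh(fr, 2.5)))[[1]]
    nu <- rnorm(3)
    nu <- nu / sqrt(sum(nu^2))
    expect_equal(ec_curve(m, nu, filt)$values,
                 brute_ec_curve(m, nu, filt$thresholds))
  }
})

test_that("DEC telescopes for t = 1 and equals lagged EC differences", {
  filt <- filtration_spec(20)
  fr <- random_frame(30, box = 6, seed = 9)
  m <- normalize_meshes(list(build_mesh(fr, 2.5)))[[1]]
  nu <- c(1, 0, 0)
  ec <- ec_curve(m, nu, filt)
  d1 <- dec_curve(m, nu, filt, t = 1)
  expect_equal(cumsum(d1$values), ec$values)
  expect_equal(d1$values[1], ec$values[1])
  ## t = 2 equals the finite difference of the EC oracle
  d2 <- dec_curve(m, nu, filt, t = 2)
  ecv <- brute_ec_curve(m, nu, filt$thresholds)
  expect_equal(d2$values, ecv - c(0, 0, ecv[seq_len(filt$l - 2)]))
  ## a step where nothing enters is zero
  expect_true(any(d1$values == 0))
  expect_error(dec_curve(m, nu, filt, t = 20), "must be < l")
})

test_that("rotating mesh and directions together leaves curves unchanged", {
  filt <- filtration_spec(18)
  fr <- random_frame(20, box = 5, seed = 13)
  m <- normalize_meshes(list(build_mesh(fr, 2.5)))[[1]]
  set.seed(7)
  axis <- rnorm(3)
  ang <- 1.1
  m_rot <- m
  m_rot$vertices <- dect:::rodrigues(m$vertices, axis, ang)
  for (i in 1:4) {
    nu <- rnorm(3)
    nu <- nu / sqrt(sum(nu^2))
    nu_rot <- drop(dect:::rodrigues(matrix(nu, 1), axis, ang))
    expect_equal(ec_curve(m, nu, filt)$values,
                 ec_curve(m_rot, nu_rot, filt)$values)
  }
})

test_that("design matrix columns are ordered and provenance is a bijection", {
  filt <- filtration_spec(10)
  dirs <- generate_cones(3, 2, 0.5, seed = 4)
  fr <- random_frame(15, box = 5, seed = 21)
  meshes <- normalize_meshes(list(build_mesh(fr, 2.5),
                                  build_mesh(fr, 2.5)))
  des <- build_design_matrix(meshes, dirs, filt)
  expect_equal(ncol(des$X), 3 * 2 * 10)
  expect_equal(des$X[1, ], des$X[2, ])         # identical meshes
  pv <- des$provenance
  expect_equal(nrow(unique(pv[, c("cone", "direction", "sublevel")])),
               nrow(pv))
  ## column order: cones outer, directions middle, sublevels inner
  expect_equal(pv$cone, rep(1:3, each = 20))
  expect_equal(pv$sublevel[1:10], 1:10)

  ## per-direction block sums telescope to the final EC of that mesh
  m <- meshes[[1]]
  for (v in 1:6) {
    block <- des$X[1, (v - 1) * 10 + 1:10]
    expect_equal(sum(block),
                 tail(ec_curve(m, dirs$directions[v, ], filt)$values, 1))
  }

  ## atom -> feature map: entry sublevel is the ceil-search of h in thresholds
  map <- des$atom_feature_map[[1]]
  expect_equal(dim(map), c(15L, 6L))
  h <- drop(m$vertices %*% dirs$directions[2, ])
  expected_k <- vapply(h, function(z) which(filt$thresholds >= z)[1], 0L)
  expect_equal(((map[, 2] - 1L) %% 10L) + 1L, expected_k)
  expect_true(all(((map[, 2] - 1L) %/% 10L) + 1L == 2L))
})

test_that("a mismatched normalization is rejected", {
  filt <- filtration_spec(5)
  dirs <- generate_cones(1, 1, 0.5)
  fr <- random_frame(10, seed = 2)
  m1 <- normalize_meshes(list(build_mesh(fr, 3)))[[1]]
  m2 <- build_mesh(fr, 3)   # scale_factor 1
  expect_error(build_design_matrix(list(m1, m2), dirs, filt),
               "normalization")
})
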