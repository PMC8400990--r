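test_that("ring neighbourhoods are monotone and exclude the centre", {
  fix <- ball_fixture()
  mesh <- fix$mesh
  adj <- vertex_adjacency(mesh)
  v <- which.max(lengths(adj))
  n1 <- vertex_neighborhood(mesh, v, rings = 1L, adj = adj)
  n2 <- vertex_neighborhood(mesh, v, rings = 2L, adj = adj)
  expect_true(all(n1 %in% n2))
  expect_gt(length(n2), length(n1))
  expect_false(v %in% n2)
  expect_identical(n1, sort(n1))
  expect_identical(n1, adj[[v]])

  # isolated vertex errors
  iso <- trimesh(rbind(diag(3), c(1, 1, 1)), rbind(c(1, 2, 3)))
  expect_error(vertex_neighborhood(iso, 4L), "isolated")
})

test_that("the tangent frame map is rigid with height along the normal", {
  origin <- c(2, -1, 3)
  n <- c(1, 2, 2) / 3
  pts <- matrix(rnorm(30), 10, 3)
  loc <- rotate_to_normal_frame(rbind(origin, origin + n, pts), origin, n)
  expect_equal(loc[1, ], c(0, 0, 0))
  expect_equal(loc[2, ], c(0, 0, 1))
  d_world <- as.matrix(dist(pts))
  d_local <- as.matrix(dist(loc[-(1:2), ]))
  expect_lt(max(abs(d_world - d_local)), 1e-9)
  basis <- attr(loc, "basis")
  expect_equal(basis %*% t(basis), diag(3), tolerance = 1e-12)
  expect_error(rotate_to_normal_frame(pts, origin, c(0, 0, 0)), "zero")
  expect_error(rotate_to_normal_frame(pts, origin, c(0, 0, 2)), "unit")
})

test_that("quadric fits are exact on exact quadrics", {
  g <- as.matrix(expand.grid(x = seq(-1, 1, 0.4), y = seq(-1, 1, 0.4)))
  cases <- list(
    list(h = function(x, y) x^2 + y^2, want = c(1, 1, 0, 0, 0, 0)),
    list(h = function(x, y) 0 * x, want = c(0, 0, 0, 0, 0, 0)),
    list(h = function(x, y) 3 * x^2 + 2 * x * y - y^2 + 4,
         want = c(3, -1, 2, 0, 0, 4)))
  for (cs in cases) {
    pts <- cbind(g, cs$h(g[, 1], g[, 2]))
    expect_equal(unname(fit_quadric_patch(pts)), cs$want, tolerance = 1e-8)
  }
  expect_error(fit_quadric_patch(cbind(g[1:5, ], 0)), "at least 6")
  line <- cbind(seq(0, 1, 0.1), 2 * seq(0, 1, 0.1), 0)
  expect_error(fit_quadric_patch(line), "rank")
})

test_that("principal curvatures follow the Hessian eigenstructure", {
  pc <- principal_curvatures(c(a = 1, b = 1, c = 0, d = 0, e = 0, f = 0))
  expect_equal(c(pc$lambda1, pc$lambda2), c(2, 2))
  pc <- principal_curvatures(c(a = 0.5, b = 0, c = 0, d = 0, e = 0, f = 0))
  expect_equal(c(pc$lambda1, pc$lambda2), c(1, 0))
  expect_equal(sum(pc$dir1 * pc$dir2), 0, tolerance = 1e-12)
  # ordering lambda1 >= lambda2 for random coefficients
  set.seed(4)
  for (i in 1:20) {
    co <- stats::setNames(c(rnorm(3), 0, 0, 0), c("a", "b", "c", "d", "e", "f"))
    pc <- principal_curvatures(co)
    expect_gte(pc$lambda1, pc$lambda2)
  }
})

test_that("descriptor closed forms match their definitions", {
  expect_equal(unname(shape_descriptors(0.1, 0.1)), c(0.01, 0.1, 0, 0.1))
  expect_equal(unname(shape_descriptors(2, 0)), c(0, 1, 4, sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(shape_descriptors(1, -1)), c(-1, 0, 4, 1))
})

test_that("descriptors are invariant to rigid motion and covariant to scale", {
  fix <- ball_fixture()
  mesh <- fix$mesh
  base <- fix$shapes
  # random rotation + translation
  set.seed(7)
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- c(12, -3, 8)
  moved <- trimesh(mesh$vertices %*% t(R) +
                     matrix(t0, nrow(mesh$vertices), 3, byrow = TRUE),
                   mesh$faces)
  sf_m <- mesh_shape_features(moved)
  for (col in c("gaussian", "mean", "sharpness", "curvedness"))
    expect_lt(max(abs(sf_m[[col]] - base[[col]])), 1e-6)

  s <- 2
  scaled <- trimesh(mesh$vertices * s, mesh$faces)
  sf_s <- mesh_shape_features(scaled)
  expect_equal(sf_s$mean, base$mean / s, tolerance = 1e-6)
  expect_equal(sf_s$curvedness, base$curvedness / s, tolerance = 1e-6)
  expect_equal(sf_s$gaussian, base$gaussian / s^2, tolerance = 1e-6)
  expect_equal(sf_s$sharpness, base$sharpness / s^2, tolerance = 1e-6)
})

test_that("ball surface descriptors match the analytic sphere", {
  fix <- ball_fixture()
  sf <- fix$shapes
  R <- 10
  expect_lt(abs(median(sf$mean) * R - 1), 0.15)
  expect_lt(abs(median(sf$gaussian) * R^2 - 1), 0.3)
  expect_lt(median(sf$sharpness) * R^2, 0.1)
  # principal curvatures individually near 1/R (fixture-calibrated bound)
  expect_lt(abs(median(sf$lambda1) * R - 1), 0.35)
  expect_lt(abs(median(sf$lambda2) * R - 1), 0.35)
})
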