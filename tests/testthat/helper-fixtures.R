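# Shared fixtures, computed once per test run and memoized. Everything is
# generated in code; no binary fixtures on disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# moderate-resolution ball phantom + mesh + per-vertex shapes (R = 10 mm)
ball_fixture <- function() {
  memo("ball", {
    ph <- make_phantom("ball", size = 10, grid_shape = c(48L, 48L, 48L),
                       seed = 3L)
    alpha <- select_isovalue(ph$vol)
    mesh <- marching_cubes(ph$vol, alpha)
    list(phantom = ph, alpha = alpha, mesh = mesh,
         shapes = mesh_shape_features(mesh))
  })
}

# hand-built unit cube with outward winding (12 triangles)
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left
             c(2, 3, 7), c(2, 7, 6))   # right
  trimesh(v, f)
}

# small synthetic cohort for fast classifier tests
small_cohort <- function(seed = 5L, effect = 3, n = c(nc = 30L, mci = 30L)) {
  memo(paste0("cohort_", seed, "_", effect, "_", n[1], "_", n[2]),
       make_cohort(n_per_group = n, n_regions = 12L,
                   affected_regions = 1:5, effect_size = effect,
                   seed = seed))
}

expect_rel_error <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
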