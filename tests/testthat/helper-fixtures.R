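# Shared fixtures, built in code once per test session.

.fixture_env <- new.env(parent = emptyenv())

cube_mesh <- function(side = 1) {
  s <- side / 2
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  # faces grouped per cube face (2 triangles each), -x +x -y +y -z +z
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # x = -s
    c(2, 8, 4), c(2, 6, 8),   # x = +s
    c(1, 5, 6), c(1, 6, 2),   # y = -s
    c(3, 4, 8), c(3, 8, 7),   # y = +s
    c(1, 2, 4), c(1, 4, 3),   # z = -s
    c(5, 8, 6), c(5, 7, 8))   # z = +s
  vc$new_surface_mesh(v, f)
}

sphere_mesh <- function(radius = 0.8, n_stack = 16, n_slice = 24) {
  vc$.make_ellipsoid_mesh(c(0, 0, 0), rep(radius, 3),
                          n_stack = n_stack, n_slice = n_slice)
}

# Toy two-tube dataset used by the training tests; cached per session.
toy_manifest <- function() {
  if (!is.null(.fixture_env$manifest)) return(.fixture_env$manifest)
  dir <- file.path(tempdir(), "toy_dataset")
  meshes <- list(generate_toy_shape("tube", 1),
                 generate_toy_shape("tube", 2))
  man <- suppressWarnings(build_dataset(
    meshes, c("vessel", "vessel"), dir,
    n_complete = 256L, n_partial = 64L, n_views = 4L,
    rng_seed = 3L, resolution = 96L))
  .fixture_env$manifest <- man
  man
}

toy_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  .fixture_env$model <- init_model(model_config("toy"))
  .fixture_env$model
}
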