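## Shared fixtures. Heavy objects (lookup tables, simulated cubes) are
## built lazily and cached for the duration of the test session.

.cspws_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cspws_cache)) {
    assign(key, builder(), envir = .cspws_cache)
  }
  get(key, envir = .cspws_cache)
}

test_instrument <- function() make_default_instrument()

## Small but physically valid simulation grid: voxel resolves the lower
## fractal bound, transverse extent exceeds the upper bound, axial extent
## covers most of the collection window.
test_grid_small <- function() grid_spec(36, 36, 448, 10)

## Grid used for cube-scale acceptance runs.
test_grid_cube <- function() grid_spec(128, 128, 512, 10)

test_template <- function() acf_model(2.2)

## Continuous-geometry lookup (65 nodes keeps unit tests quick).
test_map_cont <- function() {
  cached("map_cont", function() {
    build_sigma_db_lookup(test_template(), instrument = test_instrument(),
                          grid_size = 65)
  })
}

## Discrete-geometry lookup matching test_grid_cube().
test_map_cube <- function() {
  cached("map_cube", function() {
    build_sigma_db_lookup(test_template(), instrument = test_instrument(),
                          geometry = test_grid_cube())
  })
}

## A small cohort spec for fast feature/classification tests.
test_cohort_spec_small <- function(...) {
  cohort_spec(n_case = 8, n_control = 8, cells_per_patient = 4,
              image_width = 192, image_height = 144, seed = 42, ...)
}

test_backbone_small <- function() {
  cached("backbone_small", function() backbone_spec(width_mult = 0.25, seed = 7))
}

test_preproc_small <- function() preproc_config(c(64, 64))

## Elliptical mask helper for segmentation tests.
ellipse_mask <- function(h, w, cy, cx, a, b, theta = 0) {
  yy <- outer(seq_len(h) - cy, rep(1, w))
  xx <- outer(rep(1, h), seq_len(w) - cx)
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
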