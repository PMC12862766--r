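# Shared fixtures: all built in code at test time.

# Closed ring of a unit square with lower-left corner (x, y).
unit_square <- function(x, y) {
  cbind(x + c(0, 1, 1, 0, 0), y + c(0, 0, 1, 1, 0))
}

# Named list of unit-square polygons forming an nr x nc grid, row-major,
# IDs matching make_lattice().
grid_polygons <- function(nr, nc) {
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[[paste0("r", i, "c", j)]] <- unit_square(j - 1, nr - i)
    }
  }
  out
}

# Write a polygon list as a GeoJSON FeatureCollection.
write_grid_geojson <- function(polys, path, id_field = "GEOID") {
  feats <- lapply(names(polys), function(id) {
    ring <- lapply(seq_len(nrow(polys[[id]])), function(k) as.list(polys[[id]][k, ]))
    props <- list()
    props[[id_field]] <- id
    list(
      type = "Feature", properties = props,
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  path
}

# Minimal rate_samples object around a given cells x draws matrix, for
# testing the postprocessing layer without running a sampler.
fake_samples <- function(draw_mat, regions = NULL, groups = "all", times = 0,
                         events = NULL, pops = NULL) {
  n_cells <- nrow(draw_mat)
  G <- length(groups)
  Tt <- length(times)
  n <- n_cells / (G * Tt)
  stopifnot(n == round(n))
  if (is.null(regions)) regions <- paste0("u", seq_len(n))
  if (is.null(events)) events <- rep(1, n_cells)
  if (is.null(pops)) pops <- rep(1000, n_cells)
  structure(
    list(
      theta = array(draw_mat, c(n, G, Tt, ncol(draw_mat))),
      model = "ucar", likelihood = "binomial",
      region_ids = regions, group_labels = groups, time_labels = times,
      events = array(events, c(n, G, Tt)),
      pops = array(pops, c(n, G, Tt)),
      censored = array(FALSE, c(n, G, Tt)),
      censor_bound = array(NA_real_, c(n, G, Tt)),
      config = model_config(iterations = 2, burn_in = 0, seed = 1),
      hyper = NULL, effects = NULL, imputed = NULL,
      acceptance = c(z = NA_real_, eps = NA_real_, beta = NA_real_)
    ),
    class = "rate_samples"
  )
}

# Fits reused across test files (computed once per session).
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# Default sparse 10x10 scenario and its UCAR fit: the package's
# miniature stand-in for a tract-level mortality analysis.
default_sim <- function() {
  cached("default_sim", simulate_dataset(make_lattice(10, 10, "queen"), "ucar", seed = 101))
}

default_fit <- function() {
  cached(
    "default_fit",
    fit_ucar(default_sim()$input, model_config(iterations = 6000, burn_in = 2000, seed = 102))
  )
}
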