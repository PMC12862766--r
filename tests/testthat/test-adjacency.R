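test_that("grid contiguity matches the queen and rook rules", {
  polys2 <- grid_polygons(2, 2) # ids r1c1 r1c2 r2c1 r2c2
  rook <- build_adjacency(polys2, rule = "rook")
  expect_equal(rook$neighbors[[1]], c(2L, 3L)) # edge-sharing squares only
  queen <- build_adjacency(polys2, rule = "queen")
  expect_equal(queen$neighbors[[1]], c(2L, 3L, 4L)) # diagonal joins too

  q3 <- build_adjacency(grid_polygons(3, 3), rule = "queen")
  center <- match("r2c2", q3$region_ids)
  expect_length(q3$neighbors[[center]], 8)
})

test_that("queen adjacency is a superset of rook adjacency", {
  for (dims in list(c(2, 3), c(4, 4))) {
    polys <- grid_polygons(dims[1], dims[2])
    q <- build_adjacency(polys, rule = "queen")
    r <- build_adjacency(polys, rule = "rook")
    for (i in seq_along(q$neighbors)) {
      expect_true(all(r$neighbors[[i]] %in% q$neighbors[[i]]))
    }
  }
})

test_that("polygon contiguity agrees with the lattice generator", {
  for (rule in c("queen", "rook")) {
    from_polys <- build_adjacency(grid_polygons(4, 5), rule = rule)
    from_lattice <- make_lattice(4, 5, rule = rule)
    expect_equal(from_polys$region_ids, from_lattice$region_ids)
    expect_equal(from_polys$neighbors, from_lattice$neighbors)
  }
})

test_that("isolated units and bad IDs are rejected with names", {
  far <- list(a = unit_square(0, 0), b = unit_square(10, 10))
  expect_error(build_adjacency(far), "isolated.*a.*b|a, b")
  dup <- list(a = unit_square(0, 0), a = unit_square(1, 0))
  expect_error(build_adjacency(dup), "duplicate.*a")
})

test_that("validation reports every violation and is pure", {
  ok <- adjacency(c("A", "B"), list(2L, 1L))
  expect_identical(nrow(validate_adjacency(ok)), 0L)

  bad <- structure(
    list(region_ids = c("A", "B"), neighbors = list(2L, integer())),
    class = "adjacency"
  )
  rep1 <- validate_adjacency(bad)
  expect_setequal(rep1$violation, c("asymmetry", "isolated"))
  expect_true("B" %in% rep1$region[rep1$violation == "isolated"])

  loop <- structure(
    list(region_ids = c("A", "B"), neighbors = list(c(1L, 2L), 1L)),
    class = "adjacency"
  )
  rep2 <- validate_adjacency(loop)
  expect_true("self_loop" %in% rep2$violation)
  expect_equal(rep2$region[rep2$violation == "self_loop"], "A")
  # purity: input untouched
  expect_identical(loop$neighbors, list(c(1L, 2L), 1L))
})

test_that("built structures always validate clean", {
  for (dims in list(c(2, 2), c(3, 4))) {
    adj <- build_adjacency(grid_polygons(dims[1], dims[2]), rule = "queen")
    expect_identical(nrow(validate_adjacency(adj)), 0L)
  }
})

test_that("GAL serialization keys records by unit ID and round-trips", {
  adj <- adjacency(c("A", "B"), list(2L, 1L))
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(adj, path)
  lines <- readLines(path)
  expect_equal(lines, c("2", "A 1", "B", "B 1", "A"))

  big <- make_lattice(10, 10, "queen")
  p2 <- withr::local_tempfile(fileext = ".gal")
  write_gal(big, p2)
  back <- read_gal(p2)
  expect_identical(back$region_ids, big$region_ids)
  expect_identical(back$neighbors, big$neighbors)
})

test_that("malformed GAL input errors name the offending line", {
  p <- withr::local_tempfile(fileext = ".gal")
  writeLines(c("2", "A 2", "B", "B 1", "A"), p) # claims 2 neighbors, lists 1
  expect_error(read_gal(p), "line 3.*declares 2")
  writeLines(c("nope", "A 1", "B"), p)
  expect_error(read_gal(p), "line 1.*malformed")
  writeLines(c("2", "A 1", "C", "B 1", "A"), p)
  expect_error(read_gal(p), "unknown neighbor.*C")
})

test_that("GeoJSON polygon layers build the same graph as coordinate lists", {
  polys <- grid_polygons(3, 3)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_grid_geojson(polys, path, id_field = "GEOID")
  from_file <- build_adjacency(path, rule = "queen", id_field = "GEOID")
  from_list <- build_adjacency(polys, rule = "queen")
  expect_identical(from_file$region_ids, from_list$region_ids)
  expect_identical(from_file$neighbors, from_list$neighbors)
})
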