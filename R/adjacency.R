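#' Construct an adjacency structure
#'
#' An `adjacency` object holds the neighborhood graph of the geographic
#' units: an ordered vector of unique unit identifiers and, for each unit,
#' the integer indices (1-based, into that same order) of its neighbors.
#' The semantics match neighbor lists produced by polygon-contiguity
#' routines in spatial-weights software: symmetric, irreflexive, and --
#' because the conditional autoregressive prior requires it -- every unit
#' must have at least one neighbor.
#'
#' The region order is fixed at construction and all model arrays in the
#' rest of the package inherit it.
#'
#' @param region_ids Character vector of unique, non-missing unit IDs.
#' @param neighbors List of integer vectors, one per region, giving the
#'   indices of adjacent regions.
#' @param check If `TRUE` (default), error on any structural violation.
#' @return An object of class `adjacency`.
#' @seealso [validate_adjacency()], [build_adjacency()], [read_gal()],
#'   [make_lattice()]
#' @export
#' @examples
#' adj <- adjacency(c("A", "B"), list(2L, 1L))
#' n_regions(adj)
adjacency <- function(region_ids, neighbors, check = TRUE) {
  region_ids <- as.character(region_ids)
  if (anyNA(region_ids)) stop("region_ids must not contain missing values", call. = FALSE)
  dup <- unique(region_ids[duplicated(region_ids)])
  if (length(dup) > 0) {
    stop("duplicate region IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(neighbors) != length(region_ids)) {
    stop("neighbors must have one entry per region", call. = FALSE)
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(as.integer(x))))
  obj <- structure(
    list(region_ids = region_ids, neighbors = unname(neighbors)),
    class = "adjacency"
  )
  if (check) {
    report <- validate_adjacency(obj)
    if (nrow(report) > 0) {
      stop(
        "invalid adjacency structure:\n",
        paste(utils::capture.output(print(as.data.frame(report))), collapse = "\n"),
        call. = FALSE
      )
    }
  }
  obj
}

#' @export
print.adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(
    "<adjacency> ", length(x$region_ids), " regions, ",
    sum(deg) / 2, " edges (mean degree ", round(mean(deg), 2), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Number of regions in an adjacency structure
#' @param adj An [adjacency()] object.
#' @return Integer count of regions.
#' @export
n_regions <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  length(adj$region_ids)
}

#' Validate an adjacency structure
#'
#' Pure reporting: checks symmetry, irreflexivity, index range, and the
#' at-least-one-neighbor requirement of the CAR prior, and returns every
#' violation found. An empty report means the structure is valid.
#'
#' @param adj An object with `region_ids` and `neighbors` fields (it need
#'   not have passed construction checks).
#' @return A tibble with columns `violation` (one of `"out_of_range"`,
#'   `"self_loop"`, `"asymmetry"`, `"isolated"`), `region` (unit ID), and
#'   `detail`. Zero rows if and only if the structure is valid.
#' @export
validate_adjacency <- function(adj) {
  ids <- as.character(adj$region_ids)
  nb <- adj$neighbors
  n <- length(ids)
  rows <- list()
  add <- function(violation, region, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      violation = violation, region = region, detail = detail
    )
  }
  for (i in seq_len(n)) {
    v <- as.integer(nb[[i]])
    bad <- v[v < 1L | v > n | is.na(v)]
    if (length(bad) > 0) {
      add("out_of_range", ids[i], paste("indices:", paste(bad, collapse = ", ")))
    }
    if (i %in% v) add("self_loop", ids[i], "region listed as its own neighbor")
    for (j in setdiff(v[v >= 1L & v <= n & !is.na(v)], i)) {
      if (!(i %in% as.integer(nb[[j]]))) {
        add("asymmetry", ids[i], paste0("lists ", ids[j], " but is not listed back"))
      }
    }
    if (length(v) == 0) add("isolated", ids[i], "region has no neighbors")
  }
  if (length(rows) == 0) {
    tibble::tibble(violation = character(), region = character(), detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

# ---- polygon contiguity ----------------------------------------------------

# Canonical string key for an exact coordinate (no snap tolerance).
vertex_keys <- function(coords) {
  unique(paste(sprintf("%.17g", coords[, 1]), sprintf("%.17g", coords[, 2]), sep = "|"))
}

#' Build polygon contiguity (queen or rook)
#'
#' Computes the neighborhood graph of a polygon layer from shared boundary
#' points: under the queen rule two units are neighbors if their boundaries
#' share at least one point; under the rook rule they must share an edge of
#' positive length, detected as two or more shared boundary points.
#' Coordinates are compared exactly -- layers whose shared borders are
#' digitized with coincident vertices (the norm for census products) work
#' directly; layers with sliver gaps must be pre-cleaned or supplied as a
#' GAL file instead.
#'
#' @param boundaries Either the path to a GeoJSON file of polygon features,
#'   or a named list mapping unit IDs to ring coordinate matrices (two
#'   columns, x and y; multiple rings may be given as a list of matrices).
#' @param rule `"queen"` (default) or `"rook"`.
#' @param id_field For GeoJSON input, the property holding the unit ID.
#' @return An [adjacency()] object whose region order follows the input
#'   layer order.
#' @export
#' @examples
#' sq <- function(x, y) cbind(x + c(0, 1, 1, 0, 0), y + c(0, 0, 1, 1, 0))
#' grid2 <- list(a = sq(0, 0), b = sq(1, 0), c = sq(0, 1), d = sq(1, 1))
#' build_adjacency(grid2, rule = "rook")
build_adjacency <- function(boundaries, rule = c("queen", "rook"), id_field = "GEOID") {
  rule <- match.arg(rule)
  if (is.character(boundaries) && length(boundaries) == 1) {
    boundaries <- read_geojson_polygons(boundaries, id_field = id_field)
  }
  ids <- names(boundaries)
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    bad <- which(is.null(ids) | is.na(ids) | ids == "")
    stop("null or empty unit IDs at positions: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) stop("duplicate unit IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  n <- length(ids)
  if (n < 2) stop("need at least 2 polygons", call. = FALSE)

  keys <- lapply(boundaries, function(geom) {
    if (is.matrix(geom)) geom <- list(geom)
    unique(unlist(lapply(geom, vertex_keys), use.names = FALSE))
  })

  # invert: vertex key -> unit indices touching it
  touch <- split(
    rep(seq_len(n), lengths(keys)),
    unlist(keys, use.names = FALSE)
  )
  pair_count <- new.env(hash = TRUE, parent = emptyenv())
  for (units in touch) {
    units <- unique(units)
    if (length(units) < 2) next
    for (a in seq_along(units)) {
      for (b in seq_along(units)) {
        if (a < b) {
          key <- paste(units[a], units[b])
          prev <- get0(key, envir = pair_count, ifnotfound = 0L)
          assign(key, prev + 1L, envir = pair_count)
        }
      }
    }
  }
  need <- if (rule == "queen") 1L else 2L
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  for (key in ls(pair_count)) {
    if (get(key, envir = pair_count) >= need) {
      ij <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
      nb[[ij[1]]] <- c(nb[[ij[1]]], ij[2])
      nb[[ij[2]]] <- c(nb[[ij[2]]], ij[1])
    }
  }
  isolated <- ids[lengths(nb) == 0]
  if (length(isolated) > 0) {
    stop(
      "isolated unit(s) with no neighbors: ", paste(isolated, collapse = ", "),
      "; every geographic unit must have at least 1 neighbor",
      call. = FALSE
    )
  }
  adjacency(ids, nb)
}

#' Read polygon features from a GeoJSON file
#'
#' Minimal GeoJSON FeatureCollection reader for Polygon and MultiPolygon
#' geometries, returning the ring coordinates needed for contiguity.
#'
#' @param path Path to a GeoJSON file.
#' @param id_field Feature property carrying the unit ID.
#' @return Named list (unit ID -> list of ring coordinate matrices), in
#'   feature order.
#' @export
read_geojson_polygons <- function(path, id_field = "GEOID") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  if (anyNA(ids)) {
    stop(
      "null unit ID (property '", id_field, "') in feature(s): ",
      paste(which(is.na(ids)), collapse = ", "),
      call. = FALSE
    )
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) stop("duplicate unit IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
  }
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g$type)) stop("feature without geometry", call. = FALSE)
    if (g$type == "Polygon") {
      lapply(g$coordinates, ring_to_matrix)
    } else if (g$type == "MultiPolygon") {
      unlist(lapply(g$coordinates, function(poly) lapply(poly, ring_to_matrix)),
        recursive = FALSE
      )
    } else {
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    }
  })
  names(geoms) <- ids
  geoms
}

# ---- GAL serialization -----------------------------------------------------

#' Write an adjacency structure as GAL text
#'
#' The GAL neighbor-list format written here keys records by the unit IDs
#' themselves (not positional integers), so files join unambiguously
#' against event and population tables. The first line holds the region
#' count; each region then contributes a `"<id> <k>"` line followed by a
#' line listing its `k` neighbor IDs.
#'
#' @param adj A valid [adjacency()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  if (any(grepl("[[:space:]]", adj$region_ids))) {
    stop("GAL serialization requires whitespace-free unit IDs", call. = FALSE)
  }
  lines <- character(1 + 2 * length(adj$region_ids))
  lines[1] <- as.character(length(adj$region_ids))
  for (i in seq_along(adj$region_ids)) {
    nb <- adj$neighbors[[i]]
    lines[2 * i] <- paste(adj$region_ids[i], length(nb))
    lines[2 * i + 1] <- paste(adj$region_ids[nb], collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GAL neighbor-list file
#'
#' Inverse of [write_gal()]; `read_gal(write_gal(adj))` reproduces the
#' structure exactly, including region order. Malformed headers, truncated
#' records, neighbor-count mismatches, and unknown neighbor IDs raise
#' errors naming the offending line.
#'
#' @param path Path to a GAL file.
#' @return An [adjacency()] object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  while (length(lines) > 0 && trimws(lines[length(lines)]) == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 1) stop("empty GAL file", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n) || n < 1) stop("line 1: malformed GAL header '", lines[1], "'", call. = FALSE)
  if (length(lines) < 1 + 2 * n) {
    stop("GAL file truncated: header declares ", n, " regions but only ",
      (length(lines) - 1) %/% 2, " records present",
      call. = FALSE
    )
  }
  ids <- character(n)
  raw_nb <- vector("list", n)
  for (i in seq_len(n)) {
    hline <- 2 * i
    rec <- strsplit(trimws(lines[hline]), "[[:space:]]+")[[1]]
    if (length(rec) != 2) {
      stop("line ", hline, ": expected '<id> <count>', got '", lines[hline], "'", call. = FALSE)
    }
    k <- suppressWarnings(as.integer(rec[2]))
    if (is.na(k) || k < 0) {
      stop("line ", hline, ": bad neighbor count '", rec[2], "'", call. = FALSE)
    }
    ids[i] <- rec[1]
    nbids <- strsplit(trimws(lines[hline + 1]), "[[:space:]]+")[[1]]
    nbids <- nbids[nbids != ""]
    if (length(nbids) != k) {
      stop(
        "line ", hline + 1, ": region '", rec[1], "' declares ", k,
        " neighbors but lists ", length(nbids),
        call. = FALSE
      )
    }
    raw_nb[[i]] <- nbids
  }
  nb <- lapply(seq_len(n), function(i) {
    idx <- match(raw_nb[[i]], ids)
    if (anyNA(idx)) {
      stop(
        "line ", 2 * i + 1, ": unknown neighbor ID(s): ",
        paste(raw_nb[[i]][is.na(idx)], collapse = ", "),
        call. = FALSE
      )
    }
    idx
  })
  adjacency(ids, nb)
}
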