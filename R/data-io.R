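#' The fixed 10-year age-group vocabulary
#'
#' Age-standardization and individual-record aggregation use a fixed set of
#' ten-year age bands. Labels supplied elsewhere must be drawn from this
#' vocabulary (in ascending age order) when age-standardizing with the
#' shipped US Standard Population weights.
#'
#' @return Character vector of the ten labels, youngest first.
#' @export
age_group_labels <- function() {
  c(
    "0-4", "5-14", "15-24", "25-34", "35-44",
    "45-54", "55-64", "65-74", "75-84", "85up"
  )
}

age_group_bounds <- function(labels = age_group_labels()) {
  full <- age_group_labels()
  lo <- c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85)
  hi <- c(4, 14, 24, 34, 44, 54, 64, 74, 84, Inf)
  idx <- match(labels, full)
  if (anyNA(idx)) {
    stop(
      "unknown age group label(s): ", paste(labels[is.na(idx)], collapse = ", "),
      "; allowed: ", paste(full, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(group = full[idx], lo = lo[idx], hi = hi[idx])[order(idx), ]
}

#' Aggregate individual-level event records to unit (and age-group) counts
#'
#' Counts one row per event into the cells of the analysis: each record
#' carries a unit ID and, when age groups are requested, a non-negative
#' integer age that is binned into the ten-year vocabulary (for example age
#' 84 falls in "75-84" and age 85 in "85up"). Units with no records receive
#' a zero count, so aggregation conserves the number of retained records.
#'
#' @param records Data frame with a `region` column and, if `groups` is
#'   given, an `age` column of non-negative integers.
#' @param regions Ordered character vector of all unit IDs in the analysis.
#' @param groups Optional character vector of age-group labels (a subset of
#'   [age_group_labels()], ascending).
#' @param strict If `TRUE` (default), a record whose unit ID is not in
#'   `regions` is an error naming the offending IDs; if `FALSE`, such
#'   records are dropped with a warning.
#' @return Tibble with columns `region`, (`group`,) `events`, one row per
#'   cell, in `regions` (and vocabulary) order.
#' @export
#' @examples
#' rec <- tibble::tibble(region = c("A", "A", "A"), age = c(84, 85, 30))
#' aggregate_events(rec, regions = c("A", "B"), groups = age_group_labels())
aggregate_events <- function(records, regions, groups = NULL, strict = TRUE) {
  records <- tibble::as_tibble(records)
  if (!"region" %in% names(records)) stop("records must have a 'region' column", call. = FALSE)
  regions <- as.character(regions)
  rid <- as.character(records$region)
  unknown <- unique(rid[!rid %in% regions])
  if (length(unknown) > 0) {
    if (strict) {
      stop(
        "record unit ID(s) not in the region list: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    warning(
      "dropping ", sum(!rid %in% regions), " record(s) with unknown unit ID(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
    records <- records[rid %in% regions, , drop = FALSE]
    rid <- as.character(records$region)
  }
  if (is.null(groups)) {
    counts <- table(factor(rid, levels = regions))
    return(tibble::tibble(region = regions, events = as.integer(counts)))
  }
  if (!"age" %in% names(records)) {
    stop("records must have an 'age' column when groups are requested", call. = FALSE)
  }
  age <- records$age
  if (any(is.na(age)) || any(age < 0) || any(age != floor(age))) {
    stop("ages must be non-negative integers", call. = FALSE)
  }
  bounds <- age_group_bounds(groups)
  bin <- rep(NA_character_, length(age))
  for (k in seq_len(nrow(bounds))) {
    bin[age >= bounds$lo[k] & age <= bounds$hi[k]] <- bounds$group[k]
  }
  if (anyNA(bin)) {
    stop(
      "age(s) outside all requested groups: ",
      paste(unique(age[is.na(bin)]), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- table(
    factor(rid, levels = regions),
    factor(bin, levels = bounds$group)
  )
  tidyr::expand_grid(region = regions, group = bounds$group) |>
    dplyr::mutate(events = as.integer(counts[cbind(.data$region, .data$group)]))
}

#' Validate an event or population table
#'
#' Pure reporting of the data problems that break model assembly: missing
#' (null) cells, non-numeric values in the numeric column, and duplicated
#' keys (unit ID, optionally crossed with group and time). An empty report
#' means the table is usable.
#'
#' @param table Data frame with a `region` column, optionally `group` and
#'   `time`, and the value column named by `value_col`.
#' @param value_col Name of the numeric column to check
#'   (`"population"` for population tables, `"events"` for event tables).
#' @return Tibble with columns `violation` (`"null"`, `"non_numeric"`,
#'   `"duplicate_key"`), `row`, `detail`; zero rows iff clean.
#' @export
validate_count_table <- function(table, value_col = "population") {
  table <- tibble::as_tibble(table)
  rows <- list()
  add <- function(violation, row, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      violation = violation, row = as.integer(row), detail = detail
    )
  }
  if (!"region" %in% names(table)) {
    add("null", NA, "missing 'region' column")
  }
  if (!value_col %in% names(table)) {
    add("null", NA, paste0("missing '", value_col, "' column"))
  }
  key_cols <- intersect(c("region", "group", "time"), names(table))
  for (cn in key_cols) {
    bad <- which(is.na(table[[cn]]) | as.character(table[[cn]]) == "")
    for (r in bad) add("null", r, paste0("null ", cn))
  }
  if (value_col %in% names(table)) {
    v <- table[[value_col]]
    if (is.character(v) || is.factor(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      for (r in which(is.na(parsed) & !is.na(v))) {
        add("non_numeric", r, paste0(value_col, " = '", v[r], "'"))
      }
      for (r in which(is.na(v))) add("null", r, paste0("null ", value_col))
    } else {
      for (r in which(is.na(v))) add("null", r, paste0("null ", value_col))
    }
  }
  if (length(key_cols) > 0 && nrow(table) > 0) {
    key <- do.call(paste, c(lapply(key_cols, function(cn) as.character(table[[cn]])), sep = "\r"))
    dup_rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    dup_rows <- dup_rows[duplicated(key[dup_rows])] # report each extra occurrence once
    for (r in dup_rows) {
      add(
        "duplicate_key", r,
        paste0("duplicate key (", paste(key_cols, collapse = ", "), ") = (",
          gsub("\r", ", ", key[r]), ")"
        )
      )
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(violation = character(), row = integer(), detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' @rdname validate_count_table
#' @export
validate_population_table <- function(table) validate_count_table(table, "population")

# ---- model input -----------------------------------------------------------

order_group_labels <- function(labels) {
  labels <- unique(as.character(labels))
  vocab <- age_group_labels()
  if (all(labels %in% vocab)) {
    vocab[vocab %in% labels]
  } else {
    sort(labels)
  }
}

check_time_spacing <- function(times) {
  times <- sort(unique(as.numeric(times)))
  if (length(times) < 2) {
    return(times)
  }
  gaps <- diff(times)
  if (all(times == floor(times))) {
    ok <- length(unique(gaps)) == 1
  } else {
    ok <- all(abs(gaps - gaps[1]) <= 1e-9 * max(abs(gaps)))
  }
  if (!ok) {
    stop(
      "time periods must be an equal distance apart; observed gaps: ",
      paste(format(gaps), collapse = ", "),
      call. = FALSE
    )
  }
  times
}

#' Assemble validated tables into a model input
#'
#' Joins an event table and a population table against an adjacency
#' structure and reshapes them into the array rank the chosen model uses:
#' a region vector for `ucar`, a region-by-group matrix for `mcar`, and a
#' region-by-group-by-time array for `mstcar`. Region order is inherited
#' from the adjacency; group order follows the age vocabulary when labels
#' are age bands (lexicographic otherwise); time labels must be numeric and
#' equally spaced. The result is row-order-stable: permuting input table
#' rows never changes the arrays.
#'
#' @param events Data frame: `region`, (`group`,) (`time`,) `events`, and
#'   optionally logical `censored` plus numeric `censor_bound` marking
#'   privacy-censored cells whose count is known only to lie in
#'   `[0, censor_bound - 1]`.
#' @param population Data frame: same keys plus `population`.
#' @param adjacency An [adjacency()] object.
#' @param kind `"ucar"`, `"mcar"`, or `"mstcar"`.
#' @param fill_zeros If `TRUE`, event cells absent from `events` are filled
#'   with 0; by default a missing cell is an error (silent zero-filling
#'   hides join bugs). Population cells must always be complete.
#' @return A `model_input` object holding the arrays, censoring mask,
#'   adjacency, and labels.
#' @export
assemble_model_input <- function(events, population, adjacency,
                                 kind = c("ucar", "mcar", "mstcar"),
                                 fill_zeros = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(adjacency, "adjacency"))
  events <- tibble::as_tibble(events)
  population <- tibble::as_tibble(population)

  # censored cells legitimately carry no count; validate the rest
  ev_check <- events
  if ("censored" %in% names(events)) {
    cflag <- isTRUE_vec(events$censored)
    ev_check$events[cflag] <- 0
  }
  ev_rep <- validate_count_table(ev_check, "events")
  if (nrow(ev_rep) > 0) {
    stop(
      "event table fails validation:\n",
      paste(utils::capture.output(print(as.data.frame(ev_rep))), collapse = "\n"),
      call. = FALSE
    )
  }
  pop_rep <- validate_count_table(population, "population")
  if (nrow(pop_rep) > 0) {
    stop(
      "population table fails validation:\n",
      paste(utils::capture.output(print(as.data.frame(pop_rep))), collapse = "\n"),
      call. = FALSE
    )
  }

  need_group <- kind %in% c("mcar", "mstcar")
  need_time <- kind == "mstcar"
  if (need_group && !"group" %in% names(events)) {
    stop(kind, " requires a 'group' column in the event table", call. = FALSE)
  }
  if (need_time && !"time" %in% names(events)) {
    stop("mstcar requires a 'time' column in the event table", call. = FALSE)
  }

  regions <- adjacency$region_ids
  for (nm in c("events", "population")) {
    tbl <- if (nm == "events") events else population
    extra <- setdiff(unique(as.character(tbl$region)), regions)
    if (length(extra) > 0) {
      stop(
        "unit(s) in ", nm, " table but not in adjacency: ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }

  groups <- if ("group" %in% names(events)) {
    order_group_labels(events$group)
  } else if ("group" %in% names(population)) {
    order_group_labels(population$group)
  } else {
    "all"
  }
  times <- if ("time" %in% names(events)) {
    if (!is.numeric(events$time)) stop("time labels must be numeric", call. = FALSE)
    check_time_spacing(events$time)
  } else {
    0
  }
  if (kind == "ucar" && (length(groups) > 1 || length(times) > 1)) {
    stop("ucar input must not vary by group or time; use mcar/mstcar", call. = FALSE)
  }
  if (kind == "mcar" && length(times) > 1) {
    stop("mcar input must not vary by time; use mstcar", call. = FALSE)
  }

  n <- length(regions)
  G <- length(groups)
  Tt <- length(times)
  dims <- c(n, G, Tt)
  dn <- list(region = regions, group = groups, time = as.character(times))

  cell_index <- function(tbl) {
    i <- match(as.character(tbl$region), regions)
    g <- if ("group" %in% names(tbl)) match(as.character(tbl$group), groups) else rep(1L, nrow(tbl))
    t <- if ("time" %in% names(tbl)) match(as.numeric(tbl$time), times) else rep(1L, nrow(tbl))
    if (anyNA(g)) {
      stop("group label(s) not in the analysis set: ",
        paste(unique(tbl$group[is.na(g)]), collapse = ", "),
        call. = FALSE
      )
    }
    cbind(i, g, t)
  }

  Y <- array(NA_real_, dims, dimnames = dn)
  idx <- cell_index(events)
  Y[idx] <- as.numeric(events$events)
  censored <- array(FALSE, dims, dimnames = dn)
  bound <- array(NA_real_, dims, dimnames = dn)
  if ("censored" %in% names(events)) {
    cflag <- isTRUE_vec(events$censored)
    censored[idx] <- cflag
    if (any(cflag)) {
      if (!"censor_bound" %in% names(events)) {
        stop("censored cells require a 'censor_bound' column", call. = FALSE)
      }
      b <- as.numeric(events$censor_bound)
      if (any(cflag & (is.na(b) | b <= 0))) {
        stop("censored cells must carry a positive censor_bound", call. = FALSE)
      }
      bound[idx] <- ifelse(cflag, b, NA_real_)
    }
  }
  missing_cells <- which(is.na(Y) & !censored, arr.ind = TRUE)
  if (nrow(missing_cells) > 0) {
    if (!fill_zeros) {
      show <- utils::head(missing_cells, 5)
      stop(
        nrow(missing_cells), " event cell(s) absent from the event table (e.g. ",
        paste(apply(show, 1, function(r) {
          paste0("(", regions[r[1]], ", ", groups[r[2]], ", ", times[r[3]], ")")
        }), collapse = " "),
        "); pass fill_zeros = TRUE to fill them with 0",
        call. = FALSE
      )
    }
    Y[is.na(Y) & !censored] <- 0
  }
  if (any(!censored & (Y < 0 | Y != floor(Y)), na.rm = TRUE)) {
    stop("event counts must be non-negative integers", call. = FALSE)
  }

  Np <- array(NA_real_, dims, dimnames = dn)
  Np[cell_index(population)] <- as.numeric(population$population)
  if (anyNA(Np)) {
    miss <- which(is.na(Np), arr.ind = TRUE)[1, ]
    stop(
      "population cell missing for (", regions[miss[1]], ", ", groups[miss[2]],
      ", ", times[miss[3]], "); population tables must be complete",
      call. = FALSE
    )
  }
  if (any(Np < 0)) stop("populations must be non-negative", call. = FALSE)

  structure(
    list(
      events = Y, pops = Np, censored = censored, censor_bound = bound,
      adjacency = adjacency, kind = kind,
      group_labels = groups, time_labels = times
    ),
    class = "model_input"
  )
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) {
    !is.na(x) & x
  } else {
    tolower(as.character(x)) %in% c("true", "t", "1", "yes")
  }
}

#' @export
print.model_input <- function(x, ...) {
  cat(
    "<model_input> kind=", x$kind, ": ",
    dim(x$events)[1], " regions x ", dim(x$events)[2], " groups x ",
    dim(x$events)[3], " periods; ", sum(x$censored), " censored cell(s)\n",
    sep = ""
  )
  invisible(x)
}

# ---- estimate table I/O ----------------------------------------------------

#' Write / read an estimates table
#'
#' Long-format delimited output with one row per (region, group, time)
#' cell and the full estimate-quality columns. Values round-trip
#' losslessly: `read_estimates(write_estimates(x, p))` reproduces `x`.
#' Suppression is a flag, not a deletion -- suppressed rows keep their
#' computed values so users can re-threshold.
#'
#' @param table An estimates tibble as produced by [get_estimates()].
#' @param path Output file path.
#' @param sep Field delimiter (`","` default; tab and pipe accepted).
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_estimates <- function(table, path, sep = ",") {
  readr::write_delim(table, path, delim = sep)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path, sep = ",") {
  readr::read_delim(
    path,
    delim = sep, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      region = readr::col_character(),
      group = readr::col_character(),
      time = readr::col_character(),
      reliable = readr::col_logical(),
      suppressed = readr::col_logical(),
      .default = readr::col_double()
    )
  )
}
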