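#' Regular lattice adjacency
#'
#' Grid contiguity graph for an `nrow` x `ncol` lattice of square cells
#' with deterministic unit IDs `"r{i}c{j}"` (row-major order). Queen
#' contiguity includes the diagonal neighbors, rook only the edge-sharing
#' ones. The synthetic worlds used for validation are built on these
#' lattices.
#'
#' @param nrow,ncol Lattice dimensions (`nrow * ncol >= 2`; a 1 x 1
#'   lattice has an isolated unit and errors).
#' @param rule `"queen"` (default) or `"rook"`.
#' @return An [adjacency()] object.
#' @export
#' @examples
#' make_lattice(3, 3, rule = "rook")
make_lattice <- function(nrow, ncol, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  if (nrow * ncol < 2) {
    stop("1 x 1 lattice has an isolated unit; need nrow * ncol >= 2", call. = FALSE)
  }
  idx <- function(i, j) (i - 1L) * ncol + j
  ids <- as.vector(t(outer(seq_len(nrow), seq_len(ncol), function(i, j) paste0("r", i, "c", j))))
  offsets <- if (rule == "rook") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3))[-5, ]
  }
  nb <- vector("list", nrow * ncol)
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      ii <- i + offsets[, 1]
      jj <- j + offsets[, 2]
      ok <- ii >= 1 & ii <= nrow & jj >= 1 & jj <= ncol
      nb[[idx(i, j)]] <- sort(idx(ii[ok], jj[ok]))
    }
  }
  adjacency(ids, nb)
}

# Exact draw from the intrinsic CAR prior under the sum-to-zero
# constraint, via the spectral decomposition of the graph Laplacian: the
# improper prior is proper on the span of the eigenvectors with nonzero
# eigenvalue, with variance tau2 / lambda_k along each.
ricar <- function(Qeig, tau2) {
  keep <- Qeig$values > 1e-8
  as.vector(Qeig$vectors[, keep, drop = FALSE] %*%
    (stats::rnorm(sum(keep)) * sqrt(tau2 / Qeig$values[keep])))
}

# Draw an N x G matrix from the proper multivariate CAR: columns couple
# through Sigma, rows through (D - rho W)^-1.
rmcar <- function(Uq, Sigma) {
  G <- nrow(Sigma)
  E <- matrix(stats::rnorm(ncol(Uq) * G), ncol(Uq), G)
  backsolve(Uq, E) %*% chol(Sigma)
}

#' Simulate a lattice world with known true rates
#'
#' Generates event and population data from the model's own generative
#' assumptions so that every estimator in the package can be validated
#' against a known truth. Spatial effects are drawn from the stated CAR
#' prior (intrinsic pairwise-difference CAR under the sum-to-zero
#' constraint for `ucar`; the proper multivariate CAR for `mcar`, plus a
#' stationary per-group AR(1) across periods for `mstcar`), heterogeneity
#' is iid normal, rates come through the model's link, populations are
#' uniform on `pop_range`, and counts are drawn from the likelihood.
#' Optionally, small positive counts below `censor_bound` are marked
#' censored to exercise imputation. Fully seeded: the same seed
#' reproduces the dataset exactly.
#'
#' The default scenario mirrors a sparse tract-level mortality setting in
#' miniature: a 10 x 10 lattice stands in for a state's tracts,
#' populations span 50-2,000, and the baseline rate (about 1,200 per
#' 100,000) is low enough that a "fewer than 16 events" crude-display
#' rule suppresses a large share of cells.
#'
#' @param adj An [adjacency()] object (e.g. from [make_lattice()]).
#' @param kind `"ucar"`, `"mcar"`, or `"mstcar"`.
#' @param params Named list overriding generative parameters: `base_rate`
#'   (default 0.012), `beta` (link-scale intercept per group, overrides
#'   `base_rate`), `tau2` (0.2, ucar), `sigma2` (0.05), `Sigma`
#'   (between-group covariance; default variance 0.15, correlation 0.5),
#'   `rho` (0.9), `ar` (0.8 per group), `n_groups` (2), `n_times` (3),
#'   `likelihood` (`"binomial"`), `group_labels`, `time_labels`.
#' @param pop_range Positive population bounds, default `c(50, 2000)`.
#' @param censor_bound Optional bound: counts in `(0, censor_bound)` are
#'   censored.
#' @param seed Integer seed.
#' @return List with `input` (a `model_input` ready for the matching
#'   `fit_*`) and `truth` (per-cell true rates plus the generative
#'   parameters).
#' @export
simulate_dataset <- function(adj, kind = c("ucar", "mcar", "mstcar"),
                             params = list(), pop_range = c(50, 2000),
                             censor_bound = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(adj, "adjacency"))
  if (any(pop_range <= 0) || pop_range[2] < pop_range[1]) {
    stop("pop_range must be positive and non-decreasing", call. = FALSE)
  }
  n <- n_regions(adj)
  lik <- params$likelihood %||% "binomial"
  if (!lik %in% c("binomial", "poisson")) stop("invalid likelihood", call. = FALSE)

  G <- if (kind == "ucar") 1L else as.integer(params$n_groups %||% 2L)
  Tt <- if (kind == "mstcar") as.integer(params$n_times %||% 3L) else 1L
  base_rate <- params$base_rate %||% 0.012
  beta <- params$beta %||% rep(
    if (lik == "binomial") stats::qlogis(base_rate) else log(base_rate), G
  )
  beta <- rep(beta, length.out = G)
  sigma2 <- params$sigma2 %||% 0.05
  tau2 <- params$tau2 %||% 0.2
  Sigma <- params$Sigma %||% (0.15 * (diag(G) * 0.5 + 0.5))
  Sigma <- as.matrix(Sigma)
  rho <- params$rho %||% 0.9
  ar <- rep(params$ar %||% 0.8, length.out = G)
  group_labels <- params$group_labels %||% (if (G == 1) "all" else paste0("g", seq_len(G)))
  time_labels <- params$time_labels %||% (if (Tt == 1) 0 else seq_len(Tt))

  W <- adjacency_matrix(adj)
  m <- lengths(adj$neighbors)

  set.seed(seed)
  Z <- array(0, c(n, G, Tt))
  if (kind == "ucar") {
    Qeig <- eigen(diag(m) - W, symmetric = TRUE)
    Z[, 1, 1] <- ricar(Qeig, tau2)
  } else {
    Uq <- chol(diag(m) - rho * W)
    Z[, , 1] <- rmcar(Uq, Sigma)
    if (Tt > 1) {
      for (t in 2:Tt) {
        Z[, , t] <- sweep(slice2(Z, t - 1), 2, ar, "*") + rmcar(Uq, Sigma)
      }
    }
  }
  eps <- array(stats::rnorm(n * G * Tt, sd = sqrt(sigma2)), c(n, G, Tt))
  lin <- Z + eps
  for (t in seq_len(Tt)) lin[, , t] <- sweep(slice2(lin, t), 2, beta, "+")
  theta <- linkinv(lin, lik)

  pops <- array(round(stats::runif(n * G * Tt, pop_range[1], pop_range[2])), c(n, G, Tt))
  Y <- array(
    if (lik == "binomial") {
      stats::rbinom(n * G * Tt, size = as.vector(pops), prob = as.vector(theta))
    } else {
      stats::rpois(n * G * Tt, lambda = as.vector(pops) * as.vector(theta))
    },
    c(n, G, Tt)
  )

  censored <- array(FALSE, c(n, G, Tt))
  bound <- array(NA_real_, c(n, G, Tt))
  events <- array(as.numeric(Y), c(n, G, Tt))
  if (!is.null(censor_bound)) {
    stopifnot(censor_bound > 0)
    censored <- Y > 0 & Y < censor_bound
    bound[censored] <- censor_bound
    events[censored] <- NA_real_
  }
  dn <- list(
    region = adj$region_ids, group = group_labels, time = as.character(time_labels)
  )
  dimnames(events) <- dimnames(pops) <- dimnames(censored) <- dimnames(bound) <- dn

  input <- structure(
    list(
      events = events, pops = pops, censored = censored, censor_bound = bound,
      adjacency = adj, kind = kind,
      group_labels = group_labels, time_labels = time_labels
    ),
    class = "model_input"
  )
  truth <- list(
    table = tibble::tibble(
      region = rep(adj$region_ids, times = G * Tt),
      group = rep(rep(group_labels, each = n), times = Tt),
      time = rep(as.character(time_labels), each = n * G),
      true_theta = as.vector(theta),
      true_events = as.vector(Y)
    ),
    beta = beta, tau2 = tau2, sigma2 = sigma2, Sigma = Sigma,
    rho = rho, ar = ar, likelihood = lik, seed = seed
  )
  list(input = input, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
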