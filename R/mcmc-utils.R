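# Internal MCMC helpers shared by the CAR samplers.

# Greedy vertex coloring of the neighborhood graph. Sites sharing a color
# are mutually non-adjacent, so their full conditionals factorize given the
# rest and can be Metropolis-updated simultaneously as one valid Gibbs
# block. Deterministic: vertices processed by decreasing degree, ties by
# index.
greedy_coloring <- function(neighbors) {
  n <- length(neighbors)
  ord <- order(-lengths(neighbors), seq_len(n))
  color <- integer(n)
  for (i in ord) {
    used <- color[neighbors[[i]]]
    used <- used[used > 0L]
    k <- 1L
    while (k %in% used) k <- k + 1L
    color[i] <- k
  }
  color
}

n_components <- function(neighbors) {
  n <- length(neighbors)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in neighbors[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  comps
}

# Unique undirected edges (i < j) as a 2-column matrix.
edge_list <- function(neighbors) {
  i <- rep(seq_along(neighbors), lengths(neighbors))
  j <- unlist(neighbors, use.names = FALSE)
  keep <- i < j
  cbind(i[keep], j[keep])
}

adjacency_matrix <- function(adj) {
  n <- length(adj$region_ids)
  W <- matrix(0, n, n)
  e <- edge_list(adj$neighbors)
  W[e] <- 1
  W[e[, c(2, 1), drop = FALSE]] <- 1
  W
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

# Inverse-Wishart draw via the Wishart of the inverse scale.
riwish <- function(df, S) {
  Si <- chol2inv(chol(S))
  Si <- (Si + t(Si)) / 2
  X <- stats::rWishart(1, df, Si)[, , 1]
  out <- chol2inv(chol(X))
  (out + t(out)) / 2
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Unnormalized cell log-likelihood (terms constant in the linear predictor
# dropped): binomial-logit y*l - n*log(1+e^l); Poisson-log with population
# offset y*l - n*e^l. Zero-population cells contribute nothing.
loglik_term <- function(y, n, lin, likelihood) {
  out <- if (likelihood == "binomial") {
    y * lin - n * softplus(lin)
  } else {
    y * lin - n * exp(ifelse(lin > 300, 300, lin))
  }
  out[n <= 0] <- 0
  out
}

linkinv <- function(lin, likelihood) {
  if (likelihood == "binomial") stats::plogis(lin) else exp(lin)
}

# Truncated count draw: the censored-cell likelihood restricted to
# {0, ..., bound - 1}, sampled by inversion of the CDF.
rtrunc_count <- function(theta, n, bound, likelihood) {
  stopifnot(all(bound > 0))
  k <- pmax(ceiling(bound) - 1, 0)
  if (likelihood == "binomial") {
    size <- round(n)
    hi <- stats::pbinom(k, size, pmin(theta, 1))
    u <- stats::runif(length(theta)) * hi
    out <- stats::qbinom(u, size, pmin(theta, 1))
  } else {
    lam <- n * theta
    hi <- stats::ppois(k, lam)
    u <- stats::runif(length(theta)) * hi
    out <- stats::qpois(u, lam)
  }
  pmin(out, k)
}

# Batch-means Monte Carlo standard error of the chain median: split the
# (ordered) chain into nb contiguous batches and take the spread of the
# batch medians.
mcse_median <- function(x, nb = 20) {
  n <- length(x)
  nb <- min(nb, max(2, n %/% 10))
  idx <- cut(seq_len(n), nb, labels = FALSE)
  bm <- tapply(x, idx, stats::median)
  stats::sd(bm) / sqrt(nb)
}

# Effective sample size from the initial positive autocorrelations.
ess_chain <- function(x, lag_max = min(500, length(x) - 1)) {
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  neg <- which(a < 0)
  if (length(neg) > 0) a <- a[seq_len(neg[1] - 1)]
  max(1, length(x) / (1 + 2 * sum(a)))
}

# Robbins-Monro step for log proposal scales during burn-in.
adapt_step <- function(sweep) 2 * sweep^-0.6
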