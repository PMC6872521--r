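#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-norm distance between the empirical CDFs of two samples,
#' `sup_x |ECDF_a(x) - ECDF_b(x)|`, in \[0, 1\]. Implemented directly (the
#' statistic is evaluated thousands of times inside the MCMC loop);
#' agreement with [stats::ks.test()] is exercised in the test suite.
#'
#' @param a,b non-empty numeric vectors.
#' @return The KS statistic.
#' @export
ks_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("samples must be finite")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  ind <- c(rep(1 / n_a, n_a), rep(-1 / n_b, n_b))[ord]
  cum <- cumsum(ind)
  # at tied pooled values only the last cumulative value is an ECDF gap
  x <- pooled[ord]
  keep <- c(diff(x) != 0, TRUE)
  max(abs(cum[keep]))
}

#' Fit the antigen-representation factor model
#'
#' Infers the factor vector `p` (one weight in \[-1, 1\] per
#' physicochemical feature) that makes the feature-sum distribution of
#' represented antigens (`F1`) maximally different from that of the
#' control proteome (`F0`), by Metropolis-Hastings sampling from the
#' pseudo-posterior `exp(beta * KS(F1(p), F0(p)))` under a uniform prior
#' on the box \[-1, 1\]^4.
#'
#' Because the KS objective is invariant under `p -> -p`, each retained
#' sample is sign-aligned to the convention that negative factors favor
#' representation: a sample is flipped when it places the represented
#' set's mean feature sum above the control's.
#'
#' @param represented feature table (see [compute_feature_table()]) of
#'   represented antigens; standardized internally against `control`.
#' @param control feature table of the control set (e.g. whole proteome).
#' @param n_samples number of retained posterior samples (default 1000).
#' @param burn_in number of discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param proposal_sd standard deviation of the Gaussian random-walk
#'   proposal, reflected at the box boundary.
#' @param beta inverse temperature of the pseudo-likelihood.
#' @param seed integer seed; the fit is fully reproducible given it.
#' @param standardized set `TRUE` if both tables are already standardized.
#' @return An object of class `antigen_factors`: a list with `samples`
#'   (n_samples x 4 matrix), `objective` (KS distance per sample),
#'   `acceptance_rate`, `scaling`, the standardized feature tables and
#'   the call configuration.
#' @seealso [predict.antigen_factors()] for candidate ranking,
#'   [density_difference()] for the representation-density curve.
#' @export
fit_antigen_factors <- function(represented, control,
                                n_samples = 1000L, burn_in = 1000L,
                                thin = 1L, proposal_sd = 0.1, beta = 50,
                                seed = 1L, standardized = FALSE) {
  if (!nrow(represented) || !nrow(control)) stop("both protein sets must be non-empty")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (proposal_sd <= 0) stop("proposal_sd must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (thin < 1L || burn_in < 0L) stop("invalid thin/burn_in")

  if (standardized) {
    ctrl_std <- control
    rep_std <- represented
    scaling <- attr(control, "scaling")
  } else {
    ctrl_std <- standardize_features(control)
    scaling <- attr(ctrl_std, "scaling")
    rep_std <- standardize_features(represented, scaling = scaling)
  }
  cols <- c("length", "hydrophobicity", "isoelectric_point", "instability")
  rep_mat <- as.matrix(rep_std[cols])
  ctrl_mat <- as.matrix(ctrl_std[cols])

  objective <- function(p) {
    ks_distance(as.numeric(rep_mat %*% p), as.numeric(ctrl_mat %*% p))
  }
  reflect <- function(x) {
    # reflect into [-1, 1]
    x <- (x + 1) %% 4
    x <- ifelse(x > 2, 4 - x, x)
    x - 1
  }

  set.seed(seed)
  p <- stats::runif(4L, -1, 1)
  obj <- objective(p)
  n_iter <- burn_in + n_samples * thin
  samples <- matrix(NA_real_, n_samples, 4L,
                    dimnames = list(NULL, cols))
  obj_out <- numeric(n_samples)
  n_acc <- 0L
  kept <- 0L
  for (it in seq_len(n_iter)) {
    prop <- reflect(p + stats::rnorm(4L, 0, proposal_sd))
    obj_prop <- objective(prop)
    if (log(stats::runif(1L)) < beta * (obj_prop - obj)) {
      p <- prop; obj <- obj_prop; n_acc <- n_acc + 1L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- p
      obj_out[kept] <- obj
    }
  }

  # sign alignment: negative factors favor representation
  flip <- apply(samples, 1L, function(q) {
    mean(rep_mat %*% q) > mean(ctrl_mat %*% q)
  })
  samples[flip, ] <- -samples[flip, ]

  structure(list(
    samples = samples,
    objective = obj_out,
    acceptance_rate = n_acc / n_iter,
    scaling = scaling,
    represented = rep_std,
    control = ctrl_std,
    config = list(n_samples = n_samples, burn_in = burn_in, thin = thin,
                  proposal_sd = proposal_sd, beta = beta, seed = seed)
  ), class = "antigen_factors")
}

#' @export
print.antigen_factors <- function(x, ...) {
  cat("Antigen-representation factor model\n")
  cat(sprintf("  %d posterior samples (burn-in %d, thinning %d, beta %g)\n",
              nrow(x$samples), x$config$burn_in, x$config$thin, x$config$beta))
  cat(sprintf("  MH acceptance rate: %.2f\n", x$acceptance_rate))
  cat("  Posterior mean factors (negative favors representation):\n")
  print(round(colMeans(x$samples), 3))
  invisible(x)
}

#' @method coef antigen_factors
#' @export
coef.antigen_factors <- function(object, ...) colMeans(object$samples)

#' @method summary antigen_factors
#' @export
summary.antigen_factors <- function(object, ...) {
  qs <- apply(object$samples, 2L, stats::quantile,
              probs = c(0.05, 0.5, 0.95))
  out <- list(
    factors = data.frame(
      mean = colMeans(object$samples),
      q5 = qs[1L, ], median = qs[2L, ], q95 = qs[3L, ]
    ),
    ks_at_mean = ks_objective(object, coef(object)),
    acceptance_rate = object$acceptance_rate
  )
  class(out) <- "summary.antigen_factors"
  out
}

#' @export
print.summary.antigen_factors <- function(x, ...) {
  cat("Posterior factor summary (negative favors representation):\n")
  print(round(x$factors, 3))
  cat(sprintf("KS objective at posterior mean: %.3f\n", x$ks_at_mean))
  cat(sprintf("MH acceptance rate: %.2f\n", x$acceptance_rate))
  invisible(x)
}

#' KS objective of a fitted model at a given factor vector
#'
#' @param object an `antigen_factors` fit.
#' @param factors numeric factor vector in \[-1, 1\]^4.
#' @return The KS distance between represented and control feature sums.
#' @export
ks_objective <- function(object, factors) {
  stopifnot(inherits(object, "antigen_factors"))
  ks_distance(feature_sum(factors, object$represented),
              feature_sum(factors, object$control))
}

#' Difference between two kernel density estimates of feature sums
#'
#' Gaussian-kernel densities of the represented (`F1`) and control
#' (`F0`) feature-sum samples are evaluated on a common grid, each
#' renormalised to unit mass over that grid, and differenced
#' (`F_diff = F1 - F0`). Positive values mark feature sums favoring
#' representation.
#'
#' @param rep_values,ctrl_values non-empty numeric feature-sum samples.
#' @param n_grid number of grid points (default 512).
#' @param pad grid extension beyond the pooled range, in bandwidths.
#' @return data.frame with columns `f` (grid) and `diff`, plus attributes
#'   `d1`, `d0` (the component densities on the grid).
#' @export
density_difference <- function(rep_values, ctrl_values, n_grid = 512L,
                               pad = 3) {
  if (!length(rep_values) || !length(ctrl_values)) stop("empty sample")
  if (length(unique(rep_values)) < 2L || length(unique(ctrl_values)) < 2L) {
    stop("degenerate sample: need at least two distinct values per set")
  }
  bw1 <- stats::bw.nrd0(rep_values)
  bw0 <- stats::bw.nrd0(ctrl_values)
  if (!is.finite(bw1) || !is.finite(bw0) || bw1 <= 0 || bw0 <= 0) {
    stop("degenerate sample: zero-bandwidth density estimate")
  }
  bw <- max(bw1, bw0)
  lo <- min(rep_values, ctrl_values) - pad * bw
  hi <- max(rep_values, ctrl_values) + pad * bw
  d1 <- stats::density(rep_values, bw = bw1, from = lo, to = hi, n = n_grid)
  d0 <- stats::density(ctrl_values, bw = bw0, from = lo, to = hi, n = n_grid)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  y1 <- d1$y / trapz(d1$x, d1$y)
  y0 <- d0$y / trapz(d0$x, d0$y)
  out <- data.frame(f = d1$x, diff = y1 - y0)
  attr(out, "d1") <- y1
  attr(out, "d0") <- y0
  out
}

#' Rank candidate antigens by posterior representation-density difference
#'
#' For every posterior factor sample, the candidate's feature sum is
#' evaluated on that sample's `F_diff` curve (represented-minus-control
#' density difference); the per-candidate distribution over samples is
#' summarised and candidates are ranked by median `F_diff` (higher is
#' better). Feature sums outside the density grid evaluate to 0 with a
#' warning (negligible density).
#'
#' @param object a fitted `antigen_factors` model.
#' @param candidates feature table of candidate antigens (raw scale; the
#'   model's scaling is applied), or a named character vector of
#'   sequences.
#' @param n_grid,pad passed to [density_difference()].
#' @param ... unused.
#' @return data.frame with one row per candidate: `id`, `median_fdiff`,
#'   `q5`, `q95`, `rank` (1 = most favored; ties broken by id and
#'   reported in the `tied` column).
#' @export
predict.antigen_factors <- function(object, candidates, n_grid = 512L,
                                    pad = 3, ...) {
  if (is.character(candidates)) {
    candidates <- compute_feature_table(candidates)
  }
  cand_std <- standardize_features(candidates, scaling = object$scaling)
  cols <- c("length", "hydrophobicity", "isoelectric_point", "instability")
  cand_mat <- as.matrix(cand_std[cols])
  rep_mat <- as.matrix(object$represented[cols])
  ctrl_mat <- as.matrix(object$control[cols])

  n_cand <- nrow(cand_mat)
  n_post <- nrow(object$samples)
  vals <- matrix(NA_real_, n_post, n_cand)
  outside <- FALSE
  for (s in seq_len(n_post)) {
    p <- object$samples[s, ]
    dd <- density_difference(as.numeric(rep_mat %*% p),
                             as.numeric(ctrl_mat %*% p),
                             n_grid = n_grid, pad = pad)
    fc <- as.numeric(cand_mat %*% p)
    y <- stats::approx(dd$f, dd$diff, xout = fc, rule = 1L)$y
    if (anyNA(y)) { outside <- TRUE; y[is.na(y)] <- 0 }
    vals[s, ] <- y
  }
  if (outside) {
    warning("some candidate feature sums fell outside the density grid; evaluated as 0")
  }
  med <- apply(vals, 2L, stats::median)
  q5 <- apply(vals, 2L, stats::quantile, probs = 0.05)
  q95 <- apply(vals, 2L, stats::quantile, probs = 0.95)
  ord <- order(-med, candidates$id)
  rank <- integer(n_cand); rank[ord] <- seq_len(n_cand)
  data.frame(id = candidates$id, median_fdiff = med, q5 = q5, q95 = q95,
             rank = rank, tied = duplicated(med) | duplicated(med, fromLast = TRUE),
             stringsAsFactors = FALSE)
}

#' @method plot antigen_factors
#' @export
plot.antigen_factors <- function(x, which = c("posterior", "fdiff"), ...) {
  which <- match.arg(which)
  if (which == "posterior") {
    op <- graphics::par(mfrow = c(2L, 2L)); on.exit(graphics::par(op))
    for (j in colnames(x$samples)) {
      graphics::hist(x$samples[, j], breaks = 30, main = j,
                     xlab = "factor", xlim = c(-1, 1), ...)
    }
  } else {
    p <- coef(x)
    dd <- density_difference(feature_sum(p, x$represented),
                             feature_sum(p, x$control))
    graphics::plot(dd$f, dd$diff, type = "l", xlab = "feature sum f",
                   ylab = expression(F[diff]), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
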