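#' EM configuration for univariate Gaussian mixture fitting
#'
#' Bundles the initialization and stopping rules used by [fit_gmm()]. The
#' defaults are the method's canonical starting point for three methylation
#' states on the M-value scale: means \eqn{(-4, 0, 4)}, unit standard
#' deviations, uniform weights. Small perturbations of these starting values
#' do not change the fitted model on realistic methylation mixtures.
#'
#' @param init_means,init_sds,init_weights Numeric vectors of length `K`
#'   giving the starting component means, standard deviations and mixing
#'   proportions, or `NULL` for the built-in defaults (for `K = 4` the default
#'   means are \eqn{(-4, 0, 3, 6)}, adding a far-right component).
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Iteration cap.
#' @param sigma_floor Minimum component standard deviation; updates are clipped
#'   here to prevent collapse onto near-duplicate values.
#' @param seed Optional integer, recorded for provenance; EM itself is
#'   deterministic given the initialization.
#' @return An object of class `em_config`.
#' @export
em_config <- function(init_means = NULL, init_sds = NULL, init_weights = NULL,
                      tol = 1e-8, max_iter = 500L, sigma_floor = 1e-4,
                      seed = NULL) {
  stopifnot(tol > 0, max_iter >= 1, sigma_floor > 0)
  structure(
    list(init_means = init_means, init_sds = init_sds,
         init_weights = init_weights, tol = tol,
         max_iter = as.integer(max_iter), sigma_floor = sigma_floor,
         seed = seed),
    class = "em_config"
  )
}

default_init <- function(K) {
  means <- switch(as.character(K),
    "1" = 0, "2" = c(-4, 4), "3" = c(-4, 0, 4), "4" = c(-4, 0, 3, 6),
    seq(-4, 4, length.out = K))
  list(means = means, sds = rep(1, K), weights = rep(1 / K, K))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a `K`-component Gaussian mixture to a vector of
#' M-values via expectation-maximization. The log-likelihood is non-decreasing
#' across iterations; components are reported sorted by ascending mean.
#'
#' @param values Finite numeric vector, at least `10 * K` values.
#' @param K Number of components.
#' @param config An [em_config()].
#' @return An object of class `mgmin_gmm`: a list with elements `K`, `weights`,
#'   `means`, `sds`, `loglik_trace`, `converged`, `iter` and `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, -4), rnorm(300, 0), rnorm(400, 4))
#' fit <- fit_gmm(x, K = 3)
#' tidy(fit)
#' @export
fit_gmm <- function(values, K = 3L, config = em_config()) {
  K <- as.integer(K)
  x <- values[!is.na(values)]
  if (any(!is.finite(x))) stop("`values` must be finite.", call. = FALSE)
  if (length(x) < 10L * K) {
    stop("insufficient data: need at least ", 10L * K, " values for K = ", K,
         ", got ", length(x), ".", call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    stop("degenerate data: all values are identical.", call. = FALSE)
  }
  init <- default_init(K)
  mu <- config$init_means %||% init$means
  sd <- config$init_sds %||% init$sds
  pi <- config$init_weights %||% init$weights
  if (length(mu) != K || length(sd) != K || length(pi) != K) {
    stop("initialization vectors must have length K = ", K, ".", call. = FALSE)
  }
  pi <- pi / sum(pi)
  n <- length(x)

  if (K == 1L) {
    mu <- mean(x)
    sd <- max(sqrt(mean((x - mu)^2)), config$sigma_floor)
    ll <- sum(stats::dnorm(x, mu, sd, log = TRUE))
    return(new_gmm(1L, 1, mu, sd, ll, TRUE, 0L, n))
  }

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  floored <- FALSE
  for (iter in seq_len(config$max_iter)) {
    # E-step: responsibilities via log-sum-exp for numerical stability
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sd[k], log = TRUE) + log(pi[k])
    }, numeric(n))
    mx <- logd[, 1L]
    for (k in seq_len(K)[-1L]) mx <- pmax(mx, logd[, k])
    w <- exp(logd - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    loglik <- c(loglik, ll)
    gamma <- w / rs
    # M-step
    nk <- colSums(gamma)
    pi <- nk / n
    mu <- colSums(gamma * x) / nk
    v <- colSums(gamma * (x - rep(mu, each = n))^2) / nk
    sd_new <- sqrt(pmax(v, 0))
    if (any(sd_new < config$sigma_floor)) floored <- TRUE
    sd <- pmax(sd_new, config$sigma_floor)
    if (iter > 1L) {
      rel <- abs(ll - loglik[iter - 1L]) / (abs(loglik[iter - 1L]) + 1e-300)
      if (rel < config$tol) { converged <- TRUE; break }
    }
  }
  if (floored) {
    warning("a component standard deviation hit the floor (",
            config$sigma_floor, "); fit may be degenerate.", call. = FALSE)
  }
  ord <- order(mu)
  new_gmm(K, pi[ord], mu[ord], sd[ord], loglik, converged, iter, n)
}

new_gmm <- function(K, weights, means, sds, loglik, converged, iter, n) {
  structure(
    list(K = K, weights = unname(weights), means = unname(means),
         sds = unname(sds), loglik_trace = unname(loglik),
         converged = converged, iter = iter, n = n),
    class = "mgmin_gmm"
  )
}

#' @export
print.mgmin_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K = %d, n = %d, logLik = %.2f (%s)\n",
              x$K, x$n, utils::tail(x$loglik_trace, 1),
              if (x$converged) "converged" else "iteration cap"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Gaussian mixture fit
#'
#' @param x An `mgmin_gmm` object.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `state` (U/H/F),
#'   `weight`, `mean`, `sd`.
#' @export
tidy.mgmin_gmm <- function(x, ...) {
  states <- if (x$K %in% c(3L, 4L)) relabel_states(x) else rep(NA_character_, x$K)
  tibble::tibble(component = seq_len(x$K), state = states,
                 weight = x$weights, mean = x$means, sd = x$sds)
}

#' Glance at a Gaussian mixture fit
#'
#' @param x An `mgmin_gmm` object.
#' @param ... Unused.
#' @return A one-row tibble with `K`, `logLik`, `iter`, `converged`, `nobs`.
#' @export
glance.mgmin_gmm <- function(x, ...) {
  tibble::tibble(K = x$K,
                 logLik = utils::tail(x$loglik_trace, 1) %||% NA_real_,
                 iter = x$iter, converged = x$converged, nobs = x$n)
}

#' Choose the number of type I components
#'
#' The type I mixture is refitted with four components when the left flank of
#' its hypermethylated component falls below that of type II, i.e. when
#' \eqn{\mu_I^F - \sigma_I^F < \mu_{II}^F - \sigma_{II}^F}. The extra
#' component guarantees that the highest type I mean sits to the right of the
#' highest type II mean, avoiding a spurious peak in the transformed
#' hypermethylated type II values. Equality keeps three components.
#'
#' @param fit_I,fit_II Three-component `mgmin_gmm` fits for type I and type II
#'   probes of one sample.
#' @return `3L` or `4L`.
#' @export
select_k_type1 <- function(fit_I, fit_II) {
  for (f in list(fit_I, fit_II)) {
    if (!inherits(f, "mgmin_gmm") || f$K != 3L) {
      stop("`fit_I` and `fit_II` must be 3-component mgmin_gmm fits.",
           call. = FALSE)
    }
    if (is.unsorted(f$means)) stop("fit components must be sorted by mean.",
                                   call. = FALSE)
  }
  if (fit_I$means[3L] - fit_I$sds[3L] < fit_II$means[3L] - fit_II$sds[3L]) 4L else 3L
}

#' Map mixture components to methylation states
#'
#' With three components the states are U (hypomethylated), H (hemimethylated)
#' and F (hypermethylated) in ascending order of mean. With four components the
#' lowest mean is U, the highest is F, and both middle components are H.
#'
#' @param fit An `mgmin_gmm` with 3 or 4 components.
#' @return A character vector of length `K` with values in `c("U", "H", "F")`,
#'   aligned with the (mean-sorted) components.
#' @export
relabel_states <- function(fit) {
  if (!inherits(fit, "mgmin_gmm")) stop("`fit` must be an mgmin_gmm.",
                                        call. = FALSE)
  if (!fit$K %in% c(3L, 4L)) {
    stop("unsupported K = ", fit$K, ": state labels are defined for 3 or 4 ",
         "components.", call. = FALSE)
  }
  if (fit$K == 3L) c("U", "H", "F") else c("U", "H", "H", "F")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
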