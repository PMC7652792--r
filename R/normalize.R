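#' Assign M-values to methylation states and sides
#'
#' Each value goes to the component maximizing the posterior
#' \eqn{\pi_k N(x \mid \mu_k, \sigma_k^2)} (ties break to the lower-mean
#' component), then through the component-to-state map of [relabel_states()].
#' The side is `"L"` when the value lies strictly below the mean of its
#' assigned component and `"R"` otherwise, so a value exactly at the mean is
#' a right-side value.
#'
#' @param values Finite numeric vector of M-values.
#' @param fit An `mgmin_gmm` with 3 or 4 components.
#' @param state_map Character vector mapping components to states; defaults to
#'   [relabel_states()] on `fit`.
#' @return A tibble with one row per value: `value`, `component`, `state`,
#'   `side`.
#' @export
assign_states <- function(values, fit, state_map = relabel_states(fit)) {
  if (!inherits(fit, "mgmin_gmm")) stop("`fit` must be an mgmin_gmm.",
                                        call. = FALSE)
  if (length(state_map) != fit$K) {
    stop("`state_map` must have one entry per component.", call. = FALSE)
  }
  post <- vapply(seq_len(fit$K), function(k) {
    fit$weights[k] * stats::dnorm(values, fit$means[k], fit$sds[k])
  }, numeric(length(values)))
  if (length(values) == 1L) post <- matrix(post, nrow = 1L)
  comp <- max.col(post, ties.method = "first")
  tibble::tibble(
    value = values,
    component = comp,
    state = state_map[comp],
    side = ifelse(values < fit$means[comp], "L", "R")
  )
}

#' Gaussian-to-Gaussian quantile map
#'
#' Maps values through the cumulative distribution of the source Gaussian and
#' back through the inverse cumulative distribution of the destination
#' Gaussian: \eqn{q = \Phi^{-1}(\Phi((x - \mu_s)/\sigma_s)) \cdot \sigma_d +
#' \mu_d}. The composition is evaluated on the log scale of the nearer tail,
#' so it agrees with the affine closed form
#' \eqn{\mu_d + \sigma_d (x - \mu_s)/\sigma_s} to full floating-point
#' precision over the entire range of real methylation data, and is strictly
#' monotone; a floor on the log tail probability keeps even absurd outliers
#' finite.
#'
#' @param values Numeric vector of M-values.
#' @param src_mu,src_sd Source component mean and standard deviation
#'   (`src_sd > 0`).
#' @param dst_mu,dst_sd Destination component mean and standard deviation
#'   (`dst_sd > 0`).
#' @return A numeric vector the length of `values`.
#' @export
quantile_map <- function(values, src_mu, src_sd, dst_mu, dst_sd) {
  if (!is.numeric(src_sd) || src_sd <= 0 || !is.numeric(dst_sd) || dst_sd <= 0) {
    stop("standard deviations must be positive.", call. = FALSE)
  }
  z <- (values - src_mu) / src_sd
  # work with the log probability of the nearer tail: full relative precision
  lower <- z <= 0
  lp <- ifelse(lower, stats::pnorm(z, log.p = TRUE),
               stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
  lp <- pmax(lp, log(1e-300))
  zq <- ifelse(lower, stats::qnorm(lp, log.p = TRUE),
               stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE))
  dst_mu + dst_sd * zq
}

#' Conformal (shift + dilation) transform of the middle probe set
#'
#' Applies the affine map \eqn{x \mapsto minG' + df\,(x - minG)} with dilation
#' factor \eqn{df = (maxG' - minG') / (maxG - minG)}, placing the middle set G
#' between the quantile-mapped flanks while conserving the original gaps
#' \eqn{\Delta_{UG}} and \eqn{\Delta_{GF}}.
#'
#' @param g_values Numeric vector of M-values in set G.
#' @param params A list or one-row data frame carrying `min_g`, `max_g`,
#'   `min_g_new`, `max_g_new` (e.g. from [normalize_sample()] provenance).
#' @return The transformed values; when `max_g == min_g` all values map to the
#'   midpoint of the new range, with a warning.
#' @export
conformal_transform <- function(g_values, params) {
  p <- as.list(params)
  need <- c("min_g", "max_g", "min_g_new", "max_g_new")
  if (!all(need %in% names(p))) {
    stop("`params` must provide ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  delta <- p$max_g - p$min_g
  if (delta == 0) {
    warning("degenerate middle set (max_g == min_g); mapping to midpoint.",
            call. = FALSE)
    return(rep((p$min_g_new + p$max_g_new) / 2, length(g_values)))
  }
  df <- (p$max_g_new - p$min_g_new) / delta
  p$min_g_new + df * (g_values - p$min_g)
}

#' Normalize one sample's type II M-values onto the type I scale
#'
#' The per-sample transform: fit 3-component Gaussian mixtures to type I and
#' type II M-values, escalate the type I fit to 4 components when
#' [select_k_type1()] requires it, assign type II probes to states and sides,
#' quantile-map the hypomethylated-left (`U_IIL`) and hypermethylated-right
#' (`F_IIR`) sets onto the corresponding type I components, and carry the
#' remaining middle set G (`U_IIR` together with `H_II` and `F_IIL`) by a
#' conformal shift + dilation that conserves the gaps to the flanks. Type I
#' values are never modified.
#'
#' @param m_type1,m_type2 Finite numeric vectors of M-values for the sample's
#'   type I and type II probes.
#' @param config An [em_config()] applied to the 3-component fits.
#' @param k_type1 `"auto"` (default) applies the 4-component escalation rule;
#'   `3` or `4` forces the component count.
#' @return A list with `normalized` (type II M-values, input order), and
#'   provenance: `fit_type1`, `fit_type2`, `k_type1`, `states` (the type II
#'   state/side tibble), `conformal` (one-row tibble of the transform
#'   parameters), and `noncontiguous_runs`, a diagnostic counting state-run
#'   changes beyond the expected one-per-component along sorted values.
#' @examples
#' set.seed(7)
#' m1 <- c(rnorm(300, -4), rnorm(300, 0), rnorm(400, 4))
#' m2 <- c(rnorm(300, -2.6), rnorm(300, 0), rnorm(400, 2.6))
#' res <- normalize_sample(m1, m2)
#' res$conformal$df
#' @export
normalize_sample <- function(m_type1, m_type2, config = em_config(),
                             k_type1 = "auto") {
  if (length(m_type1) == 0L || length(m_type2) == 0L) {
    stop("both probe-type vectors must be non-empty.", call. = FALSE)
  }
  if (any(!is.finite(m_type1)) || any(!is.finite(m_type2))) {
    stop("M-values must be finite; drop missing values first.", call. = FALSE)
  }
  k_type1 <- as.character(k_type1)
  if (!k_type1 %in% c("auto", "3", "4")) {
    stop('`k_type1` must be "auto", 3 or 4.', call. = FALSE)
  }

  fit2 <- fit_gmm(m_type2, 3L, config)
  fit1 <- fit_gmm(m_type1, 3L, config)
  k1 <- if (k_type1 == "auto") select_k_type1(fit1, fit2) else as.integer(k_type1)
  if (k1 == 4L) {
    # refit from scratch; K=4 uses the default far-right initialization
    cfg4 <- em_config(tol = config$tol, max_iter = config$max_iter,
                      sigma_floor = config$sigma_floor)
    fit1 <- fit_gmm(m_type1, 4L, cfg4)
  }

  states <- assign_states(m_type2, fit2)
  in_uiil <- states$state == "U" & states$side == "L"
  in_fiir <- states$state == "F" & states$side == "R"
  in_g <- !(in_uiil | in_fiir)
  for (nm in c("U_IIL", "F_IIR", "G")) {
    idx <- switch(nm, U_IIL = in_uiil, F_IIR = in_fiir, G = in_g)
    if (!any(idx)) {
      stop("empty partition: set ", nm, " contains no probes; the sample ",
           "cannot be normalized.", call. = FALSE)
    }
  }

  # U/F parameters: the lowest- and highest-mean components of each fit
  q_u <- quantile_map(m_type2[in_uiil], fit2$means[1L], fit2$sds[1L],
                      fit1$means[1L], fit1$sds[1L])
  q_f <- quantile_map(m_type2[in_fiir], fit2$means[fit2$K], fit2$sds[fit2$K],
                      fit1$means[fit1$K], fit1$sds[fit1$K])

  g <- m_type2[in_g]
  min_g <- min(g); max_g <- max(g)
  max_u <- max(m_type2[in_uiil]); min_f <- min(m_type2[in_fiir])
  delta_ug <- min_g - max_u
  delta_gf <- min_f - max_g
  max_u_new <- max(q_u); min_f_new <- min(q_f)
  min_g_new <- max_u_new + delta_ug
  max_g_new <- min_f_new - delta_gf
  conformal <- tibble::tibble(
    min_g = min_g, max_g = max_g, delta_g = max_g - min_g,
    max_u = max_u, min_f = min_f, delta_ug = delta_ug, delta_gf = delta_gf,
    max_u_new = max_u_new, min_f_new = min_f_new,
    min_g_new = min_g_new, max_g_new = max_g_new,
    df = if (max_g > min_g) (max_g_new - min_g_new) / (max_g - min_g) else NA_real_
  )

  out <- numeric(length(m_type2))
  out[in_uiil] <- q_u
  out[in_fiir] <- q_f
  out[in_g] <- conformal_transform(g, conformal)

  ord <- order(m_type2)
  runs <- rle(states$state[ord])$lengths
  noncontig <- max(0L, length(runs) - fit2$K)

  list(normalized = out, fit_type1 = fit1, fit_type2 = fit2, k_type1 = k1,
       states = states, conformal = conformal, noncontiguous_runs = noncontig)
}

#' Normalize a probe-by-sample methylation matrix
#'
#' Applies [normalize_sample()] independently to each sample column of a
#' methylation data frame, leaving type I probes untouched. Beta-scale input
#' is converted to M-values on entry and back to beta-values on exit. `NA`
#' cells are excluded from the per-sample fit and propagated. A sample with
#' fewer than 30 non-missing probes of either type is left unnormalized and
#' flagged rather than failing the whole run.
#'
#' @param data A data frame: first column probe IDs (character), remaining
#'   columns numeric sample values on `scale`.
#' @param annotation A data frame with columns `probe_id` and `type`
#'   (`"I"`/`"II"`) covering every probe in `data`; see
#'   [read_probe_annotation()].
#' @param scale `"beta"` or `"m"`, the scale of the input values.
#' @inheritParams normalize_sample
#' @param beta_eps Clamp applied before the beta-to-M transform.
#' @return An object of class `mgmin_norm` with elements `normalized` (a
#'   tibble shaped like `data`, on the input scale), `scale`, `annotation`,
#'   and `samples`, a named list of per-sample provenance (fits, chosen
#'   `k_type1`, conformal parameters, state counts, failure flag). Use
#'   [tidy()], [glance()] and [ggplot2::autoplot()] to inspect it.
#' @examples
#' sim <- simulate_array(simulation_spec(n_type1 = 600, n_type2 = 1500,
#'                                       n_samples = 1, seed = 1))
#' res <- mgmin_normalize(sim$data, sim$annotation, scale = "m")
#' glance(res)
#' @export
mgmin_normalize <- function(data, annotation, scale = c("beta", "m"),
                            config = em_config(), k_type1 = "auto",
                            beta_eps = 1e-6) {
  scale <- match.arg(scale)
  mm <- as_methyl_matrix(data, annotation, scale)
  vals <- mm$values
  if (scale == "beta") vals <- beta_to_m(vals, eps = beta_eps)

  is2 <- mm$type == "II"
  out <- vals
  samples <- list()
  for (s in colnames(vals)) {
    col <- vals[, s]
    ok1 <- !is.na(col) & !is2
    ok2 <- !is.na(col) & is2
    if (sum(ok1) < 30L || sum(ok2) < 30L) {
      samples[[s]] <- list(failed = TRUE,
                           message = "fewer than 30 non-missing probes of a type")
      next
    }
    res <- normalize_sample(col[ok1], col[ok2], config = config,
                            k_type1 = k_type1)
    out[ok2, s] <- res$normalized
    samples[[s]] <- list(
      failed = FALSE, fit_type1 = res$fit_type1, fit_type2 = res$fit_type2,
      k_type1 = res$k_type1, conformal = res$conformal,
      state_counts = table(paste0(res$states$state, res$states$side)),
      noncontiguous_runs = res$noncontiguous_runs
    )
  }
  if (scale == "beta") out <- m_to_beta(out)

  norm_tbl <- tibble::as_tibble(cbind(
    tibble::tibble(probe_id = rownames(vals)),
    tibble::as_tibble(out)
  ))
  names(norm_tbl)[1L] <- names(data)[1L]
  structure(
    list(normalized = norm_tbl, scale = scale,
         annotation = tibble::tibble(probe_id = rownames(vals), type = mm$type),
         samples = samples, input = data),
    class = "mgmin_norm"
  )
}

#' @export
print.mgmin_norm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "MGMIN normalization: %d probes (%d type I, %d type II), %d sample(s), scale = %s\n",
    g$n_probes, g$n_type1, g$n_type2, g$n_samples, x$scale))
  if (g$n_failed > 0) cat(g$n_failed, "sample(s) left unnormalized (flagged)\n")
  invisible(x)
}

#' Tidy an MGMIN normalization
#'
#' @param x An `mgmin_norm` object.
#' @param ... Unused.
#' @return A tibble with one row per sample: the chosen type I component count,
#'   the conformal-transform parameters (ranges, gaps, dilation factor `df`)
#'   and the failure flag.
#' @export
tidy.mgmin_norm <- function(x, ...) {
  purrr::map_dfr(names(x$samples), function(s) {
    p <- x$samples[[s]]
    if (isTRUE(p$failed)) {
      return(tibble::tibble(sample = s, failed = TRUE, k_type1 = NA_integer_))
    }
    dplyr::bind_cols(
      tibble::tibble(sample = s, failed = FALSE, k_type1 = p$k_type1,
                     noncontiguous_runs = p$noncontiguous_runs),
      p$conformal
    )
  })
}

#' Summarize an MGMIN normalization
#'
#' @param x An `mgmin_norm` object.
#' @param ... Unused.
#' @return A one-row tibble with probe/sample counts, number of failed
#'   samples, and the value scale.
#' @export
glance.mgmin_norm <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$annotation),
    n_type1 = sum(x$annotation$type == "I"),
    n_type2 = sum(x$annotation$type == "II"),
    n_samples = length(x$samples),
    n_failed = sum(purrr::map_lgl(x$samples, ~ isTRUE(.x$failed))),
    scale = x$scale
  )
}

#' Density plot of type I vs type II values before and after normalization
#'
#' @param object An `mgmin_norm` object.
#' @param samples Sample IDs to plot; defaults to all.
#' @param ... Unused.
#' @return A ggplot: density curves per probe class (type I, raw type II,
#'   normalized type II), faceted by sample.
#' @export
autoplot.mgmin_norm <- function(object, samples = NULL, ...) {
  long <- function(tbl, label) {
    tbl |>
      rlang::set_names(c("probe_id", names(tbl)[-1L])) |>
      tidyr::pivot_longer(-"probe_id", names_to = "sample",
                          values_to = "value") |>
      dplyr::left_join(object$annotation, by = "probe_id") |>
      dplyr::mutate(class = ifelse(.data$type == "I", "type I", label))
    }
  d <- dplyr::bind_rows(
    long(object$input, "type II (raw)"),
    long(object$normalized, "type II (normalized)") |>
      dplyr::filter(.data$type == "II")
  )
  if (!is.null(samples)) d <- dplyr::filter(d, .data$sample %in% samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, colour = .data$class)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = paste0(object$scale, "-value"), y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write per-sample normalization provenance as JSON
#'
#' Serializes the fitted mixture parameters, chosen component counts and
#' conformal-transform parameters of an `mgmin_norm` object.
#'
#' @param x An `mgmin_norm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(x, path) {
  stopifnot(inherits(x, "mgmin_norm"))
  per_sample <- purrr::map(x$samples, function(p) {
    if (isTRUE(p$failed)) return(list(failed = TRUE, message = p$message))
    list(
      failed = FALSE,
      k_type1 = p$k_type1,
      fit_type1 = p$fit_type1[c("K", "weights", "means", "sds", "converged", "n")],
      fit_type2 = p$fit_type2[c("K", "weights", "means", "sds", "converged", "n")],
      conformal = as.list(p$conformal),
      noncontiguous_runs = p$noncontiguous_runs
    )
  })
  jsonlite::write_json(list(scale = x$scale, samples = per_sample), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
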