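#' Per-probe standard deviation across replicates
#'
#' Sample SD of each probe across the named replicate columns, skipping `NA`s.
#'
#' @param data A data frame, probe IDs first, samples after.
#' @param samples Character vector of at least two sample column names;
#'   defaults to all sample columns.
#' @return A tibble with columns `probe_id` and `sd`.
#' @export
probe_sd <- function(data, samples = NULL) {
  samples <- samples %||% names(data)[-1L]
  missing <- setdiff(samples, names(data))
  if (length(missing)) {
    stop("samples not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(samples) < 2L) {
    stop("need at least 2 replicate samples.", call. = FALSE)
  }
  m <- as.matrix(data[samples])
  tibble::tibble(
    probe_id = as.character(data[[1L]]),
    sd = apply(m, 1L, stats::sd, na.rm = TRUE)
  )
}

#' Mean absolute beta difference between two samples
#'
#' Average of `|a - b|` over probes of the requested design type, skipping
#' probe rows where either value is `NA`.
#'
#' @inheritParams probe_sd
#' @param sample_a,sample_b Sample column names.
#' @param annotation Optional annotation tibble (`probe_id`, `type`); required
#'   when `probe_type` filtering is requested.
#' @param probe_type `"II"` (default), `"I"`, or `NULL` for all probes.
#' @return A single number.
#' @export
mean_abs_diff <- function(data, sample_a, sample_b, annotation = NULL,
                          probe_type = "II") {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(data)) stop("sample not in data: ", s, call. = FALSE)
  }
  keep <- rep(TRUE, nrow(data))
  if (!is.null(probe_type)) {
    if (is.null(annotation)) {
      stop("`annotation` is required to filter by probe type.", call. = FALSE)
    }
    type <- annotation$type[match(as.character(data[[1L]]),
                                  annotation$probe_id)]
    keep <- !is.na(type) & type %in% probe_type
  }
  mean(abs(data[[sample_a]][keep] - data[[sample_b]][keep]), na.rm = TRUE)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The maximum vertical distance between the empirical CDFs of two value
#' vectors, in `[0, 1]`; 0 for identical distributions, 1 for disjoint
#' supports.
#'
#' @param values_a,values_b Non-empty numeric vectors (`NA`s dropped).
#' @return The KS statistic.
#' @export
distribution_distance <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both inputs must be non-empty.", call. = FALSE)
  }
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Summaries of absolute deviation from a reference
#'
#' Elementwise `|values - reference|` summarized by maximum, mean and root
#' mean square, e.g. for comparing normalized beta-values against matched
#' gold-standard bisulfite pyrosequencing measurements.
#'
#' @param values,reference Numeric vectors of equal length (at least 1).
#' @return A one-row tibble with columns `max`, `mean`, `rmse`.
#' @export
deviation_summary <- function(values, reference) {
  if (length(values) != length(reference) || length(values) < 1L) {
    stop("`values` and `reference` must have equal length >= 1.",
         call. = FALSE)
  }
  d <- abs(values - reference)
  tibble::tibble(max = max(d), mean = mean(d), rmse = sqrt(mean(d^2)))
}

#' Detect differentially methylated probes between two groups
#'
#' Fits the moderated two-group comparison of the limma empirical-Bayes
#' framework to per-probe values (on the M scale by default, where variances
#' are closer to homoscedastic) and calls probes at a Benjamini-Hochberg FDR
#' threshold. Probes constant across all samples get `NA` statistics and are
#' never called.
#'
#' @param data A data frame, probe IDs first, samples after.
#' @param labels Per-sample group labels (length = number of sample columns,
#'   exactly 2 distinct values, each with at least 2 samples).
#' @param fdr FDR threshold for the DMP call (default 0.35).
#' @param scale Scale of the input values; `"beta"` input is converted to
#'   M-values before testing.
#' @param beta_eps Clamp used for the beta-to-M conversion.
#' @return An object of class `mgmin_dmp`: list with `table` (tibble
#'   `probe_id`, `stat`, `p`, `q`, `is_dmp`), `n_dmp`, `fdr`, `scale`,
#'   `groups`. `tidy()` returns the table, `glance()` the summary row.
#' @export
detect_dmps <- function(data, labels, fdr = 0.35, scale = c("m", "beta"),
                        beta_eps = 1e-6) {
  scale <- match.arg(scale)
  m <- as.matrix(data[-1L])
  if (length(labels) != ncol(m)) {
    stop("`labels` must have one entry per sample column.", call. = FALSE)
  }
  groups <- unique(labels)
  if (length(groups) != 2L || any(table(labels) < 2L)) {
    stop("need exactly 2 groups with at least 2 samples each.", call. = FALSE)
  }
  if (scale == "beta") m <- beta_to_m(m, eps = beta_eps)
  design <- stats::model.matrix(~ factor(labels, levels = groups))
  fit <- limma::eBayes(limma::lmFit(m, design))
  stat <- fit$t[, 2L]
  p <- fit$p.value[, 2L]
  constant <- apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && max(r) == min(r)
  })
  stat[constant] <- NA_real_
  p[constant] <- NA_real_
  q <- stats::p.adjust(p, method = "BH")
  is_dmp <- !is.na(q) & q < fdr
  tbl <- tibble::tibble(probe_id = as.character(data[[1L]]),
                        stat = unname(stat), p = unname(p), q = unname(q),
                        is_dmp = is_dmp)
  structure(list(table = tbl, n_dmp = sum(is_dmp), fdr = fdr, scale = scale,
                 groups = groups),
            class = "mgmin_dmp")
}

#' @export
print.mgmin_dmp <- function(x, ...) {
  cat(sprintf("DMP detection: %d of %d probes at FDR < %g (%s vs %s, %s scale)\n",
              x$n_dmp, nrow(x$table), x$fdr, x$groups[1], x$groups[2], x$scale))
  invisible(x)
}

#' @export
tidy.mgmin_dmp <- function(x, ...) x$table

#' @export
glance.mgmin_dmp <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x$table), n_dmp = x$n_dmp, fdr = x$fdr,
                 scale = x$scale)
}

#' Validate training DMPs in an independent test set
#'
#' A training DMP counts as a true positive when its test-set statistic is
#' significant at the test FDR threshold with the same sign of effect. Both
#' the threshold and the sign requirement are configurable.
#'
#' @param train,test `mgmin_dmp` objects sharing probe IDs.
#' @param fdr FDR threshold applied in the test set; defaults to the training
#'   threshold.
#' @param concordant_sign Require the test statistic to have the same sign.
#' @return A one-row tibble: `n_dmp`, `n_tp`, `ppv`, `ppv_rounded`.
#' @export
validate_dmps <- function(train, test, fdr = NULL, concordant_sign = TRUE) {
  stopifnot(inherits(train, "mgmin_dmp"), inherits(test, "mgmin_dmp"))
  fdr <- fdr %||% train$fdr
  tr <- train$table[train$table$is_dmp, ]
  te <- test$table[match(tr$probe_id, test$table$probe_id), ]
  ok <- !is.na(te$q) & te$q < fdr
  if (concordant_sign) ok <- ok & sign(te$stat) == sign(tr$stat)
  n_tp <- sum(ok, na.rm = TRUE)
  if (nrow(tr) == 0L) {
    return(tibble::tibble(n_dmp = 0L, n_tp = 0L, ppv = NA_real_,
                          ppv_rounded = NA_real_))
  }
  dplyr::bind_cols(tibble::tibble(n_dmp = nrow(tr)), ppv(n_tp, nrow(tr)))[
    , c("n_dmp", "n_tp", "ppv", "ppv_rounded")]
}

#' Positive predictive value of a DMP set
#'
#' `n_tp / n_dmp`, reported at full precision and rounded half-up to two
#' decimals (the convention used for published PPV tables).
#'
#' @param n_tp Number of validated (true positive) DMPs.
#' @param n_dmp Total number of DMPs called; must be positive.
#' @return A one-row tibble: `n_tp`, `ppv`, `ppv_rounded`.
#' @examples
#' ppv(16, 51)   # 0.31
#' ppv(37, 220)  # 0.17
#' @export
ppv <- function(n_tp, n_dmp) {
  if (!is.numeric(n_dmp) || n_dmp <= 0) {
    stop("undefined PPV: `n_dmp` must be positive.", call. = FALSE)
  }
  if (n_tp < 0 || n_tp > n_dmp) {
    stop("`n_tp` must lie in [0, n_dmp].", call. = FALSE)
  }
  value <- n_tp / n_dmp
  tibble::tibble(n_tp = n_tp, ppv = value,
                 ppv_rounded = floor(value * 100 + 0.5) / 100)
}

#' Filter samples by detection p-value quality control
#'
#' A probe is "bad" in a sample when its detection p-value exceeds `tau_p`;
#' a sample is dropped when its fraction of bad probes exceeds `tau_r` (both
#' strictly, so a sample exactly at the threshold is kept).
#'
#' @param detection_p A data frame of detection p-values, probe IDs first,
#'   samples after; all values in `[0, 1]`.
#' @param tau_p Detection p-value threshold defining a bad probe, in (0, 1).
#' @param tau_r Maximum tolerated bad-probe fraction per sample, in (0, 0.3].
#' @return A list: `samples` (tibble `sample`, `bad_fraction`, `kept`),
#'   `kept` (character vector of kept sample IDs) and `kept_ratio`.
#' @export
qc_filter_samples <- function(detection_p, tau_p, tau_r) {
  stopifnot(tau_p > 0, tau_p < 1, tau_r > 0, tau_r <= 0.3)
  p <- as.matrix(detection_p[-1L])
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0, 1].", call. = FALSE)
  }
  bad_fraction <- colMeans(p > tau_p, na.rm = TRUE)
  kept <- bad_fraction <= tau_r
  tbl <- tibble::tibble(sample = colnames(p), bad_fraction = unname(bad_fraction),
                        kept = unname(kept))
  list(samples = tbl, kept = tbl$sample[tbl$kept], kept_ratio = mean(kept))
}
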