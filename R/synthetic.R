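#' Specification for a synthetic 450K-like methylation array
#'
#' Defines the generating model for [simulate_array()]: per-probe true
#' M-values drawn from a three-component Gaussian mixture per probe type,
#' replicate noise, and optional spiked group differences. The defaults
#' emulate the design bias the normalization corrects: type I outer components
#' at \eqn{\mu = \pm 4} and type II compressed to \eqn{\pm 2.6} (both with
#' unit component SDs and weights 0.3/0.3/0.4), mirroring the compressed
#' dynamic range of type II probes on real arrays.
#'
#' @param n_type1,n_type2 Probe counts per design type.
#' @param mix_1 Type I generating mixture: a list with `weights`, `means`,
#'   `sds`.
#' @param mix_2 Type II generating mixture. `NULL` (default) derives it from
#'   `mix_1` by the compression rule below.
#' @param compression How the type II mixture is compressed relative to type I
#'   when `mix_2` is `NULL`: `"affine"` scales the component means by
#'   `compression_factor` (SDs unchanged); `"sigmoid"` instead passes type II
#'   true M-values drawn from `mix_1` through `L * tanh(m / L)` with
#'   `L = sigmoid_scale`, a saturating squash of the tails.
#' @param compression_factor Mean-shrink factor for `"affine"` (default 0.65,
#'   i.e. \eqn{\pm 4 \to \pm 2.6}).
#' @param sigmoid_scale Saturation level `L` for `"sigmoid"`.
#' @param n_samples Number of sample columns.
#' @param n_replicate_groups Number of distinct biological truths; samples are
#'   split into contiguous groups sharing a truth, so
#'   `n_replicate_groups = 1` yields pure technical replicates.
#' @param replicate_noise_sd SD (M-value units) of i.i.d. noise added per
#'   sample column.
#' @param n_spiked Number of truly differential probes.
#' @param effect_size M-value shift added to spiked probes in the second
#'   phenotype group.
#' @param group_labels Per-sample phenotype labels (length `n_samples`); the
#'   second distinct level receives the spike. Default: all samples in one
#'   group.
#' @param seed Integer seed; identical specs produce bit-identical output.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_type1 = 20000, n_type2 = 50000,
                            mix_1 = list(weights = c(0.3, 0.3, 0.4),
                                         means = c(-4, 0, 4),
                                         sds = c(1, 1, 1)),
                            mix_2 = NULL,
                            compression = c("affine", "sigmoid"),
                            compression_factor = 0.65,
                            sigmoid_scale = 3,
                            n_samples = 3, n_replicate_groups = 1,
                            replicate_noise_sd = 0.3,
                            n_spiked = 0, effect_size = 2,
                            group_labels = NULL, seed = 1L) {
  compression <- match.arg(compression)
  stopifnot(n_type1 > 0, n_type2 > 0, n_samples >= 1,
            n_replicate_groups >= 1, replicate_noise_sd >= 0,
            n_spiked >= 0, n_spiked <= n_type1 + n_type2)
  check_mix <- function(m, nm) {
    if (!all(c("weights", "means", "sds") %in% names(m)) ||
        length(m$weights) != length(m$means) ||
        length(m$means) != length(m$sds) || any(m$sds <= 0) ||
        abs(sum(m$weights) - 1) > 1e-9) {
      stop("`", nm, "` must be a list(weights, means, sds) with positive SDs ",
           "and weights summing to 1.", call. = FALSE)
    }
  }
  check_mix(mix_1, "mix_1")
  if (is.null(mix_2) && compression == "affine") {
    mix_2 <- list(weights = mix_1$weights,
                  means = mix_1$means * compression_factor,
                  sds = mix_1$sds)
  }
  if (!is.null(mix_2)) check_mix(mix_2, "mix_2")
  if (is.null(group_labels)) group_labels <- rep("1", n_samples)
  if (length(group_labels) != n_samples) {
    stop("invalid spec: `group_labels` must have one label per sample (",
         n_samples, "), got ", length(group_labels), ".", call. = FALSE)
  }
  structure(
    list(n_type1 = as.integer(n_type1), n_type2 = as.integer(n_type2),
         mix_1 = mix_1, mix_2 = mix_2, compression = compression,
         compression_factor = compression_factor,
         sigmoid_scale = sigmoid_scale,
         n_samples = as.integer(n_samples),
         n_replicate_groups = as.integer(n_replicate_groups),
         replicate_noise_sd = replicate_noise_sd,
         n_spiked = as.integer(n_spiked), effect_size = effect_size,
         group_labels = as.character(group_labels), seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a 450K-like methylation matrix with known truth
#'
#' Draws per-probe true M-values from the probe-type's generating mixture
#' (one truth per replicate group), adds per-column Gaussian replicate noise,
#' and shifts spiked probes by the effect size in the second phenotype group.
#'
#' @param spec A [simulation_spec()].
#' @return A list:
#'   \describe{
#'     \item{data}{tibble, `probe_id` plus one M-value column per sample}
#'     \item{annotation}{tibble `probe_id`, `type`}
#'     \item{truth}{list with `probes` (tibble `probe_id`, `type`, `component`,
#'       `true_m` for replicate group 1, `spiked`), matrices `true_m` and
#'       `component` (probe by replicate group), `replicate_group` and
#'       `group_labels` per sample, and the spiked probe IDs}
#'     \item{spec}{the input spec}
#'   }
#' @examples
#' sim <- simulate_array(simulation_spec(n_type1 = 50, n_type2 = 100,
#'                                       n_samples = 2, seed = 42))
#' dim(sim$data)
#' @export
simulate_array <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_type1 + spec$n_type2
  probe_id <- sprintf("cg%08d", seq_len(n))
  type <- rep(c("I", "II"), c(spec$n_type1, spec$n_type2))

  draw_truth <- function() {
    comp <- integer(n)
    m <- numeric(n)
    for (tt in c("I", "II")) {
      idx <- which(type == tt)
      mix <- if (tt == "I" || is.null(spec$mix_2)) spec$mix_1 else spec$mix_2
      k <- sample.int(length(mix$weights), length(idx), replace = TRUE,
                      prob = mix$weights)
      v <- stats::rnorm(length(idx), mix$means[k], mix$sds[k])
      if (tt == "II" && is.null(spec$mix_2)) {
        # sigmoid compression: saturate the tails of the type I mixture
        v <- spec$sigmoid_scale * tanh(v / spec$sigmoid_scale)
      }
      comp[idx] <- k
      m[idx] <- v
    }
    list(component = comp, true_m = m)
  }
  truths <- lapply(seq_len(spec$n_replicate_groups), function(g) draw_truth())
  true_m <- vapply(truths, `[[`, numeric(n), "true_m")
  component <- vapply(truths, `[[`, integer(n), "component")

  spiked_idx <- if (spec$n_spiked > 0) sample.int(n, spec$n_spiked) else integer(0)
  spiked <- seq_len(n) %in% spiked_idx
  labels <- spec$group_labels
  second <- unique(labels)[2]

  rep_group <- rep(seq_len(spec$n_replicate_groups),
                   length.out = spec$n_samples)
  rep_group <- sort(rep_group)
  sample_id <- sprintf("sample_%02d", seq_len(spec$n_samples))
  values <- matrix(NA_real_, n, spec$n_samples,
                   dimnames = list(probe_id, sample_id))
  for (s in seq_len(spec$n_samples)) {
    m <- true_m[, rep_group[s]]
    if (!is.na(second) && labels[s] == second && length(spiked_idx)) {
      m[spiked_idx] <- m[spiked_idx] + spec$effect_size
    }
    noise <- if (spec$replicate_noise_sd > 0) {
      stats::rnorm(n, 0, spec$replicate_noise_sd)
    } else 0
    values[, s] <- m + noise
  }

  list(
    data = tibble::as_tibble(cbind(tibble::tibble(probe_id = probe_id),
                                   tibble::as_tibble(values))),
    annotation = tibble::tibble(probe_id = probe_id, type = type),
    truth = list(
      probes = tibble::tibble(probe_id = probe_id, type = type,
                              component = component[, 1L],
                              true_m = true_m[, 1L], spiked = spiked),
      true_m = true_m, component = component,
      replicate_group = stats::setNames(rep_group, sample_id),
      group_labels = stats::setNames(labels, sample_id),
      spiked_probes = probe_id[spiked_idx]
    ),
    spec = spec
  )
}

#' Write a simulated array to disk
#'
#' Emits the matrix and annotation in the same delimited formats the
#' normalizer reads, plus the truth record as JSON.
#'
#' @param sim Result of [simulate_array()].
#' @param prefix Output path prefix; writes `<prefix>_matrix.tsv`,
#'   `<prefix>_annotation.tsv` and `<prefix>_truth.json`.
#' @return The three paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             annotation = paste0(prefix, "_annotation.tsv"),
             truth = paste0(prefix, "_truth.json"))
  write_methyl_matrix(sim$data, paths[["matrix"]])
  readr::write_tsv(sim$annotation, paths[["annotation"]], progress = FALSE)
  jsonlite::write_json(
    list(spiked_probes = sim$truth$spiked_probes,
         group_labels = as.list(sim$truth$group_labels),
         replicate_group = as.list(sim$truth$replicate_group),
         seed = sim$spec$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
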