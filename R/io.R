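#' Read a probe-by-sample methylation matrix
#'
#' Reads a delimited text file with probe IDs in the first column and one
#' numeric column per sample; the delimiter (tab or comma) is auto-detected
#' from the header line. Values are validated against the declared scale:
#' beta-values must lie in `[0, 1]`.
#'
#' @param path Path to the matrix file.
#' @param annotation Optional annotation data frame (or path passed to
#'   [read_probe_annotation()]). When supplied, every probe in the matrix must
#'   be annotated; missing probes raise an error naming them.
#' @param scale `"beta"` or `"m"`.
#' @return A tibble (first column `probe_id`, then samples), with attributes
#'   `scale` and, when given, `annotation`.
#' @export
read_methyl_matrix <- function(path, annotation = NULL,
                               scale = c("beta", "m")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("NA", ""), progress = FALSE)
  if (nrow(tbl) == 0L || ncol(tbl) < 2L) {
    stop("matrix is empty: need at least one probe row and one sample column.",
         call. = FALSE)
  }
  names(tbl)[1L] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  if (is.character(annotation)) annotation <- read_probe_annotation(annotation)
  validate_matrix_tbl(tbl, annotation, scale)
  attr(tbl, "scale") <- scale
  if (!is.null(annotation)) attr(tbl, "annotation") <- annotation
  tbl
}

#' Write a methylation matrix
#'
#' Writes probes-as-rows delimited text with a sample-ID header, `NA` cells as
#' `"NA"`, full double precision.
#'
#' @param data A data frame: probe IDs first, samples after.
#' @param path Output path; extension `.csv` selects comma, anything else tab.
#' @param delim Override the delimiter (`"\t"` or `","`).
#' @return `path`, invisibly.
#' @export
write_methyl_matrix <- function(data, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(data, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a probe design-type annotation
#'
#' Accepts either a two-column delimited file `probe_id<TAB>type` with type in
#' `{I, II}`, or an Illumina 450K manifest CSV, from which the `IlmnID` and
#' `Infinium_Design_Type` columns are extracted (leading `[Assay]`-style
#' banner lines before the header are skipped).
#'
#' @param path Path to the annotation or manifest file.
#' @return A tibble with columns `probe_id` and `type`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L)
  header_at <- grep("IlmnID", lines)[1]
  if (!is.na(header_at) && grepl("Infinium_Design_Type", lines[header_at])) {
    man <- readr::read_csv(path, skip = header_at - 1L, show_col_types = FALSE,
                           progress = FALSE)
    ann <- tibble::tibble(probe_id = as.character(man$IlmnID),
                          type = as.character(man$Infinium_Design_Type))
  } else {
    header <- lines[1L]
    delim <- if (grepl("\t", header)) "\t" else ","
    first <- strsplit(header, delim, fixed = TRUE)[[1L]]
    has_header <- any(tolower(first) %in% c("probe_id", "type"))
    ann <- readr::read_delim(path, delim = delim, col_names = has_header,
                             show_col_types = FALSE, progress = FALSE)
    if (!has_header) names(ann)[1:2] <- c("probe_id", "type")
    names(ann)[1:2] <- c("probe_id", "type")
    ann <- tibble::tibble(probe_id = as.character(ann$probe_id),
                          type = as.character(ann$type))
  }
  bad <- !ann$type %in% c("I", "II")
  if (any(bad)) {
    stop("invalid design types for probes: ",
         paste(utils::head(ann$probe_id[bad], 5), collapse = ", "),
         " (expected I or II).", call. = FALSE)
  }
  ann
}

validate_matrix_tbl <- function(tbl, annotation, scale) {
  if (anyDuplicated(tbl$probe_id)) {
    stop("duplicated probe IDs: ",
         paste(utils::head(unique(tbl$probe_id[duplicated(tbl$probe_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  num <- vapply(tbl[-1L], is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric sample columns: ",
         paste(names(tbl)[-1L][!num], collapse = ", "), call. = FALSE)
  }
  if (scale == "beta") {
    vals <- as.matrix(tbl[-1L])
    bad <- which(rowSums(vals < 0 | vals > 1, na.rm = TRUE) > 0)
    if (length(bad)) {
      stop("beta-values outside [0, 1] for probes: ",
           paste(utils::head(tbl$probe_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(annotation)) {
    missing <- setdiff(tbl$probe_id, annotation$probe_id)
    if (length(missing)) {
      stop("probes missing from annotation: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
           call. = FALSE)
    }
  }
  invisible(tbl)
}

# Internal: convert a probes-first data frame + annotation into a values
# matrix with aligned design types.
as_methyl_matrix <- function(data, annotation, scale) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    stop("`data` must be a data frame with a probe-ID column and at least ",
         "one sample column.", call. = FALSE)
  }
  tbl <- data
  names(tbl)[1L] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  if (!is.data.frame(annotation) ||
      !all(c("probe_id", "type") %in% names(annotation))) {
    stop("`annotation` must have columns probe_id and type.", call. = FALSE)
  }
  validate_matrix_tbl(tbl, annotation, scale)
  values <- as.matrix(tbl[-1L])
  rownames(values) <- tbl$probe_id
  type <- annotation$type[match(tbl$probe_id, annotation$probe_id)]
  list(values = values, type = type)
}
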