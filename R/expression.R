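#' Probe-level expression matrix container
#'
#' Thin wrapper around a numeric probes-by-samples matrix tagging the scale
#' of the values: raw single-channel `intensity` (strictly positive) or
#' `log2`. Probe and sample ids live in the dimnames and must be unique.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param scale `"intensity"` or `"log2"`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, scale = c("intensity", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry probe ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!is.numeric(values)) stop("values must be numeric")
  if (scale == "intensity") assert_positive(values)
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

assert_positive <- function(values) {
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- paste0(rownames(values)[bad[, 1]], "/",
                    colnames(values)[bad[, 2]])
    stop("non-positive or missing intensities at: ",
         paste(head(cells, 10), collapse = ", "),
         if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10))
  }
  invisible(values)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples, scale: ", x$scale, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read / write a tab-delimited expression matrix
#'
#' Format: header row of sample ids, first column `probe_id`, one row per
#' probe.
#'
#' @param path file path.
#' @param scale scale tag of the stored values.
#' @return [expr_matrix()] for the reader; invisibly `path` for the writer.
#' @export
read_expression <- function(path, scale = "intensity") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, scale = scale)
}

#' @rdname read_expression
#' @param m an [expr_matrix()].
#' @export
write_expression <- function(m, path) {
  df <- data.frame(probe_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-design table
#'
#' Columns: `sample_id`, `chemical`, `dose_level` (one of control/low/mid/
#' high), `dose_value` (mg/kg), `time_value`, `time_unit` (`hour` or
#' `day`), `replicate`.
#'
#' @param path file path.
#' @return tibble for the reader; invisibly `path` for the writer.
#' @export
read_design <- function(path) {
  d <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  validate_design(d)
}

#' @rdname read_design
#' @param design a design tibble.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_design <- function(design) {
  need <- c("sample_id", "chemical", "dose_level", "dose_value",
            "time_value", "time_unit", "replicate")
  missing <- setdiff(need, names(design))
  if (length(missing)) stop("design lacks column(s): ",
                            paste(missing, collapse = ", "))
  bad <- setdiff(design$dose_level, c("control", "low", "mid", "high"))
  if (length(bad)) stop("unknown dose_level: ", paste(bad, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids in design")
  design
}

#' Read / write a probe annotation table
#'
#' Two tab-delimited columns, `probe_id` and `gene`, mapping each array
#' probe to a gene symbol.
#'
#' @param path file path.
#' @return tibble for the reader; invisibly `path` for the writer.
#' @export
read_annotation <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotation
#' @param annotation an annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize probe intensities across samples
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the across-sample mean of order statistics. Tied values within a column
#' receive the mean of the reference values at their tied ranks. Probe
#' identity is preserved. Idempotent.
#'
#' @param m an [expr_matrix()] on the intensity scale with no missing or
#'   non-positive values.
#' @return an [expr_matrix()] on the intensity scale.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "intensity") stop("expected an intensity-scale matrix")
  assert_positive(m$values)
  out <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(out) <- dimnames(m$values)
  expr_matrix(out, scale = "intensity")
}

#' Log2-transform an intensity matrix
#'
#' @param m an [expr_matrix()] on the intensity scale.
#' @return an [expr_matrix()] on the log2 scale.
#' @export
to_log2 <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "intensity") stop("expected an intensity-scale matrix")
  assert_positive(m$values)
  out <- log2(m$values)
  structure(list(values = out, scale = "log2"), class = "expr_matrix")
}

#' Per-group mean and standard error of log2 expression
#'
#' Summarizes replicate animals within each (chemical, dose level, time)
#' exposure group: `y` is the mean log2 expression over replicates and `se`
#' the standard error of that mean, the two quantities the hierarchical
#' model conditions on. Groups need at least two replicates; a standard
#' error of zero (constant replicates, possible only in degenerate
#' synthetic input) is floored at `se_floor` and flagged.
#'
#' @param m an [expr_matrix()] on the log2 scale.
#' @param design a sample-design tibble covering every sample in `m`.
#' @param se_floor lower bound applied to `se` (default `1e-6`).
#' @return tibble with columns `probe_id`, `chemical`, `dose_level`,
#'   `time_value`, `time_unit`, `y`, `se`, `n`, `se_floored`.
#' @export
group_estimates <- function(m, design, se_floor = 1e-6) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("expected a log2-scale matrix")
  design <- validate_design(tibble::as_tibble(design))
  missing <- setdiff(colnames(m$values), design$sample_id)
  if (length(missing)) {
    stop("design lacks sample(s): ", paste(missing, collapse = ", "))
  }
  design <- design[match(colnames(m$values), design$sample_id), ]
  key <- paste(design$chemical, design$dose_level, design$time_value,
               design$time_unit, sep = "\r")
  groups <- !duplicated(key)
  counts <- table(key)
  if (any(counts < 2)) {
    small <- unique(key)[unique(key) %in% names(counts)[counts < 2]]
    stop("group(s) with fewer than 2 replicates: ",
         paste(gsub("\r", "/", small), collapse = "; "))
  }
  res <- lapply(unique(key), function(k) {
    cols <- key == k
    v <- m$values[, cols, drop = FALSE]
    y <- rowMeans(v)
    raw_se <- apply(v, 1, sd) / sqrt(sum(cols))
    info <- design[match(k, key), ]
    tibble::tibble(
      probe_id = rownames(m$values),
      chemical = info$chemical,
      dose_level = info$dose_level,
      time_value = info$time_value,
      time_unit = info$time_unit,
      y = unname(y),
      se = unname(pmax(raw_se, se_floor)),
      n = sum(cols),
      se_floored = unname(raw_se < se_floor))
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$probe_id, .data$chemical, .data$time_value,
                 factor(.data$dose_level,
                        levels = c("control", "low", "mid", "high")))
}
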