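#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilising map \code{atanh(r)} applied after clipping \code{r}
#' to \code{[-r_clip, r_clip]} so that perfectly correlated (or duplicated)
#' series yield a large finite value instead of infinity.
#'
#' @param r Numeric vector of correlations, each in \code{[-1, 1]}.
#' @param r_clip Clipping bound in \code{(0, 1)}; values of \code{|r|} above
#'   it are clipped before the transform. Default \code{0.999999}.
#' @return Numeric vector of Fisher-z values; odd and strictly increasing in
#'   \code{r} on the unclipped range.
#' @examples
#' fisher_z(c(-0.5, 0, 0.9))
#' @export
fisher_z <- function(r, r_clip = 0.999999) {
  stopifnot(is.numeric(r), length(r_clip) == 1L, r_clip > 0, r_clip < 1)
  if (anyNA(r)) stop("correlations contain missing values")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| > 1: not a correlation")
  atanh(pmin(pmax(r, -r_clip), r_clip))
}

#' ROI time-series container
#'
#' @param values Numeric matrix, T timepoints x R regions.
#' @param subject_id Subject identifier.
#' @param region_labels Optional character vector of length R.
#' @return An object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(values, subject_id = "subject", region_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time series must be numeric")
  if (anyNA(values)) stop("time series contain missing values")
  if (nrow(values) < 3L) stop("need at least 3 timepoints (T >= 3)")
  if (ncol(values) < 2L) stop("need at least 2 regions (R >= 2)")
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ", paste(which(sds == 0), collapse = ", "))
  }
  if (!is.null(region_labels) && length(region_labels) != ncol(values)) {
    stop("region_labels length must equal the number of regions")
  }
  structure(list(subject_id = as.character(subject_id),
                 values = values,
                 region_labels = region_labels),
            class = "roi_timeseries")
}

#' Compute a Fisher-z functional-connectivity matrix
#'
#' Pearson correlation between every pair of regional time series, Fisher
#' z-transformed. The diagonal is forced to zero (self-connectivity carries
#' no information and \code{atanh(1)} diverges).
#'
#' @param ts An [roi_timeseries], or a plain T x R numeric matrix.
#' @param r_clip Clipping bound applied to \code{|r|} before \code{atanh};
#'   see [fisher_z()].
#' @param subject_id Used when \code{ts} is a plain matrix.
#' @return An object of class \code{fc_matrix}: list with \code{subject_id},
#'   \code{z} (R x R symmetric, zero diagonal, finite) and \code{r_clip}.
#' @export
compute_fc <- function(ts, r_clip = 0.999999, subject_id = NULL) {
  if (!inherits(ts, "roi_timeseries")) {
    ts <- roi_timeseries(ts, subject_id = if (is.null(subject_id)) "subject" else subject_id)
  }
  r <- stats::cor(ts$values)
  z <- matrix(fisher_z(as.vector(r), r_clip), nrow(r), ncol(r))
  z <- (z + t(z)) / 2          # enforce exact symmetry against fp asymmetry
  diag(z) <- 0
  if (!is.null(ts$region_labels)) dimnames(z) <- list(ts$region_labels, ts$region_labels)
  fc_matrix(z, subject_id = ts$subject_id, r_clip = r_clip, validate = TRUE)
}

#' Construct / validate an fc_matrix object
#'
#' @param z R x R numeric matrix of Fisher-z connectivity values.
#' @param subject_id Subject identifier.
#' @param r_clip Clipping bound recorded with the matrix.
#' @param validate Check invariants (symmetry, zero diagonal, finiteness).
#' @return Object of class \code{fc_matrix}.
#' @export
fc_matrix <- function(z, subject_id = "subject", r_clip = 0.999999, validate = TRUE) {
  z <- as.matrix(z)
  if (validate) {
    if (nrow(z) != ncol(z)) stop("FC matrix must be square")
    if (nrow(z) < 2L) stop("FC matrix needs at least 2 regions")
    if (any(!is.finite(z))) stop("FC matrix contains non-finite values")
    if (!identical(z, t(z))) stop("FC matrix must be exactly symmetric")
    if (any(diag(z) != 0)) stop("FC matrix diagonal must be zero")
  }
  structure(list(subject_id = as.character(subject_id), z = z, r_clip = r_clip),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> subject", x$subject_id, "-", nrow(x$z), "x", ncol(x$z),
      "Fisher-z connectivity\n")
  cat("  off-diagonal range:",
      sprintf("[%.4f, %.4f]", min(x$z[upper.tri(x$z)]), max(x$z[upper.tri(x$z)])), "\n")
  invisible(x)
}

#' Read ROI time series from delimited text
#'
#' Rows are timepoints, columns are regions; an optional single header row
#' holds region labels.
#'
#' @param path File path (TSV/CSV; separator sniffed from the first line).
#' @param header Whether the first row holds region labels.
#' @param subject_id Defaults to the file name without extension.
#' @return An [roi_timeseries].
#' @export
read_roi_timeseries <- function(path, header = FALSE, subject_id = NULL) {
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = header, sep = sep)
  roi_timeseries(as.matrix(df), subject_id = subject_id,
                 region_labels = if (header) colnames(df) else NULL)
}

#' Read a per-subject FC matrix from delimited text
#'
#' @param path Path to an R x R delimited text file (no header).
#' @param subject_id Defaults to the file name stem.
#' @param r_clip Clipping bound recorded with the matrix.
#' @return An [fc_matrix].
#' @export
read_fc_matrix <- function(path, subject_id = NULL, r_clip = 0.999999) {
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  sep <- .sniff_sep(path)
  z <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(z) <- NULL
  if (nrow(z) != ncol(z)) stop("malformed FC matrix file (not square): ", path)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  fc_matrix(z, subject_id = subject_id, r_clip = r_clip)
}

#' Write an FC matrix as delimited text
#'
#' @param fc An [fc_matrix].
#' @param path Output file; tab-separated, no header.
#' @return \code{path}, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.table(fc$z, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}
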