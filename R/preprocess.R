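#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto the identical value distribution: the
#' per-rank means of the sorted input columns. Within-column rank order is
#' preserved; tied values are resolved by rank interpolation
#' (\code{limma::normalizeQuantiles} with \code{ties = TRUE}).
#'
#' @param m Numeric genes x samples matrix, no missing values.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  check_expression(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("quantile normalization needs >= 2 genes and >= 2 samples")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Centralize an expression matrix gene-wise
#'
#' Subtracts from each gene its mean over all samples, so every row has mean
#' zero. The reference population is the full sample set (controls included).
#'
#' @param m Numeric genes x samples matrix.
#' @return Centralized matrix.
#' @export
centralize <- function(m) {
  check_expression(m)
  m - rowMeans(m)
}

#' Standard preprocessing: quantile normalization then centralization
#'
#' @param m Numeric genes x samples matrix of log-scale expression.
#' @return Preprocessed matrix ready for SOM training.
#' @export
preprocess_expression <- function(m) {
  centralize(quantile_normalize(m))
}

check_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (anyNA(m) || any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values")
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m))) {
    stop("duplicated gene IDs: ",
         paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 5),
               collapse = ", "))
  }
  invisible(TRUE)
}
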