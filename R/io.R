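#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Values are log-scale expression intensities.
#'
#' @param path Path to a tab-separated text file.
#' @return Numeric matrix (genes x samples) with gene IDs as row names and
#'   sample IDs as column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene ID column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicated gene ID(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the first (gene identifier) column.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' @param path Path to a tab-separated annotation table with a `sample_id`
#'   column.
#' @return A data.frame.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("annotation table must contain a 'sample_id' column")
  }
  df
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Trailing empty fields
#' are ignored; duplicate set names and empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(x) {
    f <- strsplit(x, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need name, description, members): ",
                            substr(x, 1, 40), call. = FALSE)
    members <- f[-(1:2)]
    members <- unique(members[nzchar(members)])
    if (length(members) == 0) stop("empty gene set in GMT: ", f[1], call. = FALSE)
    list(name = f[1], members = members)
  })
  nm <- vapply(sets, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    stop("duplicate gene set name(s) in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(sets, `[[`, "members")
  names(out) <- nm
  out
}

#' Write gene sets to GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  if (any(lengths(sets) == 0)) stop("cannot write empty gene sets")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival record table
#'
#' @param annotation A data.frame with columns `sample_id` and `survived_28d`
#'   (logical or 0/1; `NA` for samples without outcome, e.g. controls).
#' @return data.frame with `sample_id` and logical `survived_28d`, restricted
#'   to outcome-bearing samples.
#' @export
survival_records <- function(annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("sample_id", "survived_28d") %in% colnames(annotation)))
  out <- data.frame(sample_id = as.character(annotation$sample_id),
                    survived_28d = as.logical(annotation$survived_28d),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$survived_28d), , drop = FALSE]
  if (anyDuplicated(out$sample_id)) stop("duplicate sample_id in survival records")
  rownames(out) <- NULL
  out
}
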