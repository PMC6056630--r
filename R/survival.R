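#' Prognostic map: per-metagene 28-day survivor percentage
#'
#' For each metagene the supporting cases are the outcome-bearing samples
#' whose (centralized) portrait value exceeds `sd_factor` times the
#' metagene's across-sample SD, i.e. the samples over-expressing that
#' metagene. The map value is the percentage of 28-day survivors among the
#' supporting cases. Metagenes supported by fewer than 10% of the
#' outcome-bearing samples (or with zero expression SD) are masked and
#' serialized as `NA` ("white areas").
#'
#' Only outcome-bearing samples (typically the disease cases; controls carry
#' no outcome) enter both the SD estimate and the support counts.
#'
#' @param model A `som_model`.
#' @param survival data.frame with `sample_id` and logical `survived_28d`
#'   (see [survival_records()]).
#' @param sd_factor Over-expression threshold in SD units (default 1, i.e.
#'   value > +1 SD).
#' @return Object of class `prognostic_map`: `pct` (per-metagene percentage,
#'   `NA` where masked), `support`, `mask`, `grid`, `n_outcome`,
#'   `min_support`, `sd_factor`.
#' @export
prognostic_map <- function(model, survival, sd_factor = 1) {
  stopifnot(inherits(model, "som_model"))
  survival <- survival_records(survival)
  ids <- intersect(survival$sample_id, colnames(model$codebook))
  if (length(ids) == 0) stop("no outcome-bearing samples in the model", call. = FALSE)
  survived <- survival$survived_28d[match(ids, survival$sample_id)]
  P <- model$codebook[, ids, drop = FALSE]
  n_out <- length(ids)
  sigma <- unname(apply(P, 1, stats::sd))
  over <- P > sd_factor * sigma           # nodes x samples
  support <- unname(rowSums(over))
  survivors <- as.vector(over %*% as.numeric(survived))
  min_support <- ceiling(0.10 * n_out)
  mask <- support < min_support | sigma == 0
  pct <- 100 * survivors / support
  pct[mask] <- NA_real_
  structure(list(pct = as_portrait(pct, model$grid),
                 support = support, mask = mask, grid = model$grid,
                 n_outcome = n_out, min_support = min_support,
                 sd_factor = sd_factor),
            class = "prognostic_map")
}

#' @export
print.prognostic_map <- function(x, ...) {
  cat("prognostic_map:", x$grid[1], "x", x$grid[2], "grid,", x$n_outcome,
      "outcome-bearing samples;", sum(!x$mask), "metagenes unmasked (support >=",
      x$min_support, ")\n")
  if (any(!x$mask)) {
    cat("survivor percentage range:",
        paste(round(range(x$pct[!x$mask]), 1), collapse = " - "), "\n")
  }
  invisible(x)
}

#' Prognostic map as a tidy table
#'
#' @param pm A `prognostic_map`.
#' @return data.frame: 0-based `row`/`col`, `support`, `pct` (survivor
#'   percentage to 0.1, `NA` where masked), `mask`.
#' @export
prognostic_map_table <- function(pm) {
  stopifnot(inherits(pm, "prognostic_map"))
  coords <- node_coords(pm$grid)
  data.frame(row = coords[, "row"], col = coords[, "col"],
             support = pm$support, pct = round(as.numeric(pm$pct), 1),
             mask = pm$mask)
}

#' Per-class 28-day survivor percentages with class-vs-rest Fisher tests
#'
#' For every class with outcome data: the percentage of survivors, and the
#' one-sided Fisher exact p of the class-vs-rest 2x2 table, with the
#' alternative oriented along the observed direction (enrichment of survival
#' when the class rate exceeds the rest, depletion otherwise). Classes
#' without any outcome-bearing sample are omitted from the table.
#'
#' @param labels Class labels named by sample ID (or a `class_assignment`).
#' @param survival data.frame with `sample_id` and `survived_28d`.
#' @return data.frame: class, n, survivors, pct_survived, direction, p_value.
#' @export
class_survival_rates <- function(labels, survival) {
  if (inherits(labels, "class_assignment")) labels <- labels$labels
  if (is.null(names(labels))) stop("labels must be named by sample ID", call. = FALSE)
  survival <- survival_records(survival)
  ids <- intersect(names(labels), survival$sample_id)
  if (length(ids) == 0) stop("no overlap between classes and outcomes", call. = FALSE)
  lab <- as.character(labels[ids])
  survived <- survival$survived_28d[match(ids, survival$sample_id)]
  classes <- sort(unique(lab))
  rows <- lapply(classes, function(k) {
    inc <- lab == k
    n <- sum(inc)
    surv_in <- sum(survived[inc])
    rate_in <- surv_in / n
    rate_out <- if (any(!inc)) sum(survived[!inc]) / sum(!inc) else NA_real_
    direction <- if (is.na(rate_out) || rate_in >= rate_out) "greater" else "less"
    p <- if (any(!inc)) {
      tab <- matrix(c(surv_in, n - surv_in,
                      sum(survived[!inc]), sum(!inc) - sum(survived[!inc])), 2, 2)
      stats::fisher.test(tab, alternative = direction)$p.value
    } else NA_real_
    data.frame(class = k, n = n, survivors = surv_in,
               pct_survived = 100 * rate_in, direction = direction,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
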