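#' One-sided Fisher exact spot enrichment
#'
#' Tests over-representation of a gene set within a spot's member genes via
#' the 2x2 table (in/out spot x in/out set) over the gene universe, with the
#' one-sided (enrichment) alternative.
#'
#' @param spot_genes Character vector of spot member genes (subset of the
#'   universe).
#' @param set_genes Character vector of gene set members.
#' @param universe Character vector of all genes considered.
#' @return List with `p_value`, `overlap`, `odds_ratio`, `expected` (overlap
#'   expected under independence) and the table margins.
#' @export
fisher_spot_enrichment <- function(spot_genes, set_genes, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  spot_genes <- unique(spot_genes)
  set_genes <- intersect(unique(set_genes), universe)
  if (length(set_genes) == 0) stop("gene set does not intersect the universe", call. = FALSE)
  if (!all(spot_genes %in% universe)) stop("spot genes must be inside the universe", call. = FALSE)
  k <- length(intersect(spot_genes, set_genes))
  K <- length(spot_genes)
  S <- length(set_genes)
  N <- length(universe)
  tab <- matrix(c(k, S - k, K - k, N - S - K + k), 2, 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = unname(ft$p.value), overlap = k,
       odds_ratio = unname(ft$estimate), expected = K * S / N,
       spot_size = K, set_size = S, universe_size = N)
}

#' Fisher enrichment of every gene set in every spot
#'
#' @param seg A `spot_segmentation`.
#' @param sets Named list of gene sets.
#' @param universe Gene universe (defaults to the union of all spot genes and
#'   set members present; normally pass `rownames(expr)`).
#' @param p_threshold Raw-p annotation threshold (the reporting convention is
#'   `p < 1e-7`).
#' @return data.frame with one row per spot x set: raw one-sided p,
#'   Benjamini-Hochberg adjusted p per spot, overlap, odds ratio and a
#'   `significant` flag at `p_threshold`.
#' @export
spot_enrichment_table <- function(seg, sets, universe, p_threshold = 1e-7) {
  stopifnot(inherits(seg, "spot_segmentation"), is.list(sets), !is.null(names(sets)))
  rows <- list()
  for (s in seg$spots) {
    sg <- intersect(s$genes, universe)
    res <- lapply(names(sets), function(nm) {
      r <- fisher_spot_enrichment(sg, sets[[nm]], universe)
      data.frame(spot = s$label, set = nm, overlap = r$overlap,
                 spot_size = r$spot_size, set_size = r$set_size,
                 odds_ratio = r$odds_ratio, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
    rows[[s$label]] <- df
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < p_threshold
  rownames(out) <- NULL
  out
}

#' Sample-wise gene set Z (GSZ) profile
#'
#' For a centralized matrix, the score of sample `j` is the standardized mean
#' difference between the set genes and the transcriptome background with
#' finite-population correction:
#' \deqn{GSZ_j = \frac{\bar e_{G,j} - \bar e_{\cdot,j}}
#'   {s_j \sqrt{1/|G| - 1/N}}}
#' where \eqn{\bar e_{G,j}} is the mean over the `|G|` set genes,
#' \eqn{\bar e_{\cdot,j}} the mean over all `N` genes and \eqn{s_j} the
#' (n-1 denominator) SD of sample `j` over all genes. This is the Z score of
#' the set mean under random draws of `|G|` genes without replacement.
#' Set members absent from the matrix are dropped with a warning; if the set
#' covers all genes the score is identically zero.
#'
#' @param set Character vector of member gene IDs.
#' @param m Centralized genes x samples matrix.
#' @return Named numeric vector of per-sample scores (`NA` for zero-variance
#'   samples).
#' @export
gsz_profile <- function(set, m) {
  check_expression(m)
  set <- unique(set)
  members <- intersect(set, rownames(m))
  dropped <- length(set) - length(members)
  if (dropped > 0) {
    warning(dropped, " gene set member(s) absent from the matrix were dropped")
  }
  if (length(members) == 0) stop("gene set has no members in the matrix", call. = FALSE)
  nG <- length(members)
  N <- nrow(m)
  mg <- colMeans(m[members, , drop = FALSE])
  mall <- colMeans(m)
  if (nG == N) return(stats::setNames(rep(0, ncol(m)), colnames(m)))
  s <- apply(m, 2, stats::sd)
  z <- (mg - mall) / (s * sqrt(1 / nG - 1 / N))
  z[s == 0] <- NA_real_
  z
}

#' GSZ profiles of a gene set collection
#'
#' @param sets Named list of gene sets.
#' @param m Centralized genes x samples matrix.
#' @return samples x sets numeric matrix of GSZ scores.
#' @export
gsz_matrix <- function(sets, m) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- vapply(sets, gsz_profile, numeric(ncol(m)), m = m)
  rownames(out) <- colnames(m)
  out
}

#' Population map of a gene set on the SOM
#'
#' Pixel counts of the set genes' BMU positions, plus per-spot local
#' percentages (set genes in spot / all genes in spot).
#'
#' @param set Character vector of member gene IDs.
#' @param model A `som_model`.
#' @param seg Optional `spot_segmentation` for the per-spot percentages.
#' @return List with `counts` (per-pixel `som_portrait`, sums to the number
#'   of set genes present in the model) and `spot_percentage` (named numeric,
#'   `NULL` without a segmentation).
#' @export
population_map <- function(set, model, seg = NULL) {
  stopifnot(inherits(model, "som_model"))
  members <- intersect(unique(set), names(model$bmu))
  counts <- tabulate(model$bmu[members], prod(model$grid))
  pct <- NULL
  if (!is.null(seg)) {
    pct <- vapply(seg$spots, function(s) {
      if (length(s$genes) == 0) return(NA_real_)
      100 * length(intersect(members, s$genes)) / length(s$genes)
    }, numeric(1))
    names(pct) <- vapply(seg$spots, `[[`, "", "label")
  }
  list(counts = as_portrait(counts, model$grid), spot_percentage = pct)
}

#' Named transcriptomic scores per sample
#'
#' The severity score is the mean expression profile of a designated spot
#' (the over-expression module of severe disease); every other score is the
#' GSZ profile of a named gene set (e.g. viral/IFN, erythrocyte, platelet,
#' coagulation signatures).
#'
#' @param m Centralized genes x samples matrix.
#' @param seg A `spot_segmentation`.
#' @param severity_spot Label of the designated severity spot.
#' @param sets Named list of gene sets, one score column each.
#' @return data.frame: `sample_id`, `severity`, then one column per set.
#' @export
named_scores <- function(m, seg, severity_spot, sets = list()) {
  sev <- spot_expression_profile(seg, severity_spot, m)
  out <- data.frame(sample_id = colnames(m), severity = unname(sev),
                    stringsAsFactors = FALSE)
  for (nm in names(sets)) out[[nm]] <- unname(gsz_profile(sets[[nm]], m))
  rownames(out) <- NULL
  out
}

#' Designate the severity spot from a control/case contrast
#'
#' Picks the spot whose mean expression profile shows the largest
#' standardized case-minus-control difference (mean difference divided by
#' the profile's SD within cases), i.e. the over-expression module that
#' separates disease from control most reliably. Raw mean differences are
#' not used because a diffuse disease module (high contrast, high spread)
#' and a tight unrelated module can tie on them.
#'
#' @param seg A `spot_segmentation`.
#' @param m Centralized genes x samples matrix.
#' @param is_case Logical vector over samples (or named by sample ID).
#' @return Spot label.
#' @export
designate_severity_spot <- function(seg, m, is_case) {
  if (!is.null(names(is_case))) is_case <- is_case[colnames(m)]
  is_case <- as.logical(is_case)
  stopifnot(length(is_case) == ncol(m), any(is_case), any(!is_case))
  labels <- vapply(seg$spots, `[[`, "", "label")
  delta <- vapply(labels, function(l) {
    p <- spot_expression_profile(seg, l, m)
    s <- stats::sd(p[is_case])
    if (s == 0) return(-Inf)
    (mean(p[is_case]) - mean(p[!is_case])) / s
  }, numeric(1))
  labels[which.max(delta)]
}
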