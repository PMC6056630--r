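# 8-neighborhood pixel adjacency (king's moves) among a set of node indices;
# optionally an edge between two pixels is kept only if the Euclidean
# distance between their codebook vectors does not exceed max_dist
pixel_components <- function(pixels, grid, codebook = NULL, max_dist = Inf) {
  if (length(pixels) == 0) return(list())
  coords <- node_coords(grid)[pixels, , drop = FALSE]
  n <- length(pixels)
  if (n == 1) return(list(pixels))
  pairs <- which(outer(coords[, "row"], coords[, "row"], function(a, b) abs(a - b) <= 1) &
                   outer(coords[, "col"], coords[, "col"], function(a, b) abs(a - b) <= 1),
                 arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  if (is.finite(max_dist) && !is.null(codebook) && nrow(pairs) > 0) {
    d <- sqrt(rowSums((codebook[pixels[pairs[, 1]], , drop = FALSE] -
                         codebook[pixels[pairs[, 2]], , drop = FALSE])^2))
    pairs <- pairs[d <= max_dist, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  unname(split(pixels, comp))
}

# median codebook distance between all 8-neighborhood pixel pairs of the map
median_neighbor_distance <- function(model) {
  coords <- node_coords(model$grid)
  n <- prod(model$grid)
  pairs <- which(outer(coords[, "row"], coords[, "row"], function(a, b) abs(a - b) <= 1) &
                   outer(coords[, "col"], coords[, "col"], function(a, b) abs(a - b) <= 1),
                 arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums((model$codebook[pairs[, 1], , drop = FALSE] -
                       model$codebook[pairs[, 2], , drop = FALSE])^2))
  stats::median(d)
}

# U-value: mean Euclidean distance between a node's codebook vector and its
# grid neighbors' (8-neighborhood over the full map)
#' U-matrix of a trained SOM
#'
#' Per-pixel mean Euclidean distance between the pixel's codebook vector and
#' those of its 8-neighborhood grid neighbors; ridges of high U mark borders
#' between clusters of co-expressed genes.
#'
#' @param model A `som_model`.
#' @return Numeric per-pixel vector of class `som_portrait`.
#' @export
u_matrix <- function(model) {
  stopifnot(inherits(model, "som_model"))
  grid <- model$grid
  coords <- node_coords(grid)
  n <- prod(grid)
  u <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(abs(coords[, "row"] - coords[i, "row"]) <= 1 &
                  abs(coords[, "col"] - coords[i, "col"]) <= 1)
    nb <- setdiff(nb, i)
    d <- sqrt(rowSums((model$codebook[nb, , drop = FALSE] -
                         rep(model$codebook[i, ], each = length(nb)))^2))
    u[i] <- mean(d)
  }
  as_portrait(u, grid)
}

#' Segment the variance map into spot modules
#'
#' Pixels whose variance reaches the given percentile of the variance map
#' form the candidate region; its connected components (8-neighborhood)
#' become spots. With `split_umap` (the default), the U-map
#' ("maximum distance between neighboring pixels") topology is applied:
#' an adjacency edge between two supra-threshold pixels is cut when the
#' Euclidean distance between their codebook vectors exceeds `umap_factor`
#' times the median codebook distance of all neighboring pixel pairs of the
#' map, so that distinct co-expression modules that abut on the map are not
#' fused into one spot. Member genes of a spot are the genes whose BMU lies
#' inside it. Spots are labelled `A`, `B`, ... in descending order of total
#' spot variance.
#'
#' @param model A `som_model`.
#' @param vmap Variance map (defaults to [variance_map()] of the model).
#' @param percentile Variance percentile in (0, 100) defining the
#'   supra-threshold region (default 90).
#' @param split_umap Logical; apply the U-map edge-cut split (default on).
#' @param umap_factor Edge-cut factor over the map-wide median neighboring
#'   codebook distance.
#' @param min_genes Minimum member genes a spot must collect (default 5):
#'   supra-threshold pixel regions carrying no or only a few stray genes are
#'   border/interpolation artifacts, not co-expression modules, and are
#'   discarded.
#' @return Object of class `spot_segmentation`: list with `spots` (per spot:
#'   `label`, `pixels` (node indices), `genes`, `total_variance`), `grid` and
#'   the parameters used.
#' @export
segment_spots <- function(model, vmap = variance_map(model), percentile = 90,
                          split_umap = TRUE, umap_factor = 2,
                          min_genes = 5L) {
  stopifnot(inherits(model, "som_model"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be inside (0, 100)", call. = FALSE)
  }
  vmap <- as.numeric(vmap)
  if (length(vmap) != prod(model$grid)) stop("variance map does not match the grid")
  thr <- stats::quantile(vmap, percentile / 100)
  pixels <- which(vmap >= thr)
  max_dist <- if (split_umap) umap_factor * median_neighbor_distance(model) else Inf
  comps <- pixel_components(pixels, model$grid, model$codebook, max_dist)
  if (min_genes > 0) {
    n_genes_in <- vapply(comps, function(px) sum(model$bmu %in% px), numeric(1))
    comps <- comps[n_genes_in >= min_genes]
  }

  tv <- vapply(comps, function(px) sum(vmap[px]), numeric(1))
  comps <- comps[order(tv, decreasing = TRUE)]
  tv <- sort(tv, decreasing = TRUE)
  labels <- spot_labels(length(comps))
  spots <- lapply(seq_along(comps), function(i) {
    px <- sort(comps[[i]])
    list(label = labels[i], pixels = px,
         genes = names(model$bmu)[model$bmu %in% px],
         total_variance = tv[i])
  })
  structure(list(spots = spots, grid = model$grid,
                 parameters = list(percentile = percentile,
                                   threshold = unname(thr),
                                   split_umap = split_umap,
                                   umap_factor = umap_factor,
                                   min_genes = min_genes)),
            class = "spot_segmentation")
}

spot_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), rep(LETTERS, 26)))[seq_len(n)]
}

#' @export
print.spot_segmentation <- function(x, ...) {
  cat("spot_segmentation:", length(x$spots), "spots at variance percentile",
      x$parameters$percentile, "\n")
  for (s in x$spots) {
    cat(sprintf("  %-3s %3d pixels %5d genes  total variance %.3g\n",
                s$label, length(s$pixels), length(s$genes), s$total_variance))
  }
  invisible(x)
}

spot_by_label <- function(seg, label) {
  for (s in seg$spots) if (s$label == label) return(s)
  stop("no spot labelled '", label, "'", call. = FALSE)
}

#' Genes of one spot
#'
#' @param seg A `spot_segmentation`.
#' @param label Spot label.
#' @return Character vector of member gene IDs.
#' @export
spot_genes <- function(seg, label) spot_by_label(seg, label)$genes

#' Overexpression spots active in one sample portrait
#'
#' A spot is active iff the mean portrait value over its pixels strictly
#' exceeds the `q`-quantile of the portrait outside the spot and is
#' positive. Excluding the spot's own pixels from the reference quantile
#' keeps the rule meaningful for large spots, which would otherwise set
#' their own threshold; for small spots the two references coincide.
#'
#' @param p A portrait (per-metagene vector).
#' @param seg A `spot_segmentation`.
#' @param q Activation quantile in (0, 1), default 0.98.
#' @return Character vector of active spot labels.
#' @export
sample_spot_activation <- function(p, seg, q = 0.98) {
  stopifnot(inherits(seg, "spot_segmentation"))
  if (length(seg$spots) == 0) stop("empty segmentation", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be inside (0, 1)", call. = FALSE)
  p <- as.numeric(p)
  active <- vapply(seg$spots, function(s) {
    m <- mean(p[s$pixels])
    rest <- p[-s$pixels]
    thr <- if (length(rest) > 0) stats::quantile(rest, q) else stats::quantile(p, q)
    m > thr && m > 0
  }, logical(1))
  labels <- vapply(seg$spots, `[[`, "", "label")
  labels[active]
}

#' Per-sample mean expression profile of a spot
#'
#' @param seg A `spot_segmentation`.
#' @param label Spot label.
#' @param m Genes x samples expression matrix containing the spot genes.
#' @return Named numeric vector over samples (per-sample mean of the spot's
#'   member genes).
#' @export
spot_expression_profile <- function(seg, label, m) {
  s <- spot_by_label(seg, label)
  genes <- intersect(s$genes, rownames(m))
  if (length(genes) == 0) stop("spot ", label, " has no genes in the matrix", call. = FALSE)
  colMeans(m[genes, , drop = FALSE])
}

#' Active-spot counts per sample and their distribution by group
#'
#' @param model A `som_model`.
#' @param seg A `spot_segmentation`.
#' @param groups Named character vector or factor of group labels, named by
#'   sample ID (or in codebook column order).
#' @param q Activation quantile, see [sample_spot_activation()].
#' @return List with `counts` (data.frame: sample_id, group, n_active) and
#'   `histogram` (table of n_active by group).
#' @export
spot_frequency_distribution <- function(model, seg, groups = NULL, q = 0.98) {
  stopifnot(inherits(model, "som_model"))
  ids <- colnames(model$codebook)
  n_active <- vapply(ids, function(s) {
    length(sample_spot_activation(sample_portrait(model, s), seg, q))
  }, integer(1))
  if (is.null(groups)) groups <- rep("all", length(ids))
  if (!is.null(names(groups))) groups <- groups[ids]
  counts <- data.frame(sample_id = ids, group = as.character(groups),
                       n_active = unname(n_active), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  hist <- table(group = counts$group, n_active = counts$n_active)
  list(counts = counts, histogram = hist)
}
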