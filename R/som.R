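#' Grid coordinates of SOM nodes
#'
#' Nodes are indexed 1..rows*cols in row-major order; coordinates are 0-based
#' `(row, col)` pairs, the convention used by every serialized output.
#'
#' @param grid Integer vector `c(rows, cols)`.
#' @return Integer matrix (nodes x 2) with columns `row`, `col`.
#' @export
node_coords <- function(grid) {
  nr <- grid[1]; nc <- grid[2]
  i <- seq_len(nr * nc) - 1L
  cbind(row = i %/% nc, col = i %% nc)
}

# squared Euclidean distances genes x nodes
dist2_to_codebook <- function(m, codebook, x2 = rowSums(m^2)) {
  w2 <- rowSums(codebook^2)
  d2 <- -2 * tcrossprod(m, codebook)
  d2 <- sweep(d2, 2, w2, "+") + x2
  d2[d2 < 0] <- 0
  d2
}

assign_bmu <- function(m, codebook, x2 = rowSums(m^2)) {
  d2 <- dist2_to_codebook(m, codebook, x2)
  max.col(-d2, ties.method = "first")
}

# PCA initialization: codebook spans the plane of the first two principal
# directions of the gene cloud; seeded random fallback for degenerate input.
som_init <- function(m, grid, seed) {
  n_nodes <- prod(grid)
  coords <- node_coords(grid)
  ctr <- colMeans(m)
  a1 <- if (grid[1] > 1) 2 * coords[, "row"] / (grid[1] - 1) - 1 else rep(0, n_nodes)
  a2 <- if (grid[2] > 1) 2 * coords[, "col"] / (grid[2] - 1) - 1 else rep(0, n_nodes)
  mc <- sweep(m, 2, ctr)
  sv <- tryCatch(svd(mc, nu = 0, nv = 2), error = function(e) NULL)
  ok <- !is.null(sv) && length(sv$d) >= 1 && sv$d[1] > 1e-10
  if (!ok) {
    set.seed(seed)
    idx <- sample(nrow(m), n_nodes, replace = TRUE)
    return(m[idx, , drop = FALSE] +
             matrix(stats::rnorm(n_nodes * ncol(m), sd = 1e-4), n_nodes))
  }
  sd1 <- sv$d[1] / sqrt(nrow(m))
  v1 <- sv$v[, 1]
  if (ncol(sv$v) >= 2 && sv$d[2] > 1e-10) {
    sd2 <- sv$d[2] / sqrt(nrow(m)); v2 <- sv$v[, 2]
  } else {
    sd2 <- 0; v2 <- rep(0, ncol(m))
  }
  cb <- outer(a1 * sd1, v1) + outer(a2 * sd2, v2)
  sweep(cb, 2, ctr, "+")
}

#' Train a batch self-organizing map of metagenes
#'
#' Genes are data points in sample space; each SOM node ("metagene") carries
#' a codebook profile over samples. Training is the deterministic batch
#' algorithm: all genes are assigned to their best-matching unit (BMU,
#' nearest codebook vector in Euclidean distance), then every codebook vector
#' is replaced by the neighborhood-weighted mean of the assigned genes, with
#' a Gaussian neighborhood whose radius decays linearly from
#' `max(grid) / 2` to 0.5 over the epochs. Initialization spans the first two
#' principal directions of the gene cloud; the seed is used only for the
#' degenerate fallback.
#'
#' Two winner rules are available for the assignment step during training:
#' `"nearest"` (the standard batch SOM; each gene joins its nearest codebook
#' vector) and `"heskes"` (each gene joins the node minimizing its
#' neighborhood-weighted distortion, which makes every epoch at fixed radius
#' a coordinate descent of the batch-SOM energy). The two coincide as the
#' radius shrinks; the final reported BMU of every gene is always its
#' nearest codebook vector.
#'
#' @param m Preprocessed (quantile normalized, centralized) genes x samples
#'   matrix.
#' @param grid `c(rows, cols)` of the map; `rows * cols` metagenes.
#' @param epochs Number of batch epochs.
#' @param radius Optional explicit radius schedule (length `epochs`);
#'   overrides the linear default.
#' @param winner Assignment rule during training, see Details.
#' @param seed Integer seed (degenerate-initialization fallback only).
#' @return Object of class `som_model` with elements `grid`, `codebook`
#'   (metagenes x samples), `bmu` (named gene -> node index), `energy`
#'   (per-epoch neighborhood-weighted distortion) and `training_meta`.
#' @export
som_train <- function(m, grid = c(20L, 20L), epochs = 30L, radius = NULL,
                      winner = c("nearest", "heskes"), seed = 1L) {
  winner <- match.arg(winner)
  check_expression(m)
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1)) stop("grid must be two positive integers")
  n_nodes <- prod(grid)
  if (is.null(colnames(m))) colnames(m) <- sprintf("sample%03d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene%05d", seq_len(nrow(m)))
  if (is.null(radius)) {
    radius <- if (epochs > 1) seq(max(grid) / 2, 0.5, length.out = epochs) else 0.5
  }
  if (length(radius) != epochs) stop("radius schedule must have length 'epochs'")

  coords <- node_coords(grid)
  gd2 <- as.matrix(stats::dist(coords))^2
  codebook <- som_init(m, grid, seed)
  x2 <- rowSums(m^2)
  energy <- numeric(epochs)
  for (e in seq_len(epochs)) {
    H <- exp(-gd2 / (2 * radius[e]^2))
    bmu <- if (winner == "heskes") {
      d2 <- dist2_to_codebook(m, codebook, x2)
      max.col(-(d2 %*% H), ties.method = "first")
    } else {
      assign_bmu(m, codebook, x2)
    }
    rs <- rowsum(m, bmu)
    S <- matrix(0, n_nodes, ncol(m))
    S[as.integer(rownames(rs)), ] <- rs
    cnt <- tabulate(bmu, n_nodes)
    num <- H %*% S
    den <- as.vector(H %*% cnt)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    energy[e] <- som_energy(m, codebook, bmu, H, x2)
  }
  bmu <- assign_bmu(m, codebook, x2)
  names(bmu) <- rownames(m)
  colnames(codebook) <- colnames(m)
  structure(list(grid = grid, codebook = codebook, bmu = bmu,
                 energy = energy,
                 training_meta = list(epochs = epochs, radius = radius,
                                      winner = winner,
                                      seed = as.integer(seed),
                                      n_genes = nrow(m))),
            class = "som_model")
}

#' Neighborhood-weighted SOM distortion
#'
#' `sum_g sum_k h(bmu(g), k) * ||x_g - w_k||^2`; the quantity the batch
#' update step minimizes at fixed assignment and radius.
#'
#' @param m Genes x samples matrix.
#' @param codebook Nodes x samples codebook.
#' @param bmu Gene BMU indices.
#' @param H Nodes x nodes neighborhood weight matrix.
#' @param x2 Optional precomputed `rowSums(m^2)`.
#' @return Scalar energy.
#' @export
som_energy <- function(m, codebook, bmu, H, x2 = rowSums(m^2)) {
  d2 <- dist2_to_codebook(m, codebook, x2)
  sum(H[bmu, , drop = FALSE] * d2)
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$grid[1], "x", x$grid[2], "grid (", prod(x$grid),
      "metagenes ),", length(x$bmu), "genes,", ncol(x$codebook), "samples\n")
  invisible(x)
}

#' Expression portrait of one sample
#'
#' The sample's column of the codebook, arranged on the grid (row-major).
#'
#' @param model A `som_model`.
#' @param sample_id Sample identifier (codebook column name).
#' @return Numeric vector of length `rows * cols` of class `som_portrait`
#'   with the grid stored as an attribute.
#' @export
sample_portrait <- function(model, sample_id) {
  stopifnot(inherits(model, "som_model"))
  if (!sample_id %in% colnames(model$codebook)) {
    stop("unknown sample id: ", sample_id, call. = FALSE)
  }
  as_portrait(model$codebook[, sample_id], model$grid)
}

as_portrait <- function(v, grid) {
  structure(as.numeric(v), grid = as.integer(grid), class = "som_portrait")
}

#' Mean portrait over a group of samples
#'
#' @param model A `som_model`.
#' @param sample_ids Non-empty character vector of sample identifiers.
#' @return Entrywise mean portrait.
#' @export
group_mean_portrait <- function(model, sample_ids) {
  stopifnot(inherits(model, "som_model"), length(sample_ids) > 0)
  missing <- setdiff(sample_ids, colnames(model$codebook))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  as_portrait(rowMeans(model$codebook[, sample_ids, drop = FALSE]), model$grid)
}

#' Difference of two portraits
#'
#' @param a,b Portraits on the same grid.
#' @return Entrywise `a - b`.
#' @export
difference_portrait <- function(a, b) {
  ga <- attr(a, "grid"); gb <- attr(b, "grid")
  if (length(a) != length(b) || (!is.null(ga) && !is.null(gb) && !all(ga == gb))) {
    stop("portraits must live on the same grid")
  }
  as_portrait(as.numeric(a) - as.numeric(b), if (is.null(ga)) gb else ga)
}

#' Arrange a portrait (or any per-metagene vector) as a grid matrix
#'
#' @param p Numeric vector of length `rows * cols` (row-major node order).
#' @param grid `c(rows, cols)`; taken from the portrait attribute if absent.
#' @return `rows x cols` matrix; `[i, j]` is grid row `i - 1`, column `j - 1`.
#' @export
portrait_matrix <- function(p, grid = attr(p, "grid")) {
  if (is.null(grid)) stop("grid not supplied and not attached to the portrait")
  matrix(as.numeric(p), nrow = grid[1], ncol = grid[2], byrow = TRUE)
}

#' Variance map of a trained SOM
#'
#' Per-metagene unbiased variance of the codebook profile across samples;
#' high-variance areas mark the spot clusters of co-expressed genes.
#'
#' @param model A `som_model`.
#' @return Numeric vector (length nodes, all `>= 0`) of class `som_portrait`.
#' @export
variance_map <- function(model) {
  stopifnot(inherits(model, "som_model"))
  as_portrait(apply(model$codebook, 1, stats::var), model$grid)
}
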