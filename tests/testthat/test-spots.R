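# toy map: 4 x 5 grid, codebook irrelevant for vmap-driven segmentation
flat_model <- function(n_genes = 40, grid = c(4, 5), seed = 1) {
  set.seed(seed)
  cb <- matrix(rnorm(prod(grid) * 3, sd = 0.01), prod(grid), 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  bmu <- stats::setNames(rep_len(seq_len(prod(grid)), n_genes),
                         sprintf("g%02d", seq_len(n_genes)))
  toy_model(cb, grid, bmu)
}

test_that("two disjoint variance plateaus become exactly two spots", {
  mod <- flat_model()
  vmap <- rep(0.01, 20)
  plateau1 <- c(1, 2, 6)        # pixels (0,0) (0,1) (1,0)
  plateau2 <- c(14, 15, 19, 20) # bottom-right block
  vmap[plateau1] <- 5
  vmap[plateau2] <- 3
  seg <- segment_spots(mod, vmap, percentile = 70, split_umap = FALSE,
                       min_genes = 0)
  expect_length(seg$spots, 2)
  expect_equal(seg$spots[[1]]$pixels, sort(plateau1))  # higher total variance
  expect_equal(seg$spots[[2]]$pixels, sort(plateau2))
  expect_equal(vapply(seg$spots, `[[`, "", "label"), c("A", "B"))
})

test_that("a single supra-threshold pixel forms a singleton spot", {
  mod <- flat_model()
  vmap <- rep(0.01, 20); vmap[7] <- 10
  seg <- segment_spots(mod, vmap, percentile = 99, split_umap = FALSE,
                       min_genes = 0)
  expect_length(seg$spots, 1)
  expect_equal(seg$spots[[1]]$pixels, 7)
})

test_that("percentile bounds and empty segmentations are rejected", {
  mod <- flat_model()
  expect_error(segment_spots(mod, percentile = 0), "percentile")
  expect_error(segment_spots(mod, percentile = 100), "percentile")
  seg <- segment_spots(mod, rep(1, 20), percentile = 50, split_umap = FALSE,
                       min_genes = 0)
  expect_error(sample_spot_activation(rep(0, 20),
                                      structure(list(spots = list(),
                                                     grid = c(4L, 5L)),
                                                class = "spot_segmentation")),
               "empty")
})

test_that("spots are disjoint, connected, and own their genes' BMUs", {
  sim <- small_sim(seed = 2)
  expr <- preprocess_expression(sim$expr)
  mod <- som_train(expr, grid = c(8, 8), epochs = 15, seed = 2)
  seg <- segment_spots(mod)
  all_px <- unlist(lapply(seg$spots, `[[`, "pixels"))
  expect_equal(anyDuplicated(all_px), 0L)
  coords <- node_coords(mod$grid)
  for (s in seg$spots) {
    # connectivity under the 8-neighborhood: breadth-first search in-test
    px <- s$pixels
    if (length(px) > 1) {
      reached <- px[1]
      repeat {
        nb <- px[vapply(px, function(i) {
          any(abs(coords[reached, "row"] - coords[i, "row"]) <= 1 &
                abs(coords[reached, "col"] - coords[i, "col"]) <= 1)
        }, logical(1))]
        newly <- setdiff(nb, reached)
        if (length(newly) == 0) break
        reached <- c(reached, newly)
      }
      expect_setequal(reached, px)
    }
    expect_true(all(mod$bmu[s$genes] %in% s$pixels))
  }
  genes <- unlist(lapply(seg$spots, `[[`, "genes"))
  expect_equal(anyDuplicated(genes), 0L)
  expect_lte(length(genes), nrow(expr))
})

test_that("raising the variance percentile never adds supra pixels", {
  sim <- small_sim(seed = 3)
  mod <- som_train(preprocess_expression(sim$expr), grid = c(8, 8),
                   epochs = 15, seed = 3)
  vmap <- variance_map(mod)
  px_of <- function(p) {
    unlist(lapply(segment_spots(mod, vmap, percentile = p,
                                min_genes = 0)$spots, `[[`, "pixels"))
  }
  expect_true(all(px_of(95) %in% px_of(90)))
  expect_true(all(px_of(90) %in% px_of(80)))
})

test_that("spot activation follows the exclusion-quantile rule", {
  mod <- flat_model()
  vmap <- rep(0.01, 20)
  vmap[c(1, 2)] <- 5; vmap[9] <- 4; vmap[c(19, 20)] <- 3
  seg <- segment_spots(mod, vmap, percentile = 75, split_umap = FALSE,
                       min_genes = 0)
  expect_length(seg$spots, 3)
  # uniform portrait: nothing strictly exceeds its own quantile
  expect_length(sample_spot_activation(rep(1, 20), seg), 0)
  # positive only on the first spot's pixels
  p <- rep(0, 20); p[seg$spots[[1]]$pixels] <- 2
  expect_equal(sample_spot_activation(p, seg, q = 0.9),
               seg$spots[[1]]$label)
  # hand-set means: two spots above the outside quantile, one negative
  p2 <- rep(0, 20)
  p2[seg$spots[[1]]$pixels] <- 3
  p2[seg$spots[[2]]$pixels] <- 2
  p2[seg$spots[[3]]$pixels] <- -1
  got <- sample_spot_activation(p2, seg, q = 0.9)
  expect_setequal(got, c(seg$spots[[1]]$label, seg$spots[[2]]$label))
  # direct-computation cross-check of the rule
  for (i in 1:3) {
    s <- seg$spots[[i]]
    mu <- mean(p2[s$pixels])
    thr <- stats::quantile(p2[-s$pixels], 0.9)
    expect_equal(s$label %in% got, mu > thr && mu > 0)
  }
})

test_that("spot expression profiles are member-gene column means", {
  mod <- flat_model(n_genes = 6, grid = c(2, 3))
  mod$bmu <- stats::setNames(c(1L, 1L, 2L, 4L, 5L, 6L), paste0("g", 1:6))
  vmap <- c(5, 0.1, 0.1, 0.1, 0.1, 0.1)
  seg <- segment_spots(mod, vmap, percentile = 90, split_umap = FALSE,
                       min_genes = 0)
  m <- rbind(g1 = c(1, 3), g2 = c(3, 5), g3 = c(100, 100))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(spot_expression_profile(seg, "A", m)), c(2, 4))
  # only the member genes present in the matrix contribute
  expect_equal(unname(spot_expression_profile(seg, "A", m[c("g1", "g3"), ])),
               c(1, 3))
  # single-gene spot reproduces the gene profile
  expect_equal(unname(spot_expression_profile(seg, "A", m[1, , drop = FALSE])),
               c(1, 3))
})

test_that("spot frequency histograms conserve the sample count", {
  sim <- small_sim(seed = 4)
  mod <- som_train(preprocess_expression(sim$expr), grid = c(8, 8),
                   epochs = 15, seed = 4)
  seg <- segment_spots(mod)
  groups <- stats::setNames(sim$samples$group, sim$samples$sample_id)
  freq <- spot_frequency_distribution(mod, seg, groups)
  expect_equal(nrow(freq$counts), ncol(sim$expr))
  expect_equal(sum(freq$histogram), ncol(sim$expr))
  # all-uniform portraits activate nothing
  cb0 <- matrix(1, 16, 4, dimnames = list(NULL, paste0("s", 1:4)))
  mod0 <- toy_model(cb0, c(4, 4))
  seg0 <- segment_spots(mod0, c(rep(1, 8), rep(0, 8)), percentile = 50,
                        split_umap = FALSE, min_genes = 0)
  freq0 <- spot_frequency_distribution(mod0, seg0)
  expect_true(all(freq0$counts$n_active == 0))
})
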