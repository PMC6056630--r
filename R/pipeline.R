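#' Pipeline configuration
#'
#' Bundles the file paths and parameters of one portrayal run. All referenced
#' input paths must resolve when [run_pipeline()] starts; parameter ranges
#' are validated here.
#'
#' @param expression Path to the expression TSV (genes x samples).
#' @param out_dir Output directory (created if absent).
#' @param annotation Optional path to a sample annotation TSV (`sample_id`
#'   column; `group` enables group portraits and spot frequency histograms;
#'   `survived_28d` enables the prognostic map).
#' @param gene_sets Optional path to a GMT file for enrichment and GSZ
#'   scoring.
#' @param grid SOM grid `c(rows, cols)`.
#' @param epochs SOM training epochs.
#' @param seed Integer seed for every stochastic stage.
#' @param spot_percentile Variance percentile for [segment_spots()].
#' @param activation_q Overexpression-spot activation quantile.
#' @param K Number of classes for [discover_classes()].
#' @param bootstrap_B Bootstrap replicates for class stability (0 disables).
#' @param sd_factor Over-expression threshold of the prognostic map.
#' @param severity_spot Spot label for the severity score; `NULL`
#'   auto-designates it from the case/control contrast when the annotation
#'   has a `group` column with a `"control"` level.
#' @param score_sets Names of gene sets (in the GMT) to carry as named GSZ
#'   score columns; `NULL` scores every set.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, out_dir, annotation = NULL,
                            gene_sets = NULL, grid = c(20L, 20L),
                            epochs = 30L, seed = 1L, spot_percentile = 90,
                            activation_q = 0.98, K = 6L, bootstrap_B = 0L,
                            sd_factor = 1, severity_spot = NULL,
                            score_sets = NULL) {
  cfg <- list(expression = expression, out_dir = out_dir,
              annotation = annotation, gene_sets = gene_sets,
              grid = as.integer(grid), epochs = as.integer(epochs),
              seed = as.integer(seed), spot_percentile = spot_percentile,
              activation_q = activation_q, K = as.integer(K),
              bootstrap_B = as.integer(bootstrap_B), sd_factor = sd_factor,
              severity_spot = severity_spot, score_sets = score_sets)
  if (length(cfg$grid) != 2 || any(cfg$grid < 1)) stop("grid must be two positive integers")
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  if (cfg$spot_percentile <= 0 || cfg$spot_percentile >= 100) {
    stop("spot_percentile must be inside (0, 100)")
  }
  if (cfg$activation_q <= 0 || cfg$activation_q >= 1) stop("activation_q must be inside (0, 1)")
  if (cfg$K < 2) stop("K must be >= 2")
  class(cfg) <- "pipeline_config"
  cfg
}

write_table_with_header <- function(df, path, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based, row-major", extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full portrayal pipeline
#'
#' Executes preprocess -> SOM training -> portraits -> variance map -> spot
#' segmentation -> enrichment/GSZ/named scores -> class discovery ->
#' prognostic map, writing every tabular artifact (TSV), the rendered maps
#' (PNG) and a run manifest into `config$out_dir`. Any stage failure aborts
#' with the stage name and cause and leaves a `FAILED` marker next to the
#' partial outputs. Identical configuration and seed reproduce byte-identical
#' tabular outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`model`, `seg`,
#'   `classes`, `scores`, `prognostic`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # resolve every input path before any compute
  for (p in c(config$expression, config$annotation, config$gene_sets)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name, " -- ",
                                     conditionMessage(e))), failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    line <- sprintf("stage %-12s ok  %.2fs", name, dt)
    log_lines <<- c(log_lines, line)
    message(line)
    res
  }

  expr0 <- stage("read", read_expression_tsv(config$expression))
  ann <- if (!is.null(config$annotation)) read_annotation_tsv(config$annotation) else NULL
  sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL

  expr <- stage("preprocess", preprocess_expression(expr0))
  model <- stage("train", som_train(expr, grid = config$grid,
                                    epochs = config$epochs, seed = config$seed))
  vmap <- variance_map(model)
  seg <- stage("spots", segment_spots(model, vmap,
                                      percentile = config$spot_percentile))

  groups <- NULL
  if (!is.null(ann) && "group" %in% colnames(ann)) {
    groups <- stats::setNames(as.character(ann$group), ann$sample_id)
  }

  # spot table, activation counts
  stage("spot_tables", {
    spot_df <- do.call(rbind, lapply(seg$spots, function(s) {
      data.frame(label = s$label, n_pixels = length(s$pixels),
                 n_genes = length(s$genes),
                 total_variance = s$total_variance,
                 genes = paste(s$genes, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write_table_with_header(spot_df, file.path(config$out_dir, "spots.tsv"))
    freq <- spot_frequency_distribution(model, seg, groups, q = config$activation_q)
    write_table_with_header(freq$counts,
                            file.path(config$out_dir, "spot_counts.tsv"))
  })

  # scores and enrichment
  sev_label <- config$severity_spot
  if (is.null(sev_label) && !is.null(groups) && any(groups == "control")) {
    sev_label <- designate_severity_spot(seg, expr,
                                         groups[colnames(expr)] != "control")
  }
  scores <- NULL
  stage("score", {
    score_sets <- sets
    if (!is.null(sets) && !is.null(config$score_sets)) {
      score_sets <- sets[intersect(config$score_sets, names(sets))]
    }
    if (!is.null(sev_label)) {
      scores <- named_scores(expr, seg, sev_label,
                              if (is.null(score_sets)) list() else score_sets)
    } else if (!is.null(score_sets)) {
      gm <- gsz_matrix(score_sets, expr)
      scores <- data.frame(sample_id = rownames(gm), gm,
                            check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (!is.null(scores)) {
      write_table_with_header(scores, file.path(config$out_dir, "scores.tsv"))
    }
    if (!is.null(sets)) {
      enr <- spot_enrichment_table(seg, sets, universe = rownames(expr))
      write_table_with_header(enr, file.path(config$out_dir, "enrichment.tsv"))
    }
  })

  # class discovery + network
  classes <- stage("classify", discover_classes(model, K = config$K,
                                                seed = config$seed))
  stability <- NULL
  if (config$bootstrap_B >= 2) {
    stability <- stage("stability",
                       bootstrap_stability(model, K = config$K,
                                           B = config$bootstrap_B,
                                           seed = config$seed))
  }
  stage("class_tables", {
    cls_df <- data.frame(sample_id = names(classes$labels),
                         class = unname(classes$labels),
                         S = unname(classes$S), stringsAsFactors = FALSE)
    write_table_with_header(cls_df, file.path(config$out_dir, "classes.tsv"))
    net <- correlation_network(classes$r, rule = "knn", param = 3)
    write_table_with_header(net, file.path(config$out_dir, "network.tsv"))
  })

  # prognostic map
  prog <- NULL
  if (!is.null(ann) && "survived_28d" %in% colnames(ann) &&
      any(!is.na(ann$survived_28d))) {
    prog <- stage("prognosis", prognostic_map(model, ann,
                                              sd_factor = config$sd_factor))
    write_table_with_header(prognostic_map_table(prog),
                            file.path(config$out_dir, "prognostic_map.tsv"))
  }

  stage("render", {
    render_portrait_png(vmap, file.path(config$out_dir, "variance_map.png"),
                        diverging = FALSE)
    render_segmentation_png(seg, file.path(config$out_dir, "segmentation.png"))
    if (!is.null(groups)) {
      for (g in unique(groups[colnames(expr)])) {
        ids <- colnames(expr)[groups[colnames(expr)] == g]
        render_portrait_png(group_mean_portrait(model, ids),
                            file.path(config$out_dir,
                                      paste0("portrait_group_", g, ".png")),
                            main = g)
      }
    }
    if (!is.null(prog)) {
      render_prognostic_png(prog, file.path(config$out_dir, "prognostic_map.png"))
    }
  })

  manifest <- c(
    paste0("package: somportraits ",
           as.character(utils::packageVersion("somportraits"))),
    paste0("r_version: ", R.version.string),
    paste0("expression: ", config$expression),
    paste0("annotation: ", if (is.null(config$annotation)) "-" else config$annotation),
    paste0("gene_sets: ", if (is.null(config$gene_sets)) "-" else config$gene_sets),
    paste0("grid: ", paste(config$grid, collapse = "x")),
    paste0("epochs: ", config$epochs),
    paste0("seed: ", config$seed),
    paste0("spot_percentile: ", config$spot_percentile),
    paste0("activation_q: ", config$activation_q),
    paste0("K: ", config$K),
    paste0("bootstrap_B: ", config$bootstrap_B),
    paste0("sd_factor: ", config$sd_factor),
    paste0("severity_spot: ", if (is.null(sev_label)) "-" else sev_label),
    "log:",
    paste0("  ", log_lines))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  invisible(list(model = model, seg = seg, classes = classes,
                 scores = scores, prognostic = prog, stability = stability,
                 severity_spot = sev_label, manifest = manifest))
}
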