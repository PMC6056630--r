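#' Run the synthetic recovery benchmark for one seed
#'
#' Generates a synthetic cohort (the study-scale desk benchmark: 2,000 genes,
#' 10 controls + 170 CAP samples, 12 planted modules of 16 genes, 20 x 20
#' SOM), runs the full portrayal analysis and measures how well the planted
#' structure is recovered:
#' \itemize{
#'   \item `severity_spearman`: Spearman correlation between the severity
#'     score (mean expression of the recovered severity-up spot) and the
#'     latent severity `u` over CAP samples;
#'   \item `module_purity`: median over planted modules of the largest
#'     fraction of a module's genes collected by a single recovered spot;
#'   \item `class_ari`: adjusted Rand index of [discover_classes()] (K = 6,
#'     CAP samples) against the planted six classes;
#'   \item `worst_class` / `class_survival`: per-planted-class 28-day
#'     survivor percentages and the identity of the minimum;
#'   \item `severity_spot_prognosis` vs `prognostic_median`: mean unmasked
#'     survivor percentage over the recovered severity-spot pixels against
#'     the map-wide median;
#'   \item `active_spots_control` / `active_spots_hs`: mean overexpression
#'     spot counts of control and high-severity samples;
#'   \item `bd_mid_minus_outer`: mean erythrocyte/platelet (BD) GSZ score in
#'     the middle severity tertile minus the mean over the outer tertiles
#'     (positive = mid-severity peak).
#' }
#'
#' @param seed Integer seed for the generator, SOM and clustering.
#' @param n_genes,module_size,grid Benchmark problem size.
#' @param ... Further arguments passed to [sim_config()].
#' @return Named list of metrics plus the per-class survival table.
#' @export
run_recovery_benchmark <- function(seed = 1L, n_genes = 2000L,
                                   module_size = 16L, grid = c(20L, 20L),
                                   ...) {
  cfg <- sim_config(n_genes = n_genes, module_size = module_size,
                    seed = seed, ...)
  sim <- simulate_cap_cohort(cfg)
  expr <- preprocess_expression(sim$expr)
  model <- som_train(expr, grid = grid, seed = seed)
  seg <- segment_spots(model)

  modules <- sim$truth$modules
  labels <- vapply(seg$spots, `[[`, "", "label")
  overlap <- vapply(seg$spots, function(s) {
    vapply(modules, function(g) length(intersect(g, s$genes)), numeric(1))
  }, numeric(length(modules)))             # modules x spots
  if (is.null(dim(overlap))) overlap <- matrix(overlap, nrow = length(modules))
  purity <- apply(overlap, 1, max) / lengths(modules)
  names(purity) <- names(modules)

  sev_label <- labels[which.max(overlap["severity_up", ])]
  cap <- sim$samples$group == "CAP"
  sev_score <- spot_expression_profile(seg, sev_label, expr)
  severity_spearman <- stats::cor(sev_score[cap], sim$truth$u[cap],
                                  method = "spearman")

  # blood-disturbance GSZ score (signature = half of the planted BD module)
  sets <- simulate_gene_sets(sim)
  bd_score <- gsz_profile(sets$sig_bd, expr)
  tert <- cut(rank(sev_score[cap], ties.method = "first"), 3, labels = FALSE)
  bd_cap <- bd_score[cap]
  bd_mid_minus_outer <- mean(bd_cap[tert == 2]) - mean(bd_cap[tert != 2])

  # class recovery on CAP samples
  cls <- discover_classes(model, K = 6L, seed = seed,
                          samples = colnames(expr)[cap])
  class_ari <- mclust::adjustedRandIndex(cls$labels, sim$truth$class[cap])

  # planted-class survival
  surv_tab <- class_survival_rates(
    stats::setNames(sim$truth$class, sim$samples$sample_id), sim$samples)
  worst_class <- surv_tab$class[which.min(surv_tab$pct_survived)]

  # prognostic map vs recovered severity spot
  pm <- prognostic_map(model, sim$samples)
  sev_px <- spot_by_label(seg, sev_label)$pixels
  sev_pct <- as.numeric(pm$pct)[sev_px]
  severity_spot_prognosis <- mean(sev_pct, na.rm = TRUE)
  prognostic_median <- stats::median(as.numeric(pm$pct), na.rm = TRUE)

  # active-spot counts by group; "HS" is the high-severity stratum (top
  # severity latent), irrespective of IFN/BD status
  groups <- ifelse(cap, ifelse(sim$truth$u > 0.625, "HS", "CAP_other"),
                   "control")
  freq <- spot_frequency_distribution(
    model, seg, stats::setNames(groups, sim$samples$sample_id))
  cnt <- freq$counts
  active_spots_control <- mean(cnt$n_active[cnt$group == "control"])
  active_spots_hs <- mean(cnt$n_active[cnt$group == "HS"])

  list(seed = seed,
       n_spots = length(seg$spots),
       severity_spot = sev_label,
       severity_spearman = severity_spearman,
       module_purity = stats::median(purity),
       min_module_purity = min(purity),
       purity_by_module = purity,
       class_ari = class_ari,
       class_survival = surv_tab,
       worst_class = worst_class,
       severity_spot_prognosis = severity_spot_prognosis,
       prognostic_median = prognostic_median,
       active_spots_control = active_spots_control,
       active_spots_hs = active_spots_hs,
       bd_mid_minus_outer = bd_mid_minus_outer)
}
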