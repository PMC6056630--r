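#' Configuration for the synthetic CAP blood-transcriptome cohort
#'
#' The generator plants the latent structure the portrayal pipeline assumes:
#' a control group plus CAP samples spread along a dominant severity axis
#' `u`, two partially independent axes `v` (interferon response) and `w`
#' (erythrocyte/platelet "blood disturbance" mRNA, peaking at mid severity),
#' a dozen co-expression modules, two cohorts with asymmetric IFN prevalence,
#' longitudinal sampling at days 1/3/5 with severity decay, and a 28-day
#' survival outcome coupled to `u` and `u*v`.
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted co-expression modules (>= 5:
#'   severity-up, severity-down, mid-severity, IFN, blood disturbance,
#'   remainder decoys driven by independent per-sample factors).
#' @param module_size Genes per module; `n_modules * module_size <= n_genes`.
#' @param n_controls,n_cap Control and CAP sample counts.
#' @param ifn_prevalence Named probabilities (cohorts "A" and "B") that a
#'   patient mounts a strong interferon response; A > B plants the cohort
#'   asymmetry.
#' @param beta_sev,beta_sev_down,beta_mid,beta_ifn,beta_bd,beta_decoy
#'   Loadings of module genes on their latent axes, in log-expression units
#'   per unit latent. The severity-down (adaptive immune) module may be
#'   given its own loading; `beta_mid` drives the medium-severity module.
#' @param noise_sd Residual gene-level noise SD (> 0).
#' @param survival_intercept,survival_slope,survival_interaction Logistic
#'   death model: `P(death) = plogis(intercept + slope*u + interaction*u*v)`.
#' @param u_distribution Day-1 severity distribution of CAP patients:
#'   `"trimodal"` (default) draws from an equal-weight mixture of
#'   Beta(16, 48), Beta(60, 60) and Beta(48, 16) — three strata of low, middle
#'   and high severity whose density gaps hold the class cut points
#'   (0.375 and 0.625);
#'   `"beta"` draws the unstructured Beta(2, 2) continuum.
#' @param bd_prevalence Probability that a patient carries a strong
#'   erythrocyte/platelet disturbance amplitude (the BD axis is bimodal:
#'   disturbed vs. quiescent).
#' @param longitudinal_fraction Fraction of CAP samples that belong to
#'   day-1/3/5 series of the same patient.
#' @param day_decay Per-day multiplicative decay of `u`:
#'   `u(day d) = u(day 1) * day_decay^(d - 1)`.
#' @param baseline_mean,baseline_sd Gene baseline `mu_g ~ N(mean, sd)`,
#'   mimicking log-intensity arrays.
#' @param seed Integer seed; identical configurations give bitwise-identical
#'   output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L, n_modules = 12L, module_size = 150L,
                       n_controls = 10L, n_cap = 170L,
                       ifn_prevalence = c(A = 0.45, B = 0.15),
                       beta_sev = 6, beta_sev_down = 6, beta_mid = 3, beta_ifn = 5, beta_bd = 6,
                       beta_decoy = 0.5,
                       noise_sd = 0.5,
                       survival_intercept = -2.2, survival_slope = 2.0,
                       survival_interaction = 1.5,
                       u_distribution = c("trimodal", "beta"),
                       bd_prevalence = 1 / 3,
                       longitudinal_fraction = 0.25, day_decay = 0.8,
                       baseline_mean = 8, baseline_sd = 1,
                       seed = 1L) {
  u_distribution <- match.arg(u_distribution)
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_controls = as.integer(n_controls), n_cap = as.integer(n_cap),
              ifn_prevalence = ifn_prevalence,
              beta_sev = beta_sev, beta_sev_down = beta_sev_down,
              beta_mid = beta_mid,
              beta_ifn = beta_ifn, beta_bd = beta_bd,
              beta_decoy = beta_decoy, noise_sd = noise_sd,
              survival_intercept = survival_intercept,
              survival_slope = survival_slope,
              survival_interaction = survival_interaction,
              u_distribution = u_distribution,
              bd_prevalence = bd_prevalence,
              longitudinal_fraction = longitudinal_fraction,
              day_decay = day_decay,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_modules, cfg$module_size, cfg$n_controls, cfg$n_cap)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_modules < 5) {
    stop("need >= 5 modules (severity up/down/mid, IFN, BD)", call. = FALSE)
  }
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    stop("module_size * n_modules exceeds n_genes", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (length(cfg$ifn_prevalence) != 2 ||
      !all(c("A", "B") %in% names(cfg$ifn_prevalence)) ||
      any(cfg$ifn_prevalence < 0 | cfg$ifn_prevalence > 1)) {
    stop("ifn_prevalence must be named probabilities for cohorts A and B", call. = FALSE)
  }
  if (cfg$bd_prevalence < 0 || cfg$bd_prevalence > 1) {
    stop("bd_prevalence must be in [0, 1]", call. = FALSE)
  }
  if (cfg$longitudinal_fraction < 0 || cfg$longitudinal_fraction > 1) {
    stop("longitudinal_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$day_decay <= 0 || cfg$day_decay > 1) stop("day_decay must be in (0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_modules, "modules x",
      x$module_size, "genes;", x$n_controls, "controls +", x$n_cap,
      "CAP samples; seed", x$seed, "\n")
  invisible(x)
}

# lognormal truncated to [0, upper] by rejection, then scaled to [0, 1]
rtrunc_lnorm01 <- function(n, meanlog, sdlog, upper = 3) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out / upper
}

#' Death probability of the planted survival model
#'
#' @param u,v Severity and interferon latents.
#' @param config A [sim_config()].
#' @return `plogis(intercept + slope*u + interaction*u*v)`.
#' @export
death_probability <- function(u, v, config) {
  stats::plogis(config$survival_intercept + config$survival_slope * u +
                  config$survival_interaction * u * v)
}

#' Simulate 28-day outcomes from the planted logistic model
#'
#' @param u,v Latent vectors (equal length).
#' @param config A [sim_config()].
#' @return Logical vector, `TRUE` = survived 28 days.
#' @export
simulate_survival <- function(u, v, config) {
  stopifnot(length(u) == length(v))
  p <- death_probability(u, v, config)
  stats::rbinom(length(u), 1L, p) == 0L
}

# mid-severity bump: the envelope shared by the mid-severity and
# blood-disturbance modules (maximal at u = 0.5, negligible in the low- and
# high-severity strata and in controls)
mid_severity_envelope <- function(u) exp(-((u - 0.5) / 0.15)^2)

planted_class <- function(u, v, w, thresholds) {
  lab <- character(length(u))
  ifn <- v > thresholds$v_threshold
  bd <- !ifn & w > thresholds$w_threshold
  hi <- u > thresholds$u_tertiles[2]
  mid <- !hi & u > thresholds$u_tertiles[1]
  lab[ifn & hi] <- "IFN-HS"
  lab[ifn & !hi] <- "IFN-LS"
  lab[bd] <- "BD"
  rest <- !ifn & !bd
  lab[rest & hi] <- "HS"
  lab[rest & mid] <- "MS"
  lab[rest & !hi & !mid] <- "LS"
  lab
}

#' Generate a synthetic CAP cohort with ground truth
#'
#' Expression model: `e_gj = mu_g + L_g * latent_j + eps`,
#' `eps ~ N(0, noise_sd)`, `mu_g ~ N(baseline_mean, baseline_sd)`. Module 1
#' loads `+beta_sev * u`, module 2 `-beta_sev_down * u`, module 3 loads
#' `beta_mid` times a mid-severity bump of `u` (the medium-severity module),
#' module 4 `+beta_ifn * v`, module 5 `+beta_bd * w`; remaining modules load
#' on independent standard normal per-sample factors (decoys). Per-gene loadings are jittered by
#' Uniform(0.8, 1.2). Controls have `u = v = w = 0`. CAP severity `u` at
#' day 1 follows the configured `u_distribution` (trimodal Beta mixture by
#' default), decaying over longitudinal days; `v` is a truncated-lognormal
#' draw whose scale depends on a cohort-prevalence Bernoulli "IFN-active"
#' state; `w` is a truncated-lognormal base amplitude (bimodal: disturbed
#' with probability `bd_prevalence`) times `4 u (1 - u)`, planting the
#' mid-severity blood-disturbance peak.
#'
#' @param config A [sim_config()].
#' @return Object of class `cap_sim`: list with `expr` (genes x samples
#'   matrix), `samples` (annotation data.frame: sample_id, group, cohort,
#'   patient, day, survived_28d), and `truth` (per-sample latents and planted
#'   class, module membership, class thresholds, config).
#' @export
simulate_cap_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  # --- patients and longitudinal design -------------------------------------
  n_series <- floor(cfg$longitudinal_fraction * cfg$n_cap / 3)
  n_single <- cfg$n_cap - 3L * n_series
  n_pat <- n_series + n_single
  pat_id <- sprintf("P%03d", seq_len(n_pat))
  pat_days <- c(rep(list(c(1L, 3L, 5L)), n_series), rep(list(1L), n_single))

  cohort_pat <- sample(c("A", "B"), n_pat, replace = TRUE)
  ifn_active <- stats::rbinom(n_pat, 1L, cfg$ifn_prevalence[cohort_pat]) == 1L
  u_pat <- if (cfg$u_distribution == "trimodal") {
    # non-IFN patients fall into three severity strata; IFN-active patients
    # span a broad low-to-middle severity continuum (70%) or the high
    # stratum (30%), matching an "IFN low-to-middle / IFN high" split
    stratum <- sample.int(3L, n_pat, replace = TRUE)
    ifn_low <- stats::runif(n_pat) < 0.7
    shapes1 <- ifelse(ifn_active, ifelse(ifn_low, 10, 48), c(16, 60, 48)[stratum])
    shapes2 <- ifelse(ifn_active, ifelse(ifn_low, 14, 16), c(48, 60, 16)[stratum])
    stats::rbeta(n_pat, shapes1, shapes2)
  } else {
    stats::rbeta(n_pat, 2, 2)
  }
  v_pat <- ifelse(ifn_active,
                  rtrunc_lnorm01(n_pat, log(1.8), 0.25),
                  rtrunc_lnorm01(n_pat, log(0.25), 0.5))
  bd_active <- stats::rbinom(n_pat, 1L, cfg$bd_prevalence) == 1L
  bd_base_pat <- ifelse(bd_active,
                        rtrunc_lnorm01(n_pat, log(2.2), 0.3),
                        rtrunc_lnorm01(n_pat, log(0.25), 0.5))
  survived_pat <- simulate_survival(u_pat, v_pat, cfg)

  pat_idx <- rep(seq_len(n_pat), times = lengths(pat_days))
  day <- unlist(pat_days)
  u <- u_pat[pat_idx] * cfg$day_decay^(day - 1L)
  v <- v_pat[pat_idx] * cfg$day_decay^(day - 1L)
  w <- bd_base_pat[pat_idx] * mid_severity_envelope(u)

  # controls: all latents zero, no outcome
  n_ctl <- cfg$n_controls
  u <- c(rep(0, n_ctl), u)
  v <- c(rep(0, n_ctl), v)
  w <- c(rep(0, n_ctl), w)
  day <- c(rep(NA_integer_, n_ctl), day)
  patient <- c(sprintf("C%03d", seq_len(n_ctl)), pat_id[pat_idx])
  cohort <- c(rep(NA_character_, n_ctl), cohort_pat[pat_idx])
  group <- c(rep("control", n_ctl), rep("CAP", cfg$n_cap))
  survived <- c(rep(NA, n_ctl), survived_pat[pat_idx])
  n_samples <- n_ctl + cfg$n_cap
  sample_id <- sprintf("S%03d", seq_len(n_samples))

  # --- planted classes ------------------------------------------------------
  # class thresholds: under the trimodal severity default the u cut points
  # sit at the antimodes between the three strata; under the Beta(2, 2)
  # continuum they are the severity tertiles. v and w are bimodal on/off
  # axes, so their thresholds sit in the density gap between the quiescent
  # and active modes.
  cap <- group == "CAP"
  u_cuts <- if (cfg$u_distribution == "trimodal") c(0.375, 0.625) else
    unname(stats::quantile(u[cap], c(1, 2) / 3))
  thresholds <- list(u_tertiles = u_cuts,
                     v_threshold = 0.30,
                     w_threshold = 0.35)
  class_label <- rep("CTRL", n_samples)
  class_label[cap] <- planted_class(u[cap], v[cap], w[cap], thresholds)

  # --- expression -----------------------------------------------------------
  gene_id <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_acc_names <- min(2L, cfg$n_modules - 5L)
  module_names <- c("severity_up", "severity_down", "severity_mid", "ifn", "bd",
                    if (n_acc_names > 0) sprintf("sev_acc%02d", seq_len(n_acc_names)),
                    if (cfg$n_modules > 5L + n_acc_names)
                      sprintf("decoy%02d", seq_len(cfg$n_modules - 5L - n_acc_names)))
  modules <- split(gene_id[seq_len(cfg$n_modules * cfg$module_size)],
                   rep(seq_len(cfg$n_modules), each = cfg$module_size))
  names(modules) <- module_names

  # accessory modules co-activate with severity but carry independent
  # variation (innate/myeloid programs gained in severe disease); decoy
  # factors are fully independent across samples
  n_acc <- min(2L, cfg$n_modules - 5L)
  n_decoy <- cfg$n_modules - 5L - n_acc
  acc_latents <- if (n_acc > 0) {
    matrix(stats::rnorm(n_acc * n_samples, sd = 0.3), n_acc, n_samples) +
      rep(u, each = n_acc)
  } else NULL
  decoy_latents <- if (n_decoy > 0) {
    matrix(stats::rnorm(n_decoy * n_samples), n_decoy, n_samples)
  } else NULL
  latents <- rbind(u, -u, mid_severity_envelope(u), v, w, acc_latents,
                   decoy_latents)
  betas <- c(cfg$beta_sev, cfg$beta_sev_down, cfg$beta_mid, cfg$beta_ifn,
             cfg$beta_bd, rep(1.5, n_acc), rep(cfg$beta_decoy, n_decoy))

  mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  expr <- matrix(stats::rnorm(cfg$n_genes * n_samples, sd = cfg$noise_sd),
                 cfg$n_genes, n_samples) + mu
  for (k in seq_len(cfg$n_modules)) {
    rows <- (k - 1L) * cfg$module_size + seq_len(cfg$module_size)
    loading <- betas[k] * stats::runif(cfg$module_size, 0.8, 1.2)
    expr[rows, ] <- expr[rows, ] + outer(loading, latents[k, ])
  }
  dimnames(expr) <- list(gene_id, sample_id)

  samples <- data.frame(sample_id = sample_id, group = group, cohort = cohort,
                        patient = patient, day = day, survived_28d = survived,
                        stringsAsFactors = FALSE)
  truth <- list(sample_id = sample_id, u = u, v = v, w = w,
                class = class_label, thresholds = thresholds,
                modules = modules, survived_28d = survived,
                cohort = cohort, day = day, config = cfg)
  structure(list(expr = expr, samples = samples, truth = truth),
            class = "cap_sim")
}

#' @export
print.cap_sim <- function(x, ...) {
  cat("cap_sim:", nrow(x$expr), "genes x", ncol(x$expr), "samples (",
      sum(x$samples$group == "control"), "controls ),",
      length(x$truth$modules), "planted modules, classes:",
      paste(names(table(x$truth$class)), collapse = "/"), "\n")
  invisible(x)
}

#' Generate signature and decoy gene sets from a simulated cohort
#'
#' For each planted module one signature set is drawn as a random 50% subset
#' of its genes; in addition, decoy sets of matched sizes are drawn uniformly
#' from the gene universe.
#'
#' @param sim A `cap_sim` object.
#' @param fraction Fraction of module genes per signature set.
#' @param decoy_universe `"all"` draws decoy members uniformly from all genes
#'   (so the expected overlap of a decoy with a planted module is
#'   `size^2 / n_genes`); `"non_module"` restricts to genes outside every
#'   planted module.
#' @param seed Seed (defaults to the simulation seed); identical seeds give
#'   byte-identical [write_gmt()] output.
#' @return Named list of gene sets (`sig_<module>` and `decoy_<k>`).
#' @export
simulate_gene_sets <- function(sim, fraction = 0.5,
                               decoy_universe = c("all", "non_module"),
                               seed = NULL) {
  stopifnot(inherits(sim, "cap_sim"))
  decoy_universe <- match.arg(decoy_universe)
  if (is.null(seed)) seed <- sim$truth$config$seed
  set.seed(seed)
  modules <- sim$truth$modules
  if (any(lengths(modules) < 2)) stop("all modules need >= 2 genes")
  sigs <- lapply(modules, function(g) sort(sample(g, ceiling(fraction * length(g)))))
  names(sigs) <- paste0("sig_", names(modules))
  universe <- rownames(sim$expr)
  if (decoy_universe == "non_module") {
    universe <- setdiff(universe, unlist(modules))
  }
  decoys <- lapply(sigs, function(s) sort(sample(universe, length(s))))
  names(decoys) <- sprintf("decoy_%02d", seq_along(decoys))
  c(sigs, decoys)
}
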