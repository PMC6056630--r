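test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 100, n_modules = 12, module_size = 20),
               "exceeds")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_modules = 3), "modules")
  expect_error(sim_config(ifn_prevalence = c(X = 0.5, Y = 0.1)), "cohorts")
  expect_error(sim_config(day_decay = 0), "day_decay")
})

test_that("identical configurations reproduce bitwise-identical cohorts", {
  cfg <- sim_config(n_genes = 400, n_modules = 6, module_size = 10,
                    n_controls = 4, n_cap = 40, seed = 7)
  a <- simulate_cap_cohort(cfg)
  b <- simulate_cap_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless severity-module genes are perfectly correlated", {
  cfg <- sim_config(n_genes = 200, n_modules = 5, module_size = 8,
                    n_controls = 4, n_cap = 30, noise_sd = 1e-9, seed = 3)
  sim <- simulate_cap_cohort(cfg)
  genes <- sim$truth$modules$severity_up
  r <- cor(t(sim$expr[genes, ]))
  expect_true(all(r > 1 - 1e-6))
})

test_that("the default structure plants 12 modules and 6 CAP classes", {
  cfg <- sim_config(n_genes = 2000, module_size = 16, seed = 1)
  sim <- simulate_cap_cohort(cfg)
  expect_length(sim$truth$modules, 12)
  expect_equal(anyDuplicated(unlist(sim$truth$modules)), 0L)
  cap_classes <- unique(sim$truth$class[sim$samples$group == "CAP"])
  expect_setequal(cap_classes, c("LS", "MS", "HS", "BD", "IFN-LS", "IFN-HS"))
  expect_true(all(sim$truth$class[sim$samples$group == "control"] == "CTRL"))
  # controls sit at the origin of the latent space
  ctl <- sim$samples$group == "control"
  expect_true(all(sim$truth$u[ctl] == 0 & sim$truth$v[ctl] == 0 &
                    sim$truth$w[ctl] == 0))
  # cohort A mounts more interferon response than cohort B
  cap <- !ctl
  expect_gt(mean(sim$truth$v[cap & sim$truth$cohort == "A"]),
            mean(sim$truth$v[cap & sim$truth$cohort == "B"]))
  # labels are a deterministic function of the recorded thresholds
  relabel <- somportraits:::planted_class(sim$truth$u[cap], sim$truth$v[cap],
                                          sim$truth$w[cap],
                                          sim$truth$thresholds)
  expect_identical(relabel, sim$truth$class[cap])
})

test_that("longitudinal severity decays by the configured factor", {
  cfg <- sim_config(n_genes = 300, n_modules = 5, module_size = 10,
                    n_controls = 2, n_cap = 60,
                    longitudinal_fraction = 0.5, day_decay = 0.8, seed = 5)
  sim <- simulate_cap_cohort(cfg)
  cap <- sim$samples$group == "CAP"
  series <- split(which(cap), sim$samples$patient[cap])
  series <- Filter(function(i) length(i) == 3, series)
  expect_gt(length(series), 0)
  for (idx in series[1:3]) {
    d <- sim$samples$day[idx]
    u <- sim$truth$u[idx]
    expect_equal(u[d == 3], u[d == 1] * 0.8^2, tolerance = 1e-12)
    expect_equal(u[d == 5], u[d == 1] * 0.8^4, tolerance = 1e-12)
  }
})

test_that("empirical death rates match the quadrature of the logistic model", {
  cfg <- sim_config(n_genes = 100, n_modules = 5, module_size = 5,
                    survival_intercept = -2.2, survival_slope = 2.0,
                    survival_interaction = 1.5, seed = 1)
  set.seed(2024)
  u <- runif(10000); v <- runif(10000)
  died <- !simulate_survival(u, v, cfg)
  # 2-d quadrature oracle over the uniform latent square
  inner <- function(uu) {
    vapply(uu, function(x) {
      stats::integrate(function(vv) {
        plogis(-2.2 + 2 * x + 1.5 * x * vv)
      }, 0, 1)$value
    }, numeric(1))
  }
  expected <- stats::integrate(inner, 0, 1)$value
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(died) - expected), 2 * se)
})

test_that("death rate is non-decreasing in severity decile", {
  cfg <- sim_config(seed = 1)
  set.seed(7)
  n <- 50000
  u <- runif(n); v <- runif(n)
  died <- !simulate_survival(u, v, cfg)
  decile <- cut(u, breaks = quantile(u, 0:10 / 10), include.lowest = TRUE,
                labels = FALSE)
  rates <- tapply(died, decile, mean)
  expect_true(all(diff(rates) > -0.01))
})

test_that("stronger severity loadings tighten within-module correlation", {
  rs <- sapply(c(2, 4, 8), function(b) {
    cfg <- sim_config(n_genes = 300, n_modules = 5, module_size = 10,
                      n_controls = 4, n_cap = 50, beta_sev = b, seed = 11)
    sim <- simulate_cap_cohort(cfg)
    r <- cor(t(sim$expr[sim$truth$modules$severity_up, ]))
    mean(r[upper.tri(r)])
  })
  expect_true(all(diff(rs) > 0))
})

test_that("signature sets are module subsets; decoys hit the uniform rate", {
  cfg <- sim_config(n_genes = 500, n_modules = 5, module_size = 16,
                    n_controls = 4, n_cap = 30, seed = 2)
  sim <- simulate_cap_cohort(cfg)
  sets <- simulate_gene_sets(sim)
  for (nm in names(sim$truth$modules)) {
    sig <- sets[[paste0("sig_", nm)]]
    expect_length(sig, 8)
    expect_true(all(sig %in% sim$truth$modules[[nm]]))
  }
  # expected decoy/module overlap under uniform draws: s * m / N
  overlaps <- vapply(1:1000, function(s) {
    ds <- simulate_gene_sets(sim, seed = 1000 + s)
    length(intersect(ds$decoy_01, sim$truth$modules$severity_up))
  }, numeric(1))
  expected <- 8 * 16 / 500
  se <- sqrt(expected / 1000)
  expect_lt(abs(mean(overlaps) - expected), 4 * se)
})

test_that("gene set generation is byte-deterministic through GMT", {
  cfg <- sim_config(n_genes = 300, n_modules = 5, module_size = 10,
                    n_controls = 4, n_cap = 20, seed = 9)
  sim <- simulate_cap_cohort(cfg)
  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  write_gmt(simulate_gene_sets(sim, seed = 42), f1)
  write_gmt(simulate_gene_sets(sim, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
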