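test_that("published correlation targets are symmetric and near-PSD", {
  R <- rumen_correlation_targets()
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 7))
  ev <- eigen(R, symmetric = TRUE)$values
  expect_gt(min(ev), -1e-3)   # printed matrix has a tiny rounding deficit
  Rp <- repair_correlation(R)
  expect_gte(min(eigen(Rp, symmetric = TRUE)$values), 0)
  expect_lt(max(abs(Rp - R)), 1e-3)
  # an already-PSD matrix passes through unchanged
  expect_identical(repair_correlation(diag(3)), diag(3))
})

test_that("same seed gives bit-identical datasets", {
  p <- synthetic_params(n_samples = 40, n_subpops = 4)
  a <- gen_rumen_samples(p, seed = 99)
  b <- gen_rumen_samples(p, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$samples, b$samples)
  c <- gen_rumen_samples(p, seed = 100)
  expect_false(identical(a$records$ash, c$records$ash))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- rnorm(3)
  set.seed(1234)
  invisible(suppressWarnings(
    gen_rumen_samples(synthetic_params(n_samples = 20, n_subpops = 3),
                      seed = 5)))
  expect_identical(rnorm(3), before)
})

test_that("every generated record passes derivation with exact closure", {
  sim <- gen_rumen_samples(synthetic_params(n_samples = 200), seed = 17)
  prof <- derive_profiles(sim$records, "rumen")
  expect_equal(nrow(prof), 200)
  expect_closure(prof, tol = 1e-9)
  expect_equal(nrow(validation_report(prof)), 0)
  # derivation reproduces the generator's own constituents
  m <- match(prof$sample_id, sim$samples$sample_id)
  expect_equal(prof$ap, sim$samples$ap[m], tolerance = 1e-12)
  expect_equal(prof$tnc2_lipids, sim$samples$tnc2_lipids[m],
               tolerance = 1e-9)
  expect_equal(prof$microbial_n, sim$samples$microbial_n[m],
               tolerance = 1e-12)
})

test_that("empirical correlations converge to the targets as 1/sqrt(n)", {
  R <- rumen_correlation_targets()
  cols <- colnames(R)
  err_at <- function(n, seed) {
    sim <- gen_rumen_samples(synthetic_params(n_samples = n), seed = seed)
    e <- abs(cor(sim$samples[, cols]) - R)
    max(e[lower.tri(e)])
  }
  e3 <- err_at(1000, 23)
  e4 <- err_at(10000, 23)
  expect_lt(e4, 0.05)
  expect_lt(e3, 0.12)
  expect_lt(e4, e3 + 0.02)   # larger n does not get materially worse
})

test_that("diet-type contrasts in lignin and microbial N are realized", {
  sim <- gen_rumen_samples(synthetic_params(n_samples = 6000), seed = 29)
  s <- sim$samples
  lig <- tapply(s$lignin, s$diet_type, mean)
  mic <- tapply(s$microbial_n, s$diet_type, mean)
  expect_equal(unname(lig["shrub_sugar"]), 18, tolerance = 0.05)
  expect_equal(unname(lig["broadleaf"]), 16, tolerance = 0.05)
  expect_equal(unname(mic["shrub_sugar"]), 0.92, tolerance = 0.05)
  expect_equal(unname(mic["conifer"]), 0.70, tolerance = 0.05)
  expect_equal(unname(table(s$diet_type)["broadleaf"]) / 6000, 0.5,
               tolerance = 0.05)
})

test_that("subpopulation structure: 30 units, minimum membership, areas", {
  p <- synthetic_params()
  sub <- gen_subpop_structure(p, seed = 3)
  expect_equal(nrow(sub), 30)
  expect_setequal(unique(sub$mma), c("A", "B", "C", "D", "E", "F", "G"))
  expect_equal(sum(sub$diet_type == "conifer"), 6)
  expect_true(all(sub$mma[sub$diet_type == "conifer"] %in% c("A", "C")))

  sim <- gen_rumen_samples(p, seed = 3)
  expect_true(all(table(sim$records$mmu) >= p$min_per_subpop))
  # samples inherit their subpopulation's diet type
  agg <- tapply(sim$samples$diet_type, sim$samples$mmu,
                function(v) length(unique(v)))
  expect_true(all(agg == 1))
})

test_that("sampling dates follow the early:late split, inverted in area A", {
  sim <- gen_rumen_samples(synthetic_params(n_samples = 4000), seed = 37)
  s <- sim$samples
  early <- s$date < as.Date("2014-12-01")
  inA <- s$mma == "A"
  expect_equal(mean(early[!inA]), 0.7, tolerance = 0.05)
  expect_equal(mean(early[inA]), 0.3, tolerance = 0.08)
  expect_true(any(s$date < as.Date("2014-10-23")))  # filter is exercised
  expect_true(all(s$date >= as.Date("2014-10-13") &
                    s$date <= as.Date("2015-02-22")))
})

test_that("null body mass is unrelated to ratio; injected slope recovers", {
  p0 <- synthetic_params()
  sim0 <- gen_rumen_samples(p0, seed = 41)
  rep0 <- run_pipeline(pipeline_config(input = sim0$records))
  expect_gt(rep0$subpop_bodymass$p_two_sided, 0.001)  # null: no tiny p

  slope_in <- 60  # kg calf BM per unit ratio, vs ratio spread ~0.1
  fits <- lapply(c(43, 44, 45), function(sd) {
    sim <- gen_rumen_samples(
      synthetic_params(bm_ratio_slope = slope_in), seed = sd)
    rep <- run_pipeline(pipeline_config(input = sim$records))
    rep$subpop_bodymass
  })
  within2se <- vapply(fits, function(f) {
    abs(f$slope - slope_in) < 2 * f$slope_se
  }, logical(1))
  expect_gte(sum(within2se), 2)   # at least 2 of 3 seeds within 2 se
})

test_that("range-box filter keeps every point inside the observed box", {
  p <- synthetic_params(n_samples = 300, range_box_filter = TRUE)
  sim <- gen_rumen_samples(p, seed = 47)
  box <- rumen_range_box()
  expect_true(all(sim$samples$x >= box["min", "x"] &
                    sim$samples$x <= box["max", "x"]))
  expect_true(all(sim$samples$y >= box["min", "y"] &
                    sim$samples$y <= box["max", "y"]))
  expect_true(all(sim$samples$i >= box["min", "i"] &
                    sim$samples$i <= box["max", "i"]))
})

test_that("balance-pair simulator hits its population slope", {
  d <- gen_balance_pairs(200000, 0.84, seed = 51)
  expect_equal(cor(d$x, d$y), 0.84, tolerance = 0.01)
  expect_equal(sd(d$x), 1, tolerance = 0.01)
  # sd_ratio rescales x so the population OLS slope becomes slope/sd_ratio
  d1 <- gen_balance_pairs(200000, 0.84, seed = 52, sd_ratio = 0.84)
  fit <- isometry_test(d1$y, d1$x, standardize = FALSE)
  expect_equal(fit$slope, 1, tolerance = 0.02)
})

test_that("spectra are linear in composition and reproducible", {
  comp <- data.frame(ap = c(100, 0, 50), cellulose = c(0, 100, 50))
  bank <- default_basis_bank(c("ap", "cellulose"))
  sp <- gen_spectra(comp, bank, noise_sd = 0, seed = 1)
  expect_equal(nrow(sp), 3)
  # one-hot compositions return pure component spectra (up to the common
  # baseline, which cancels in the difference)
  expect_equal(sp[1, ] - sp[2, ], bank["ap", ] - bank["cellulose", ],
               tolerance = 1e-12)
  # mixing is linear at zero noise
  expect_equal(sp[3, ], (sp[1, ] + sp[2, ]) / 2, tolerance = 1e-12)
  expect_identical(gen_spectra(comp, bank, noise_sd = 0.01, seed = 9),
                   gen_spectra(comp, bank, noise_sd = 0.01, seed = 9))
  expect_error(gen_spectra(data.frame(unknown = 1), bank, seed = 1),
               "unknown")
})
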