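# The within-between design, the hierarchical Student-t model, its
# cycle-shuffled null, and the modality comparison.

test_that("the design decomposition satisfies its scaling contract", {
  rows <- feature_table(0.4, n_subjects = 3, n_channels = 2, n_cycles = 50, seed = 2)
  des <- build_design(rows, "rise_time")
  for (s in levels(des$subject)) {
    expect_lt(abs(mean(des$xw[des$subject == s])), 1e-9)
  }
  expect_lt(abs(sd(des$xw) - 1), 1e-6)
  expect_lt(abs(sd(des$y) - 1), 1e-6)
  expect_error(build_design(rows[1:10, ], "rise_time"), class = "rs_invalid_argument")
  expect_error(build_design(rows, "no_such_feature"), class = "rs_invalid_argument")
})

test_that("the between component matches a hand-computed toy table", {
  # two subjects with raw means 1 and 3: grand mean 2, components +/-1
  # before scaling by the between-SD
  toy <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                    channel_id = "c1", modality = "airflow",
                    resp_rise_time_s = c(0.5, 1.0, 1.5, 2.5, 3.0, 3.5),
                    neural_rise_time_s = rnorm(6))
  toy <- toy[rep(1:6, 4), ]   # >= 20 cycles
  des <- build_design(toy, "rise_time")
  ms <- tapply(toy$resp_rise_time_s, toy$subject_id, mean)
  expect_equal(as.vector(ms), c(1, 3))
  s_b <- sd(ms)
  expect_equal(sort(unique(round(des$xb, 9))), c(-1, 1) / s_b)
})

test_that("a single subject gets a zero between component with a warning", {
  rows <- feature_table(0.3, n_subjects = 1, n_channels = 2, n_cycles = 40, seed = 3)
  expect_warning(des <- build_design(rows, "rise_time"), "single subject")
  expect_true(all(des$xb == 0))
})

test_that("an identity-slope outcome is recovered near 1", {
  rows <- feature_table(0, n_subjects = 2, n_channels = 1, n_cycles = 120, seed = 4)
  des <- build_design(rows, "rise_time")
  set.seed(5)
  rows$neural_rise_time_s <- des$xw + rnorm(nrow(rows), 0, 0.02)
  fit <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 2,
                                         iter = 1200, warmup = 600, seed = 6))
  expect_gt(fit$beta_within_median, 0.9)
  expect_lt(fit$beta_within_median, 1.1)
  expect_gt(fit$p_positive, 0.99)
})

test_that("the null permutation preserves each subject's predictor multiset", {
  rows <- feature_table(0.5, n_subjects = 3, n_channels = 2, n_cycles = 40, seed = 7)
  fit <- suppressWarnings(shape_coupling(rows, "rise_time", null = TRUE,
                                         chains = 1, iter = 220, warmup = 200, seed = 8))
  expect_true(fit$is_null_model)
  des <- fit$design
  for (s in levels(des$subject)) {
    sel <- des$subject == s
    expect_identical(sort(fit$xw_used[sel]), sort(des$xw[sel]))
  }
  expect_false(identical(fit$xw_used, des$xw))
})

test_that("standardized posteriors are invariant to raw feature rescaling", {
  rows <- feature_table(0.5, n_subjects = 3, n_channels = 2, n_cycles = 40, seed = 9)
  rows2 <- rows
  rows2$resp_rise_time_s <- rows2$resp_rise_time_s * 7
  rows2$neural_rise_time_s <- rows2$neural_rise_time_s * 0.2
  f1 <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 1,
                                        iter = 500, warmup = 300, seed = 10))
  f2 <- suppressWarnings(shape_coupling(rows2, "rise_time", chains = 1,
                                        iter = 500, warmup = 300, seed = 10))
  # the standardized design is identical, so the draws are bit-identical
  expect_equal(f1$beta_within_draws, f2$beta_within_draws)
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  rows <- feature_table(0.5, n_subjects = 3, n_channels = 2, n_cycles = 40,
                        seed = 11, noise_sd = 0.74)
  fit <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 2,
                                         iter = 1700, warmup = 500, seed = 12,
                                         random_slope = TRUE))
  library(rjags)
  des <- build_design(rows, "rise_time")
  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dt(mu[i], prec, nu)
      mu[i] <- alpha + (bw + w[subj[i]]) * xw[i] + bb * xb[i] + u[subj[i]] + v[chan[i]]
    }
    for (s in 1:S) { u[s] ~ dnorm(0, pow(sd_u, -2)); w[s] ~ dnorm(0, pow(sd_w, -2)) }
    for (c in 1:C) { v[c] ~ dnorm(0, pow(sd_v, -2)) }
    alpha ~ dnorm(0, 0.25); bw ~ dnorm(0, 1); bb ~ dnorm(0, 1)
    sd_u ~ dexp(1); sd_w ~ dexp(1); sd_v ~ dexp(1); sigma ~ dexp(1)
    prec <- pow(sigma, -2); nu ~ dgamma(2, 0.1) T(1.5,)
  }"
  jm <- jags.model(textConnection(model),
                   data = list(y = des$y, xw = des$xw, xb = des$xb,
                               subj = as.integer(des$subject),
                               chan = as.integer(des$channel),
                               N = nrow(des), S = nlevels(des$subject),
                               C = nlevels(des$channel)),
                   n.chains = 2, n.adapt = 200, quiet = TRUE)
  update(jm, 300)
  sm <- coda.samples(jm, c("bw", "sigma", "nu"), n.iter = 1200)
  d <- as.matrix(sm)
  expect_lt(abs(fit$beta_within_median - median(d[, "bw"])), 0.08)
  expect_lt(abs(median(fit$draws[, "sigma"]) - median(d[, "sigma"])), 0.08)
  # posterior predictive check: central intervals cover at their level
  expect_lt(abs(fit$ppc_coverage["central50"] - 0.5), 0.1)
  expect_lt(abs(fit$ppc_coverage["central90"] - 0.9), 0.06)
})

test_that("model methods behave like a classed fit should", {
  rows <- feature_table(0.5, n_subjects = 3, n_channels = 2, n_cycles = 40, seed = 13)
  fit <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 2,
                                         iter = 700, warmup = 400, seed = 14))
  expect_s3_class(fit, "shape_coupling")
  expect_named(coef(fit), c("intercept", "beta_within", "beta_between"))
  expect_length(fitted(fit), nrow(fit$design))
  expect_equal(residuals(fit), fit$design$y - fitted(fit))
  expect_lt(sd(residuals(fit)), sd(fit$design$y))   # the model explains something
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$design), 2))
  out <- capture.output(print(fit))
  expect_true(any(grepl("beta_within", out)))
  out2 <- capture.output(print(summary(fit)))
  expect_true(any(grepl("sigma", out2)))
  pdf(NULL); on.exit(dev.off())
  expect_no_error(plot(fit))
})

test_that("the null posterior is calibrated on uncoupled feature data", {
  # 20 seeded replicates of the generator's feature contract at beta = 0;
  # a 40-replicate Monte Carlo oracle of this exact setup puts P(beta>0)
  # inside [0.1, 0.9] with probability 0.925 per replicate and mean 0.49,
  # so >= 16/20 in-band (and a mean near one half) is the sound bound
  mkrows <- function(seed) {
    set.seed(seed)
    do.call(rbind, lapply(1:4, function(s) do.call(rbind, lapply(1:2, function(c) {
      x <- pmax(rnorm(60, 1.6, 0.25), 0.2)
      y <- pmax(1.6 + rt(60, 5) * 0.74 * sd(x), 0.2)
      data.frame(subject_id = sprintf("s%02d", s), channel_id = sprintf("ch%d", c),
                 modality = "airflow", resp_rise_time_s = x,
                 neural_rise_time_s = y)
    }))))
  }
  pp <- vapply(1:20, function(k) {
    suppressWarnings(shape_coupling(mkrows(1900 + k), "rise_time", chains = 2,
                                    iter = 1000, warmup = 500, seed = 1900 + k,
                                    random_slope = TRUE))$p_positive
  }, numeric(1))
  expect_gte(sum(pp >= 0.1 & pp <= 0.9), 16)
  expect_lt(abs(mean(pp) - 0.5), 0.2)
})

test_that("real and null fits are indistinguishable when nothing is coupled", {
  rows_of <- function(seed) feature_table(0, n_subjects = 4, n_channels = 2,
                                          n_cycles = 50, seed = seed,
                                          noise_sd = 0.74)
  overlap <- vapply(1:20, function(k) {
    rows <- rows_of(2900 + k)
    real <- suppressWarnings(shape_coupling(rows, "rise_time", chains = 1,
                                            iter = 700, warmup = 350,
                                            seed = 2900 + k))
    nul <- suppressWarnings(shape_coupling(rows, "rise_time", null = TRUE,
                                           chains = 1, iter = 700, warmup = 350,
                                           seed = 2900 + k))
    real$cri95[["lower"]] <= nul$cri95[["upper"]] &&
      nul$cri95[["lower"]] <= real$cri95[["upper"]]
  }, logical(1))
  expect_gte(sum(overlap), 18)
})

test_that("the Wilcoxon modality comparison matches exact enumeration", {
  set.seed(15)
  mk <- function(vals, mod) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      data.frame(subject_id = sprintf("s%02d", i), channel_id = "c1",
                 modality = mod,
                 resp_rise_time_s = vals[i] + rnorm(20, 0, 1e-6),
                 neural_rise_time_s = 0)
    }))
  }
  a_vals <- 1 + runif(10); b_vals <- a_vals - runif(10, 0.1, 0.5)
  ta <- mk(a_vals, "airflow"); tb <- mk(b_vals, "belt")
  res <- compare_modalities(ta, tb, features = "rise_time_s")
  # all ten differences share one sign: two-sided exact p = 2 / 2^10
  expect_equal(res$p_value, 2 / 2^10, tolerance = 1e-12)
  expect_gt(res$median_diff, 0)
  # swapping the tables negates the difference and keeps p
  ta2 <- tb; ta2$modality <- "airflow"
  tb2 <- ta; tb2$modality <- "belt"
  swp <- compare_modalities(ta2, tb2, features = "rise_time_s")
  expect_equal(swp$median_diff, -res$median_diff)
  expect_equal(swp$p_value, res$p_value)
  # identical inputs: degenerate, p reported as 1
  tb3 <- ta; tb3$modality <- "belt"
  same <- compare_modalities(ta, tb3, features = "rise_time_s")
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_error(compare_modalities(mk(a_vals[1:3], "airflow"), mk(b_vals[1:3], "belt")),
               class = "rs_invalid_argument")
})

test_that("airflow and belt from one generator differ in sharpness, not duration", {
  feats <- lapply(c("airflow", "belt"), function(mod) {
    do.call(rbind, lapply(1:6, function(s) {
      sim <- simulate_respiration(breath_template(modality = mod),
                                  duration_s = 200, fs = 100,
                                  seed = 100 * s + (mod == "belt"),
                                  subject_id = sprintf("s%02d", s))
      z <- zscore_recording(bandpass_for_timedomain(sim$recording))
      ext <- detect_extrema(z)
      pairs <- match_peaks(ext, ext, tau = 4)
      cycle_features(pairs, z, z)
    }))
  })
  res <- compare_modalities(feats[[1]], feats[[2]],
                            features = c("cycle_duration_s", "peak_sharpness"))
  dur <- res[res$feature == "cycle_duration_s", ]
  shp <- res[res$feature == "peak_sharpness", ]
  # belt smoothing blunts the inhale peak but leaves timing intact
  expect_gt(shp$median_diff, 0)
  expect_lt(abs(dur$median_diff), 0.3)
})
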