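# Hierarchical Bayesian estimation of cycle-by-cycle shape coupling.
#
# Model, per waveform feature:
#   y_i ~ StudentT(nu, mu_i, sigma)
#   mu_i = alpha + (beta_w + w_{s(i)}) * xw_i + beta_b * xb_i
#          + u_{s(i)} + v_{c(i)}
# with y the standardized neural feature, xw the subject-mean-centered
# respiration feature scaled by the pooled within-subject SD, and xb the
# grand-mean-centered subject means scaled by the between-subject SD.
# Priors: fixed effects ~ Normal(0, 1); intercept ~ Normal(0, 2); all SD
# components (random-effect SDs and sigma) ~ Exponential(1);
# nu ~ Gamma(2, 0.1).
#
# The sampler is a blocked Gibbs scheme exploiting the scale-mixture
# representation of the Student-t (per-observation Gamma mixing weights),
# with conjugate normal updates for all coefficients and univariate slice
# updates (on the log scale) for the SD components and nu.

normalize_feature <- function(feature, cols) {
  cand <- c(feature, paste0(feature, "_s"), sub("_s$", "", feature))
  hit <- cand[paste0("resp_", cand) %in% cols & paste0("neural_", cand) %in% cols]
  if (!length(hit)) {
    stop_invalid(sprintf("feature '%s' not found in the cycle table", feature))
  }
  hit[1L]
}

#' Build the standardized within-between design for one feature
#'
#' Splits the respiration predictor into a within-subject component
#' (subject-mean-centered, scaled by the pooled within-subject SD) and a
#' between-subject component (grand-mean-centered subject means, scaled by
#' their SD), and standardizes the neural outcome by its pooled SD, so the
#' within-subject slope is a standardized coupling coefficient comparable
#' across features.
#'
#' @param rows A [cycle_features()] table with at least 20 cycles.
#' @param feature Feature name, e.g. `"rise_time"` or `"rise_time_s"`.
#' @return An object of class `"coupling_design"`: data frame with columns
#'   `y`, `xw`, `xb`, `subject`, `channel` plus scaling metadata in
#'   attributes.
#' @export
build_design <- function(rows, feature) {
  if (!is.data.frame(rows)) stop_invalid("rows must be a cycle feature table")
  feature <- normalize_feature(feature, names(rows))
  xr <- rows[[paste0("resp_", feature)]]
  yn <- rows[[paste0("neural_", feature)]]
  ok <- is.finite(xr) & is.finite(yn)
  rows <- rows[ok, ]; xr <- xr[ok]; yn <- yn[ok]
  if (nrow(rows) < 20L) stop_invalid("need at least 20 cycles to fit the coupling model")
  subject <- factor(rows$subject_id)
  channel <- factor(paste(rows$subject_id, rows$channel_id, sep = "/"))
  sm <- tapply(xr, subject, mean)[subject]
  xw_raw <- xr - sm
  s_within <- stats::sd(xw_raw)
  if (!is.finite(s_within) || s_within == 0) {
    stop_invalid("respiration feature has no within-subject variance")
  }
  xw <- xw_raw / s_within
  if (nlevels(subject) >= 2L) {
    ms <- tapply(xr, subject, mean)
    s_between <- stats::sd(ms)
    xb <- if (is.finite(s_between) && s_between > 0) {
      ((ms - mean(ms)) / s_between)[subject]
    } else rep(0, nrow(rows))
  } else {
    warning("single subject: between-subject component set to zero", call. = FALSE)
    xb <- rep(0, nrow(rows))
  }
  s_y <- stats::sd(yn)
  if (!is.finite(s_y) || s_y == 0) stop_invalid("neural feature has no variance")
  out <- data.frame(y = (yn - mean(yn)) / s_y, xw = xw, xb = as.numeric(xb),
                    subject = subject, channel = channel)
  structure(out, class = c("coupling_design", "data.frame"),
            feature = feature, s_within = s_within, s_y = s_y)
}

# Univariate slice sampler with stepping out, for a log-density `logf`.
slice1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf, max_steps = 30L) {
  y <- logf(x0) - stats::rexp(1)
  l <- x0 - stats::runif(1) * w
  r <- l + w
  k <- max_steps
  while (l > lower && k > 0L && logf(l) > y) { l <- l - w; k <- k - 1L }
  k <- max_steps
  while (r < upper && k > 0L && logf(r) > y) { r <- r + w; k <- k - 1L }
  l <- max(l, lower); r <- min(r, upper)
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# One chain of the blocked Gibbs sampler. Returns post-warmup draws of the
# population-level parameters and posterior-mean random effects.
gibbs_chain <- function(y, X, P0, subj, chan, xw, use_v, use_w,
                        iter, warmup, chain_seed) {
  n <- length(y)
  S <- max(subj); C <- max(chan)
  p <- ncol(X)
  with_seed(chain_seed, {
    # initialization: weakly jittered least squares
    beta <- stats::lm.fit(X, y)$coefficients
    beta[!is.finite(beta)] <- 0
    beta <- beta + stats::rnorm(p, 0, 0.1)
    u <- stats::rnorm(S, 0, 0.1); v <- rep(0, C); w <- rep(0, S)
    sd_u <- sd_v <- sd_w <- 0.3
    sigma <- max(stats::sd(y - X %*% beta), 0.1) * stats::runif(1, 0.7, 1.3)
    nu <- stats::runif(1, 5, 30)
    lam <- rep(1, n)
    xw2 <- xw^2
    xb_subj <- if (p >= 3L) {
      vapply(seq_len(S), function(s) X[match(s, subj), 3L], numeric(1))
    } else numeric(0)

    keep <- iter - warmup
    draws <- matrix(NA_real_, keep, 8L,
                    dimnames = list(NULL, c("intercept", "beta_within",
                                            "beta_between", "sd_subject",
                                            "sd_channel", "sd_slope",
                                            "sigma", "nu")))
    u_acc <- rep(0, S); v_acc <- rep(0, C); w_acc <- rep(0, S)

    Xb <- as.numeric(X %*% beta)
    reu <- u[subj]; rev_ <- v[chan]; rw <- w[subj] * xw
    for (it in seq_len(iter)) {
      r <- y - Xb - reu - rev_ - rw
      lam <- stats::rgamma(n, (nu + 1) / 2, rate = (nu + (r / sigma)^2) / 2)
      pr <- lam / sigma^2

      e <- y - reu - rev_ - rw
      A <- crossprod(X, X * pr) + P0
      bvec <- crossprod(X, pr * e)
      R <- chol(A)
      mean_b <- backsolve(R, forwardsolve(t(R), bvec))
      beta <- as.numeric(mean_b + backsolve(R, stats::rnorm(p)))
      Xb <- as.numeric(X %*% beta)

      e <- y - Xb - rev_ - rw
      pu <- as.numeric(rowsum(pr, subj)) + 1 / sd_u^2
      mu_u <- as.numeric(rowsum(pr * e, subj)) / pu
      u <- stats::rnorm(S, mu_u, 1 / sqrt(pu))
      reu <- u[subj]

      if (use_v) {
        e <- y - Xb - reu - rw
        pv <- as.numeric(rowsum(pr, chan)) + 1 / sd_v^2
        mu_v <- as.numeric(rowsum(pr * e, chan)) / pv
        v <- stats::rnorm(C, mu_v, 1 / sqrt(pv))
        rev_ <- v[chan]
      }
      if (use_w) {
        e <- y - Xb - reu - rev_
        pw <- as.numeric(rowsum(pr * xw2, subj)) + 1 / sd_w^2
        mu_w <- as.numeric(rowsum(pr * xw * e, subj)) / pw
        w <- stats::rnorm(S, mu_w, 1 / sqrt(pw))
        rw <- w[subj] * xw
      }

      # interweaving sweeps: shift mass between the intercept and each
      # random-intercept block (and between the slope and the random
      # slopes), leaving the likelihood untouched; this breaks the strong
      # posterior correlation that otherwise stalls the location parameters
      sweep_loc <- function(fixed, res, prior_prec, sd_re) {
        prec <- prior_prec + length(res) / sd_re^2
        m <- (-fixed * prior_prec + sum(res) / sd_re^2) / prec
        stats::rnorm(1, m, 1 / sqrt(prec))
      }
      d <- sweep_loc(beta[1L], u, 0.25, sd_u)
      beta[1L] <- beta[1L] + d; u <- u - d
      if (use_v) {
        d <- sweep_loc(beta[1L], v, 0.25, sd_v)
        beta[1L] <- beta[1L] + d; v <- v - d
        rev_ <- v[chan]
      }
      if (use_w) {
        d <- sweep_loc(beta[2L], w, 1, sd_w)
        beta[2L] <- beta[2L] + d; w <- w - d
        rw <- w[subj] * xw
      }
      if (p >= 3L) {
        # between-slope vs subject intercepts, along the per-subject xb
        prec <- 1 + sum(xb_subj^2) / sd_u^2
        m <- (-beta[3L] + sum(u * xb_subj) / sd_u^2) / prec
        d <- stats::rnorm(1, m, 1 / sqrt(prec))
        beta[3L] <- beta[3L] + d; u <- u - d * xb_subj
      }
      Xb <- as.numeric(X %*% beta)
      reu <- u[subj]

      # SD components: Exponential(1) priors, slice-sampled on log scale
      ssq_u <- sum(u^2)
      sd_u <- exp(slice1(log(sd_u), function(ls) {
        sd <- exp(ls); -S * ls - ssq_u / (2 * sd^2) - sd + ls
      }, lower = log(1e-4), upper = log(100)))
      if (use_v) {
        ssq_v <- sum(v^2)
        sd_v <- exp(slice1(log(sd_v), function(ls) {
          sd <- exp(ls); -C * ls - ssq_v / (2 * sd^2) - sd + ls
        }, lower = log(1e-4), upper = log(100)))
      }
      if (use_w) {
        ssq_w <- sum(w^2)
        sd_w <- exp(slice1(log(sd_w), function(ls) {
          sd <- exp(ls); -S * ls - ssq_w / (2 * sd^2) - sd + ls
        }, lower = log(1e-4), upper = log(100)))
      }

      r <- y - Xb - reu - rev_ - rw
      S2 <- sum(lam * r^2)
      sigma <- exp(slice1(log(sigma), function(ls) {
        s <- exp(ls); -n * ls - S2 / (2 * s^2) - s + ls
      }, lower = log(1e-6), upper = log(100)))

      SL <- sum(log(lam)); SS <- sum(lam)
      nu <- exp(slice1(log(nu), function(ln) {
        nv <- exp(ln)
        n * (nv / 2 * log(nv / 2) - lgamma(nv / 2)) +
          nv / 2 * (SL - SS) + 2 * ln - 0.1 * nv
      }, w = 0.5, lower = log(1.5), upper = log(200)))

      if (it > warmup) {
        j <- it - warmup
        draws[j, ] <- c(beta[1L], beta[2L], if (p >= 3L) beta[3L] else NA_real_,
                        sd_u, if (use_v) sd_v else NA_real_,
                        if (use_w) sd_w else NA_real_, sigma, nu)
        u_acc <- u_acc + u; v_acc <- v_acc + v; w_acc <- w_acc + w
      }
    }
    list(draws = draws, u = u_acc / keep, v = v_acc / keep, w = w_acc / keep)
  })
}

# Split-Rhat across chains (Gelman et al.), one parameter at a time.
split_rhat <- function(chains_mat) {
  halves <- list()
  for (m in chains_mat) {
    n <- nrow(m)
    h <- n %/% 2L
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1L):(2L * h), , drop = FALSE]))
  }
  vapply(colnames(chains_mat[[1L]]), function(cn) {
    seqs <- lapply(halves, function(h) h[, cn])
    if (anyNA(seqs[[1L]])) return(NA_real_)
    m <- length(seqs); n <- length(seqs[[1L]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Fit the hierarchical Bayesian shape-coupling model for one feature
#'
#' Estimates the standardized within-subject slope linking a respiration
#' waveform feature to the matched neural feature, cycle by cycle, using a
#' Student-t multilevel regression with a within-between decomposition of
#' the respiration predictor: random intercepts for subject and for channel
#' within subject, plus a by-subject random within-slope. Priors are weakly
#' informative: Normal(0, 1) on slopes, Normal(0, 2) on the intercept,
#' Exponential(1) on all SD components, Gamma(2, 0.1) on the Student-t
#' degrees of freedom.
#'
#' With `null = TRUE` the within-subject respiration predictor is randomly
#' permuted across cycles within each subject before fitting — cycle-level
#' pairing is destroyed while the predictor's distribution and the
#' multilevel structure are preserved — giving the matched chance model.
#'
#' @param data A [cycle_features()] table or a prebuilt [build_design()]
#'   object.
#' @param feature Feature name (ignored when `data` is already a design).
#' @param null Fit the cycle-shuffled null model instead (default `FALSE`).
#' @param chains,iter,warmup MCMC settings (defaults 4 chains of 3000
#'   iterations, 1500 warmup).
#' @param seed Integer seed driving permutation and all chains.
#' @param random_slope Include the by-subject random within-slope; default
#'   `TRUE` when there are at least 5 subjects.
#' @param channel_effect Include the channel-within-subject intercept;
#'   default `TRUE` when channels outnumber subjects.
#' @return An object of class `"shape_coupling"` with posterior draws and
#'   summaries: `beta_within_median`, `cri95`, `p_positive`, `rhat`,
#'   `ppc_coverage`, plus the design and sampler settings. Convergence is
#'   flagged (not fatal) when any split-Rhat is >= 1.01.
#' @export
shape_coupling <- function(data, feature = "rise_time", null = FALSE,
                           chains = 4, iter = 3000, warmup = 1500, seed = 1,
                           random_slope = NULL, channel_effect = NULL) {
  design <- if (inherits(data, "coupling_design")) data else build_design(data, feature)
  if (iter <= warmup) stop_invalid("iter must exceed warmup")
  y <- design$y
  xw <- design$xw
  if (null) {
    xw <- with_seed(substream_seed(seed, "null_permutation"), {
      out <- xw
      for (s in levels(design$subject)) {
        sel <- which(design$subject == s)
        out[sel] <- out[sel][sample.int(length(sel))]
      }
      out
    })
  }
  subj <- as.integer(design$subject)
  chan <- as.integer(design$channel)
  n_subj <- max(subj); n_chan <- max(chan)
  use_v <- channel_effect %||% (n_chan > n_subj)
  use_w <- random_slope %||% (n_subj >= 5L)
  use_xb <- stats::sd(design$xb) > 0
  X <- if (use_xb) cbind(1, xw, design$xb) else cbind(1, xw)
  # prior precisions: intercept Normal(0, 2) -> 1/4; slopes Normal(0, 1)
  P0 <- diag(c(0.25, rep(1, ncol(X) - 1L)), ncol(X))

  res <- lapply(seq_len(chains), function(cc) {
    gibbs_chain(y, X, P0, subj, chan, xw, use_v, use_w, iter, warmup,
                chain_seed = substream_seed(seed, paste0("chain", cc)))
  })
  mats <- lapply(res, `[[`, "draws")
  draws <- do.call(rbind, mats)
  rhat <- if (chains >= 2L || (iter - warmup) >= 4L) split_rhat(mats) else NULL
  bw <- draws[, "beta_within"]

  ranef <- list(
    subject = Reduce(`+`, lapply(res, `[[`, "u")) / chains,
    channel = if (use_v) Reduce(`+`, lapply(res, `[[`, "v")) / chains else NULL,
    slope = if (use_w) Reduce(`+`, lapply(res, `[[`, "w")) / chains else NULL)
  names(ranef$subject) <- levels(design$subject)
  if (use_v) names(ranef$channel) <- levels(design$channel)
  if (use_w) names(ranef$slope) <- levels(design$subject)

  obj <- structure(list(
    feature = attr(design, "feature"), design = design, xw_used = xw,
    draws = draws, chains = chains, iter = iter, warmup = warmup,
    seed = seed, is_null_model = null,
    use_random_slope = use_w, use_channel_effect = use_v,
    beta_within_draws = bw,
    beta_within_median = stats::median(bw),
    cri95 = c(lower = percentile(bw, 0.025), upper = percentile(bw, 0.975)),
    p_positive = mean(bw > 0),
    rhat = rhat, rhat_max = if (is.null(rhat)) NA_real_ else max(rhat, na.rm = TRUE),
    ranef = ranef,
    n_cycles = length(y), n_subjects = n_subj, n_channels = n_chan),
    class = "shape_coupling")
  obj$ppc_coverage <- ppc_coverage(obj)
  if (is.finite(obj$rhat_max) && obj$rhat_max >= 1.01) {
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f", obj$rhat_max),
            call. = FALSE)
  }
  obj
}

# Posterior predictive coverage of the observed outcome by the central
# 50 and 90 percent predictive intervals, using a subsample of draws and
# posterior-mean random effects.
ppc_coverage <- function(object, n_draws = 200L) {
  d <- object$draws
  take <- round(seq(1L, nrow(d), length.out = min(n_draws, nrow(d))))
  mu0 <- linpred(object)
  y <- object$design$y
  reps <- vapply(take, function(i) {
    mu <- mu0 - object$beta_within_median * object$xw_used +
      d[i, "beta_within"] * object$xw_used +
      (d[i, "intercept"] - stats::median(d[, "intercept"]))
    mu + d[i, "sigma"] * stats::rt(length(y), d[i, "nu"])
  }, numeric(length(y)))
  q <- apply(reps, 1L, stats::quantile, probs = c(0.25, 0.75, 0.05, 0.95),
             names = FALSE)
  c(central50 = mean(y >= q[1L, ] & y <= q[2L, ]),
    central90 = mean(y >= q[3L, ] & y <= q[4L, ]))
}

# Posterior-median linear predictor (standardized scale).
linpred <- function(object) {
  d <- object$draws
  design <- object$design
  mu <- stats::median(d[, "intercept"]) +
    stats::median(d[, "beta_within"]) * object$xw_used +
    object$ranef$subject[as.integer(design$subject)]
  if (!all(is.na(d[, "beta_between"]))) {
    mu <- mu + stats::median(d[, "beta_between"]) * design$xb
  }
  if (!is.null(object$ranef$channel)) {
    mu <- mu + object$ranef$channel[as.integer(design$channel)]
  }
  if (!is.null(object$ranef$slope)) {
    mu <- mu + object$ranef$slope[as.integer(design$subject)] * object$xw_used
  }
  unname(mu)
}

#' @export
print.shape_coupling <- function(x, ...) {
  cat(sprintf("<shape_coupling%s> feature: %s\n",
              if (x$is_null_model) " (cycle-shuffled null)" else "", x$feature))
  cat(sprintf("  %d cycles, %d subjects, %d channels; %d chains x %d iter (%d warmup)\n",
              x$n_cycles, x$n_subjects, x$n_channels, x$chains, x$iter, x$warmup))
  cat(sprintf("  beta_within = %.3f [95%% CrI %.3f, %.3f], P(beta > 0) = %.3f\n",
              x$beta_within_median, x$cri95[1L], x$cri95[2L], x$p_positive))
  if (is.finite(x$rhat_max)) {
    cat(sprintf("  max split-Rhat = %.3f%s\n", x$rhat_max,
                if (x$rhat_max >= 1.01) "  <- check convergence" else ""))
  }
  invisible(x)
}

#' @export
summary.shape_coupling <- function(object, ...) {
  d <- object$draws
  tab <- t(apply(d, 2L, function(v) {
    if (all(is.na(v))) return(c(NA, NA, NA))
    c(stats::median(v), percentile(v, 0.025), percentile(v, 0.975))
  }))
  colnames(tab) <- c("median", "cri_2.5", "cri_97.5")
  tab <- cbind(tab, rhat = if (is.null(object$rhat)) NA else object$rhat[rownames(tab)])
  structure(list(feature = object$feature, is_null_model = object$is_null_model,
                 table = tab, p_positive = object$p_positive,
                 ppc_coverage = object$ppc_coverage,
                 n_cycles = object$n_cycles, n_subjects = object$n_subjects,
                 n_channels = object$n_channels),
            class = "summary.shape_coupling")
}

#' @export
print.summary.shape_coupling <- function(x, ...) {
  cat(sprintf("Hierarchical Student-t shape-coupling model%s - feature: %s\n",
              if (x$is_null_model) " (null)" else "", x$feature))
  cat(sprintf("%d cycles, %d subjects, %d channels\n\n",
              x$n_cycles, x$n_subjects, x$n_channels))
  print(round(x$table, 3))
  cat(sprintf("\nP(beta_within > 0) = %.3f\n", x$p_positive))
  cat(sprintf("Posterior predictive coverage: %.2f (50%% interval), %.2f (90%% interval)\n",
              x$ppc_coverage[1L], x$ppc_coverage[2L]))
  invisible(x)
}

#' @export
coef.shape_coupling <- function(object, ...) {
  d <- object$draws
  out <- c(intercept = stats::median(d[, "intercept"]),
           beta_within = stats::median(d[, "beta_within"]),
           beta_between = stats::median(d[, "beta_between"]))
  out[!is.na(out)]
}

#' @export
fitted.shape_coupling <- function(object, ...) linpred(object)

#' @export
residuals.shape_coupling <- function(object, ...) object$design$y - linpred(object)

#' @importFrom stats simulate
#' @export
simulate.shape_coupling <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(with_seed(seed, simulate(object, nsim = nsim)))
  d <- object$draws
  mu0 <- linpred(object)
  out <- as.data.frame(vapply(seq_len(nsim), function(j) {
    i <- sample.int(nrow(d), 1L)
    mu <- mu0 + (d[i, "beta_within"] - object$beta_within_median) * object$xw_used
    mu + d[i, "sigma"] * stats::rt(length(mu0), d[i, "nu"])
  }, numeric(length(mu0))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the posterior of the within-subject coupling slope
#'
#' Density of the `beta_within` posterior draws, optionally overlaid with a
#' matched cycle-shuffled null model's posterior — separation between the
#' two is the visual evidence for coupling beyond chance.
#'
#' @param x A [shape_coupling()] fit.
#' @param null Optional null-model [shape_coupling()] fit to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.shape_coupling <- function(x, null = NULL, ...) {
  dr <- stats::density(x$beta_within_draws)
  dn <- if (!is.null(null)) stats::density(null$beta_within_draws)
  xlim <- range(dr$x, if (!is.null(dn)) dn$x, 0)
  ylim <- c(0, max(dr$y, if (!is.null(dn)) dn$y))
  graphics::plot(dr, xlim = xlim, ylim = ylim, col = "steelblue", lwd = 2,
                 main = sprintf("beta_within posterior - %s", x$feature),
                 xlab = "standardized slope", ...)
  if (!is.null(dn)) {
    graphics::lines(dn, col = "grey50", lwd = 2, lty = 2)
    graphics::legend("topright", c("real", "cycle-shuffled null"),
                     col = c("steelblue", "grey50"), lwd = 2, lty = c(1, 2),
                     bty = "n")
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Compare airflow and belt respiration morphology
#'
#' For each waveform feature, the median value across cycles is computed
#' per participant and modality, and the paired airflow-minus-belt
#' differences are tested with the two-sided Wilcoxon signed-rank test
#' (exact for up to 25 pairs). Participants lacking either modality are
#' dropped. All-zero differences are reported as degenerate with p = 1.
#'
#' @param airflow_rows,belt_rows [cycle_features()] tables for the two
#'   respiration modalities.
#' @param features Respiration feature names to compare; defaults to all
#'   eight shape metrics plus amplitude.
#' @return A data frame of class `"modality_comparison"`: one row per
#'   feature with the median paired difference, Wilcoxon `V`, `p_value`,
#'   `degenerate` flag and `n_pairs`.
#' @export
compare_modalities <- function(airflow_rows, belt_rows,
                               features = shape_feature_names) {
  for (tb in list(airflow_rows, belt_rows)) {
    if (!is.data.frame(tb)) stop_invalid("inputs must be cycle feature tables")
  }
  shared <- intersect(unique(airflow_rows$subject_id), unique(belt_rows$subject_id))
  if (length(shared) < 5L) {
    stop_invalid("need >= 5 participants with both modalities")
  }
  out <- lapply(features, function(ft) {
    col <- paste0("resp_", ft)
    if (!col %in% names(airflow_rows) || !col %in% names(belt_rows)) return(NULL)
    a <- vapply(shared, function(s) {
      stats::median(airflow_rows[[col]][airflow_rows$subject_id == s], na.rm = TRUE)
    }, numeric(1))
    b <- vapply(shared, function(s) {
      stats::median(belt_rows[[col]][belt_rows$subject_id == s], na.rm = TRUE)
    }, numeric(1))
    d <- a - b
    if (all(d == 0)) {
      return(data.frame(feature = ft, median_diff = 0, statistic = NA_real_,
                        p_value = 1, degenerate = TRUE, n_pairs = length(d)))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = length(d) <= 25,
                                              correct = TRUE))
    data.frame(feature = ft, median_diff = stats::median(d),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               degenerate = FALSE, n_pairs = length(d))
  })
  res <- do.call(rbind, out)
  class(res) <- c("modality_comparison", "data.frame")
  res
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf("Airflow vs belt paired Wilcoxon signed-rank (n = %d participants)\n",
              x$n_pairs[1L]))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3)
  df$median_diff <- signif(df$median_diff, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
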