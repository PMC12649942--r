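#' Bayesian stable-isotope mixing model
#'
#' Estimates the diet-proportion simplex p over K sources from consumer
#' tracer values under the standard Gaussian mixing likelihood: for tracer j
#' and consumer i,
#' \deqn{y_{ij} \sim N\!\left(\sum_k p_k(\mu_{kj} + \mu_{TEF,j}),\;
#'   \sqrt{\sum_k p_k^2(\sigma_{kj}^2 + \sigma_{TEF,j}^2) + \sigma_j^2}\right)}
#' with a Dirichlet prior on p (flat, Dirichlet(1, ..., 1), by default) and a
#' half-Normal(0, 5 permil) prior on each residual SD sigma_j. Discrimination
#' is applied once (a single trophic step), its variance entering the mixture
#' variance term.
#'
#' Sampling is multi-chain adaptive random-walk Metropolis on the
#' unconstrained parameterisation (additive log-ratio transform of p, with
#' its Jacobian, and log sigma). During burn-in the proposal scale follows a
#' Robbins-Monro recursion targeting 23% acceptance and the proposal
#' covariance adapts to the chain history; after burn-in the proposal is
#' frozen. Convergence is monitored with split-chain R-hat per parameter.
#'
#' @param consumers Consumer sample table (>= 1 row).
#' @param sources Source-summary table (K >= 1 rows).
#' @param tef A [tef_spec()].
#' @param chains Number of chains (default 4).
#' @param iterations Iterations per chain including burn-in (default 10000).
#' @param burn_in Burn-in iterations discarded per chain (default 1000).
#' @param seed Integer seed (chain c uses `seed + 1000003 * (c - 1)`).
#' @param prior Dirichlet concentration vector (length K, default all 1).
#' @param sigma_prior_sd Scale of the half-normal prior on residual SDs.
#' @return Object of class `mixing_fit`: pooled post-burn-in draws `p`
#'   (draws x K), `sigma` (draws x 2), `loglik`, `deviance_draws`, per-chain
#'   arrays, `rhat`, `converged` flag, and the inputs.
#' @export
fit_mixing <- function(consumers, sources, tef, chains = 4,
                       iterations = 10000, burn_in = 1000, seed = 1L,
                       prior = NULL, sigma_prior_sd = 5) {
  consumers <- validate_samples(consumers)
  sources <- validate_sources(sources)
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  K <- nrow(sources)
  if (is.null(prior)) prior <- rep(1, K)
  if (length(prior) != K || any(prior <= 0))
    stop("prior must be a positive concentration vector of length K")
  y <- cbind(consumers$d13C, consumers$d15N)
  N <- nrow(y); J <- 2L
  mu_s <- cbind(sources$mean_d13C + tef$mean_d13C,
                sources$mean_d15N + tef$mean_d15N)
  v_s <- cbind(sources$sd_d13C^2 + tef$sd_d13C^2,
               sources$sd_d15N^2 + tef$sd_d15N^2)
  ybar <- colMeans(y)
  yss <- colSums(sweep(y, 2, ybar)^2)  # sufficient statistics per tracer

  # log likelihood from (mean, variance) per tracer using sufficient stats
  loglik_pars <- function(mu_mix, var_mix) {
    sum(-0.5 * N * log(2 * pi * var_mix) -
          (yss + N * (ybar - mu_mix)^2) / (2 * var_mix))
  }
  nfree <- K - 1L
  d <- nfree + J
  unpack <- function(th) {
    if (nfree > 0) {
      e <- exp(c(th[seq_len(nfree)], 0))
      p <- e / sum(e)
    } else p <- 1
    list(p = p, sig = exp(th[nfree + seq_len(J)]))
  }
  logpost <- function(th) {
    u <- unpack(th)
    mu_mix <- as.numeric(u$p %*% mu_s)
    var_mix <- as.numeric(u$p^2 %*% v_s) + u$sig^2
    ll <- loglik_pars(mu_mix, var_mix)
    # Dirichlet prior + ALR Jacobian (sum over k of alpha_k * log p_k),
    # half-normal prior on sigma + log-Jacobian of the log transform
    lp <- ll + sum(prior * log(u$p)) +
      sum(-u$sig^2 / (2 * sigma_prior_sd^2) + log(u$sig))
    c(lp = lp, ll = ll)
  }

  keep <- iterations - burn_in

  # Laplace approximation: MAP + inverse Hessian seed the proposal
  # covariance; chains start overdispersed around the mode
  opt <- tryCatch(
    stats::optim(rep(0, d), function(th) -logpost(th)["lp"],
                 method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  S0 <- diag(d) * 0.05
  th0 <- rep(0, d)
  if (!is.null(opt) && all(is.finite(opt$hessian))) {
    S_try <- tryCatch(chol2inv(chol(opt$hessian + diag(1e-6, d))),
                      error = function(e) NULL)
    if (!is.null(S_try)) { S0 <- S_try; th0 <- opt$par }
  }

  # Phase A: per-chain burn-in with scale and covariance adaptation,
  # started overdispersed around the mode
  warm_chain <- function(chain_seed) {
    set.seed(chain_seed)
    th <- th0 + stats::rnorm(d) * 2 * sqrt(pmax(diag(S0), 1e-4))
    cur <- logpost(th)
    if (!is.finite(cur["lp"])) { th <- th0; cur <- logpost(th) }
    lsc <- log(2.38^2 / d)
    S <- S0
    cS <- chol(S)
    hist <- matrix(NA_real_, burn_in, d)
    for (i in seq_len(burn_in)) {
      prop <- th + sqrt(exp(lsc)) * as.numeric(stats::rnorm(d) %*% cS)
      cand <- logpost(prop)
      lr <- cand["lp"] - cur["lp"]
      acc_p <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < acc_p) { th <- prop; cur <- cand }
      hist[i, ] <- th
      lsc <- lsc + (acc_p - 0.234) / max(1, i)^0.6
      if (i >= 200 && i %% 50 == 0) {
        S <- stats::cov(hist[seq_len(i), , drop = FALSE]) + diag(1e-8, d)
        cS <- chol(S)
      }
    }
    list(th = th, cur = cur, hist = hist)
  }
  chain_seeds <- as.integer(seed) + 1000003L * (seq_len(chains) - 1L)
  warm <- lapply(chain_seeds, warm_chain)

  # pooled kernel from the second half of every chain's burn-in: a random
  # walk scaled to the pooled covariance plus an independence component
  halves <- lapply(warm, function(w)
    w$hist[seq.int(floor(burn_in / 2) + 1L, burn_in), , drop = FALSE])
  pool <- do.call(rbind, halves)
  m_pool <- colMeans(pool)
  # random-walk shape: average within-chain covariance (pooling with the
  # between-chain spread of unconverged warmups would oversize the steps);
  # independence proposal: total covariance, inflated, for full coverage
  S_within <- Reduce(`+`, lapply(halves, stats::cov)) / length(halves) +
    diag(1e-8, d)
  S_pool <- stats::cov(pool) + diag(1e-8, d)
  # heavy-tailed independence proposal: multivariate t (4 df) on the pooled
  # location/scale, so distant ridge segments stay reachable
  t_df <- 4
  cS_ind <- chol(S_pool)
  ldet_ind <- sum(log(diag(cS_ind)))
  r_ind <- function() {
    m_pool + as.numeric(stats::rnorm(d) %*% cS_ind) /
      sqrt(stats::rchisq(1, t_df) / t_df)
  }
  d_ind <- function(x) {
    z <- backsolve(cS_ind, x - m_pool, transpose = TRUE)
    -ldet_ind - (t_df + d) / 2 * log1p(sum(z^2) / t_df)
  }

  # Phase B: short scale recalibration on the pooled shape (discarded),
  # then fixed-kernel sampling of the retained draws
  run_chain <- function(w, chain_seed) {
    set.seed(chain_seed + 500009L)
    th <- w$th; cur <- w$cur
    lsc <- log(2.38^2 / d)
    cS_w <- chol(S_within)
    n_cal <- min(500L, burn_in)
    for (i in seq_len(n_cal)) {
      prop <- th + sqrt(exp(lsc)) * as.numeric(stats::rnorm(d) %*% cS_w)
      cand <- logpost(prop)
      lr <- cand["lp"] - cur["lp"]
      acc_p <- if (is.finite(lr)) min(1, exp(lr)) else 0
      if (stats::runif(1) < acc_p) { th <- prop; cur <- cand }
      lsc <- lsc + (acc_p - 0.234) / max(1, i)^0.6
    }
    cS_rw <- sqrt(exp(lsc)) * cS_w
    p_dr <- matrix(NA_real_, keep, K)
    s_dr <- matrix(NA_real_, keep, J)
    ll_dr <- numeric(keep)
    for (i in seq_len(keep)) {
      indep <- stats::runif(1) < 0.25
      if (indep) {
        prop <- r_ind()
        cand <- logpost(prop)
        lr <- cand["lp"] - cur["lp"] + d_ind(th) - d_ind(prop)
      } else {
        prop <- th + as.numeric(stats::rnorm(d) %*% cS_rw)
        cand <- logpost(prop)
        lr <- cand["lp"] - cur["lp"]
      }
      if (is.finite(lr) && log(stats::runif(1)) < lr) { th <- prop; cur <- cand }
      u <- unpack(th)
      p_dr[i, ] <- u$p
      s_dr[i, ] <- u$sig
      ll_dr[i] <- cur["ll"]
    }
    list(p = p_dr, sigma = s_dr, loglik = ll_dr)
  }

  ch <- lapply(seq_len(chains), function(c)
    run_chain(warm[[c]], chain_seeds[c]))

  p_pool <- do.call(rbind, lapply(ch, `[[`, "p"))
  colnames(p_pool) <- sources$name
  s_pool <- do.call(rbind, lapply(ch, `[[`, "sigma"))
  colnames(s_pool) <- c("sigma_d13C", "sigma_d15N")
  ll_pool <- unlist(lapply(ch, `[[`, "loglik"))

  par_mats <- lapply(seq_len(chains), function(c)
    cbind(ch[[c]]$p, ch[[c]]$sigma))
  rh <- split_rhat(par_mats)
  names(rh) <- c(sources$name, "sigma_d13C", "sigma_d15N")
  if (K == 1) rh <- rh[-1]  # p is fixed at 1

  structure(list(
    source_names = sources$name, K = K,
    p = p_pool, sigma = s_pool, loglik = ll_pool,
    deviance_draws = -2 * ll_pool,
    chains = ch, n_chains = chains, iterations = iterations,
    burn_in = burn_in, seed = as.integer(seed), prior = prior,
    sigma_prior_sd = sigma_prior_sd,
    rhat = rh, converged = all(rh <= 1.1, na.rm = TRUE),
    consumers = consumers, sources = sources, tef = tef),
    class = "mixing_fit")
}

# split-chain Gelman-Rubin R-hat; input: list of (draws x params) matrices
split_rhat <- function(par_mats) {
  halves <- list()
  for (m in par_mats) {
    n2 <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(n2), , drop = FALSE],
                             m[(nrow(m) - n2 + 1):nrow(m), , drop = FALSE]))
  }
  nseq <- length(halves); L <- nrow(halves[[1]]); P <- ncol(halves[[1]])
  vapply(seq_len(P), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- L * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((L - 1) / L * W + B / L) / W)
  }, numeric(1))
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf("Bayesian mixing model: %d sources, %d consumers\n",
              x$K, nrow(x$consumers)))
  cat(sprintf("  %d chains x %d iterations (%d burn-in); %s\n",
              x$n_chains, x$iterations, x$burn_in,
              if (x$converged) "converged (all R-hat <= 1.1)"
              else "NOT converged (R-hat > 1.1)"))
  print(mixing_summary(x), digits = 3)
  invisible(x)
}

#' Posterior summary table of source contributions
#'
#' Mean, SD, and 95% credible interval of each source's contribution, in
#' percent, with the residual SDs (per mil) and R-hat per parameter.
#'
#' @param fit A `mixing_fit`.
#' @return Data frame with one row per source and per residual SD.
#' @export
mixing_summary <- function(fit) {
  stopifnot(inherits(fit, "mixing_fit"))
  qs <- function(m) t(apply(m, 2, stats::quantile, c(0.025, 0.975)))
  pq <- qs(fit$p); sq <- qs(fit$sigma)
  prh <- fit$rhat[colnames(fit$p)]
  srh <- fit$rhat[colnames(fit$sigma)]
  rbind(
    data.frame(parameter = colnames(fit$p), unit = "%",
               mean = 100 * colMeans(fit$p), sd = 100 * apply(fit$p, 2, stats::sd),
               ci_2.5 = 100 * pq[, 1], ci_97.5 = 100 * pq[, 2],
               rhat = as.numeric(prh), row.names = NULL),
    data.frame(parameter = colnames(fit$sigma), unit = "permil",
               mean = colMeans(fit$sigma), sd = apply(fit$sigma, 2, stats::sd),
               ci_2.5 = sq[, 1], ci_97.5 = sq[, 2],
               rhat = as.numeric(srh), row.names = NULL))
}

#' Posterior of a combined (summed) contribution
#'
#' Distribution of the summed diet proportion over a subset of sources, e.g.
#' a functionally equivalent prey pool whose members are isotopically
#' inseparable.
#'
#' @param fit A `mixing_fit`.
#' @param subset Character vector of source names.
#' @return List `draws`, `mean`, `sd`, `ci` (95% credible interval), on the
#'   proportion scale.
#' @export
combined_contribution <- function(fit, subset) {
  stopifnot(inherits(fit, "mixing_fit"))
  if (length(subset) == 0) stop("subset must be non-empty")
  bad <- setdiff(subset, fit$source_names)
  if (length(bad)) stop("unknown source label(s): ", paste(bad, collapse = ", "))
  s <- rowSums(fit$p[, subset, drop = FALSE])
  list(draws = s, mean = mean(s), sd = stats::sd(s),
       ci = stats::quantile(s, c(0.025, 0.975), names = FALSE))
}

#' Pairwise posterior correlations of source contributions
#'
#' Pearson correlations of the pooled post-burn-in proportion draws. Strongly
#' negative entries signal isotopically inseparable sources whose individual
#' contributions trade off while their sum stays stable.
#'
#' @param fit A `mixing_fit`.
#' @return K x K symmetric correlation matrix (unit diagonal).
#' @export
posterior_correlation <- function(fit) {
  stopifnot(inherits(fit, "mixing_fit"))
  if (nrow(fit$p) < 2) stop("need >= 2 retained draws")
  sds <- apply(fit$p, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant draws for some source(s); correlations set to NA")
    cm <- matrix(NA_real_, fit$K, fit$K,
                 dimnames = list(fit$source_names, fit$source_names))
    diag(cm) <- 1
    ok <- sds > 0
    cm[ok, ok] <- stats::cor(fit$p[, ok, drop = FALSE])
    return(cm)
  }
  stats::cor(fit$p)
}

#' Posterior predictive check
#'
#' Draws replicate datasets from the fitted likelihood and summarises, per
#' consumer and tracer, the predictive mean and central 50% / 95% intervals,
#' together with the fraction of observations covered by each interval.
#'
#' @param fit A `mixing_fit`.
#' @param n_rep Number of posterior draws used for replication (thinned from
#'   the pooled draws; default 2000).
#' @param seed Integer seed.
#' @return List with `table` (per consumer x tracer predictive summaries and
#'   observed values) and `coverage` (named fractions for the 50% and 95%
#'   intervals).
#' @export
posterior_predictive <- function(fit, n_rep = 2000, seed = 1L) {
  stopifnot(inherits(fit, "mixing_fit"))
  idx <- unique(round(seq(1, nrow(fit$p), length.out = min(n_rep, nrow(fit$p)))))
  mu_s <- cbind(fit$sources$mean_d13C + fit$tef$mean_d13C,
                fit$sources$mean_d15N + fit$tef$mean_d15N)
  v_s <- cbind(fit$sources$sd_d13C^2 + fit$tef$sd_d13C^2,
               fit$sources$sd_d15N^2 + fit$tef$sd_d15N^2)
  P <- fit$p[idx, , drop = FALSE]
  SG <- fit$sigma[idx, , drop = FALSE]
  mu_mix <- P %*% mu_s                    # draws x 2
  sd_mix <- sqrt(P^2 %*% v_s + SG^2)
  set.seed(seed)
  nd <- nrow(P)
  yrep <- mu_mix + matrix(stats::rnorm(nd * 2), nd, 2) * sd_mix
  y <- cbind(fit$consumers$d13C, fit$consumers$d15N)
  tracer <- c("d13C", "d15N")
  tab <- do.call(rbind, lapply(1:2, function(j) {
    qs <- stats::quantile(yrep[, j], c(0.025, 0.25, 0.75, 0.975))
    data.frame(sample_id = fit$consumers$sample_id, tracer = tracer[j],
               observed = y[, j], pred_mean = mean(yrep[, j]),
               lo95 = qs[1], lo50 = qs[2], hi50 = qs[3], hi95 = qs[4],
               row.names = NULL)
  }))
  cov50 <- mean(tab$observed >= tab$lo50 & tab$observed <= tab$hi50)
  cov95 <- mean(tab$observed >= tab$lo95 & tab$observed <= tab$hi95)
  list(table = tab, coverage = c(cov50 = cov50, cov95 = cov95))
}

#' Prior versus posterior concentration per source
#'
#' Under a Dirichlet(a) prior the marginal prior of p_k is
#' Beta(a_k, sum(a) - a_k) (Beta(1, K - 1) for the flat prior). For each
#' source this compares that marginal with the posterior draws via an overlap
#' coefficient on a common histogram grid: values well below 1 indicate
#' data-driven (not prior-driven) inference.
#'
#' @param fit A `mixing_fit`.
#' @param n_bins Histogram bins on \[0, 1\].
#' @return Data frame `source, prior_mean, posterior_mean, overlap_coef`.
#' @export
prior_vs_posterior <- function(fit, n_bins = 50) {
  stopifnot(inherits(fit, "mixing_fit"))
  a <- fit$prior; a0 <- sum(a)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- diff(breaks)
  out <- lapply(seq_len(fit$K), function(k) {
    prior_d <- stats::dbeta(mids, a[k], a0 - a[k])
    h <- graphics::hist(fit$p[, k], breaks = breaks, plot = FALSE)
    ovl <- sum(pmin(prior_d, h$density) * w)
    data.frame(source = fit$source_names[k], prior_mean = a[k] / a0,
               posterior_mean = mean(fit$p[, k]), overlap_coef = ovl)
  })
  do.call(rbind, out)
}

#' Posterior mean deviance
#'
#' Mean over retained draws of -2 x log-likelihood of the data, the usual
#' raw model-fit measure for comparing source configurations.
#'
#' @param object A `mixing_fit`.
#' @param ... Unused.
#' @return Scalar posterior mean deviance.
#' @export
deviance.mixing_fit <- function(object, ...) {
  mean(object$deviance_draws)
}
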