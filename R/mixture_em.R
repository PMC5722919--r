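# Finite mixture of linear regressions with brain regions as latent units.
#
# Model: event i in region r has rat_pcd_i ~ Normal(a_k * human_pcw_i + b_k,
# sigma_k^2) given region r belongs to group k; P(group k) = pi_k. The latent
# label attaches to the REGION, so the E-step responsibility of a region is
# proportional to pi_k times the product of its events' densities.

.em_prepare <- function(table) {
  if (nrow(table) == 0) abort("empty event table", "devtrans_domain_error")
  f <- factor(table$region, levels = unique(table$region))
  list(x = table$human_pcw, y = table$rat_pcd, f = f,
       idx = as.integer(f), n = nrow(table), R = nlevels(f),
       regions = levels(f))
}

# n x K matrix of per-event log densities under each group.
.log_density_matrix <- function(x, y, groups) {
  n <- length(x)
  K <- nrow(groups)
  pred <- x %o% groups$slope + rep(groups$intercept, each = n)
  matrix(
    stats::dnorm(y - as.vector(pred), mean = 0,
                 sd = rep(groups$sigma, each = n), log = TRUE),
    n, K
  )
}

#' Gaussian residual density of one event under one group
#'
#' @param event A single-row [event_table()] (or list with `human_pcw`,
#'   `rat_pcd`).
#' @param params List or single-row data.frame with `slope`, `intercept` and
#'   `sigma` (> 0).
#' @return The Normal density of the residual
#'   `rat_pcd - (slope * human_pcw + intercept)` at scale `sigma`.
#' @export
group_density <- function(event, params) {
  if (params$sigma <= 0) abort("sigma must be positive", "devtrans_domain_error")
  stats::dnorm(event$rat_pcd - (params$slope * event$human_pcw + params$intercept),
               mean = 0, sd = params$sigma)
}

#' Observed-data log-likelihood of a mixture of regressions
#'
#' Sum over regions of `log sum_k pi_k * prod_{i in r} density(event_i | k)`,
#' computed in the log domain.
#'
#' @param table An [event_table()].
#' @param groups Data.frame with columns `slope`, `intercept`, `sigma`,
#'   `weight` (one row per group; weights sum to 1).
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(table, groups) {
  p <- .em_prepare(table)
  logd <- .log_density_matrix(p$x, p$y, groups)
  region_ll <- rowsum(logd, p$f)                     # R x K
  a <- sweep(region_ll, 2, log(groups$weight), "+")
  sum(logsumexp_rows(a))
}

.estep <- function(p, groups) {
  logd <- .log_density_matrix(p$x, p$y, groups)
  region_ll <- rowsum(logd, p$f)
  a <- sweep(region_ll, 2, log(groups$weight), "+")
  lse <- logsumexp_rows(a)
  if (any(!is.finite(lse))) {
    bad <- p$regions[which(!is.finite(lse))[1]]
    abort(sprintf("responsibility underflow for region '%s'", bad),
          "devtrans_numerical_error")
  }
  gamma <- exp(a - lse)
  rownames(gamma) <- p$regions
  list(gamma = gamma, loglik = sum(lse))
}

# Responsibility-weighted least squares for all K groups at once.
# W is n x K per-event weights. Returns groups data.frame or a failure string.
.mstep <- function(x, y, W, sigma_floor, min_group_events) {
  ess <- colSums(W)
  if (any(ess < min_group_events)) {
    return(list(failure = sprintf(
      "effective event count %.3g in group %d below minimum %g (sigma not estimable)",
      min(ess), which.min(ess), min_group_events)))
  }
  sx <- colSums(W * x); sy <- colSums(W * y)
  sxx <- colSums(W * x * x); sxy <- colSums(W * x * y)
  vxx <- sxx - sx^2 / ess
  if (any(vxx <= 1e-10)) {
    return(list(failure = sprintf(
      "degenerate design in group %d (weighted x-variance ~ 0)",
      which(vxx <= 1e-10)[1])))
  }
  slope <- (sxy - sx * sy / ess) / vxx
  intercept <- sy / ess - slope * sx / ess
  n <- length(x)
  res <- y - (x %o% slope + rep(intercept, each = n))
  sigma2 <- colSums(W * res^2) / ess
  sigma <- pmax(sqrt(sigma2), sigma_floor)
  list(groups = data.frame(slope = slope, intercept = intercept,
                           sigma = sigma, weight = ess / sum(ess)),
       ess = ess)
}

#' Region-level responsibilities given group parameters
#'
#' E-step of the EM algorithm: the posterior probability that each region
#' belongs to each group, proportional to the group weight times the product
#' of the region's per-event Gaussian densities. Computed in the log domain.
#'
#' @inheritParams mixture_loglik
#' @return Region x group matrix with rows summing to 1 (rownames are
#'   region labels).
#' @export
region_responsibilities <- function(table, groups) {
  if (any(groups$sigma <= 0)) abort("sigma must be positive", "devtrans_domain_error")
  .estep(.em_prepare(table), groups)$gamma
}

#' Weighted least-squares fit of one regression group
#'
#' The M-step primitive: `(slope, intercept)` solve the weighted normal
#' equations and `sigma` is the maximum-likelihood (weighted mean squared
#' residual) estimate, floored at `sigma_floor`.
#'
#' @param table An [event_table()].
#' @param weights Per-event non-negative weights, summing to > 0.
#' @param sigma_floor Lower bound applied to the residual SD.
#' @return List with `slope`, `intercept`, `sigma`, `ess` (effective sample
#'   size, the weight sum) and `degenerate` (`TRUE` when the unfloored sigma
#'   fell below `sigma_floor`, e.g. exact interpolation).
#' @export
weighted_group_fit <- function(table, weights, sigma_floor = 1e-3) {
  stopifnot(length(weights) == nrow(table))
  if (sum(weights) <= 0) abort("weights must sum to > 0", "devtrans_domain_error")
  x <- table$human_pcw; y <- table$rat_pcd; w <- weights
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vxx <- sum(w * (x - mx)^2)
  if (vxx <= 1e-10) {
    abort("degenerate design: weighted x-variance is zero",
          "devtrans_degenerate_error")
  }
  slope <- sum(w * (x - mx) * (y - my)) / vxx
  intercept <- my - slope * mx
  sigma_raw <- sqrt(sum(w * (y - slope * x - intercept)^2) / sw)
  list(slope = slope, intercept = intercept,
       sigma = max(sigma_raw, sigma_floor), ess = sw,
       degenerate = sigma_raw < sigma_floor)
}

.groups_from_assignment <- function(p, z, K, sigma_floor, min_group_events) {
  W <- matrix(0, p$n, K)
  W[cbind(seq_len(p$n), z[p$idx])] <- 1
  .mstep(p$x, p$y, W, sigma_floor, min_group_events)
}

#' Fit a K-group mixture of regressions by EM
#'
#' Alternates region-level responsibilities (E) with responsibility-weighted
#' least squares plus weight updates `pi_k = mean_r gamma_rk` (M) until the
#' log-likelihood change falls below `tol` or `max_iter` is reached. A group
#' whose effective event count drops below `min_group_events` (sigma no
#' longer estimable — the failure mode that caps the usable number of
#' groups) marks the fit non-converged rather than raising.
#'
#' @param table An [event_table()]; must have at least `K` regions.
#' @param K Number of groups (>= 1).
#' @param init Either an integer vector assigning each region (in first-
#'   appearance order) to a group in `1:K`, or a `groups` data.frame with
#'   `slope`, `intercept`, `sigma`, `weight`. `NULL` is allowed only for
#'   `K = 1`.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound on each group's residual SD (pcd).
#' @param min_group_events Minimum effective event count per group.
#' @return A `mixture_fit`: list with `K`, `groups` (slope/intercept/sigma/
#'   weight per group), `responsibilities` (region x group), `loglik`, `aic`
#'   (`-2 loglik + 2 (4K - 1)`), `converged`, `n_iter`, `loglik_trace` and
#'   `failure` (message or `NULL`).
#' @export
fit_em <- function(table, K, init = NULL, tol = 1e-8, max_iter = 500,
                   sigma_floor = 1e-3, min_group_events = 3) {
  if (K < 1) abort("K must be >= 1", "devtrans_argument_error")
  p <- .em_prepare(table)
  if (K > p$R) {
    abort(sprintf("K = %d exceeds the number of regions (%d)", K, p$R),
          "devtrans_argument_error")
  }

  make_fit <- function(groups, gamma, loglik, converged, n_iter, trace,
                       failure = NULL) {
    structure(
      list(K = K, groups = groups, responsibilities = gamma, loglik = loglik,
           aic = -2 * loglik + 2 * (4 * K - 1), converged = converged,
           n_iter = n_iter, loglik_trace = trace, failure = failure),
      class = "mixture_fit"
    )
  }

  if (is.null(init)) {
    if (K != 1) abort("init is required for K > 1", "devtrans_argument_error")
    init <- rep(1L, p$R)
  }
  if (is.data.frame(init)) {
    stopifnot(nrow(init) == K)
    groups <- init
  } else {
    z <- as.integer(init)
    stopifnot(length(z) == p$R, all(z >= 1L & z <= K))
    m <- .groups_from_assignment(p, z, K, sigma_floor, min_group_events)
    if (!is.null(m$failure)) {
      gamma <- matrix(NA_real_, p$R, K, dimnames = list(p$regions, NULL))
      return(make_fit(NULL, gamma, -Inf, FALSE, 0L, numeric(0), m$failure))
    }
    groups <- m$groups
    groups$weight <- as.vector(table(factor(z, levels = 1:K))) / p$R
  }
  if (any(groups$weight <= 0)) {
    groups$weight <- pmax(groups$weight, 1e-12)
    groups$weight <- groups$weight / sum(groups$weight)
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  gamma <- NULL
  failure <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e <- .estep(p, groups)
    trace <- c(trace, e$loglik)
    gamma <- e$gamma
    if (it > 1L && abs(e$loglik - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
    W <- e$gamma[p$idx, , drop = FALSE]
    m <- .mstep(p$x, p$y, W, sigma_floor, min_group_events)
    if (!is.null(m$failure)) {
      failure <- m$failure
      break
    }
    groups <- m$groups
    groups$weight <- colMeans(e$gamma)
  }
  if (!converged && is.null(failure)) {
    # max_iter exhausted: one final E-step so responsibilities match params
    e <- .estep(p, groups)
    trace <- c(trace, e$loglik)
    gamma <- e$gamma
    failure <- sprintf("max_iter = %d reached without convergence", max_iter)
  }
  make_fit(groups, gamma, trace[length(trace)], converged, it, trace, failure)
}

#' Best-of-many EM fits from random initial region assignments
#'
#' EM on mixtures of regressions is sensitive to its starting values, so the
#' search draws `n_restarts` random hard region assignments (uniform over
#' groups, each group seeded with at least one region), runs [fit_em()] from
#' each, and keeps the converged fit with minimal AIC (at fixed `K` that is
#' the maximal log-likelihood). Fully reproducible given `seed`; ties go to
#' the earlier restart.
#'
#' @inheritParams fit_em
#' @param n_restarts Number of random initialisations (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param ... Passed on to [fit_em()].
#' @return The best `mixture_fit`, with extra fields `seed`, `n_restarts`
#'   and `n_converged`.
#' @export
random_restart_search <- function(table, K, n_restarts = 200, seed = NULL, ...) {
  if (n_restarts < 1) abort("n_restarts must be >= 1", "devtrans_argument_error")
  p <- .em_prepare(table)
  if (K > p$R) {
    abort(sprintf("K = %d exceeds the number of regions (%d)", K, p$R),
          "devtrans_argument_error")
  }
  if (K == 1) {
    fit <- fit_em(table, 1L, init = rep(1L, p$R), ...)
    fit$seed <- seed; fit$n_restarts <- 1L
    fit$n_converged <- as.integer(fit$converged)
    if (!fit$converged) {
      abort(sprintf("single-group fit failed: %s", fit$failure),
            "devtrans_search_error")
    }
    return(fit)
  }
  inits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      z <- integer(p$R)
      perm <- sample.int(p$R)
      z[perm[1:K]] <- 1:K
      if (p$R > K) z[perm[(K + 1):p$R]] <- sample.int(K, p$R - K, replace = TRUE)
      z
    })
  })
  best <- NULL
  n_converged <- 0L
  failures <- character(0)
  for (z in inits) {
    fit <- fit_em(table, K, init = z, ...)
    if (fit$converged) {
      n_converged <- n_converged + 1L
      if (is.null(best) || fit$aic < best$aic - 1e-12) best <- fit
    } else {
      failures <- c(failures, fit$failure)
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "no EM restart converged in %d attempts; failure modes: %s",
      n_restarts, paste(unique(failures), collapse = " | ")),
      "devtrans_search_error")
  }
  best$seed <- seed
  best$n_restarts <- n_restarts
  best$n_converged <- n_converged
  best
}

#' Exhaustive search over hard region assignments
#'
#' Independent reference for the EM search on small instances: enumerates
#' every region-to-group hard assignment, fits each group by OLS with the
#' maximum-likelihood residual SD, and maximises the complete-data
#' log-likelihood (per-event Gaussian terms plus `log pi_k` region terms
#' with `pi_k` the group's region share). Assignments leaving a group with
#' fewer than 2 events or zero x-variance are inadmissible. Ties are broken
#' by the lexicographically smallest assignment vector.
#'
#' @inheritParams fit_em
#' @return List with `assignment` (named integer vector), `loglik`, `groups`
#'   and `n_evaluated`.
#' @export
exhaustive_assignment_oracle <- function(table, K, sigma_floor = 1e-3) {
  p <- .em_prepare(table)
  n_assign <- K^p$R
  if (n_assign > 1e6) {
    abort(sprintf("instance too large: %d^%d assignments", K, p$R),
          "devtrans_size_error")
  }
  best_ll <- -Inf
  best_z <- NULL
  best_groups <- NULL
  z <- rep(1L, p$R)
  repeat {
    counts <- tabulate(z, nbins = K)
    ll <- 0
    groups <- data.frame(slope = rep(NA_real_, K), intercept = NA_real_,
                         sigma = NA_real_, weight = counts / p$R)
    ok <- TRUE
    for (k in seq_len(K)) {
      if (counts[k] == 0) next
      sel <- z[p$idx] == k
      xk <- p$x[sel]; yk <- p$y[sel]
      if (length(xk) < 2 || stats::var(xk) <= 1e-12) { ok <- FALSE; break }
      mx <- mean(xk); my <- mean(yk)
      a <- sum((xk - mx) * (yk - my)) / sum((xk - mx)^2)
      b <- my - a * mx
      s <- max(sqrt(mean((yk - a * xk - b)^2)), sigma_floor)
      groups$slope[k] <- a; groups$intercept[k] <- b; groups$sigma[k] <- s
      ll <- ll + sum(stats::dnorm(yk - a * xk - b, sd = s, log = TRUE)) +
        counts[k] * log(counts[k] / p$R)
    }
    if (ok && ll > best_ll + 1e-12) {
      best_ll <- ll; best_z <- z; best_groups <- groups
    }
    # advance counter in lexicographic order (last region fastest)
    j <- p$R
    while (j >= 1L && z[j] == K) { z[j] <- 1L; j <- j - 1L }
    if (j < 1L) break
    z[j] <- z[j] + 1L
  }
  if (is.null(best_z)) {
    abort("no admissible assignment (every split leaves a degenerate group)",
          "devtrans_degenerate_error")
  }
  names(best_z) <- p$regions
  list(assignment = best_z, loglik = best_ll, groups = best_groups,
       n_evaluated = n_assign)
}

#' Hard region-to-group assignments of a fit
#'
#' @param fit A `mixture_fit`.
#' @return Named integer vector: each region's maximum-responsibility group.
#' @export
hard_assignments <- function(fit) {
  z <- max.col(fit$responsibilities, ties.method = "first")
  names(z) <- rownames(fit$responsibilities)
  z
}

#' Event-level posterior group probabilities
#'
#' Unlike the region-level responsibilities that drive the EM, each event is
#' here classified on its own: posterior proportional to
#' `pi_k * density(event | group k)`. An event's maximum-posterior group can
#' therefore disagree with its region's group, which is informative —
#' events close to the onset of neurogenesis are intrinsically hard to
#' classify because the group lines converge there.
#'
#' @param fit A converged `mixture_fit`.
#' @param table An [event_table()] (any events, not only those used to fit).
#' @return Event x group matrix of posteriors, rows summing to 1.
#' @export
event_posteriors <- function(fit, table) {
  if (!isTRUE(fit$converged)) {
    abort("fit did not converge", "devtrans_domain_error")
  }
  logd <- .log_density_matrix(table$human_pcw, table$rat_pcd, fit$groups)
  a <- sweep(logd, 2, log(fit$groups$weight), "+")
  post <- exp(a - logsumexp_rows(a))
  rownames(post) <- as.character(table$event_id)
  post
}

#' Root mean squared prediction error of a fitted mixture
#'
#' Each event is predicted from its region's maximum-responsibility group's
#' regression line; the RMSE is over all events, in rat pcd.
#'
#' @inheritParams event_posteriors
#' @return RMSE in days.
#' @export
model_rmse <- function(fit, table) {
  if (nrow(table) == 0) abort("empty event table", "devtrans_domain_error")
  z <- hard_assignments(fit)
  unknown <- setdiff(unique(table$region), names(z))
  if (length(unknown) > 0) {
    abort(sprintf("region(s) not in fit: %s", paste(unknown, collapse = ", ")),
          "devtrans_lookup_error")
  }
  g <- z[table$region]
  pred <- fit$groups$slope[g] * table$human_pcw + fit$groups$intercept[g]
  sqrt(mean((table$rat_pcd - pred)^2))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-group mixture of regressions (%s, %d EM iterations)\n",
              x$K, if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iter))
  cat(sprintf("  loglik %.3f  AIC %.3f\n", x$loglik, x$aic))
  if (!is.null(x$groups)) {
    gg <- x$groups
    for (k in seq_len(nrow(gg))) {
      cat(sprintf("  group %d: rat_pcd = %.3f * human_pcw + %.3f  (sigma %.3f, pi %.3f)\n",
                  k, gg$slope[k], gg$intercept[k], gg$sigma[k], gg$weight[k]))
    }
  }
  invisible(x)
}
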