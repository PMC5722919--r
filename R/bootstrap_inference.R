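# Bootstrap estimation and testing of group-wise developmental pace (slope)
# and onset (predicted rat pcd at human neural tube closure, 4 pcw).

.ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vxx <- sum((x - mx)^2)
  if (vxx <= 1e-10) {
    abort("degenerate design: zero x-variance", "devtrans_degenerate_error")
  }
  slope <- sum((x - mx) * (y - my)) / vxx
  c(slope = slope, intercept = my - slope * mx)
}

# Vectorised case resampling: B OLS fits on resamples of (x, y), degenerate
# columns redrawn. Returns slope/intercept/onset replicate vectors.
.boot_line_reps <- function(x, y, B, onset_pcw = 4) {
  n <- length(x)
  slope <- intercept <- rep(NA_real_, B)
  need <- seq_len(B)
  n_redrawn <- 0L
  while (length(need) > 0) {
    idx <- matrix(sample.int(n, n * length(need), replace = TRUE), n)
    X <- matrix(x[idx], n); Y <- matrix(y[idx], n)
    sx <- colSums(X); sy <- colSums(Y)
    vxx <- colSums(X * X) - sx^2 / n
    a <- (colSums(X * Y) - sx * sy / n) / vxx
    b <- (sy - a * sx) / n
    ok <- vxx > 1e-10
    slope[need[ok]] <- a[ok]
    intercept[need[ok]] <- b[ok]
    n_redrawn <- n_redrawn + sum(!ok)
    if (n_redrawn >= max(B, 10) * 50) {
      abort("persistent degenerate resamples (zero x-variance)",
            "devtrans_degenerate_error")
    }
    need <- need[!ok]
  }
  list(slope = slope, intercept = intercept,
       onset = onset_pcw * slope + intercept, n_redrawn = n_redrawn)
}

.point_stat <- function(x, y, statistic, onset_pcw = 4) {
  li <- .ols_line(x, y)
  switch(statistic,
         slope = unname(li["slope"]),
         onset = unname(onset_pcw * li["slope"] + li["intercept"]))
}

#' Bootstrap distribution of a group's developmental pace and onset
#'
#' Resamples the group's events with replacement (resample size equal to the
#' group size) `n_outer` times; each resample is fitted by ordinary least
#' squares, yielding replicate slopes (pace, pcd per pcw) and onsets
#' (predicted rat pcd at human `onset_pcw`, default 4 pcw — neural tube
#' closure). Degenerate resamples (zero x-variance) are redrawn; a redraw
#' rate of 50% or more raises a degeneracy error.
#'
#' @param group_events [event_table()] subset with >= 3 events.
#' @param n_outer Number of bootstrap replicates.
#' @param seed Integer seed or `NULL`.
#' @param onset_pcw Human anchor age (pcw) at which onset is read off.
#' @return A `group_summary`: `slope_mean`, `slope_sd`, `onset_mean`,
#'   `onset_sd`, replicate vectors `slope_reps`/`onset_reps`, `n_events`,
#'   `n_outer`, `seed`.
#' @export
bootstrap_slope_onset <- function(group_events, n_outer = 1000, seed = NULL,
                                  onset_pcw = 4) {
  if (nrow(group_events) < 3) {
    abort("group must have >= 3 events", "devtrans_domain_error")
  }
  x <- group_events$human_pcw; y <- group_events$rat_pcd
  reps <- with_seed(seed, .boot_line_reps(x, y, n_outer, onset_pcw))
  if (reps$n_redrawn >= 0.5 * n_outer) {
    abort(sprintf("degenerate resampling: %d redraws for %d replicates",
                  reps$n_redrawn, n_outer),
          "devtrans_degenerate_error")
  }
  structure(
    list(slope_mean = mean(reps$slope), slope_sd = stats::sd(reps$slope),
         onset_mean = mean(reps$onset), onset_sd = stats::sd(reps$onset),
         slope_reps = reps$slope, onset_reps = reps$onset,
         n_events = nrow(group_events), n_outer = n_outer, seed = seed),
    class = "group_summary"
  )
}

#' Two-sample bootstrap-t test of pace or onset
#'
#' Unequal-variance bootstrap-t comparison of a regression statistic (slope
#' or onset) between two event groups. The studentised statistic is
#' `t = (theta_a - theta_b) / sqrt(v_a + v_b)` with the variances estimated
#' by an inner bootstrap (`n_inner` resamples per group). The null
#' distribution is built by residual centering: each group's responses are
#' shifted by replacing its own fitted line with the pooled fitted line, so
#' both groups share the statistic exactly; `n_outer` resamples of the
#' centered groups give `t*` values (each with its own inner-bootstrap
#' variances). Two-sided p-value with the `(r + 1) / (n_outer + 1)`
#' continuity correction, so p is never exactly 0.
#'
#' @param events_a,events_b [event_table()] subsets with >= 3 events each.
#' @param statistic `"slope"` or `"onset"`.
#' @param n_outer Outer (null-distribution) replicates.
#' @param n_inner Inner (variance-estimation) replicates.
#' @param seed Integer seed or `NULL`.
#' @param onset_pcw Human anchor age for the onset statistic.
#' @return A `bootstrap_test`: `statistic`, `n_combined` (pooled event
#'   count), `observed_diff`, `t_observed`, `p_raw`, `p_adjusted` (`NA`
#'   until adjusted), `n_outer`, `n_inner`, `seed`.
#' @export
bootstrap_t_test <- function(events_a, events_b,
                             statistic = c("slope", "onset"),
                             n_outer = 1000, n_inner = 50, seed = NULL,
                             onset_pcw = 4) {
  statistic <- match.arg(statistic)
  if (nrow(events_a) < 3 || nrow(events_b) < 3) {
    abort("both groups must have >= 3 events", "devtrans_domain_error")
  }
  xa <- events_a$human_pcw; ya <- events_a$rat_pcd
  xb <- events_b$human_pcw; yb <- events_b$rat_pcd

  stat_of <- function(reps) if (statistic == "slope") reps$slope else reps$onset
  safe_t <- function(d, v) {
    if (v <= 0) { if (abs(d) < 1e-12) 0 else sign(d) * Inf } else d / sqrt(v)
  }

  with_seed(seed, {
    theta_a <- .point_stat(xa, ya, statistic, onset_pcw)
    theta_b <- .point_stat(xb, yb, statistic, onset_pcw)
    v_a <- stats::var(stat_of(.boot_line_reps(xa, ya, n_inner, onset_pcw)))
    v_b <- stats::var(stat_of(.boot_line_reps(xb, yb, n_inner, onset_pcw)))
    t_obs <- safe_t(theta_a - theta_b, v_a + v_b)

    # Residual centering: both groups get the pooled line as their truth.
    pooled <- .ols_line(c(xa, xb), c(ya, yb))
    line_a <- .ols_line(xa, ya); line_b <- .ols_line(xb, yb)
    ya_c <- ya - (line_a["slope"] * xa + line_a["intercept"]) +
      pooled["slope"] * xa + pooled["intercept"]
    yb_c <- yb - (line_b["slope"] * xb + line_b["intercept"]) +
      pooled["slope"] * xb + pooled["intercept"]

    na <- length(xa); nb <- length(xb)
    t_star <- numeric(n_outer)
    redraws <- 0L
    for (j in seq_len(n_outer)) {
      repeat {
        ia <- sample.int(na, na, replace = TRUE)
        ib <- sample.int(nb, nb, replace = TRUE)
        ok_a <- sum(xa[ia]^2) - sum(xa[ia])^2 / na > 1e-10
        ok_b <- sum(xb[ib]^2) - sum(xb[ib])^2 / nb > 1e-10
        if (ok_a && ok_b) break
        redraws <- redraws + 1L
        if (redraws >= 0.5 * n_outer && redraws > 20) {
          abort("degenerate resampling in the outer bootstrap loop",
                "devtrans_degenerate_error")
        }
      }
      th_a <- .point_stat(xa[ia], ya_c[ia], statistic, onset_pcw)
      th_b <- .point_stat(xb[ib], yb_c[ib], statistic, onset_pcw)
      va <- stats::var(stat_of(.boot_line_reps(xa[ia], ya_c[ia], n_inner, onset_pcw)))
      vb <- stats::var(stat_of(.boot_line_reps(xb[ib], yb_c[ib], n_inner, onset_pcw)))
      t_star[j] <- safe_t(th_a - th_b, va + vb)
    }
    p_raw <- (sum(abs(t_star) >= abs(t_obs)) + 1) / (n_outer + 1)

    structure(
      list(statistic = statistic, group_a = NA_character_,
           group_b = NA_character_,
           n_combined = na + nb, observed_diff = theta_a - theta_b,
           t_observed = t_obs, p_raw = p_raw, p_adjusted = NA_real_,
           n_outer = n_outer, n_inner = n_inner, seed = seed),
      class = "bootstrap_test"
    )
  })
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control (via [stats::p.adjust()]): adjusted p-values are
#' monotone in the raw ones and invariant to input order; rejection at level
#' `alpha` where the adjusted value is at most `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `p_adjusted` (in input order) and `reject` (logical).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(p_adjusted = numeric(0), reject = logical(0)))
  }
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", "devtrans_domain_error")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = adj <= alpha)
}

#' Order a fit's groups by developmental pace and attach labels
#'
#' Relabels the groups of a `mixture_fit` in slope-descending order as
#' `A<K>, B<K>, ...` (e.g. `A2`/`B2` for a two-group model), reordering the
#' parameter table and responsibility columns consistently. Log-likelihood,
#' AIC and RMSE are invariant under this permutation.
#'
#' @param fit A `mixture_fit`.
#' @return The fit with a `label` column on `groups` and reordered columns.
#' @export
label_groups <- function(fit) {
  ord <- order(fit$groups$slope, decreasing = TRUE)
  fit$groups <- fit$groups[ord, , drop = FALSE]
  rownames(fit$groups) <- NULL
  fit$groups$label <- paste0(LETTERS[seq_len(fit$K)], fit$K)
  fit$responsibilities <- fit$responsibilities[, ord, drop = FALSE]
  colnames(fit$responsibilities) <- fit$groups$label
  fit
}

.events_by_group <- function(fit, table) {
  z <- hard_assignments(fit)
  unknown <- setdiff(unique(table$region), names(z))
  if (length(unknown) > 0) {
    abort(sprintf("region(s) not in fit: %s", paste(unknown, collapse = ", ")),
          "devtrans_lookup_error")
  }
  split(seq_len(nrow(table)), factor(z[table$region], levels = seq_len(fit$K)))
}

#' All pairwise bootstrap-t comparisons among a fit's groups
#'
#' Runs [bootstrap_t_test()] for every unordered group pair, for both the
#' slope and the onset statistic, with group membership taken from the hard
#' (maximum-responsibility) region assignments. Benjamini-Hochberg
#' adjustment is applied within each statistic family by default (slopes
#' and onsets are reported as separate analyses), or jointly.
#'
#' @param fit A converged `mixture_fit` with `K >= 2` (labelled via
#'   [label_groups()] if not already).
#' @param table The [event_table()] the fit refers to.
#' @param n_outer,n_inner Bootstrap replicate counts per test.
#' @param seed Integer seed or `NULL`; per-test seeds are derived from it.
#' @param alpha FDR level.
#' @param bh_family `"per_statistic"` or `"joint"`.
#' @param onset_pcw Human anchor age for onsets.
#' @return Data.frame (class `pairwise_tests`) with one row per test:
#'   `statistic`, `group_a`, `group_b`, `n_combined`, `observed_diff`,
#'   `p_raw`, `p_adjusted`, `reject`. The label-to-group mapping is kept in
#'   the `"group_labels"` attribute.
#' @export
pairwise_group_tests <- function(fit, table, n_outer = 1000, n_inner = 50,
                                 seed = NULL, alpha = 0.05,
                                 bh_family = c("per_statistic", "joint"),
                                 onset_pcw = 4) {
  bh_family <- match.arg(bh_family)
  if (fit$K < 2) abort("need K >= 2 for pairwise tests", "devtrans_argument_error")
  if (is.null(fit$groups$label)) fit <- label_groups(fit)
  by_group <- .events_by_group(fit, table)
  labels <- fit$groups$label
  pairs <- utils::combn(fit$K, 2)
  rows <- list()
  test_idx <- 0L
  for (statistic in c("slope", "onset")) {
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      test_idx <- test_idx + 1L
      tseed <- if (is.null(seed)) NULL else derive_seed(seed, test_idx)
      tt <- bootstrap_t_test(table[by_group[[i]], , drop = FALSE],
                             table[by_group[[j]], , drop = FALSE],
                             statistic = statistic, n_outer = n_outer,
                             n_inner = n_inner, seed = tseed,
                             onset_pcw = onset_pcw)
      rows[[test_idx]] <- data.frame(
        statistic = statistic, group_a = labels[i], group_b = labels[j],
        n_combined = tt$n_combined, observed_diff = tt$observed_diff,
        t_observed = tt$t_observed, p_raw = tt$p_raw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  if (bh_family == "per_statistic") {
    for (statistic in unique(out$statistic)) {
      sel <- out$statistic == statistic
      out$p_adjusted[sel] <- benjamini_hochberg(out$p_raw[sel], alpha)$p_adjusted
    }
  } else {
    out$p_adjusted <- benjamini_hochberg(out$p_raw, alpha)$p_adjusted
  }
  out$reject <- out$p_adjusted <= alpha
  attr(out, "group_labels") <- stats::setNames(seq_len(fit$K), labels)
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

.components <- function(adj) {
  K <- nrow(adj)
  comp <- integer(K)
  cur <- 0L
  for (s in seq_len(K)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Merge statistically indistinguishable groups
#'
#' Two groups are mergeable when BOTH their pace (slope) and their onset
#' comparison are non-significant after BH adjustment; connected components
#' of the resulting graph become the merged groups. Each merged group is
#' refit two ways: per-group OLS on its member events under the hard labels
#' (the `fit` returned), and a fresh EM initialised at the merged
#' assignment (`em_fit`), for comparison. Merged groups are relabelled in
#' slope-descending order. Merging everything into one group is allowed and
#' flagged.
#'
#' @param fit A labelled, converged `mixture_fit`.
#' @param tests The [pairwise_group_tests()] result covering all pairs.
#' @param table The [event_table()] to refit on.
#' @param alpha Significance level for "different".
#' @param refit_em Also run the EM refit path (default `TRUE`).
#' @param sigma_floor Floor for merged-group residual SDs.
#' @return List with `fit` (hard-label OLS path, a `mixture_fit`),
#'   `em_fit` (or `NULL`), `mapping` (old label -> new label),
#'   `n_groups_before`, `n_groups_after`, `collapsed_to_one`.
#' @export
merge_groups <- function(fit, tests, table, alpha = 0.05, refit_em = TRUE,
                         sigma_floor = 1e-3) {
  if (is.null(fit$groups$label)) fit <- label_groups(fit)
  K <- fit$K
  adj <- diag(K) == 1
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      la <- fit$groups$label[i]; lb <- fit$groups$label[j]
      sel <- (tests$group_a == la & tests$group_b == lb) |
        (tests$group_a == lb & tests$group_b == la)
      if (!any(sel)) {
        abort(sprintf("tests do not cover pair %s vs %s", la, lb),
              "devtrans_argument_error")
      }
      both_ns <- all(tests$p_adjusted[sel] > alpha)
      adj[i, j] <- adj[j, i] <- both_ns
    }
  }
  comp <- .components(adj)
  K_new <- max(comp)

  z_old <- hard_assignments(fit)
  z_new <- comp[z_old]
  names(z_new) <- names(z_old)

  g <- z_new[table$region]
  groups <- do.call(rbind, lapply(seq_len(K_new), function(k) {
    sel <- which(g == k)
    wf <- weighted_group_fit(table[sel, , drop = FALSE], rep(1, length(sel)),
                             sigma_floor = sigma_floor)
    data.frame(slope = wf$slope, intercept = wf$intercept, sigma = wf$sigma,
               weight = mean(z_new == k))
  }))
  ord <- order(groups$slope, decreasing = TRUE)
  groups <- groups[ord, , drop = FALSE]
  rownames(groups) <- NULL
  groups$label <- paste0(LETTERS[seq_len(K_new)], K_new)
  relabel <- match(seq_len(K_new), ord)   # old comp id -> new row
  z_final <- relabel[z_new]
  gamma <- matrix(0, length(z_final), K_new,
                  dimnames = list(names(z_new), groups$label))
  gamma[cbind(seq_along(z_final), z_final)] <- 1

  merged_fit <- structure(
    list(K = K_new, groups = groups, responsibilities = gamma,
         loglik = mixture_loglik(table, groups),
         aic = NA_real_, converged = TRUE, n_iter = 0L,
         loglik_trace = numeric(0), failure = NULL),
    class = "mixture_fit"
  )
  merged_fit$aic <- -2 * merged_fit$loglik + 2 * (4 * K_new - 1)

  em_fit <- NULL
  if (refit_em && K_new < K) {
    em_fit <- tryCatch(
      label_groups(fit_em(table, K_new, init = unname(z_final),
                          sigma_floor = sigma_floor)),
      devtrans_error = function(e) NULL
    )
  } else if (refit_em) {
    em_fit <- merged_fit
  }

  old_to_new <- stats::setNames(groups$label[relabel[comp]],
                                fit$groups$label)

  list(fit = merged_fit, em_fit = em_fit, mapping = old_to_new,
       n_groups_before = K, n_groups_after = K_new,
       collapsed_to_one = K_new == 1)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), via
#' [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2", "devtrans_argument_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          "devtrans_domain_error")
  }
  stats::cor(x, y, method = "spearman")
}
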