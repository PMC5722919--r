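# Bootstrap information criterion (EIC) for choosing the number of groups.
#
# AIC penalises -2 loglik with twice the parameter count; EIC replaces the
# count with a bootstrap estimate of the optimism bias
#   b_hat = mean over bootstrap datasets y* of [ l(theta*; y*) - l(theta*; y) ]
# where theta* is the model refit on y*. EIC = -2 l(theta_hat; y) + 2 b_hat.

# Resample an event table at the latent-unit (region) level: regions drawn
# with replacement, each draw becoming its own unit under a fresh label.
.bootstrap_regions <- function(table) {
  f <- factor(table$region, levels = unique(table$region))
  blocks <- split(seq_len(nrow(table)), f)
  picks <- sample.int(length(blocks), length(blocks), replace = TRUE)
  rows <- lapply(seq_along(picks), function(j) {
    b <- table[blocks[[picks[j]]], , drop = FALSE]
    b$region <- sprintf("unit_%02d", j)
    b
  })
  out <- do.call(rbind, rows)
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

.bootstrap_events <- function(table) {
  out <- table[sample.int(nrow(table), nrow(table), replace = TRUE), ,
               drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Bootstrap information criterion for a K-group mixture
#'
#' Fits the observed table with [random_restart_search()], then estimates
#' the log-likelihood optimism by resampling the table with replacement,
#' refitting each replicate, and averaging
#' `l(theta*; y*) - l(theta*; y)`. The default resamples events (the
#' classical observation bootstrap, which calibrates the optimism of an
#' extra group well); `resample_unit = "region"` resamples whole regions —
#' the latent units — preserving within-region dependence, at the price of
#' replicate-size noise that in simulation under-penalises extra groups.
#' Replicates whose refit fails are redrawn up to `max_redraw` times, then
#' dropped with a warning (`B_effective` records how many survived).
#'
#' @param table An [event_table()].
#' @param K Number of groups.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (controls the observed fit and all replicates).
#' @param n_restarts Restart budget for the observed-data fit.
#' @param replicate_restarts Restart budget inside replicates (defaults to
#'   `n_restarts`).
#' @param resample_unit `"event"` (default) or `"region"` (cluster
#'   bootstrap, for sensitivity analysis).
#' @param max_redraw Redraw attempts per failed replicate slot.
#' @param ... Passed to [fit_em()] via [random_restart_search()].
#' @return An `eic_result`: list with `K`, `eic`, `loglik`, `bias_hat`,
#'   `n_bootstrap`, `B_effective`, `replicate_biases`, `seed` and the
#'   observed-data `fit`.
#' @export
compute_eic <- function(table, K, B = 100, seed = NULL, n_restarts = 200,
                        replicate_restarts = NULL,
                        resample_unit = c("event", "region"),
                        max_redraw = 10, ...) {
  if (B < 1) abort("B must be >= 1", "devtrans_argument_error")
  resample_unit <- match.arg(resample_unit)
  if (is.null(replicate_restarts)) replicate_restarts <- n_restarts
  resample <- switch(resample_unit,
                     region = .bootstrap_regions,
                     event = .bootstrap_events)

  obs_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1000 + K)
  obs_fit <- random_restart_search(table, K, n_restarts = n_restarts,
                                   seed = obs_seed, ...)

  biases <- rep(NA_real_, B)
  n_dropped <- 0L
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, 2000 + K), {
    for (b in seq_len(B)) {
      for (attempt in seq_len(max_redraw + 1L)) {
        boot_tab <- resample(table)
        refit <- tryCatch(
          random_restart_search(boot_tab, K, n_restarts = replicate_restarts,
                                seed = NULL, ...),
          devtrans_error = function(e) NULL
        )
        if (!is.null(refit)) {
          biases[b] <- refit$loglik - mixture_loglik(table, refit$groups)
          break
        }
      }
      if (is.na(biases[b])) n_dropped <- n_dropped + 1L
    }
  })
  if (n_dropped > 0) {
    warning(sprintf("%d of %d EIC replicates dropped after %d redraws each",
                    n_dropped, B, max_redraw))
  }
  biases <- biases[!is.na(biases)]
  if (length(biases) == 0) {
    abort("all EIC bootstrap replicates failed", "devtrans_search_error")
  }
  bias_hat <- mean(biases)
  structure(
    list(K = K, eic = -2 * obs_fit$loglik + 2 * bias_hat,
         loglik = obs_fit$loglik, bias_hat = bias_hat,
         n_bootstrap = B, B_effective = length(biases),
         replicate_biases = biases, seed = seed, fit = obs_fit),
    class = "eic_result"
  )
}

#' Select the number of groups by minimum EIC
#'
#' Evaluates `K = 1, 2, ...` with [compute_eic()], stopping at `K_max` or at
#' the first `K` whose observed-data fit fails to converge (the practical
#' upper limit: past it some group is left with too few events to estimate
#' its residual SD). Returns the `K` with minimal EIC among successful fits.
#'
#' @inheritParams compute_eic
#' @param K_max Largest group count to consider.
#' @return A `k_selection`: list with `selected_K`, `results` (one
#'   `eic_result` per successful `K`), and `failed_K` (first failing `K`,
#'   or `NA`).
#' @export
select_group_count <- function(table, K_max = 6, B = 100, seed = NULL, ...) {
  if (K_max < 1) abort("K_max must be >= 1", "devtrans_argument_error")
  results <- list()
  failed_K <- NA_integer_
  for (K in seq_len(K_max)) {
    res <- tryCatch(
      compute_eic(table, K, B = B, seed = seed, ...),
      devtrans_search_error = function(e) NULL,
      devtrans_argument_error = function(e) NULL
    )
    if (is.null(res)) {
      failed_K <- K
      break
    }
    results[[length(results) + 1L]] <- res
  }
  if (length(results) == 0) {
    abort("no group count produced a converged fit", "devtrans_selection_error")
  }
  eics <- vapply(results, `[[`, numeric(1), "eic")
  structure(
    list(selected_K = results[[which.min(eics)]]$K, results = results,
         failed_K = failed_K),
    class = "k_selection"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.k_selection <- function(x, ...) {
  cat("EIC model-order selection\n")
  for (r in x$results) {
    cat(sprintf("  K = %d: loglik %.3f  bias %.3f  EIC %.2f%s\n",
                r$K, r$loglik, r$bias_hat, r$eic,
                if (r$K == x$selected_K) "  <- selected" else ""))
  }
  if (!is.na(x$failed_K)) {
    cat(sprintf("  K = %d: EM did not converge (stopped)\n", x$failed_K))
  }
  invisible(x)
}
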