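# End-to-end analysis: cluster -> select K -> test -> merge -> refit ->
# posteriors -> translation model, with per-stage seeds derived from one
# master seed.

#' Configuration of the full analysis pipeline
#'
#' Defaults mirror the study settings: clustering on events 1-79 with the
#' birth-related events 47 and 94 excluded throughout, up to 6 candidate
#' groups, 1000 outer / 50 inner bootstrap replicates, significance at
#' 0.05. Restart and EIC replicate budgets default to reduced values that
#' keep a run in the minutes range; `n_restarts = 10000` is the full
#' reproduction setting.
#'
#' @param input Path to an event CSV/TSV, or `NULL` to use `synthetic`.
#' @param synthetic A [synthetic_config()] (default [study_design_config()]).
#' @param clustering_range Inclusive event-id interval used for clustering.
#' @param exclude_ids Event ids excluded from all model fitting.
#' @param K_max Largest group count to consider.
#' @param n_restarts EM restart budget for observed-data fits.
#' @param em_tol EM log-likelihood convergence tolerance.
#' @param eic_B EIC bootstrap replicates per K.
#' @param eic_restarts Restart budget inside EIC replicates.
#' @param n_outer,n_inner Outer/inner bootstrap replicates for tests and
#'   group summaries.
#' @param alpha Significance level / FDR level.
#' @param bh_family BH adjustment family, see [pairwise_group_tests()].
#' @param seed Master seed; every stage seed is derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            clustering_range = c(1, 79),
                            exclude_ids = c(47, 94), K_max = 6,
                            n_restarts = 200, em_tol = 1e-8,
                            eic_B = 100, eic_restarts = 100,
                            n_outer = 1000, n_inner = 50, alpha = 0.05,
                            bh_family = "per_statistic", seed = 1) {
  if (is.null(input) && is.null(synthetic)) synthetic <- study_design_config()
  stopifnot(K_max >= 1, n_restarts >= 1, eic_B >= 1, n_outer >= 1,
            n_inner >= 2, alpha > 0, alpha < 1)
  structure(
    list(input = input, synthetic = synthetic,
         clustering_range = clustering_range, exclude_ids = exclude_ids,
         K_max = K_max, n_restarts = n_restarts, em_tol = em_tol,
         eic_B = eic_B, eic_restarts = eic_restarts, n_outer = n_outer,
         n_inner = n_inner, alpha = alpha, bh_family = bh_family,
         seed = seed),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, devtrans_error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          "devtrans_stage_error")
  })
}

.assignments_out <- function(fit) {
  z <- hard_assignments(fit)
  labels <- fit$groups$label
  if (is.null(labels)) labels <- as.character(seq_len(fit$K))
  as.list(stats::setNames(labels[z], names(z)))
}

.groups_out <- function(fit) {
  g <- fit$groups
  if (is.null(g$label)) g$label <- as.character(seq_len(nrow(g)))
  g[, c("label", "slope", "intercept", "sigma", "weight")]
}

#' Run the full developmental-timing analysis pipeline
#'
#' Stages, in order: (1) load or generate the event table; (2) restrict to
#' the clustering subset; (3) select the group count by EIC; (4) summarise
#' the selected fit (bootstrap slope/onset per group, RMSE); (5) pairwise
#' bootstrap-t tests with BH adjustment; (6) merge statistically
#' indistinguishable groups and re-test; (7) refit the merged model on all
#' non-excluded events; (8) event-level posteriors on the complete table
#' and their rank correlation with human timing; (9) assemble the final
#' translation model. Two runs with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print one line per stage.
#' @return A `pipeline_report`: plain nested list, serialisable with
#'   [write_pipeline_report()].
#' @export
run_full_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(generate = derive_seed(config$seed, 1),
                select = derive_seed(config$seed, 2),
                summaries = derive_seed(config$seed, 3),
                tests = derive_seed(config$seed, 4),
                merged_tests = derive_seed(config$seed, 5),
                merged_summaries = derive_seed(config$seed, 6))

  say("stage 1: input")
  truth <- NULL
  table <- .stage("load", {
    if (!is.null(config$input)) {
      read_event_table(config$input)
    } else {
      out <- generate_dataset(config$synthetic, seed = seeds$generate)
      truth <- out$truth
      out$table
    }
  })

  say("stage 2: clustering subset")
  cluster_tab <- .stage("filter", {
    suppressWarnings(filter_events(table, exclude_ids = config$exclude_ids,
                                   keep_range = config$clustering_range))
  })

  say("stage 3: EIC model-order selection")
  selection <- .stage("select_k", {
    select_group_count(cluster_tab, K_max = config$K_max, B = config$eic_B,
                       seed = seeds$select, n_restarts = config$n_restarts,
                       replicate_restarts = config$eic_restarts,
                       tol = config$em_tol)
  })
  K <- selection$selected_K
  fit <- label_groups(selection$results[[which(
    vapply(selection$results, `[[`, integer(1), "K") == K)]]$fit)

  say("stage 4: selected fit summaries (K = %d)", K)
  summaries <- .stage("summaries", {
    by_group <- .events_by_group(fit, cluster_tab)
    lapply(seq_len(K), function(k) {
      s <- bootstrap_slope_onset(cluster_tab[by_group[[k]], , drop = FALSE],
                                 n_outer = config$n_outer,
                                 seed = derive_seed(seeds$summaries, k))
      list(label = fit$groups$label[k], n_events = s$n_events,
           slope_mean = s$slope_mean, slope_sd = s$slope_sd,
           onset_mean = s$onset_mean, onset_sd = s$onset_sd)
    })
  })
  rmse_selected <- model_rmse(fit, cluster_tab)

  say("stage 5: pairwise bootstrap-t tests")
  tests <- NULL
  if (K >= 2) {
    tests <- .stage("tests", {
      pairwise_group_tests(fit, cluster_tab, n_outer = config$n_outer,
                           n_inner = config$n_inner, seed = seeds$tests,
                           alpha = config$alpha,
                           bh_family = config$bh_family)
    })
  }

  say("stage 6: group merging")
  if (K >= 2) {
    merged <- .stage("merge", {
      merge_groups(fit, tests, cluster_tab, alpha = config$alpha)
    })
  } else {
    merged <- list(fit = fit, em_fit = fit,
                   mapping = stats::setNames(fit$groups$label,
                                             fit$groups$label),
                   n_groups_before = 1L, n_groups_after = 1L,
                   collapsed_to_one = TRUE)
  }
  K2 <- merged$n_groups_after
  merged_tests <- NULL
  merged_summaries <- NULL
  if (K2 >= 2 && K2 < K) {
    merged_tests <- .stage("merged_tests", {
      pairwise_group_tests(merged$fit, cluster_tab, n_outer = config$n_outer,
                           n_inner = config$n_inner,
                           seed = seeds$merged_tests, alpha = config$alpha,
                           bh_family = config$bh_family)
    })
  }
  if (K2 >= 1 && K2 < K) {
    merged_summaries <- .stage("merged_summaries", {
      by_group <- .events_by_group(merged$fit, cluster_tab)
      lapply(seq_len(K2), function(k) {
        s <- bootstrap_slope_onset(cluster_tab[by_group[[k]], , drop = FALSE],
                                   n_outer = config$n_outer,
                                   seed = derive_seed(seeds$merged_summaries, k))
        list(label = merged$fit$groups$label[k], n_events = s$n_events,
             slope_mean = s$slope_mean, slope_sd = s$slope_sd,
             onset_mean = s$onset_mean, onset_sd = s$onset_sd)
      })
    })
  }

  say("stage 7: final refit on all non-excluded events")
  full_tab <- suppressWarnings(
    filter_events(table, exclude_ids = config$exclude_ids))
  final <- .stage("final_refit", {
    em <- fit_em(full_tab, K2, init = merged$fit$groups[
      , c("slope", "intercept", "sigma", "weight")],
      tol = config$em_tol)
    if (!em$converged) {
      abort(sprintf("final EM refit did not converge: %s", em$failure),
            "devtrans_search_error")
    }
    em <- label_groups(em)
    z <- hard_assignments(em)
    ols <- do.call(rbind, lapply(seq_len(K2), function(k) {
      sel <- which(z[full_tab$region] == k)
      wf <- weighted_group_fit(full_tab[sel, , drop = FALSE],
                               rep(1, length(sel)))
      data.frame(label = em$groups$label[k], slope = wf$slope,
                 intercept = wf$intercept, sigma = wf$sigma)
    }))
    list(em_fit = em, ols_groups = ols)
  })
  final_fit <- final$em_fit
  rmse_final <- model_rmse(final_fit, full_tab)

  say("stage 8: event posteriors and rank correlation")
  post <- .stage("posteriors", {
    pp <- event_posteriors(final_fit, table)
    max_post <- apply(pp, 1, max)
    map_group <- final_fit$groups$label[max.col(pp, ties.method = "first")]
    # a single-group model classifies every event with certainty; the rank
    # correlation with timing is then undefined
    rho <- if (K2 >= 2) spearman_rho(max_post, table$human_pcw) else NA_real_
    list(table = data.frame(event_id = table$event_id, region = table$region,
                            max_posterior = unname(max_post),
                            map_group = map_group,
                            human_pcw = table$human_pcw,
                            stringsAsFactors = FALSE),
         spearman_rho = rho)
  })

  say("stage 9: translation model")
  translation <- translation_model_from_fit(final_fit)

  report <- list(
    config = config[setdiff(names(config), "synthetic")],
    seeds = seeds,
    n_events = nrow(table),
    n_events_clustering = nrow(cluster_tab),
    eic = data.frame(
      K = vapply(selection$results, `[[`, integer(1), "K"),
      loglik = vapply(selection$results, `[[`, numeric(1), "loglik"),
      bias_hat = vapply(selection$results, `[[`, numeric(1), "bias_hat"),
      eic = vapply(selection$results, `[[`, numeric(1), "eic"),
      B_effective = vapply(selection$results, `[[`, integer(1), "B_effective")
    ),
    failed_K = selection$failed_K,
    selected_K = K,
    selected_fit = list(groups = .groups_out(fit),
                        assignments = .assignments_out(fit),
                        loglik = fit$loglik, aic = fit$aic,
                        rmse = rmse_selected),
    group_summaries = summaries,
    tests = if (!is.null(tests)) as.data.frame(tests) else NULL,
    merge = list(mapping = as.list(merged$mapping),
                 n_groups_before = merged$n_groups_before,
                 n_groups_after = merged$n_groups_after,
                 collapsed_to_one = merged$collapsed_to_one),
    merged_tests = if (!is.null(merged_tests)) as.data.frame(merged_tests) else NULL,
    merged_summaries = merged_summaries,
    final_model = list(
      em_groups = .groups_out(final_fit),
      ols_groups = final$ols_groups,
      assignments = .assignments_out(final_fit),
      loglik = final_fit$loglik,
      rmse = rmse_final
    ),
    posteriors = post$table,
    spearman_rho = post$spearman_rho,
    translation = list(groups = translation$groups,
                       region_map = as.list(translation$region_map),
                       domain_pcw = translation$domain_pcw),
    truth = if (!is.null(truth)) {
      list(assignments = as.list(truth$assignments), groups = truth$groups)
    } else NULL
  )
  class(report) <- c("pipeline_report", "list")
  report
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
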