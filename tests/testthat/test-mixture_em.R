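test_that("group densities and region responsibilities match direct computation", {
  ev <- list(human_pcw = 10, rat_pcd = 17)
  expect_equal(group_density(ev, list(slope = 1, intercept = 7, sigma = 1)),
               1 / sqrt(2 * pi))
  expect_equal(group_density(ev, list(slope = 1, intercept = 5, sigma = 2)),
               exp(-1 / 2) / (2 * sqrt(2 * pi)))
  expect_error(group_density(ev, list(slope = 1, intercept = 7, sigma = 0)),
               class = "devtrans_domain_error")

  # K = 1: responsibilities are all 1
  tab <- line_table(c(8, 12, 20), a = 1, b = 7, sigma = 0.5, seed = 1)
  g1 <- data.frame(slope = 1, intercept = 7, sigma = 1, weight = 1)
  expect_equal(unname(region_responsibilities(tab, g1)[, 1]), 1)

  # symmetric two-group case: a region equidistant from both lines
  tab2 <- line_table(c(10, 20), a = 1, b = 7)   # exactly on line 1
  g2 <- data.frame(slope = 1, intercept = c(6, 8), sigma = 1,
                   weight = c(0.5, 0.5))        # lines offset by +-1
  expect_equal(unname(region_responsibilities(tab2, g2)[1, ]), c(0.5, 0.5))

  # 3-event region, hand-chosen params, against a brute-force product of
  # per-event densities
  tab3 <- line_table(c(6, 14, 25), a = 1.1, b = 6, sigma = 1.5, seed = 2)
  g3 <- data.frame(slope = c(1.2, 0.8), intercept = c(5, 8),
                   sigma = c(1.5, 2.5), weight = c(0.3, 0.7))
  brute <- sapply(1:2, function(k) {
    g3$weight[k] * prod(sapply(seq_len(nrow(tab3)), function(i) {
      dnorm(tab3$rat_pcd[i] - g3$slope[k] * tab3$human_pcw[i] - g3$intercept[k],
            sd = g3$sigma[k])
    }))
  })
  expect_equal(unname(region_responsibilities(tab3, g3)[1, ]),
               brute / sum(brute), tolerance = 1e-12)
})

test_that("weighted least squares reduces to OLS and handles edge weights", {
  # exact interpolation: slope 2, intercept 1, sigma degenerate
  tab <- event_table(data.frame(event_id = 1:2, name = "e", region = "r",
                                human_pcw = c(1e-9, 1), rat_pcd = c(1, 3),
                                mouse_derived = FALSE))
  wf <- weighted_group_fit(tab, c(1, 1))
  expect_equal(wf$slope, 2, tolerance = 1e-6)
  expect_equal(wf$intercept, 1, tolerance = 1e-6)
  expect_true(wf$degenerate)

  # equal weights equal ordinary least squares
  tab2 <- line_table(seq(5, 35, length.out = 12), a = 1.1, b = 6, sigma = 2,
                     seed = 3)
  wf2 <- weighted_group_fit(tab2, rep(1, 12))
  ols <- unname(coef(lm(rat_pcd ~ human_pcw, data = tab2)))
  expect_equal(c(wf2$intercept, wf2$slope), ols, tolerance = 1e-10)

  # zero weights exclude events entirely
  tab3 <- line_table(c(5, 20, 30), a = 1, b = 7, sigma = 1, seed = 4)
  wf3 <- weighted_group_fit(tab3, c(1, 1, 0))
  wf12 <- weighted_group_fit(filter_events(tab3, exclude_ids = 3), c(1, 1))
  expect_equal(wf3[c("slope", "intercept", "sigma")],
               wf12[c("slope", "intercept", "sigma")])

  expect_error(weighted_group_fit(line_table(c(10, 10), 1, 7), c(1, 1)),
               class = "devtrans_degenerate_error")
})

test_that("single-group EM equals the global Gaussian ML fit", {
  tab <- multi_region_table(list(
    list(region = "a", n = 6, a = 1.2, b = 6, sigma = 1.5),
    list(region = "b", n = 5, a = 1.2, b = 6, sigma = 1.5)
  ), seed = 5)
  fit <- fit_em(tab, 1)
  ols <- unname(coef(lm(rat_pcd ~ human_pcw, data = tab)))
  expect_equal(fit$groups$slope, ols[2], tolerance = 1e-10)
  expect_equal(fit$groups$intercept, ols[1], tolerance = 1e-10)
  res <- tab$rat_pcd - ols[1] - ols[2] * tab$human_pcw
  s_ml <- sqrt(mean(res^2))
  expect_equal(fit$groups$sigma, s_ml, tolerance = 1e-10)
  expect_equal(fit$loglik, sum(dnorm(res, sd = s_ml, log = TRUE)),
               tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 3, tolerance = 1e-8)  # p = 4K - 1
})

test_that("EM separates exactly separable regions and recovers parameters", {
  # two regions on distinct exact lines: hard responsibilities, exact lines
  tab <- rbind(as.data.frame(line_table(c(5, 15, 30), a = 1.3, b = 6.8,
                                        region = "fast")),
               as.data.frame(line_table(c(8, 18, 33), a = 0.78, b = 7.4,
                                        region = "slow", ids = 4:6)))
  tab <- event_table(tab)
  fit <- fit_em(tab, 2, init = c(1, 2))
  expect_true(fit$converged)
  expect_true(all(fit$responsibilities %in% c(0, 1)))
  expect_equal(sort(fit$groups$slope), c(0.78, 1.3), tolerance = 1e-6)
  expect_equal(fit$groups$sigma, rep(1e-3, 2))  # floored

  # noisy recovery from a truth-initialised fit
  inst <- separated_instance(12, 6, sigma = 1, seed = 6)
  fit2 <- fit_em(inst$table, 2, init = inst$truth)
  expect_true(fit2$converged)
  expect_equal(sort(fit2$groups$slope), c(0.78, 1.3), tolerance = 0.1)
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  set.seed(7)
  for (case in 1:100) {
    n_regions <- sample(3:6, 1)
    inst <- separated_instance(n_regions, sample(3:6, 1),
                               sigma = runif(1, 0.3, 3),
                               seed = sample.int(1e6, 1))
    K <- sample(1:2, 1)
    fit <- fit_em(inst$table, K,
                  init = sample.int(K, n_regions, replace = TRUE))
    if (length(fit$loglik_trace) > 1) {
      expect_true(all(diff(fit$loglik_trace) > -1e-7))
    }
  }
})

test_that("restart search is deterministic, monotone in restarts, and matches the oracle", {
  inst <- separated_instance(4, 5, sigma = 0.4, seed = 8)
  f1 <- random_restart_search(inst$table, 2, n_restarts = 1, seed = 21)
  f100 <- random_restart_search(inst$table, 2, n_restarts = 100, seed = 21)
  expect_gte(f100$loglik, f1$loglik)

  again <- random_restart_search(inst$table, 2, n_restarts = 100, seed = 21)
  f100$seed <- again$seed <- NULL
  expect_identical(f100, again)

  oracle <- exhaustive_assignment_oracle(inst$table, 2)
  expect_equal(oracle$n_evaluated, 16)
  search <- random_restart_search(inst$table, 2, n_restarts = 200, seed = 22)
  expect_equal(search$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(unname(hard_assignments(search)[names(oracle$assignment)] ==
                        hard_assignments(search)[[1]]),
               unname(oracle$assignment == oracle$assignment[[1]]))

  # degenerate single-region, K = 1 oracle equals global OLS
  tab1 <- line_table(seq(5, 30, length.out = 6), 1.1, 6, sigma = 1, seed = 9)
  o1 <- exhaustive_assignment_oracle(tab1, 1)
  f <- fit_em(tab1, 1)
  expect_equal(o1$loglik, f$loglik, tolerance = 1e-8)

  expect_error(random_restart_search(inst$table, 9),
               class = "devtrans_argument_error")
})

test_that("too many groups for the data marks the fit non-converged", {
  # 3 regions of 3 events each: K = 3 leaves each group with 3 events, but
  # K applied to fewer regions errors, and a group starved of events fails
  inst <- separated_instance(3, 3, sigma = 0.5, seed = 10)
  expect_error(fit_em(inst$table, 4, init = c(1, 2, 3)),
               class = "devtrans_argument_error")
  # one singleton region alone in its group cannot support sigma estimation
  specs <- list(list(region = "big", n = 8, a = 1.3, b = 6.8, sigma = 0.5),
                list(region = "tiny", n = 1, a = 0.5, b = 20, sigma = 0.5))
  tab <- multi_region_table(specs, seed = 11)
  fit <- fit_em(tab, 2, init = c(1, 2))
  expect_false(fit$converged)
  expect_match(fit$failure, "effective event count")
})

test_that("group label permutation leaves loglik, AIC and RMSE unchanged", {
  inst <- separated_instance(4, 5, sigma = 0.6, seed = 12)
  fit <- random_restart_search(inst$table, 2, n_restarts = 50, seed = 23)
  perm <- fit
  perm$groups <- perm$groups[2:1, ]
  rownames(perm$groups) <- NULL
  perm$responsibilities <- perm$responsibilities[, 2:1]
  expect_equal(mixture_loglik(inst$table, perm$groups), fit$loglik,
               tolerance = 1e-9)
  expect_equal(model_rmse(perm, inst$table), model_rmse(fit, inst$table))
  lab <- label_groups(fit)
  expect_equal(lab$groups$label, c("A2", "B2"))
  expect_true(all(diff(lab$groups$slope) < 0))
  expect_equal(model_rmse(lab, inst$table), model_rmse(fit, inst$table))
})

test_that("event posteriors are event-level, normalised, and side with the nearer line", {
  inst <- separated_instance(4, 5, sigma = 0.5, seed = 13)
  fit <- label_groups(random_restart_search(inst$table, 2, n_restarts = 50,
                                            seed = 24))
  post <- event_posteriors(fit, inst$table)
  expect_equal(unname(rowSums(post)), rep(1, nrow(inst$table)))

  # an event exactly on one line, equal sigmas and weights
  fit$groups$sigma <- c(1, 1)
  fit$groups$weight <- c(0.5, 0.5)
  ev <- event_table(data.frame(
    event_id = 1L, name = "probe", region = "fast",
    human_pcw = 30,
    rat_pcd = fit$groups$slope[1] * 30 + fit$groups$intercept[1],
    mouse_derived = FALSE))
  expect_gt(event_posteriors(fit, ev)[1, 1], 0.5)

  # K = 1: certainty
  f1 <- fit_em(inst$table, 1)
  expect_equal(unname(event_posteriors(f1, inst$table)[, 1]),
               rep(1, nrow(inst$table)))
})

test_that("model RMSE uses the hard group line per region", {
  tab <- line_table(c(10, 20, 30), a = 1, b = 7, region = "r1")
  fit <- fit_em(tab, 1)
  expect_equal(model_rmse(fit, tab), 0, tolerance = 1e-9)
  probe <- event_table(data.frame(event_id = 1L, name = "p", region = "r1",
                                  human_pcw = 10, rat_pcd = 19,
                                  mouse_derived = FALSE))
  expect_equal(model_rmse(fit, probe), 2, tolerance = 1e-9)
  expect_error(model_rmse(fit, probe[0, ]), class = "devtrans_domain_error")
})
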