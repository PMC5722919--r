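# In-code fixtures shared across test files.

# A minimal event table: one region, events on (or around) a given line.
line_table <- function(x, a, b, sigma = 0, region = "r1", seed = NULL,
                       ids = seq_along(x)) {
  noise <- if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    rnorm(length(x), 0, sigma)
  } else 0
  event_table(data.frame(
    event_id = ids, name = paste("event", ids), region = region,
    human_pcw = x, rat_pcd = a * x + b + noise, mouse_derived = FALSE,
    stringsAsFactors = FALSE))
}

# Stack several single-region line tables into one multi-region table.
multi_region_table <- function(specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    x <- runif(s$n, 5, 38)
    data.frame(name = "event", region = s$region, human_pcw = x,
               rat_pcd = s$a * x + s$b + rnorm(s$n, 0, s$sigma),
               mouse_derived = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$event_id <- seq_len(nrow(df))
  event_table(df)
}

# Two clearly separated groups of regions; returns table + true assignment.
separated_instance <- function(n_regions = 4, events_per_region = 5,
                               sigma = 0.4, seed = 1,
                               slopes = c(1.3, 0.78),
                               intercepts = c(6.8, 7.4)) {
  groups <- rep_len(seq_along(slopes), n_regions)
  specs <- lapply(seq_len(n_regions), function(r) {
    list(region = sprintf("r%02d", r), n = events_per_region,
         a = slopes[groups[r]], b = intercepts[groups[r]],
         sigma = sigma)
  })
  list(table = multi_region_table(specs, seed = seed), truth = groups)
}

# A mixture_fit with hard responsibilities from a given region assignment
# and per-group OLS parameters (no EM involved).
hard_fit <- function(table, z) {
  regions <- unique(table$region)
  K <- max(z)
  groups <- do.call(rbind, lapply(seq_len(K), function(k) {
    sel <- which(z[match(table$region, regions)] == k)
    wf <- weighted_group_fit(table[sel, , drop = FALSE], rep(1, length(sel)))
    data.frame(slope = wf$slope, intercept = wf$intercept, sigma = wf$sigma,
               weight = mean(z == k))
  }))
  gamma <- matrix(0, length(regions), K, dimnames = list(regions, NULL))
  gamma[cbind(seq_along(z), z)] <- 1
  structure(
    list(K = K, groups = groups, responsibilities = gamma,
         loglik = mixture_loglik(table, groups),
         aic = NA_real_, converged = TRUE, n_iter = 0L,
         loglik_trace = numeric(0), failure = NULL),
    class = "mixture_fit")
}

# Textbook BH step-up, written independently of stats::p.adjust.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj_sorted[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}
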