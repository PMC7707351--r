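# Shared generator: proportional-hazards data with known truth.
sim_ph <- function(n, beta, x = NULL, seed = NULL, censor = Inf) {
  with_seed(seed, {
    if (is.null(x)) x <- matrix(rnorm(n * length(beta)), n)
    lp <- as.vector(x %*% beta)
    t_ev <- rexp(n, 0.01 * exp(lp))
    list(x = as.data.frame(x), times = pmin(t_ev, censor),
         events = as.integer(t_ev <= censor))
  })
}

test_that("elastic-net selection has the expected penalty limits", {
  d <- sim_ph(250, c(0.8, 0, 0), seed = 3)
  names(d$x) <- c("real", "noise1", "noise2")
  all_in <- elastic_net_select(d$x, d$times, d$events, lambda = 0)
  expect_setequal(all_in, c("real", "noise1", "noise2"))
  none <- elastic_net_select(d$x, d$times, d$events, lambda = 1e6)
  expect_length(none, 0)
  expect_error(elastic_net_select(d$x[1], d$times, d$events), ">= 2")
  expect_error(elastic_net_select(transform(d$x, k = 1), d$times, d$events),
               "constant")
  expect_error(elastic_net_select(d$x, d$times, rep(0, 250)), "10 events")
})

test_that("selection keeps a true effect and is scaling-invariant", {
  hits_true <- 0L
  hits_noise <- integer(5)
  for (r in 1:40) {
    d <- sim_ph(400, c(0.5, rep(0, 5)), seed = 100 + r)
    names(d$x) <- c("true_cov", paste0("noise", 1:5))
    sel <- elastic_net_select(d$x, d$times, d$events, seed = 200 + r)
    hits_true <- hits_true + ("true_cov" %in% sel)
    hits_noise <- hits_noise + (paste0("noise", 1:5) %in% sel)
  }
  expect_gte(hits_true, 38L)  # >= 95% of 40 replicates
  expect_true(all(hits_noise < hits_true))
  # affine rescaling of a covariate does not change the selection
  d <- sim_ph(300, c(0.5, 0, 0), seed = 999)
  names(d$x) <- c("a", "b", "c")
  s1 <- elastic_net_select(d$x, d$times, d$events, seed = 7)
  d2 <- d$x; d2$a <- 1000 * d2$a + 5
  s2 <- elastic_net_select(d2, d$times, d$events, seed = 7)
  expect_setequal(s1, s2)
})

test_that("the Cox fit maximises the partial likelihood (toy oracle)", {
  # 6 subjects, one covariate, no ties: grid-search the hand-written
  # partial likelihood and compare with the fitted coefficient
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9)
  times <- c(5, 8, 11, 3, 9, 12)
  events <- c(1, 1, 0, 1, 1, 1)
  pl <- function(beta) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- which(times >= times[i])
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_oracle <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- fit_cox(data.frame(x = x), times, events)
  expect_lt(abs(fit$table$coef - beta_oracle), 1e-4)
  expect_equal(fit$n_events, 5)
})

test_that("a two-group hazard ratio of 2 is recovered", {
  grp <- rep(0:1, each = 500)
  d <- sim_ph(1000, log(2), x = matrix(grp), seed = 55)
  fit <- fit_cox(data.frame(group = grp), d$times, d$events)
  expect_gt(fit$table$hr, 1.8)
  expect_lt(fit$table$hr, 2.2)
  expect_true(fit$table$lower < 2 && fit$table$upper > 2)
})

test_that("degenerate Cox inputs are rejected", {
  expect_error(fit_cox(data.frame(x = rep(1, 20)), 1:20, rep(1, 20)),
               "constant")
  expect_error(fit_cox(data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20)),
                       1:20, c(1, 1, rep(0, 18))), "fewer events")
})

test_that("the score relation ties the Cox model to the log-rank test", {
  d <- sim_ph(120, log(1.8), x = matrix(rep(0:1, 60)), seed = 77)
  grp <- d$x[[1]]
  sd_ <- survival::survdiff(survival::Surv(d$times, d$events) ~ grp)
  p_logrank <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE)
  fit <- survival::coxph(survival::Surv(d$times, d$events) ~ grp)
  p_score <- summary(fit)$sctest["pvalue"]
  expect_equal(unname(p_score), p_logrank, tolerance = 1e-8)
})

test_that("octile partitioning and merging follow the quantile contract", {
  with_seed(91, {
    doses <- sample(seq(2, 32, by = 2))  # 16 distinct values
    delta <- rnorm(16)
    times <- rexp(16, 0.01)
  })
  oa <- octile_analysis(doses, delta, data.frame()[seq_len(16), , drop = FALSE],
                        times, rep(1L, 16), merge_lowest = 3L, min_n = 1L,
                        min_events = 1L)
  expect_length(oa$boundaries, 9L)
  expect_true(!is.unsorted(oa$boundaries))
  expect_equal(oa$boundaries[c(1, 9)], range(doses))
  # 8 groups of 2 before merging; 6 analysis subsets after merging 3
  expect_equal(as.vector(table(oa$octile_assignment)), rep(2L, 8))
  expect_equal(nrow(oa$subsets), 6L)
  expect_equal(oa$subsets$n[1], 6L)
  # pre-merge subset sizes differ by <= 1 even with heavy ties
  with_seed(92, {
    doses2 <- sample(rep(c(1, 5, 5, 9), length.out = 83))
  })
  oa2 <- octile_analysis(doses2, rnorm(83), data.frame()[1:83, , drop = FALSE],
                         rexp(83, 0.01), rep(1L, 83), min_n = 1L,
                         min_events = 1L)
  sizes <- table(oa2$octile_assignment)
  expect_lte(diff(range(sizes)), 1L)
})

test_that("undersized octile subsets are flagged, not dropped", {
  n <- 64L
  d <- sim_ph(n, 0.3, seed = 101)
  oa <- octile_analysis(with_seed(102, runif(n, 0, 40)), d$x[[1]], data.frame(),
                        d$times, d$events, min_n = 30L, min_events = 10L)
  expect_true(all(oa$subsets$flagged[oa$subsets$n < 30]))
  expect_equal(sum(oa$subsets$n), n)
  expect_true(is.na(oa$threshold_estimate) ||
                oa$threshold_estimate %in% oa$subsets$dose_lo)
})

test_that("KM validation separates groups with a known hazard ratio", {
  # null: identical exponential groups; the CI should cover 1
  null_d <- sim_ph(400, 0, x = matrix(rep(0:1, 200)), seed = 111)
  kv0 <- km_validation(with_seed(112, runif(400, 0, 40)), 20,
                       null_d$times, null_d$events)
  expect_true(kv0$lower < 1 && kv0$upper > 1)
  # true HR 0.5 for the below group, 500 per arm
  hits <- 0L
  hr <- numeric(20)
  for (r in 1:20) {
    with_seed(300 + r, {
      dose <- c(runif(500, 0, 16.2), runif(500, 16.2, 40))
      lam <- ifelse(dose < 16.2, 0.005, 0.01)
      times <- rexp(1000, lam)
    })
    kv <- km_validation(dose, 16.2, times, rep(1L, 1000))
    hits <- hits + (kv$logrank_p < 0.001)
    hr[r] <- kv$hr
  }
  expect_equal(hits, 20L)
  expect_true(all(hr > 0.42 & hr < 0.60))
  expect_error(km_validation(runif(100, 10, 40), 5, rexp(100), rep(1, 100)),
               "empty group")
})

test_that("subset delta-dose p-values are uniform under the global null", {
  ps <- numeric(0)
  for (r in 1:25) {
    d <- sim_ph(160, c(0, 0.3), seed = 400 + r)
    names(d$x) <- c("delta", "adj")
    oa <- octile_analysis(with_seed(500 + r, runif(160, 0, 40)), d$x$delta,
                          d$x["adj"], d$times, d$events, min_n = 15L,
                          min_events = 5L)
    ps <- c(ps, oa$subsets$p[!oa$subsets$flagged])
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
})
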