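## balanced noiseless metrics table with a known log2 ecotype ratio
exact_table <- function(n = 10, log2_ratio = -1) {
  tab <- expand.grid(antenna_id = c(sprintf("f%02d", 1:n),
                                    sprintf("w%02d", 1:n)),
                     pulse_duration_ms = c(15, 30, 150, 300),
                     stringsAsFactors = FALSE)
  tab$ecotype <- ifelse(grepl("^f", tab$antenna_id),
                        "full-winged", "wing-reduced")
  tab$population <- "p"
  tab$odorant <- "o"
  base <- c("15" = -1, "30" = 0, "150" = 1, "300" = 2)  # log2 scale
  y <- base[as.character(tab$pulse_duration_ms)] +
    ifelse(tab$ecotype == "wing-reduced", log2_ratio, 0)
  tab$strength_mV <- 2^y - 0.01
  tab$onset_s <- ifelse(tab$ecotype == "wing-reduced", 0.2, 0.1)
  tab$offset_s <- 1.5
  tab
}

test_that("strength transform and its inverse are exact", {
  expect_equal(transform_strength(0.99), 0)
  expect_equal(transform_strength(1.99), 1)
  for (x in c(0.001, 0.5, 7.3))
    expect_equal(inv_transform_strength(transform_strength(x)), x,
                 tolerance = 1e-12)
  expect_error(transform_strength(-0.02), "log2")
})

test_that("the mixed model recovers noiseless effects exactly", {
  fit <- fit_strength_model(exact_table(log2_ratio = -1))
  expect_equal(unname(fit$beta["ecotypewing-reduced"]), -1,
               tolerance = 1e-8)
  ints <- fit$beta[grep(":", names(fit$beta))]
  expect_equal(unname(ints), rep(0, 3), tolerance = 1e-8)
  ## shuffling rows leaves estimates unchanged
  tab <- exact_table()
  set.seed(1)
  fit2 <- fit_strength_model(tab[sample(nrow(tab)), ])
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)
  ## adding a constant on the modelling scale moves only the intercept
  tab4 <- tab
  tab4$strength_mV <- 2^(log2(tab4$strength_mV + 0.01) + 1) - 0.01
  fit4 <- fit_strength_model(tab4)
  expect_equal(unname(fit4$beta["(Intercept)"] - fit$beta["(Intercept)"]), 1,
               tolerance = 1e-8)
  expect_equal(fit4$beta[-1], fit$beta[-1], tolerance = 1e-8)
})

test_that("model preconditions are enforced", {
  tab <- exact_table()
  expect_error(fit_strength_model(tab[tab$ecotype == "full-winged", ]),
               "both ecotypes")
  expect_error(fit_strength_model(tab[tab$pulse_duration_ms == 300, ]),
               "duration levels")
  one <- tab[tab$antenna_id %in% c("f01", "w01", "w02"), ]
  expect_error(fit_strength_model(one), ">= 2 antennae")
})

test_that("the timing model is the two-group log2 mean difference", {
  fit <- fit_timing_model(exact_table(), "onset")
  expect_equal(unname(fit$beta["ecotypewing-reduced"]), 1)  # log2(0.2/0.1)
  ## equal groups -> coefficient 0
  tab <- exact_table()
  tab$onset_s <- 0.15
  expect_equal(unname(fit_timing_model(tab, "onset")$beta[2]), 0)
  ## invalid rows are excluded and counted
  tab2 <- exact_table()
  tab2$onset_s[tab2$antenna_id == "f01"] <- NA
  fit2 <- fit_timing_model(tab2, "onset")
  expect_equal(fit2$n_dropped, 1)       # one NA row at 300 ms
  expect_equal(fit2$n, 19)
})

test_that("posterior draws are reproducible and match the fit", {
  tab <- simulate_metrics_table(eag_config(n_antennae = 10), seed = 21)
  fit <- fit_strength_model(tab)
  p1 <- simulate_posterior(fit, n_sim = 2000, seed = 5)
  p2 <- simulate_posterior(fit, n_sim = 2000, seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 2000)
  ## draw means approach the estimates (Monte-Carlo SE bound)
  p3 <- simulate_posterior(fit, n_sim = 10000, seed = 6)
  se <- sqrt(diag(fit$V))
  expect_true(all(abs(colMeans(p3$draws) - fit$beta) < 4 * se / sqrt(10000)))
  ## empirical covariance close to the fitted covariance
  emp <- cov(p3$draws)
  expect_lt(norm(emp - fit$V, "F") / norm(fit$V, "F"), 0.1)
  expect_error(simulate_posterior(fit, n_sim = 0), "n_sim")
})

test_that("lm posterior scales coefficients with drawn residual SD", {
  fit <- fit_timing_model(simulate_metrics_table(eag_config(n_antennae = 10),
                                                 seed = 22), "onset")
  post <- simulate_posterior(fit, n_sim = 10000, seed = 7)
  ## sigma draws follow the scaled inverse-chi-square posterior mean
  expect_equal(mean(post$sigma^2), fit$sigma^2 * fit$df / (fit$df - 2),
               tolerance = 0.1)
  emp <- cov(post$draws)
  expect_lt(norm(emp - fit$V * fit$df / (fit$df - 2), "F") / norm(fit$V, "F"),
            0.15)
})

test_that("comparison summaries apply the certainty and star rules", {
  ## all draws positive -> certainty 1, two stars
  s <- summarize_comparison(fake_posterior(abs(rnorm(1000)) + 0.01))
  expect_equal(s$certainty, 1)
  expect_equal(s$stars, "**")
  ## symmetric draws -> certainty ~ 0.5, no stars
  s2 <- summarize_comparison(fake_posterior(c(rnorm(500), -rnorm(500))))
  expect_lt(s2$certainty, 0.6)
  expect_equal(s2$stars, "")
  ## certainty 0.97 -> one star, not two
  delta <- c(rep(1, 9700), rep(-1, 300))
  s3 <- summarize_comparison(fake_posterior(delta))
  expect_equal(s3$certainty, 0.97)
  expect_equal(s3$stars, "*")
  ## boundary: certainty exactly 0.95 earns no star
  s4 <- summarize_comparison(fake_posterior(c(rep(1, 9500), rep(-1, 500))))
  expect_equal(s4$stars, "")
})

test_that("group means are back-transformed with the right offset", {
  fit <- fit_strength_model(exact_table(log2_ratio = -1))
  post <- simulate_posterior(fit, n_sim = 2000, seed = 8)
  s <- summarize_comparison(post, duration_ms = 300)
  ## noiseless: fw at log2 = 2 -> 4 mV - 0.01 offset; wr at 2 mV scale
  expect_equal(s$fw_mean, 3.99, tolerance = 1e-6)
  expect_equal(s$wr_mean, 1.99, tolerance = 1e-6)
  expect_equal(s$delta_log2, -1, tolerance = 1e-6)
  expect_equal(s$direction, "full-winged > wing-reduced")
})
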