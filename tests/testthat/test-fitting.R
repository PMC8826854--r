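test_that("noiseless generation is recovered to 3 significant figures", {
  p <- printed_params()
  tab <- noiseless_table(small_design(), p)
  fit <- fit_growth_model(tab, fix_d = TRUE, n_starts = 6, seed = 11)
  est <- unclass(fit$params)
  for (k in c("C", "r", "a", "b", "c"))
    expect_equal(signif(est[[k]], 3), signif(unclass(p)[[k]], 3))
  expect_lt(fit$rmse, 1e-5)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_true(fit$converged)
})

test_that("self-consistency holds for other coefficient sets", {
  for (p in list(growth_params(1.2, 0.4, 10, b = 1.8, c = 0.3),
                 growth_params(4, 0.15, 0.8, b = 3, c = 0.5, d = 0))) {
    tab <- noiseless_table(small_design(), p)
    fit <- fit_growth_model(tab, fix_d = TRUE, n_starts = 6, seed = 3)
    est <- unclass(fit$params)
    for (k in c("C", "r", "a", "b", "c"))
      expect_equal(est[[k]], unclass(p)[[k]], tolerance = 1e-3)
  }
})

test_that("identifiability preconditions are enforced", {
  p <- printed_params()
  tab <- noiseless_table(small_design(), p)
  one_das <- tab[tab$das == 7, ]
  expect_error(fit_growth_model(one_das), "DAS")
  few_peg <- tab[tab$peg <= 3, ]
  expect_error(fit_growth_model(few_peg), "PEG")
})

test_that("fitted SSE never exceeds any start's initial objective", {
  tab <- generate_observations(small_design(), printed_params(),
                               noise_model(additive_sd = 5, seed = 4))
  fit <- fit_growth_model(tab, n_starts = 5, seed = 4)
  expect_length(fit$start_sses, 5)
  expect_true(all(fit$sse <= fit$start_sses + 1e-9))
  # reported sse is the objective at the reported coefficients
  pred <- predict_srl(tab$peg, tab$das, fit$params)
  expect_equal(fit$sse, sum((tab$srl - pred)^2),
               tolerance = 1e-8)
  expect_equal(fit$rmse, sqrt(fit$sse / fit$n_obs), tolerance = 1e-12)
})

test_that("scaling all observations scales a and nothing else", {
  tab <- generate_observations(small_design(), printed_params(),
                               noise_model(additive_sd = 2, seed = 8))
  f1 <- fit_growth_model(tab, n_starts = 4, seed = 8)
  tab2 <- tab
  tab2$srl <- 3 * tab$srl
  f2 <- fit_growth_model(tab2, n_starts = 4, seed = 8)
  expect_equal(f2$params[["a"]], 3 * f1$params[["a"]], tolerance = 1e-3)
  for (k in c("C", "r", "b", "c"))
    expect_equal(f2$params[[k]], f1$params[[k]], tolerance = 1e-3)
})

test_that("freeing d recovers a nonzero concentration offset", {
  p <- growth_params(2.402, 0.235, 5.64, b = 4, c = 0.677, d = 1.5)
  tab <- noiseless_table(small_design(), p)
  fit <- fit_growth_model(tab, fix_d = FALSE, n_starts = 8, seed = 5)
  expect_equal(fit$params[["d"]], 1.5, tolerance = 0.05)
  expect_equal(fit$params[["b"]], 4, tolerance = 0.05)
})

test_that("goodness_of_fit matches the pooled R-squared formula", {
  p <- printed_params()
  tab <- noiseless_table(small_design(), p)
  gof <- goodness_of_fit(tab, p)
  expect_equal(gof[["r_squared"]], 1)
  expect_equal(gof[["rmse"]], 0)
  noisy <- generate_observations(small_design(), p,
                                 noise_model(additive_sd = 5, seed = 2))
  gof2 <- goodness_of_fit(noisy, p)
  # independent row-wise evaluation of 1 - SSE/SST about the grand mean
  res <- vapply(seq_len(nrow(noisy)), function(i)
    noisy$srl[i] - predict_srl(noisy$peg[i], noisy$das[i], p), numeric(1))
  sse <- sum(res^2)
  sst <- sum((noisy$srl - mean(noisy$srl))^2)
  expect_equal(gof2[["r_squared"]], 1 - sse / sst, tolerance = 1e-12)
  expect_equal(gof2[["rmse"]], sqrt(sse / nrow(noisy)), tolerance = 1e-12)
  const <- noisy
  const$srl <- rep(50, nrow(const))
  expect_error(goodness_of_fit(const, p), "SST")
})

test_that("harvest comparison computes a plain RMSE against K", {
  p <- printed_params()
  peg <- setdiff(1:25, 6)
  exact <- data.frame(peg = peg, das = 30, replicate = 1L,
                      srl = full_length_K(peg, p), source = "ruler")
  expect_equal(compare_K_to_harvest(exact, p), 0)
  one <- data.frame(peg = 5.908, das = 30, replicate = 1L,
                    srl = full_length_K(5.908, p) + 10, source = "ruler")
  expect_equal(compare_K_to_harvest(one, p), 10, tolerance = 1e-9)
  mixed <- exact
  mixed$das[1] <- 29
  expect_error(compare_K_to_harvest(mixed, p), "single DAS")
})

test_that("harvest RMSE estimates the generating noise magnitude", {
  # Monte-Carlo check of the estimator: noise sd 13.7 mm, 24 levels x 3
  p <- printed_params()
  design <- experiment_design()
  rmses <- vapply(1:8, function(s) {
    harv <- generate_harvest(design, p,
                             noise_model(additive_sd = 13.7, seed = s))
    # compare against the harvest-day expectation, whose gap to K is < 3%
    compare_K_to_harvest(harv, p)
  }, numeric(1))
  expect_equal(mean(rmses), 13.7, tolerance = 0.15)
})

test_that("fit results serialize to JSON", {
  tab <- noiseless_table(small_design())
  fit <- fit_growth_model(tab, n_starts = 2, seed = 1)
  js <- fit_to_json(fit)
  expect_true(jsonlite::validate(js))
  back <- jsonlite::fromJSON(js)
  expect_equal(back$coefficients$b, fit$params[["b"]], tolerance = 1e-9)
  expect_equal(back$n_obs, nrow(tab))
  expect_identical(back$n_starts, 2L)
})
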