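dr_tbl <- function(doses, means, reps = 1L) {
  tibble(dose = rep(doses, each = reps),
         response = rep(means, each = reps))
}

test_that("desensitized supra-peak doses are excluded, peak retained", {
  d <- dr_tbl(c(1e-9, 1e-8, 1e-7, 1e-6), c(10, 50, 100, 60))
  out <- exclude_desensitized(d)
  expect_equal(sort(unique(out$dose)), c(1e-9, 1e-8, 1e-7))
  expect_equal(attr(out, "excluded_doses"), 1e-6)

  mono <- dr_tbl(c(1e-9, 1e-8, 1e-7), c(10, 50, 100))
  expect_equal(nrow(exclude_desensitized(mono)), 3L)

  plateau <- dr_tbl(c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5),
                    c(10, 80, 100, 100, 40))
  out2 <- exclude_desensitized(plateau)
  expect_equal(sort(unique(out2$dose)), c(1e-9, 1e-8, 1e-7, 1e-6))
})

test_that("noiseless fits recover the generating parameters", {
  doses <- 10^seq(-10, -6, length.out = 9)
  ec <- dr_tbl(doses, sapply(doses, function(x) {
    0 + (100 - 0) / (1 + exp(-1 * (log(x) - log(1e-8))))
  }))
  fit <- fit_ll3(ec, mode = "EC")
  expect_true(fit$converged)
  cf <- fit$coefficients
  expect_equal(unname(cf["b"]), -1, tolerance = 1e-6)
  expect_equal(unname(cf["c"]), 0, tolerance = 1e-4)
  expect_equal(unname(cf["d"]), 100)
  expect_true(fit$fixed[["d"]])
  expect_equal(unname(cf["e"]), 1e-8, tolerance = 1e-6)

  ic_doses <- 10^seq(-9, -5, length.out = 9)
  ic <- dr_tbl(ic_doses, sapply(ic_doses, function(x) {
    95 / (1 + exp(1 * (log(x) - log(2e-7))))
  }))
  fit2 <- fit_ll3(ic, mode = "IC")
  expect_equal(unname(fit2$coefficients["e"]), 2e-7, tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients["d"]), 95, tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients["c"]), 0)
  expect_true(fit2$fixed[["c"]])
})

test_that("fitting is invariant to uniform dose rescaling up to e", {
  doses <- 10^seq(-9, -5, length.out = 7)
  d0 <- simulate_chemotaxis(doses, b = 1, c = 0, d = 90, e = 1e-7,
                            sd = 2, seed = 20)
  f0 <- fit_ll3(d0, mode = "IC")
  d1 <- mutate(d0, dose = dose * 1e3)
  f1 <- fit_ll3(d1, mode = "IC")
  expect_equal(unname(f1$coefficients["e"]),
               unname(f0$coefficients["e"]) * 1e3, tolerance = 1e-4)
  expect_equal(unname(f1$coefficients["b"]),
               unname(f0$coefficients["b"]), tolerance = 1e-4)
})

test_that("EC fits on counts are normalised to percent of peak mean", {
  doses <- 10^seq(-10, -6, length.out = 7)
  counts <- dr_tbl(doses, sapply(doses, function(x) {
    5000 / (1 + exp(-1.2 * (log(x) - log(3e-8))))
  }))
  expect_message(fit <- fit_ll3(counts, mode = "EC",
                                response_scale = "counts"), "normalised")
  expect_equal(unname(fit$coefficients["e"]), 3e-8, tolerance = 1e-2)
})

test_that("tidy and glance summarise the fit object", {
  doses <- 10^seq(-9, -5, length.out = 7)
  fit <- fit_ll3(simulate_chemotaxis(doses, b = 1, d = 100, e = 1e-7,
                                     sd = 0, seed = 1), mode = "IC")
  td <- tidy(fit)
  expect_equal(td$term, c("b", "c", "d", "e"))
  expect_equal(td$fixed, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(glance(fit)$converged)
})

test_that("derived effect doses follow the closed form", {
  doses <- 10^seq(-10, -6, length.out = 9)
  ec <- dr_tbl(doses, sapply(doses, function(x) {
    100 / (1 + exp(-1 * (log(x) - log(1e-8))))
  }))
  fit <- fit_ll3(ec, mode = "EC")
  expect_equal(derive_ecf(fit, 50), unname(fit$coefficients["e"]))
  expect_equal(derive_ecf(fit, 80), 4e-8, tolerance = 1e-5)
  # inverse identity: the curve at EC_f is f% of the span
  cf <- fit$coefficients
  x80 <- derive_ecf(fit, 80)
  y <- cf["c"] + (cf["d"] - cf["c"]) /
    (1 + exp(cf["b"] * (log(x80) - log(cf["e"]))))
  expect_equal(unname((y - cf["c"]) / (cf["d"] - cf["c"])), 0.8,
               tolerance = 1e-9)
  expect_error(derive_ecf(fit, 100), "strictly between")
})

test_that("the potency transform is -log10 of the molar value", {
  expect_equal(p_molar(1e-6), 6)
  expect_equal(10^(-p_molar(3.7e-8)), 3.7e-8)
  expect_error(p_molar(0), "positive")
  expect_error(p_molar(-1), "positive")

  doses <- 10^seq(-9, -5, length.out = 7)
  fit <- fit_ll3(simulate_chemotaxis(doses, b = 1, d = 100, e = 1e-7,
                                     sd = 0, seed = 1), mode = "IC")
  pot <- to_potency(fit)
  expect_equal(pot$pic50, 7, tolerance = 1e-6)
  expect_true(is.na(pot$pec50))
})

test_that("pool fractions are TPM-proportional and sum to one", {
  p <- design_pool(tibble(chemokine = c("X", "Y"), tpm = c(100, 300)))
  expect_equal(p$fraction, c(0.25, 0.75))
  expect_equal(design_pool(tibble(chemokine = "X", tpm = 5))$fraction, 1)
  expect_error(design_pool(tibble(chemokine = "X", tpm = 0)), "all-zero")

  tp <- simulate_tpm(paste0("CCL", 1:10), profile = "lognormal", seed = 21)
  p10 <- design_pool(tp)
  expect_equal(p10$fraction, tp$tpm / sum(tp$tpm))
  expect_equal(sum(p10$fraction), 1)
})

test_that("Dunnett comparisons reduce to the t-test for one group", {
  set.seed(22)
  dat <- tibble(group = rep(c("ctrl", "trt"), each = 6),
                response = rnorm(12, mean = rep(c(0, 1), each = 6)))
  dn <- dunnett_compare(dat, "ctrl")
  tt <- t.test(response ~ group, data = dat, var.equal = TRUE)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(dn$p_unadj, tt$p.value, tolerance = 1e-6)
})

test_that("adjusted p-values dominate marginal ones and match multcomp", {
  set.seed(23)
  dat <- tibble(group = rep(c("ctrl", "a", "b", "c"), each = 5),
                response = rnorm(20) + rep(c(0, 0.5, 1, 0), each = 5))
  dn <- dunnett_compare(dat, "ctrl")
  expect_true(all(dn$p_adj >= dn$p_unadj - 1e-9))
  expect_true(all(dn$p_adj >= 0 & dn$p_adj <= 1))

  # independent route: multcomp's glht on the same model
  dat$group <- relevel(factor(dat$group), ref = "ctrl")
  gl <- summary(multcomp::glht(stats::aov(response ~ group, data = dat),
                               linfct = multcomp::mcp(group = "Dunnett")))
  ord <- match(dn$group, sub("^(\\w+) - ctrl$", "\\1",
                             rownames(gl$linfct)))
  expect_equal(dn$p_adj, as.numeric(gl$test$pvalues)[ord], tolerance = 5e-3)
})

test_that("identical groups give adjusted p near one and no stars", {
  set.seed(24)
  dat <- tibble(group = rep(c("ctrl", "a", "b"), each = 40),
                response = rnorm(120))
  dn <- dunnett_compare(dat, "ctrl")
  expect_true(all(dn$p_adj > 0.2))
  expect_true(all(dn$stars == ""))
  expect_error(
    dunnett_compare(tibble(group = rep(c("ctrl", "a"), each = 2),
                           response = rep(1, 4)), "ctrl"),
    "zero within-group variance")
})

test_that("significance stars bin at the legend thresholds", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001)),
               c("", "*", "**", "***", "****"))
})
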