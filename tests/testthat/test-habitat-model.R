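# Use-availability table, VIF screening, the smooth binomial selection
# model, AIC selection, importance decomposition and prediction maps.

test_that("the use-availability table stacks classes with audit counts", {
  cov_cols <- function(n, id) data.frame(
    bathy = runif(n, 0, 100), tidal = runif(n, 0, 1),
    dist_shore = runif(n, 0, 30), dist_haulout = runif(n, 0, 50),
    sediment = factor(sample(paste0("sed", 1:3), n, TRUE)),
    individual = id)
  withr::local_seed(1)
  d <- cov_cols(100, "a"); a <- cov_cols(200, "a")
  tab <- build_ua_table(d, a)
  expect_equal(nrow(tab), 300L)
  expect_equal(sum(tab$response), 100L)
  expect_equal(mean(tab$bathy[tab$response == 1]), mean(d$bathy))
  expect_error(build_ua_table(cov_cols(5, "b"), a),
               "without pseudo-absences")
  ## shuffling rows leaves the fit identical
  tab2 <- tab[sample(nrow(tab)), ]
  f1 <- fit_selection_model(tab, terms = c("bathy", "tidal"))
  f2 <- fit_selection_model(tab2, terms = c("bathy", "tidal"))
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("VIF screening matches the 1/(1-R^2) closed form", {
  withr::local_seed(7)
  n <- 5000
  tab <- data.frame(bathy = rnorm(n), tidal = rnorm(n),
                    dist_shore = rnorm(n), dist_haulout = rnorm(n),
                    sediment = factor("sed1"))
  ## independent covariates: all VIF near 1
  expect_true(all(vif_screen(tab) < 1.1))
  ## a rho = 0.9 pair: VIF ~ 1/(1 - 0.81)
  tab$dist_shore <- 0.9 * tab$bathy + sqrt(1 - 0.81) * rnorm(n)
  expect_warning(v <- vif_screen(tab), "VIF above")
  expect_equal(unname(v["bathy"]), 1 / (1 - 0.81), tolerance = 0.15)
  ## a duplicated covariate: infinite VIF with hard warning
  tab$dist_shore <- tab$bathy
  expect_warning(v2 <- vif_screen(tab), "collinearity")
  expect_true(is.infinite(v2["bathy"]))
})

test_that("a linear effect is recovered within its confidence interval", {
  tab <- sim_ua_table(n = 6000, betas = c(bathy = -0.05, tidal = 0,
                                          dist_shore = 0, dist_haulout = 0),
                      seed = 21, intercept = 2.5)
  m <- fit_selection_model(tab, terms = "bathy", linear = "bathy")
  cf <- coef(m$fit)["bathy"]
  se <- sqrt(diag(vcov(m$fit))["bathy"])
  expect_lt(abs(cf - (-0.05)), 1.96 * se)
  ## and the smooth version is monotone decreasing over the bulk
  ms <- fit_selection_model(tab, terms = "bathy")
  nd <- data.frame(bathy = seq(10, 140, length.out = 50),
                   individual = factor(levels(tab$individual)[1],
                                       levels(tab$individual)))
  pr <- predict(ms$fit, nd, type = "link", exclude = "s(individual)",
                newdata.guaranteed = TRUE)
  expect_lt(cor(nd$bathy, as.numeric(pr), method = "spearman"), -0.95)
})

test_that("a response independent of covariates explains almost nothing", {
  tab <- sim_ua_table(n = 6000, betas = c(bathy = 0, tidal = 0,
                                          dist_shore = 0, dist_haulout = 0),
                      seed = 5, re_sd = 0)
  m <- fit_selection_model(tab)
  expect_lt(m$explained_deviance, 2)
  ## refitting identical data gives identical AIC
  m2 <- fit_selection_model(tab)
  expect_equal(m$aic, m2$aic, tolerance = 1e-8)
})

test_that("sediment reference level is forced to the modal class", {
  tab <- sim_ua_table(n = 1500, seed = 3)
  lvl <- names(which.max(table(tab$sediment)))
  m <- fit_selection_model(tab, terms = c("bathy", "sediment"))
  expect_equal(m$reference_sediment, lvl)
  ## no sediment dummy for the reference level in the coefficients
  expect_false(any(grepl(paste0("sediment", lvl), names(coef(m$fit)))))
})

test_that("AIC selection prefers the generating terms and breaks ties small", {
  ## candidate menu: generating set vs the full covariate set. Under the
  ## null the two extra linear terms gain ~chi2_2 deviance against an AIC
  ## penalty of 4, so the generating set wins with probability
  ## P(chi2_2 < 4) = 0.865; assert within 3 binomial SEs at 50 replicates
  ## (0.865 - 3 * sqrt(0.865 * 0.135 / 50) = 0.72).
  win <- 0L; reps <- 50L
  for (r in seq_len(reps)) {
    tab <- sim_ua_table(n = 1200, betas = c(bathy = -0.04, tidal = 0,
                                            dist_shore = 0,
                                            dist_haulout = -0.06),
                        seed = 100 + r, re_sd = 0.2)
    sel <- select_model(
      tab,
      candidates = list(c("bathy", "dist_haulout"),
                        c("bathy", "tidal", "dist_shore", "dist_haulout")),
      linear = c("bathy", "tidal", "dist_shore", "dist_haulout"))
    if (identical(sort(sel$best$terms), c("bathy", "dist_haulout")))
      win <- win + 1L
  }
  expect_gte(win / reps, 0.72)
  ## the ledger's winner has dAIC zero
  tab <- sim_ua_table(n = 1000, seed = 77)
  sel <- select_model(tab, candidates = list("bathy", c("bathy", "tidal")))
  expect_equal(min(sel$ledger$dAIC), 0)
  ## identical candidates tie toward fewer terms (here: the same set twice
  ## plus a superset with a null covariate whose penalty removes it)
  sel2 <- select_model(tab, candidates = list("bathy", "bathy"),
                       linear = "bathy")
  expect_equal(sel2$best$terms, "bathy")
})

test_that("explained deviance matches a hand-computed binomial deviance", {
  ## 10-row table, linear logistic fit; deviance computed from first
  ## principles: D = -2 sum[y log mu + (1-y) log(1-mu)]
  tab <- data.frame(bathy = c(1:10), tidal = 0, dist_shore = 0,
                    dist_haulout = 0,
                    sediment = factor("sed1"),
                    individual = factor(rep(c("a", "b"), 5)),
                    site = factor("s1"),
                    response = c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0))
  m <- fit_selection_model(tab, terms = "bathy", linear = "bathy")
  mu <- as.numeric(predict(m$fit, type = "response"))
  d_model <- -2 * sum(tab$response * log(mu) + (1 - tab$response) * log(1 - mu))
  p0 <- mean(tab$response)
  d_null <- -2 * sum(tab$response * log(p0) + (1 - tab$response) * log(1 - p0))
  expect_equal(explained_deviance(m), 100 * (1 - d_model / d_null),
               tolerance = 1e-8)
  ## intercept-only fit explains nothing
  m0 <- mgcv::gam(response ~ 1, data = tab, family = binomial())
  expect_equal(explained_deviance(m0), 0, tolerance = 1e-10)
})

test_that("importance shares decompose explained deviance", {
  ## single covariate: everything attributed to it
  tab1 <- sim_ua_table(n = 800, betas = c(bathy = -0.05, tidal = 0,
                                          dist_shore = 0, dist_haulout = 0),
                       seed = 11)
  m1 <- fit_selection_model(tab1, terms = "bathy")
  expect_equal(unname(term_importance(m1, tab1)), 100)
  ## two equal-scale equal-effect covariates: shares near 50/50
  shares <- replicate(4, {
    sd2 <- sim_ua_table(n = 3000, betas = c(bathy = -0.04, tidal = 0,
                                            dist_shore = 0,
                                            dist_haulout = -0.04 * 150 / 80),
                        seed = sample.int(1e6, 1))
    ## rescale so both covariates span comparable ranges of effect
    m <- fit_selection_model(sd2, terms = c("bathy", "dist_haulout"))
    imp <- term_importance(m, sd2)
    expect_equal(sum(imp), 100, tolerance = 0.5)
    imp["bathy"]
  })
  expect_lt(abs(mean(shares) - 50), 10)
})

test_that("prediction maps are probabilities that track the true surface", {
  w <- tiny_world()
  ## intercept-ish check: a null model maps to a near-constant surface
  tab0 <- sim_ua_table(n = 1000, betas = c(bathy = 0, tidal = 0,
                                           dist_shore = 0, dist_haulout = 0),
                       seed = 2, re_sd = 0)
  m0 <- fit_selection_model(tab0, terms = "bathy", linear = "bathy")
  mp0 <- predict_map(m0, w$seascape, w$seagraph)
  v0 <- mp0$prob$values[!is.na(mp0$prob$values)]
  expect_true(all(v0 >= 0 & v0 <= 1))
  expect_lt(diff(range(v0)), 0.12)
  expect_true(all(is.na(mp0$prob$values[w$seascape$land])))
})

test_that("adding a term never decreases the explained deviance", {
  tab <- sim_ua_table(n = 2000, seed = 13)
  m1 <- fit_selection_model(tab, terms = c("bathy"))
  m2 <- fit_selection_model(tab, terms = c("bathy", "dist_haulout"))
  m3 <- fit_selection_model(tab, terms = c("bathy", "dist_haulout", "tidal"))
  expect_gte(m2$explained_deviance, m1$explained_deviance - 1e-6)
  expect_gte(m3$explained_deviance, m2$explained_deviance - 1e-6)
})

test_that("label swap mirrors the fitted probabilities", {
  tab <- sim_ua_table(n = 2000, seed = 17, re_sd = 0)
  tabswap <- tab; tabswap$response <- 1L - tab$response
  m <- fit_selection_model(tab, terms = c("bathy", "dist_haulout"),
                           linear = c("bathy", "dist_haulout"))
  ms <- fit_selection_model(tabswap, terms = c("bathy", "dist_haulout"),
                            linear = c("bathy", "dist_haulout"))
  p <- as.numeric(predict(m$fit, type = "response"))
  ps <- as.numeric(predict(ms$fit, type = "response"))
  expect_equal(ps, 1 - p, tolerance = 1e-6)
})

test_that("1-in-3 subsampling preserves estimates within one standard error", {
  tab <- sim_ua_table(n = 30000, betas = c(bathy = -0.03, tidal = 0.8,
                                           dist_shore = 0,
                                           dist_haulout = -0.05),
                      seed = 19, n_ind = 20)
  tab$site <- factor(rep(paste0("s", 1:4), length.out = nrow(tab)))
  full <- fit_selection_model(tab, terms = c("bathy", "dist_haulout"),
                              linear = c("bathy", "dist_haulout"),
                              mode = "global", subsample = "none")
  sub <- fit_selection_model(tab, terms = c("bathy", "dist_haulout"),
                             linear = c("bathy", "dist_haulout"),
                             mode = "global", subsample = "one_in_three")
  expect_lt(sub$n, 0.4 * full$n)
  for (tm in c("bathy", "dist_haulout")) {
    se <- sqrt(diag(vcov(sub$fit))[tm])
    expect_lt(abs(coef(full$fit)[tm] - coef(sub$fit)[tm]), se)
  }
})
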