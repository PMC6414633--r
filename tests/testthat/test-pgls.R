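test_that("design matrices have the documented dimensions", {
  d <- make_study_like_dataset(synthetic_config(seed = 4))
  # diet (7) + clade (7) additive: 1 + 1 + 6 + 6 = 14 columns, df = 141
  des <- build_design(d$traits, design_spec(c("diet", "clade")))
  expect_equal(ncol(des$X), 14)
  expect_equal(nrow(des$X) - ncol(des$X), 141)

  expect_equal(ncol(build_design(d$traits, design_spec())$X), 2)
  # one 3-level factor with interaction: 1 + 1 + 2 + 2 = 6 columns
  des3 <- build_design(d$traits, design_spec("flight", interaction = TRUE))
  expect_equal(ncol(des3$X), 6)

  expect_error(design_spec(c("diet", "clade"), interaction = TRUE),
               "exactly one factor")
  # absent level is an error, not a silent drop
  sub <- d$traits[d$traits$diet != "nectarivore", ]
  class(sub) <- class(d$traits)
  expect_error(build_design(sub, design_spec("diet")), "nectarivore")
})

test_that("independent-model GLS matches the OLS oracle", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- rnorm(n)
    C <- phylo_vcv(yule_tree(n, depth = 10, seed = 600 + i))
    fit <- gls_fit(y, X, C, evo_model("independent"))
    ora <- ols_oracle(y, X)
    expect_equal(unname(fit$beta), ora$beta, tolerance = 1e-10)
    expect_equal(fit$sigma2_ml, ora$sigma2_ml, tolerance = 1e-10)
  }
})

test_that("Brownian weighting on a star tree reduces to OLS", {
  star <- parse_tree("(A:7,B:7,C:7,D:7,E:7,F:7,G:7,H:7);")
  C <- phylo_vcv(star)
  set.seed(62)
  X <- cbind(1, rnorm(8)); colnames(X) <- c("(Intercept)", "x")
  y <- rnorm(8)
  bm <- gls_fit(y, X, C, evo_model("brownian"))
  ols <- gls_fit(y, X, C, evo_model("independent"))
  expect_equal(bm$beta, ols$beta, tolerance = 1e-12)
  expect_equal(bm$fitted, ols$fitted, tolerance = 1e-12)
})

test_that("OU weighting approaches OLS as alpha grows", {
  # depth-10 tree whose shortest patristic distance (4) makes
  # exp(-alpha d) vanish at alpha = 100
  tr <- ape::compute.brlen(ape::stree(32, "balanced"), 2)
  C <- phylo_vcv(tr)
  set.seed(64)
  X <- cbind(1, rnorm(32)); colnames(X) <- c("(Intercept)", "x")
  y <- X %*% c(1, 0.5) + rnorm(32)
  ou <- gls_fit(as.numeric(y), X, C, evo_model("ou", alpha = 100))
  ols <- gls_fit(as.numeric(y), X, C, evo_model("independent"))
  expect_equal(ou$beta, ols$beta, tolerance = 1e-4)
})

test_that("rank-deficient designs are refused with the offending column", {
  C <- phylo_vcv(yule_tree(10, depth = 10, seed = 65))
  X <- cbind(1, 1:10, 2 * (1:10))
  colnames(X) <- c("(Intercept)", "x", "x_dup")
  expect_error(gls_fit(rnorm(10), X, C, evo_model("independent")),
               "rank deficient")
})

test_that("coefficient t-tests use n - p degrees of freedom", {
  fit <- structure(list(
    beta = c(slope = 0.347821, herbivory = 0.4588238),
    se = c(slope = 0.0744129, herbivory = 0.1714065),
    df_resid = 141L), class = "gls_fit")
  iso <- coef_test(fit, "slope", hypothesized = 0.33)
  expect_equal(iso$df, 141L)
  expect_equal(iso$p, 0.81, tolerance = 0.01)
  herb <- coef_test(fit, "herbivory")
  expect_equal(round(herb$p, 4), 0.0083)
  zero <- coef_test(fit, "slope", hypothesized = 0.347821)
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(coef_test(fit, "nope"), "no coefficient")
})

test_that("releveling re-parameterizes without changing the model", {
  d <- make_study_like_dataset(synthetic_config(seed = 5, n_taxa = 80))
  spec <- design_spec(c("clade", "diet"),
                      reference_levels = c(clade = "Inopinaves",
                                           diet = "carnivore-vertebrates"))
  fit_a <- pgls_fit(d$traits, d$tree, spec, model = "brownian")
  fit_b <- relevel_fit(d$traits, d$tree, spec,
                       c(clade = "Galloanserae", diet = "herbivore"),
                       model = "brownian")
  expect_equal(fit_a$loglik, fit_b$loglik, tolerance = 1e-10)
  expect_equal(fit_a$aic, fit_b$aic, tolerance = 1e-10)
  expect_equal(fit_a$fitted, fit_b$fitted, tolerance = 1e-8)
  expect_equal(fit_b$beta[["dietcarnivore-vertebrates"]],
               -fit_a$beta[["dietherbivore"]], tolerance = 1e-8)
  expect_equal(fit_b$beta[["cladeInopinaves"]],
               -fit_a$beta[["cladeGalloanserae"]], tolerance = 1e-8)
})

test_that("fits agree with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  d <- make_study_like_dataset(synthetic_config(n_taxa = 80, seed = 55))
  spec <- design_spec(c("clade", "diet"),
                      reference_levels = c(clade = "Inopinaves",
                                           diet = "carnivore-vertebrates"))
  df <- as.data.frame(d$traits)
  df$clade <- stats::relevel(df$clade, "Inopinaves")
  df$diet <- stats::relevel(df$diet, "carnivore-vertebrates")

  mine_bm <- pgls_fit(d$traits, d$tree, spec, "brownian")
  ref_bm <- nlme::gls(log_cecum ~ log_mass + clade + diet, data = df,
                      correlation = ape::corBrownian(1, phy = d$tree,
                                                     form = ~species),
                      method = "ML")
  expect_equal(unname(mine_bm$beta), unname(coef(ref_bm)), tolerance = 1e-8)
  expect_equal(unname(mine_bm$se), unname(sqrt(diag(vcov(ref_bm)))),
               tolerance = 1e-8)
  expect_equal(mine_bm$loglik, as.numeric(logLik(ref_bm)), tolerance = 1e-8)
  expect_equal(mine_bm$aic, AIC(ref_bm), tolerance = 1e-8)

  mine_ou <- pgls_fit(d$traits, d$tree, spec, "ou")
  ref_ou <- nlme::gls(log_cecum ~ log_mass + clade + diet, data = df,
                      correlation = ape::corMartins(0.3, phy = d$tree,
                                                    form = ~species),
                      method = "ML")
  expect_equal(mine_ou$model$alpha,
               unname(coef(ref_ou$modelStruct$corStruct)), tolerance = 1e-4)
  expect_equal(unname(mine_ou$beta), unname(coef(ref_ou)), tolerance = 1e-6)
  expect_equal(mine_ou$loglik, as.numeric(logLik(ref_ou)), tolerance = 1e-6)
  expect_equal(mine_ou$aic, AIC(ref_ou), tolerance = 1e-5)
})

test_that("rescaling body-mass units shifts intercepts, never the slope", {
  d <- make_study_like_dataset(synthetic_config(seed = 6, n_taxa = 80))
  fit_g <- pgls_fit(d$traits, d$tree, design_spec("clade"), "brownian")
  kg <- d$traits
  kg$body_mass_g <- kg$body_mass_g / 1000
  kg$log_mass <- log10(kg$body_mass_g)
  class(kg) <- class(d$traits)
  fit_kg <- pgls_fit(kg, d$tree, design_spec("clade"), "brownian")
  expect_equal(fit_kg$beta[["log_mass"]], fit_g$beta[["log_mass"]],
               tolerance = 1e-8)
  expect_equal(fit_kg$beta[["(Intercept)"]],
               fit_g$beta[["(Intercept)"]] + 3 * fit_g$beta[["log_mass"]],
               tolerance = 1e-8)
})

test_that("the model ladder ranks by unrounded AIC and flags rejections", {
  d <- make_study_like_dataset(synthetic_config(seed = 7, n_taxa = 100))
  specs <- list(design_spec(), design_spec("clade"),
                design_spec(c("clade", "diet")))
  lad <- fit_ladder(d$traits, d$tree, specs = specs)
  tab <- lad$table
  expect_equal(nrow(tab), 9)
  expect_equal(sum(tab$best), 1)
  expect_true(all(tab$delta_aic >= 0))
  expect_equal(min(tab$delta_aic), 0)
  expect_true(all(tab$rejected == (tab$delta_aic >= 3)))
  # AIC bookkeeping: pairwise differences equal -2*dLR + 2*dk
  i <- which(tab$design == "simple" & tab$model == "brownian")
  j <- which(tab$design == "additive: clade" & tab$model == "brownian")
  expect_equal(tab$aic[j] - tab$aic[i],
               -2 * (tab$loglik[j] - tab$loglik[i]) + 2 * (tab$k[j] - tab$k[i]),
               tolerance = 1e-10)
  # OU fits carry their estimated alpha and the extra parameter
  ou_rows <- tab$model == "ou"
  expect_true(all(is.finite(tab$alpha[ou_rows])))
  expect_true(all(tab$k[ou_rows] == tab$k[tab$model == "brownian"] + 1))
  expect_identical(best_fit(lad)$aic, min(tab$aic))
})

test_that("failed ladder cells are reported as missing, not fatal", {
  d <- make_study_like_dataset(synthetic_config(seed = 8, n_taxa = 60))
  sub <- d$traits[d$traits$diet != "nectarivore", ]
  class(sub) <- class(d$traits)
  al <- suppressMessages(align_to_tree(sub, d$tree, policy = "prune"))
  specs <- list(design_spec(), design_spec("diet"))
  expect_message(
    lad <- fit_ladder(al$traits, al$tree, specs = specs),
    "failed")
  tab <- lad$table
  expect_true(all(is.na(tab$aic[tab$design == "additive: diet"])))
  expect_true(all(is.finite(tab$aic[tab$design == "simple"])))
  expect_equal(sum(tab$best), 1)
})
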