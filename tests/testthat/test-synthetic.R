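test_that("Brownian simulation matches its closed-form moments", {
  tr <- yule_tree(30, depth = 10, seed = 71)
  expect_equal(unname(simulate_bm(tr, sigma2 = 0, root_value = 3, seed = 1)),
               rep(3, 30))
  n_rep <- 600
  sims <- vapply(seq_len(n_rep),
                 function(i) simulate_bm(tr, sigma2 = 2, seed = 7000 + i),
                 numeric(30))
  C <- phylo_vcv(tr)
  # tip variance ~ sigma2 * depth, within 3 standard errors of a variance
  v <- var(sims[1, ])
  se_v <- sqrt(2 / (n_rep - 1)) * 2 * C[1, 1]
  expect_lt(abs(v - 2 * C[1, 1]), 3 * se_v)
  # covariance of a non-trivial pair ~ sigma2 * shared path length
  ij <- which(C == max(C[upper.tri(C)]), arr.ind = TRUE)[1, ]
  cv <- cov(sims[ij[1], ], sims[ij[2], ])
  expect_lt(abs(cv - 2 * C[ij[1], ij[2]]), 3 * 2 * C[ij[1], ij[2]] * 0.5)
})

test_that("model-based simulation respects its covariance structure", {
  tr <- yule_tree(40, depth = 10, seed = 72)
  # lambda = 0: independent given the diagonal
  x <- simulate_with_model(tr, evo_model("lambda", lambda = 0), seed = 73)
  expect_equal(length(x), 40)
  # enormous alpha: pairwise correlations vanish
  n_rep <- 200
  sims <- vapply(seq_len(n_rep), function(i)
    simulate_with_model(tr, evo_model("ou", alpha = 50), seed = 7300 + i),
    numeric(40))
  cors <- cor(t(sims))
  expect_lt(mean(abs(cors[upper.tri(cors)])), 3 / sqrt(n_rep))
  # identical seed, identical draw
  expect_identical(
    simulate_with_model(tr, evo_model("brownian"), seed = 74),
    simulate_with_model(tr, evo_model("brownian"), seed = 74))
  expect_error(simulate_with_model(tr, evo_model("lambda", lambda = 99)),
               "exceeds")
})

test_that("lambda is recovered from lambda-model simulations", {
  tr <- yule_tree(150, depth = 10, seed = 75)
  est <- vapply(1:40, function(i) {
    x <- simulate_with_model(tr, evo_model("lambda", lambda = 0.5),
                             seed = 7500 + i)
    lambda_ml(tr, x)$lam_hat
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("Mk simulation is frozen at rate zero and mixes at high rate", {
  tr <- yule_tree(40, depth = 10, seed = 76)
  frozen <- simulate_mk(tr, n_states = 4, rate = 0, seed = 77)
  expect_equal(length(unique(frozen)), 1L)
  expect_equal(fitch_length(tr, frozen), 0L)
  expect_identical(simulate_mk(tr, 4, rate = 0.2, seed = 78),
                   simulate_mk(tr, 4, rate = 0.2, seed = 78))
  # at saturation the parsimony length matches the shuffle-null expectation
  n_rep <- 100
  steps <- vapply(seq_len(n_rep), function(i)
    fitch_length(tr, simulate_mk(tr, 4, rate = 50, seed = 7800 + i)),
    integer(1))
  one <- simulate_mk(tr, 4, rate = 50, seed = 79)
  shuf <- vapply(seq_len(n_rep), function(i) {
    set.seed(7900 + i)
    fitch_length(tr, stats::setNames(sample(unname(one)), names(one)))
  }, integer(1))
  se <- sqrt(var(steps) / n_rep + var(shuf) / n_rep)
  expect_lt(abs(mean(steps) - mean(shuf)), 3 * se + 1)
})

test_that("a noiseless study-like dataset lies exactly on the true line", {
  cfg <- synthetic_config(n_taxa = 40, seed = 81, sigma2 = 1e-16,
                          intercept = 0.5,
                          clade_offsets = c(Galloanserae = 0)[0],
                          diet_offsets = c(herbivore = 0)[0])
  d <- make_study_like_dataset(cfg)
  expect_equal(d$truth$n_clipped, 0)
  fit <- pgls_fit(d$traits, d$tree, design_spec(), "independent")
  expect_equal(fit$beta[["log_mass"]], 1 / 3, tolerance = 1e-6)
  expect_equal(fit$beta[["(Intercept)"]], 0.5, tolerance = 1e-6)
})

test_that("study-like datasets are reproducible and well-formed", {
  cfg <- synthetic_config(n_taxa = 60, seed = 82)
  d1 <- make_study_like_dataset(cfg)
  d2 <- make_study_like_dataset(cfg)
  expect_identical(write_tree(d1$tree), write_tree(d2$tree))
  expect_equal(as.data.frame(d1$traits), as.data.frame(d2$traits))
  d3 <- make_study_like_dataset(synthetic_config(n_taxa = 60, seed = 83))
  expect_false(identical(d1$traits$cecal_length_cm, d3$traits$cecal_length_cm))

  expect_s3_class(d1$traits, "trait_table")
  expect_equal(d1$traits$species, d1$tree$tip.label)
  expect_equal(nlevels(droplevels(d1$traits$diet)), 7)
  expect_equal(nlevels(droplevels(d1$traits$clade)), 7)
  # clade blocks are monophyletic
  for (cl in levels(d1$traits$clade)) {
    tips <- d1$traits$species[d1$traits$clade == cl]
    if (length(tips) > 1) {
      expect_true(ape::is.monophyletic(d1$tree, tips), info = cl)
    }
  }
  # back-transform round trip where ceca are present
  pos <- d1$traits$cecal_length_cm > 0
  expect_equal(log10(d1$traits$cecal_length_cm[pos] + 0.1),
               d1$traits$log_cecum[pos], tolerance = 1e-12)
})

test_that("synthetic output feeds the file-based pipeline unchanged", {
  d <- make_study_like_dataset(synthetic_config(n_taxa = 30, seed = 84))
  tf <- tempfile(fileext = ".nwk"); cf <- tempfile(fileext = ".csv")
  write_tree(d$tree, tf)
  write_traits(d$traits, cf)
  tree <- parse_tree(tf)
  traits <- load_traits(cf)
  al <- align_to_tree(traits, tree, policy = "strict")
  # serialization may reorder tips; compare by species
  expect_setequal(al$traits$species, d$traits$species)
  expect_equal(al$traits$species, al$tree$tip.label)
  got <- stats::setNames(al$traits$log_cecum, al$traits$species)
  want <- stats::setNames(d$traits$log_cecum, d$traits$species)
  expect_equal(got[names(want)], want, tolerance = 1e-6)
})
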