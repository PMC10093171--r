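test_that("phylogenetic ANOVA reduces to ordinary ANOVA on a star tree", {
  st <- star_tree(30)
  set.seed(1)
  g <- stats::setNames(factor(rep(1:3, each = 10)), st$tip.label)
  y <- stats::setNames(rnorm(30) + 3 * (as.integer(g) == 2), st$tip.label)
  a <- phyl_anova(y, g, st, n_sim = 500, seed = 1)
  expect_lt(a$p_phylo, 0.01)                       # huge planted effect
  naive <- anova(lm(y ~ g))$`Pr(>F)`[1]
  expect_lt(naive, 0.01)
  # post hocs: group 2 differs from 1 and 3; 1 vs 3 does not
  ph <- a$pairwise
  expect_lt(ph$p_corrected[ph$group1 == "1" & ph$group2 == "2"], 0.05)
  expect_lt(ph$p_corrected[ph$group1 == "2" & ph$group2 == "3"], 0.05)
  expect_gt(ph$p_corrected[ph$group1 == "1" & ph$group2 == "3"], 0.5)
})

test_that("phylogenetic ANOVA matches the phytools oracle", {
  tr <- make_tree(40, seed = 5)
  y <- simulate_bm(tr, lambda = 1, seed = 3)
  set.seed(8)
  g <- stats::setNames(factor(sample(rep(1:2, each = 20))), names(y))
  a <- phyl_anova(y, g, tr, n_sim = 1000, seed = 2)
  pa <- phytools::phylANOVA(tr, g, y, nsim = 1000, posthoc = FALSE)
  expect_equal(a$F_obs, pa$F, tolerance = 1e-9)
  expect_lt(abs(a$p_phylo - pa$Pf), 0.05)
})

test_that("clade-confounded groups inflate the phylogenetic p-value", {
  tr <- make_tree(40, seed = 11)
  cls <- osteopose:::clade_classes(tr, 2)
  g <- stats::setNames(factor(cls), tr$tip.label)
  hits <- 0
  for (i in 1:8) {
    y <- simulate_bm(tr, lambda = 1, seed = 400 + i)
    a <- phyl_anova(y, g, tr, n_sim = 300, seed = i)
    naive <- anova(lm(y ~ g))$`Pr(>F)`[1]
    hits <- hits + (a$p_phylo > naive)
  }
  expect_gte(hits, 6)
})

test_that("exclusion lists are applied and cannot empty a group", {
  st <- star_tree(12)
  g <- stats::setNames(factor(rep(1:2, each = 6)), st$tip.label)
  y <- stats::setNames(rnorm(12), st$tip.label)
  a <- phyl_anova(y, g, st, n_sim = 100, seed = 1,
                  exclude = c("t1", "t2"))
  expect_equal(sum(a$groups_used), 10)
  expect_error(
    phyl_anova(y, g, st, n_sim = 100, exclude = paste0("t", 1:5)),
    "fewer than 2")
})

test_that("Pagel lambda is recovered from Brownian simulations", {
  tr <- make_tree(150, seed = 2)
  set.seed(9)
  lams <- vapply(1:10, function(i) {
    y <- simulate_bm(tr, lambda = 1, seed = 5000 + i)
    pagel_lambda_signal(y, tr)$statistic
  }, numeric(1))
  expect_gte(mean(lams), 0.9)
})

test_that("tip shuffling destroys the lambda signal", {
  tr <- make_tree(150, seed = 2)
  ok <- 0
  for (i in 1:10) {
    y <- simulate_bm(tr, lambda = 1, seed = 6000 + i)
    set.seed(i)
    ysh <- stats::setNames(sample(y), names(y))
    r <- pagel_lambda_signal(ysh, tr)
    ok <- ok + (r$statistic < 0.2 && r$p_value > 0.05)
  }
  expect_gte(ok, 9)
})

test_that("lambda estimate agrees with phytools and the profile is unimodal", {
  tr <- make_tree(120, seed = 4)
  y <- simulate_bm(tr, lambda = 0.7, seed = 21)
  ours <- pagel_lambda_signal(y, tr)
  pt <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(ours$statistic, pt$lambda, tolerance = 1e-3)
  expect_equal(ours$p_value, pt$P, tolerance = 1e-4)
  C1 <- phylo_covariance(tr, 1, taxa = names(y))
  ones <- matrix(1, length(y), 1)
  grid <- seq(0, 1, by = 0.05)
  ll <- vapply(grid, function(lam) {
    osteopose:::lambda_profile_loglik(lam, y = y, X = ones, tree_C = C1)
  }, numeric(1))
  peak <- which.max(ll)
  expect_true(all(diff(ll[seq_len(peak)]) > -1e-6))
  expect_true(all(diff(ll[peak:length(ll)]) < 1e-6))
})

test_that("delta statistic flags clade-clustered traits and not shuffled ones", {
  tr <- make_tree(64, seed = 7)
  cls <- osteopose:::clade_classes(tr, 2)
  clustered <- stats::setNames(factor(paste0("s", cls)), tr$tip.label)
  d1 <- delta_signal(clustered, tr, n_shuffle = 200, seed = 1)
  expect_lte(d1$p_value, 0.05)
  expect_gt(d1$statistic, 0)
  set.seed(2)
  rnd <- stats::setNames(factor(sample(rep(c("a", "b"), 32))), tr$tip.label)
  d2 <- delta_signal(rnd, tr, n_shuffle = 200, seed = 1)
  expect_gt(d2$p_value, 0.05)
  expect_gt(d2$statistic, 0)
})

test_that("delta rejects invariant or singleton-state traits", {
  tr <- make_tree(16, seed = 3)
  expect_error(
    delta_signal(stats::setNames(factor(rep("a", 16)), tr$tip.label), tr),
    "invariant")
  states <- factor(c("b", rep("a", 15)))
  expect_error(
    delta_signal(stats::setNames(states, tr$tip.label), tr),
    "at least 2 tips")
})

test_that("ancestral machinery matches the ape::ace oracle", {
  tr <- make_tree(48, seed = 9)
  cls <- osteopose:::clade_classes(tr, 2)
  states <- stats::setNames(factor(paste0("s", cls)), tr$tip.label)
  fit <- osteopose:::er_fit(tr, states)
  ac <- ape::ace(states, tr, type = "discrete", model = "ER")
  expect_equal(fit$rate, ac$rates, tolerance = 1e-3)
  expect_lt(max(abs(fit$anc - ac$lik.anc)), 1e-4)
})

test_that("PGLS at lambda 0 reproduces ordinary least squares", {
  tr <- make_tree(50, seed = 3)
  x <- simulate_bm(tr, seed = 7)
  y <- 2 * x + simulate_bm(tr, seed = 8)
  f <- pgls(y, x, tr, lambda = 0)
  ols <- lm(y ~ x)
  expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-9)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
  expect_equal(f$R2, summary(ols)$r.squared, tolerance = 1e-9)
})

test_that("PGLS recovers a planted slope under Brownian residuals", {
  hits <- 0
  for (i in 1:10) {
    tr <- make_tree(100, seed = 700 + i)
    x <- simulate_bm(tr, seed = 800 + i)
    y <- 2 * x + simulate_bm(tr, sigma2 = 0.2, seed = 900 + i)
    f <- pgls(y, x, tr)
    hits <- hits + (f$slope > 1.8 && f$slope < 2.2)
  }
  expect_gte(hits, 9)
})

test_that("PGLS ML fit matches the nlme corPagel oracle", {
  skip_if_not_installed("nlme")
  tr <- make_tree(50, seed = 3)
  x <- simulate_bm(tr, seed = 7)
  y <- 2 * x + simulate_bm(tr, seed = 8)
  f <- pgls(y, x, tr)
  gfit <- nlme::gls(y ~ x, data = data.frame(y = y, x = x, taxon = names(y)),
                    correlation = ape::corPagel(0.5, tr, form = ~taxon),
                    method = "ML")
  expect_equal(f$slope, unname(coef(gfit)[2]), tolerance = 1e-4)
  lam_nlme <- unname(coef(gfit$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(f$lambda_hat, lam_nlme, tolerance = 0.02)
})

test_that("PGLS rejects constant predictors and short data", {
  tr <- make_tree(12, seed = 1)
  y <- simulate_bm(tr, seed = 2)
  x <- stats::setNames(rep(1, 12), names(y))
  expect_error(pgls(y, x, tr), "constant")
  expect_error(pgls(y[1:5], simulate_bm(tr, seed = 3)[1:5],
                    ape::keep.tip(tr, names(y)[1:5])), "at least 10")
})

test_that("axis models find a planted mass effect and no ecology effect", {
  mass_hits <- 0
  eco_rejects <- 0
  for (i in 1:20) {
    set.seed(i)
    n <- 48
    eco <- factor(sample(c("Aq", "Te", "Fo", "Ar"), n, TRUE))
    mass <- 10^runif(n, 1, 5)
    coords <- 0.8 * log10(mass) + rnorm(n, 0, 0.3)
    r <- axis_ecology_models(coords, eco, mass)
    p_mass <- r$terms$p[r$terms$term == "logmass"]
    p_eco <- r$terms$p[r$terms$term == "ecology"]
    mass_hits <- mass_hits + (p_mass < 0.05)
    eco_rejects <- eco_rejects + (!is.na(p_eco) && p_eco < 0.05)
  }
  expect_gte(mass_hits, 18)    # the planted effect is found
  expect_lte(eco_rejects, 4)   # ecology rejections stay near the alpha level
})

test_that("planted slope heterogeneity keeps the interaction term", {
  hits <- 0
  for (i in 1:10) {
    set.seed(100 + i)
    n <- 60
    eco <- factor(sample(c("Aq", "Te"), n, TRUE))
    mass <- 10^runif(n, 1, 5)
    slope <- ifelse(eco == "Aq", 1.2, -0.6)
    coords <- slope * log10(mass) + rnorm(n, 0, 0.25)
    r <- axis_ecology_models(coords, eco, mass)
    hits <- hits + r$interaction_kept
  }
  expect_gte(hits, 9)
})

test_that("constant coordinates produce no significant terms", {
  set.seed(5)
  eco <- factor(sample(c("Aq", "Te", "Fo", "Ar"), 40, TRUE))
  mass <- 10^runif(40, 1, 5)
  r <- axis_ecology_models(rep(1, 40), eco, mass)
  expect_false(any(r$terms$p < 0.05, na.rm = TRUE))
})

test_that("a planted ecology effect triggers BH-corrected contrasts", {
  set.seed(4)
  n <- 60
  eco <- factor(sample(c("Aq", "Te", "Fo", "Ar"), n, TRUE))
  mass <- 10^runif(n, 1, 5)
  coords <- 0.5 * log10(mass) + 2 * (eco == "Aq") + rnorm(n, 0, 0.3)
  r <- axis_ecology_models(coords, eco, mass)
  expect_lt(r$terms$p[r$terms$term == "ecology"], 0.05)
  expect_s3_class(r$posthoc, "data.frame")
  aq_rows <- grepl("Aq", r$posthoc$contrast)
  expect_true(all(r$posthoc$p_adjusted[aq_rows] < 0.05))
  expect_true(all(r$posthoc$p_adjusted[!aq_rows] > 0.05))
})
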