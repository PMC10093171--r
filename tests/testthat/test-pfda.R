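test_that("correlated-variable pruning keeps one representative per cluster", {
  set.seed(1)
  x <- rnorm(60)
  d <- data.frame(a = x, b = x, c = rnorm(60))
  kept <- prune_correlated(d, c("a", "b", "c"))
  expect_length(kept, 2)
  expect_true("c" %in% kept)
  expect_length(intersect(kept, c("a", "b")), 1)
})

test_that("pruning follows the hand-computed complete-linkage clustering", {
  # |r(1,2)| = 0.99, |r(1,3)| small: clusters {1,2} and {3}
  set.seed(2)
  n <- 200
  v1 <- rnorm(n)
  v2 <- v1 + rnorm(n, sd = sqrt(1 / 0.99^2 - 1))
  v3 <- rnorm(n)
  d <- data.frame(v1 = v1, v2 = v2, v3 = v3)
  stopifnot(abs(cor(v1, v2)) > 0.97)
  kept <- prune_correlated(d, c("v1", "v2", "v3"))
  expect_length(kept, 2)
  expect_true("v3" %in% kept)
  # priority order decides the representative
  kept2 <- prune_correlated(d, c("v1", "v2", "v3"), priority = c("v2"))
  expect_setequal(kept2, c("v2", "v3"))
  # missing values are a hard error
  d$v1[3] <- NA
  expect_error(prune_correlated(d, c("v1", "v2", "v3")), "missing")
})

test_that("PFDA at lambda 0 equals the plain LDA oracle exactly", {
  for (i in 1:10) {
    d <- make_trait_dataset(n_tips = 30, n_classes = 3,
                            class_mode = "random", shifts = 1.5,
                            n_vars = 3, seed = i)
    m <- fit_pfda(d$data, d$tree, paste0("V", 1:3), "class", lambda = 0)
    ld <- MASS::lda(d$data[, paste0("V", 1:3)], grouping = d$data$class)
    expect_identical(as.character(m$training_assignments),
                     as.character(predict(ld)$class))
  }
})

test_that("equal-depth star trees reduce to LDA at any lambda", {
  st <- star_tree(24)
  for (lam in c(0, 0.4, 1)) {
    d <- make_trait_dataset(tree = st, n_classes = 2, class_mode = "random",
                            shifts = 2, n_vars = 2, seed = 7)
    m <- fit_pfda(d$data, st, c("V1", "V2"), lambda = lam)
    ld <- MASS::lda(d$data[, c("V1", "V2")], grouping = d$data$class)
    expect_identical(as.character(m$training_assignments),
                     as.character(predict(ld)$class))
  }
})

test_that("well-separated classes train and cross-validate at 100 percent", {
  d <- make_trait_dataset(n_tips = 36, n_classes = 2, class_mode = "random",
                          shifts = 8, n_vars = 2, lambda = 0, sigma2 = 0.5,
                          noise = 0.1, seed = 5)
  m <- fit_pfda(d$data, d$tree, c("V1", "V2"),
                lambda_grid = seq(0, 1, 0.1))
  expect_equal(mean(m$training_assignments == m$training_classes), 1)
  cv <- loo_cv(d$data, d$tree, c("V1", "V2"), lambda_grid = seq(0, 1, 0.1))
  expect_equal(cv$pcc, 100)
})

test_that("optimised lambda minimises the error over the grid endpoints", {
  d <- make_trait_dataset(n_tips = 30, n_classes = 2, class_mode = "clade",
                          shifts = 1, n_vars = 2, seed = 9)
  m <- fit_pfda(d$data, d$tree, c("V1", "V2"),
                lambda_grid = seq(0, 1, 0.05))
  path <- m$error_path
  expect_equal(min(path$error), m$error)
  expect_lte(m$error, path$error[path$lambda == 0])
  expect_lte(m$error, path$error[path$lambda == 1])
})

test_that("label permutation drops LOO PCC to chance level", {
  devs <- vapply(1:8, function(i) {
    d <- make_trait_dataset(n_tips = 30, n_classes = 2,
                            class_mode = "random", shifts = 2, n_vars = 2,
                            lambda = 0, seed = 100 + i)
    dd <- d$data
    set.seed(i)
    dd$class <- sample(dd$class)
    majority <- 100 * max(table(dd$class)) / nrow(dd)
    loo_cv(dd, d$tree, c("V1", "V2"),
           lambda_grid = c(0, 0.5, 1))$pcc - majority
  }, numeric(1))
  expect_lt(abs(mean(devs)), 10)
})

test_that("PCC is invariant to variable order within a subset", {
  d <- make_trait_dataset(n_tips = 24, n_classes = 2, class_mode = "random",
                          shifts = 1.5, n_vars = 3, seed = 3)
  a <- loo_cv(d$data, d$tree, c("V1", "V3", "V2"), lambda = 0.2)
  b <- loo_cv(d$data, d$tree, c("V2", "V1", "V3"), lambda = 0.2)
  expect_equal(a$pcc, b$pcc)
})

test_that("subset enumeration is complete", {
  expect_length(enumerate_subsets(letters[1:4]), 15)
  expect_length(enumerate_subsets("a"), 1)
  subs <- enumerate_subsets(letters[1:3])
  expect_setequal(vapply(subs, paste, character(1), collapse = ""),
                  c("a", "b", "c", "ab", "ac", "bc", "abc"))
  # the reference design: 9 retained variables over 100 trees
  expect_equal(length(enumerate_subsets(paste0("v", 1:9))) * 100, 51100)
  expect_gte(length(enumerate_subsets(paste0("v", 1:9))) * 100, 50000)
})

test_that("exhaustive selection ranks the planted subset on top", {
  d <- planted_dataset(1, n = 32, n_vars = 4)
  trees <- lapply(1:2, function(i) make_tree(32, seed = 100 + i))
  class(trees) <- "multiPhylo"
  sel <- exhaustive_selection(d$data, trees, paste0("V", 1:4),
                              lambda_grid = seq(0, 1, 0.25))
  expect_equal(nrow(sel$table), 15)
  expect_equal(sel$n_procedures, 30)
  expect_true(all(c("V1", "V2") %in% sel$best))
  # mean PCC lies within the per-tree envelope
  rng <- apply(sel$per_tree, 1, range)
  expect_true(all(sel$table$mean_pcc >= rng[1, as.integer(rownames(sel$table))] - 1e-9))
  expect_true(all(sel$table$mean_pcc <= rng[2, as.integer(rownames(sel$table))] + 1e-9))
})

test_that("fossil inference votes are normalised and deterministic", {
  d <- planted_dataset(4, n = 28, n_vars = 3, shift = 4)
  dd <- d$data
  # two identical inference rows placed at the class-2 signal
  dd$role[27:28] <- "inference"
  dd[27, paste0("V", 1:3)] <- dd[28, paste0("V", 1:3)]
  dd$class[27:28] <- NA
  trees <- lapply(1:3, function(i) make_tree(28, seed = 50 + i))
  class(trees) <- "multiPhylo"
  inf <- infer_extinct(dd, trees, c("V1", "V2"),
                       lambda_grid = seq(0, 1, 0.25))
  expect_equal(unname(rowSums(inf$votes)), c(1, 1))
  expect_equal(inf$votes[1, ], inf$votes[2, ])
  inf2 <- infer_extinct(dd, trees, c("V1", "V2"),
                        lambda_grid = seq(0, 1, 0.25))
  expect_identical(inf$votes, inf2$votes)
})

test_that("a training row sitting on a class centroid gets that class", {
  d <- make_trait_dataset(n_tips = 20, n_classes = 2, class_mode = "random",
                          shifts = 3, n_vars = 2, lambda = 0, noise = 0.1,
                          seed = 8)
  m <- fit_pfda(d$data, d$tree, c("V1", "V2"), lambda = 0)
  # move a synthetic query onto each centroid: nearest-centroid must agree
  for (k in seq_along(m$class_levels)) {
    cls <- osteopose:::classify_scores(m$centroids[k, , drop = FALSE],
                                       m$centroids, m$priors,
                                       m$class_levels)
    expect_equal(as.character(cls), m$class_levels[k])
  }
})

test_that("inference taxa missing model variables are dropped with warning", {
  d <- planted_dataset(6, n = 24, n_vars = 3, shift = 4)
  dd <- d$data
  dd$role[23:24] <- "inference"
  dd$class[23:24] <- NA
  dd$V1[23] <- NA
  trees <- list(make_tree(24, seed = 5))
  class(trees) <- "multiPhylo"
  expect_warning(
    inf <- infer_extinct(dd, trees, c("V1", "V2"),
                         lambda_grid = c(0, 1)),
    "dropped")
  expect_equal(rownames(inf$votes), "t24")
})
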