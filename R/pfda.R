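# Phylogenetic flexible discriminant analysis: correlated-variable pruning,
# lambda-optimised GLS-whitened discriminant fitting, leave-one-out
# cross-validation, exhaustive subset x tree selection, and fossil
# inference by vote aggregation over a tree population.

#' Prune highly correlated variables
#'
#' Builds the dissimilarity `1 - |Pearson r|` between variables, clusters it
#' by complete linkage, cuts the dendrogram at height `1 - threshold` (so
#' variables with |r| above the threshold fall in one cluster), and keeps a
#' single representative per cluster, chosen as the first member in
#' `priority` (defaulting to the conventional retained-set ordering for the
#' 13 femoral parameters, then original column order).
#'
#' @param data data frame containing the variable columns.
#' @param variables character vector of variable columns to consider.
#' @param threshold correlation threshold (default 0.95).
#' @param priority character vector of preferred representatives.
#' @return character vector of retained variable names.
#' @export
prune_correlated <- function(data, variables = NULL, threshold = 0.95,
                             priority = c("Pe_min", "Ecc", "SR", "C_obs",
                                          "P", "S", "RS", "RPSD", "RSSD")) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(length(variables) >= 2L)
  X <- as.matrix(data[, variables, drop = FALSE])
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing values in: ",
         paste(unique(paste0(variables[bad[, 2]], "[", bad[, 1], "]")),
               collapse = ", "))
  }
  dis <- stats::as.dist(1 - abs(stats::cor(X)))
  hc <- stats::hclust(dis, method = "complete")
  cl <- stats::cutree(hc, h = 1 - threshold)
  rank <- match(variables, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  keep <- vapply(split(seq_along(variables), cl), function(ix) {
    variables[ix][which.min(rank[ix])]
  }, character(1))
  # preserve original column order
  variables[variables %in% keep]
}

# Whitening operator for a taxa ordering: C(lambda) over `taxa`, normalised
# by its mean diagonal (tree-scale free), lower-Cholesky inverted. Row i of
# W %*% X involves only taxa 1..i, so ordering training taxa first keeps the
# training fit independent of the inference rows' values.
whitening <- function(tree, taxa, lambda) {
  C <- phylo_covariance(tree, lambda, taxa = taxa)
  C <- C / mean(diag(C))
  L <- t(chol(C))
  forwardsolve(L, diag(nrow(C)))
}

# Optimal-scoring model error at one lambda: the Gaussian GLS deviance of
# the whitened indicator regression, nK log(RSS/nK) + K log|C_train|. The
# log-determinant term makes the criterion comparable across lambda (a pure
# whitened RSS is not: the whitening rescales the responses); minimising it
# is profile ML for the optimal-scoring regression, so iid data drives
# lambda to 0 and Brownian-structured residuals drive it towards 1.
pfda_error <- function(W, X, G, train_idx) {
  Xw <- (W %*% cbind(1, X))[train_idx, , drop = FALSE]
  Gw <- (W %*% G)[train_idx, , drop = FALSE]
  f1 <- stats::lm.fit(Xw, Gw)
  rss <- sum(f1$residuals^2)
  K <- ncol(G)
  nobs <- length(train_idx) * K
  # W is the inverse lower Cholesky factor: log|C_train| from its diagonal
  logdet <- -2 * sum(log(diag(W)[train_idx]))
  list(error = nobs * log(rss / nobs) + K * logdet, rss = rss)
}

# Core discriminant fit on whitened data. Returns axes scaled to unit
# within-class (GLS residual) variance, GLS class centroids, priors.
pfda_core <- function(W, X, G, train_idx, priors) {
  K <- ncol(G)
  Xw_all <- W %*% X
  Gw <- (W %*% G)[train_idx, , drop = FALSE]
  Xw <- Xw_all[train_idx, , drop = FALSE]
  n <- length(train_idx)
  M <- solve(crossprod(Gw), crossprod(Gw, Xw))      # K x p GLS class means
  R <- Xw - Gw %*% M
  Sw <- crossprod(R) / (n - K)
  mu <- drop(priors %*% M)
  Mc <- sweep(M, 2, mu)
  Sb <- t(Mc) %*% (priors * Mc)
  U <- chol(Sw + diag(1e-10 * mean(diag(Sw)), ncol(Sw)))
  A0 <- backsolve(U, diag(ncol(Sw)))   # U^-1, so t(A0) Sw A0 = I
  Mstar <- t(A0) %*% Sb %*% A0
  eg <- eigen((Mstar + t(Mstar)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-8
  r <- min(K - 1L, sum(pos))
  if (r < 1L) stop("singular whitened design: no discriminating direction; ",
                   "try a smaller variable subset")
  A <- A0 %*% eg$vectors[, seq_len(r), drop = FALSE]   # a' Sw a = I
  list(axes = A, centroids = M %*% A, eigenvalues = eg$values[seq_len(r)],
       scores_all = Xw_all %*% A)
}

#' Fit a phylogenetic flexible discriminant model
#'
#' Builds the Pagel-lambda-scaled phylogenetic covariance over all rows of
#' the trait table (training and inference taxa; training ordered first),
#' whitens predictors and class indicators by the inverse lower Cholesky
#' factor, and fits a linear-basis flexible discriminant (optimal scoring /
#' canonical discriminant on the GLS-whitened data). Lambda is chosen on a
#' grid by minimising the optimal-scoring model error, measured as the
#' Gaussian GLS deviance of the whitened indicator regression (the
#' log-determinant term keeps values comparable across lambda); with
#' `lambda = 0` on an ultrametric tree the whitening is a scalar and the
#' fit reduces exactly to ordinary linear discriminant analysis.
#'
#' @param data trait table: data frame with a `taxon` column, the variable
#'   columns, the class column, and optionally a `role` column
#'   (`"training"`/`"inference"`; missing class also marks inference rows).
#' @param tree an `ape::phylo` covering all taxa in `data`.
#' @param variables character vector of predictor columns.
#' @param class_column name of the class factor column.
#' @param lambda `"grid"` (default: grid search) or a fixed value.
#' @param lambda_grid grid for the search (default `seq(0, 1, 0.01)`).
#' @param priors `"frequency"` (training class frequencies) or `"equal"`.
#' @param whiten_cache optional precomputed list mapping
#'   `as.character(lambda)` to whitening matrices for this tree/taxa order
#'   (used by [exhaustive_selection()] to share Cholesky factors between
#'   subsets).
#' @return object of class `discriminant_model`.
#' @export
fit_pfda <- function(data, tree, variables, class_column = "class",
                     lambda = "grid", lambda_grid = seq(0, 1, by = 0.01),
                     priors = c("frequency", "equal"), whiten_cache = NULL) {
  priors <- match.arg(priors)
  stopifnot(all(variables %in% names(data)),
            class_column %in% names(data),
            "taxon" %in% names(data))
  role <- if ("role" %in% names(data)) data$role else
    ifelse(is.na(data[[class_column]]), "inference", "training")
  role[is.na(data[[class_column]])] <- "inference"
  ord <- order(role != "training")     # training first, stable
  data <- data[ord, , drop = FALSE]
  role <- role[ord]
  taxa <- gsub(" ", "_", data$taxon)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  train_idx <- which(role == "training")
  X <- as.matrix(data[, variables, drop = FALSE])
  if (anyNA(X[train_idx, ])) stop("missing predictor values in training rows")
  g <- droplevels(factor(data[[class_column]][train_idx]))
  if (nlevels(g) < 2L) stop("need at least 2 classes")
  G <- matrix(0, nrow(data), nlevels(g))
  G[cbind(train_idx, as.integer(g))] <- 1
  colnames(G) <- levels(g)
  get_W <- function(lam) {
    key <- format(lam, digits = 12)
    if (!is.null(whiten_cache) && !is.null(whiten_cache[[key]])) {
      return(whiten_cache[[key]])
    }
    whitening(tree, taxa, lam)
  }
  if (identical(lambda, "grid")) {
    errs <- vapply(lambda_grid, function(lam) {
      pfda_error(get_W(lam), X, G, train_idx)$error
    }, numeric(1))
    lam_hat <- lambda_grid[which.min(errs)]
    err_path <- data.frame(lambda = lambda_grid, error = errs)
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam_hat <- lambda
    err_path <- NULL
  }
  W <- get_W(lam_hat)
  err <- pfda_error(W, X, G, train_idx)
  pri <- if (priors == "frequency") as.numeric(table(g)) / length(g)
         else rep(1 / nlevels(g), nlevels(g))
  core <- pfda_core(W, cbind(X), G, train_idx, pri)
  scores <- core$scores_all
  rownames(scores) <- taxa
  # training assignments: nearest centroid with prior adjustment
  assign_cls <- classify_scores(scores[train_idx, , drop = FALSE],
                                core$centroids, pri, levels(g))
  structure(list(
    variables = variables, class_column = class_column,
    lambda_hat = lam_hat, error = err$error, rss = err$rss,
    error_path = err_path,
    axes = core$axes, centroids = core$centroids,
    class_levels = levels(g), priors = pri,
    taxa = taxa, role = role, train_idx = train_idx,
    scores = scores, training_classes = g,
    training_assignments = assign_cls,
    eigenvalues = core$eigenvalues,
    tree = tree, data = data
  ), class = "discriminant_model")
}

# Nearest-centroid classification in the sphered discriminant space with a
# -2 log prior adjustment; ties broken deterministically by class-label
# lexical order (centroid rows are in level order).
classify_scores <- function(Z, centroids, priors, levels_) {
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), "+") -
    2 * Z %*% t(centroids)
  d2 <- sweep(d2, 2, 2 * log(priors))
  factor(levels_[apply(d2, 1, which.min)], levels = levels_)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("<discriminant_model> ", length(x$train_idx), " training taxa, ",
      length(x$class_levels), " classes, lambda_hat = ", x$lambda_hat,
      "\n  variables: ", paste(x$variables, collapse = ", "), "\n", sep = "")
  pcc <- 100 * mean(x$training_assignments == x$training_classes)
  cat("  training PCC: ", round(pcc, 1), "%\n", sep = "")
  invisible(x)
}

#' Predict classes for rows of a fitted discriminant model
#'
#' Assigns each requested taxon the class of the nearest class centroid in
#' the discriminant space (prior-adjusted), using the whitened scores
#' computed at fit time; taxa must have been present in the trait table
#' (training or inference) when the model was fitted.
#'
#' @param model a `discriminant_model`.
#' @param taxa taxa to predict; default all inference rows.
#' @return data frame: `taxon`, `class`, and the discriminant coordinates
#'   `DA1`, `DA2`, ...
#' @export
predict_pfda <- function(model, taxa = NULL) {
  if (is.null(taxa)) taxa <- model$taxa[model$role != "training"]
  taxa <- gsub(" ", "_", taxa)
  missing <- setdiff(taxa, model$taxa)
  if (length(missing)) {
    stop("taxa absent from the fitted design: ",
         paste(missing, collapse = ", "))
  }
  Z <- model$scores[taxa, , drop = FALSE]
  cls <- classify_scores(Z, model$centroids, model$priors,
                         model$class_levels)
  out <- data.frame(taxon = taxa, class = cls, stringsAsFactors = FALSE)
  colnames(Z) <- paste0("DA", seq_len(ncol(Z)))
  cbind(out, as.data.frame(Z, row.names = NULL))
}

#' Leave-one-out cross-validated percentage of correct classification
#'
#' Holds out each training taxon in turn, refits the discriminant on the
#' remaining n - 1 (lambda held at the full-data optimum for tractability),
#' predicts the held-out taxon by whitening it conditionally on the training
#' rows, and reports `PCC = 100 * correct / n`. Folds that would empty a
#' class are skipped with a warning.
#'
#' @inheritParams fit_pfda
#' @param lambda fixed lambda; `"grid"` optimises once on the full data.
#' @return list of class `loo_result`: `pcc`, `n`, `correct`, `lambda_hat`,
#'   `predictions`.
#' @export
loo_cv <- function(data, tree, variables, class_column = "class",
                   lambda = "grid", lambda_grid = seq(0, 1, by = 0.01),
                   priors = c("frequency", "equal"), whiten_cache = NULL) {
  priors <- match.arg(priors)
  full <- fit_pfda(data, tree, variables, class_column, lambda, lambda_grid,
                   priors, whiten_cache)
  lam <- full$lambda_hat
  tr <- full$train_idx
  d <- full$data[tr, , drop = FALSE]   # training rows, model order
  n <- nrow(d)
  g <- full$training_classes
  preds <- factor(rep(NA, n), levels = full$class_levels)
  for (i in seq_len(n)) {
    if (min(table(g[-i])) < 1L || nlevels(droplevels(g[-i])) < 2L) {
      warning("fold ", i, " skipped: a class would be emptied")
      next
    }
    di <- d
    di$role <- "training"
    di$role[i] <- "inference"
    m <- tryCatch(
      fit_pfda(di, tree, variables, class_column, lambda = lam,
               priors = priors),
      error = function(e) NULL)
    if (is.null(m)) next
    preds[i] <- predict_pfda(m, d$taxon[i])$class
  }
  done <- !is.na(preds)
  correct <- sum(preds[done] == g[done])
  structure(list(pcc = 100 * correct / sum(done), n = sum(done),
                 correct = correct, lambda_hat = lam,
                 predictions = data.frame(taxon = d$taxon, truth = g,
                                          predicted = preds)),
            class = "loo_result")
}

#' Enumerate all non-empty variable subsets
#'
#' @param variables character vector.
#' @return list of character vectors, `2^v - 1` of them.
#' @export
enumerate_subsets <- function(variables) {
  v <- length(variables)
  stopifnot(v >= 1L, v <= 20L)
  out <- vector("list", 2^v - 1L)
  for (m in seq_len(2^v - 1L)) {
    out[[m]] <- variables[bitwAnd(m, bitwShiftL(1L, seq_len(v) - 1L)) > 0L]
  }
  out
}

#' Exhaustive subset-by-tree model selection
#'
#' Runs leave-one-out cross-validation for every non-empty subset of the
#' retained variables on every tree of the population (lambda optimised per
#' subset and tree on the full training data), then ranks subsets by mean
#' PCC over trees (ties broken by mean AIC, then subset size). The AIC of
#' the optimal-scoring regression — its GLS deviance, log-determinant
#' included so values are comparable across lambda, plus `2 k` with
#' `k = |subset| (K - 1) + K` — is averaged alongside. Whitening matrices
#' are shared between subsets within a tree.
#'
#' @inheritParams fit_pfda
#' @param trees a `multiPhylo` (or list of `phylo`).
#' @param subsets optional list of subsets to evaluate (defaults to all
#'   `2^v - 1`).
#' @return list of class `selection_table`: `table` (data frame: subset,
#'   size, mean_pcc, mean_aic, rank), `per_tree` (matrix subsets x trees of
#'   PCC), `n_procedures`.
#' @export
exhaustive_selection <- function(data, trees, variables,
                                 class_column = "class",
                                 lambda_grid = seq(0, 1, by = 0.01),
                                 priors = c("frequency", "equal"),
                                 subsets = NULL) {
  priors <- match.arg(priors)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(subsets)) subsets <- enumerate_subsets(variables)
  ns <- length(subsets)
  nt <- length(trees)
  pcc <- matrix(NA_real_, ns, nt)
  aic <- matrix(NA_real_, ns, nt)
  role <- if ("role" %in% names(data)) data$role else "training"
  n_train <- sum(role == "training")
  for (ti in seq_len(nt)) {
    tree <- trees[[ti]]
    # precompute whitening per lambda once per tree (taxa order = model order)
    ord <- order(role != "training")
    taxa <- gsub(" ", "_", data$taxon[ord])
    cache <- lapply(lambda_grid, function(lam) whitening(tree, taxa, lam))
    names(cache) <- format(lambda_grid, digits = 12)
    for (si in seq_len(ns)) {
      cv <- loo_cv(data, tree, subsets[[si]], class_column,
                   lambda = "grid", lambda_grid = lambda_grid,
                   priors = priors, whiten_cache = cache)
      pcc[si, ti] <- cv$pcc
      K <- nlevels(factor(data[[class_column]][role == "training"]))
      m <- fit_pfda(data, tree, subsets[[si]], class_column,
                    lambda = cv$lambda_hat, priors = priors,
                    whiten_cache = cache)
      k <- length(subsets[[si]]) * (K - 1) + K
      # m$error is the GLS deviance of the optimal-scoring regression
      # (including the covariance log-determinant), so AICs are comparable
      # across subsets fitted at different lambda
      aic[si, ti] <- m$error + 2 * k
    }
  }
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets),
    mean_pcc = rowMeans(pcc),
    mean_aic = rowMeans(aic),
    stringsAsFactors = FALSE
  )
  tab$rank <- rank(-tab$mean_pcc, ties.method = "min")
  # ties on PCC are broken by mean AIC (smaller is better), then parsimony
  tab <- tab[order(-tab$mean_pcc, tab$mean_aic, tab$size), ]
  structure(list(table = tab, per_tree = pcc,
                 subsets = subsets,
                 best = subsets[[as.integer(rownames(tab)[1])]],
                 n_procedures = ns * nt * 1L),
            class = "selection_table")
}

#' Infer classes for extinct taxa over a tree population
#'
#' Fits the selected model on the training rows for each tree, predicts every
#' inference taxon, and aggregates the per-tree predictions into vote
#' fractions per class (summing to 1 per taxon). Inference taxa missing a
#' model variable are dropped with a warning.
#'
#' @inheritParams fit_pfda
#' @param trees a `multiPhylo`; fossils must already be present as tips
#'   (see [graft_fossils()]).
#' @param variables the selected variable subset.
#' @return list of class `inference_result`: `votes` (matrix taxa x classes
#'   of vote fractions), `per_tree` (data frame taxon x tree predictions),
#'   `lambda` (per-tree optimised lambda).
#' @export
infer_extinct <- function(data, trees, variables, class_column = "class",
                          lambda_grid = seq(0, 1, by = 0.01),
                          priors = c("frequency", "equal")) {
  priors <- match.arg(priors)
  if (inherits(trees, "phylo")) trees <- c(trees)
  role <- if ("role" %in% names(data)) data$role else
    ifelse(is.na(data[[class_column]]), "inference", "training")
  inf_rows <- which(role == "inference")
  if (!length(inf_rows)) stop("no inference rows flagged")
  drop <- inf_rows[apply(is.na(data[inf_rows, variables, drop = FALSE]),
                         1, any)]
  if (length(drop)) {
    warning("inference taxa missing model variables, dropped: ",
            paste(data$taxon[drop], collapse = ", "))
    data <- data[-drop, , drop = FALSE]
    role <- role[-drop]
  }
  taxa_inf <- gsub(" ", "_", data$taxon[role == "inference"])
  nt <- length(trees)
  preds <- matrix(NA_character_, length(taxa_inf), nt,
                  dimnames = list(taxa_inf, NULL))
  lambdas <- numeric(nt)
  cls_levels <- NULL
  for (ti in seq_len(nt)) {
    m <- fit_pfda(data, trees[[ti]], variables, class_column,
                  lambda = "grid", lambda_grid = lambda_grid,
                  priors = priors)
    lambdas[ti] <- m$lambda_hat
    cls_levels <- m$class_levels
    p <- predict_pfda(m, taxa_inf)
    preds[p$taxon, ti] <- as.character(p$class)
  }
  votes <- t(apply(preds, 1, function(r) {
    tabulate(factor(r, levels = cls_levels), nbins = length(cls_levels)) /
      sum(!is.na(r))
  }))
  colnames(votes) <- cls_levels
  structure(list(votes = votes, per_tree = preds, lambda = lambdas),
            class = "inference_result")
}
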