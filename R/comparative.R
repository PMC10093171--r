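# Comparative statistics: simulation-based phylogenetic ANOVA with
# Bonferroni post hocs, Pagel-lambda signal with an LR test, the
# entropy-based delta statistic for categorical traits, PGLS, and the
# ecology x mass linear models on discriminant-axis coordinates.

# ---- Gaussian phylogenetic likelihood machinery (shared) --------------------

# Profile log-likelihood of a GLS model y ~ X under covariance sigma2*C,
# with sigma2 profiled out by ML. Returns loglik, coefficients, sigma2 and
# the pieces needed for tests.
gls_profile <- function(y, X, C) {
  n <- length(y)
  L <- chol(C)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(L))) - n / 2
  list(loglik = ll, coef = fit$coefficients, sigma2 = sigma2, rss = rss,
       Xw = Xw, yw = yw, L = L)
}

lambda_profile_loglik <- function(lambda, y, X, tree_C) {
  d <- diag(tree_C)
  C <- tree_C * lambda
  diag(C) <- d
  gls_profile(y, X, C)$loglik
}

#' Pagel-lambda phylogenetic signal for a continuous trait
#'
#' Maximum-likelihood estimate of Pagel's lambda under the Gaussian
#' phylogenetic model with covariance `C(lambda)` (off-diagonals scaled,
#' diagonal untouched), with a likelihood-ratio test against `lambda = 0`
#' (chi-square, 1 df).
#'
#' @param trait named numeric vector over tips.
#' @param tree an `ape::phylo`.
#' @return list of class `signal_result`: `statistic` (lambda hat),
#'   `p_value`, `loglik`, `loglik0`, `method = "lambda"`.
#' @export
pagel_lambda_signal <- function(trait, tree) {
  trait <- align_trait(trait, tree)
  if (length(trait) < 10L) stop("need at least 10 tips")
  C1 <- phylo_covariance(tree, 1, taxa = names(trait))
  X <- matrix(1, length(trait), 1)
  opt <- stats::optimize(lambda_profile_loglik, c(0, 1), y = trait, X = X,
                         tree_C = C1, maximum = TRUE, tol = 1e-6)
  # guard the interval ends (optimize never evaluates exactly at them)
  ll_ends <- c(lambda_profile_loglik(0, trait, X, C1),
               lambda_profile_loglik(1, trait, X, C1))
  cand_l <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll_ends)
  best <- which.max(cand_ll)
  lam <- cand_l[best]
  ll <- cand_ll[best]
  ll0 <- ll_ends[1]
  p <- stats::pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE)
  structure(list(statistic = lam, p_value = p, loglik = ll, loglik0 = ll0,
                 method = "lambda"), class = "signal_result")
}

align_trait <- function(trait, tree) {
  if (is.null(names(trait))) {
    stopifnot(length(trait) == length(tree$tip.label))
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop("trait missing for tips: ", paste(missing, collapse = ", "))
  }
  trait[tree$tip.label]
}

#' Simulation-based phylogenetic ANOVA
#'
#' One-way ANOVA whose null distribution of the F statistic is generated by
#' simulating Brownian motion on the tree, with the rate and root state
#' estimated by ML from the observed trait. The phylogenetic p-value is the
#' fraction of simulated F values at or above the observed one. Pairwise
#' post hoc t statistics (pooled ANOVA variance) are referred to their own
#' simulated null distributions and Bonferroni-corrected.
#'
#' @param trait named numeric vector over tips.
#' @param groups factor over tips (same names/order as `trait`).
#' @param tree an `ape::phylo`.
#' @param n_sim number of Brownian null simulations.
#' @param seed RNG seed.
#' @param exclude optional character vector of taxa removed (with their
#'   group memberships) before the analysis, mirroring outlier screening.
#' @return list of class `anova_result`: `F_obs`, `p_phylo`, `n_sim`,
#'   `pairwise` (data frame: group1, group2, t, p_corrected), `groups_used`.
#' @export
phyl_anova <- function(trait, groups, tree, n_sim = 1000L, seed = NULL,
                       exclude = NULL) {
  trait <- align_trait(trait, tree)
  if (is.null(names(groups))) names(groups) <- names(trait)
  groups <- groups[names(trait)]
  if (!is.null(exclude)) {
    keep <- !(names(trait) %in% exclude)
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, names(trait)[keep]))
    trait <- trait[keep][tree$tip.label]
    groups <- groups[names(trait)]
  }
  groups <- droplevels(factor(groups))
  tab <- table(groups)
  if (any(tab < 2L)) {
    stop("group(s) with fewer than 2 members after exclusions: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  K <- nlevels(groups)
  n_tot <- length(trait)
  gi <- as.integer(groups)
  pr <- utils::combn(levels(groups), 2)
  pri <- utils::combn(seq_len(K), 2)
  nG <- as.numeric(tab)
  f_and_t <- function(y) {
    means <- tapply(y, gi, mean)
    gm <- mean(y)
    ssb <- sum(nG * (means - gm)^2)
    ssw <- sum((y - means[gi])^2)
    mse <- ssw / (n_tot - K)
    Fv <- (ssb / (K - 1)) / mse
    tt <- (means[pri[1, ]] - means[pri[2, ]]) /
      sqrt(mse * (1 / nG[pri[1, ]] + 1 / nG[pri[2, ]]))
    list(F = Fv, t = tt, pairs = pr)
  }
  obs <- f_and_t(trait)
  # ML Brownian rate + root under lambda = 1
  C <- phylo_covariance(tree, 1, taxa = names(trait))
  g <- gls_profile(trait, matrix(1, length(trait), 1), C)
  L <- chol(C)
  if (!is.null(seed)) set.seed(seed)
  n <- length(trait)
  npairs <- length(obs$t)
  f_sim <- numeric(n_sim)
  t_ge <- numeric(npairs)
  for (b in seq_len(n_sim)) {
    ysim <- drop(g$coef) + sqrt(g$sigma2) * drop(crossprod(L, stats::rnorm(n)))
    sm <- f_and_t(ysim)
    f_sim[b] <- sm$F
    t_ge <- t_ge + (abs(sm$t) >= abs(obs$t))
  }
  p_phylo <- (sum(f_sim >= obs$F) + 1) / (n_sim + 1)
  p_pair <- pmin(1, (t_ge + 1) / (n_sim + 1) * npairs)
  pairwise <- data.frame(group1 = obs$pairs[1, ], group2 = obs$pairs[2, ],
                         t = as.numeric(obs$t),
                         p_corrected = as.numeric(p_pair),
                         stringsAsFactors = FALSE)
  structure(list(F_obs = obs$F, p_phylo = p_phylo, n_sim = n_sim,
                 pairwise = pairwise, groups_used = tab),
            class = "anova_result")
}

# ---- delta statistic for categorical traits --------------------------------

# Felsenstein pruning for a k-state equal-rates Markov model; returns the
# log-likelihood and, on request, marginal ancestral state probabilities at
# the internal nodes (up-down algorithm).
er_pruning <- function(tree, states, rate, marginals = FALSE) {
  k <- nlevels(states)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- n + nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  # ER transition probability: P(t) = 1/k + (I - 1/k) exp(-k r t)
  pmat <- function(t) {
    e <- exp(-k * rate * t)
    matrix((1 - e) / k, k, k) + diag(e, k)
  }
  down <- matrix(1, ntot, k)          # conditional likelihoods (scaled)
  scale_log <- numeric(ntot)
  down[seq_len(n), ] <- 0
  down[cbind(seq_len(n), as.integer(states))] <- 1
  Plist <- vector("list", nrow(edge))
  for (e in seq_len(nrow(edge))) {
    Plist[[e]] <- pmat(elen[e])
  }
  # postorder edge traversal accumulates child messages into parents
  msg <- matrix(NA_real_, nrow(edge), k)  # message along each edge (to parent)
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2]
    msg[e, ] <- Plist[[e]] %*% down[ch, ]
    down[edge[e, 1], ] <- down[edge[e, 1], ] * msg[e, ]
    m <- max(down[edge[e, 1], ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      down[edge[e, 1], ] <- down[edge[e, 1], ] / m
      scale_log[edge[e, 1]] <- scale_log[edge[e, 1]] + log(m)
    }
  }
  root <- n + 1L
  # propagate accumulated scaling up to the root total
  total_scale <- 0
  for (nd in (n + seq_len(nnode))) total_scale <- total_scale + scale_log[nd]
  lik_root <- sum(down[root, ] / k)
  ll <- log(lik_root) + total_scale
  if (!marginals) return(list(loglik = ll))
  # upward pass: partial likelihoods excluding the subtree below each node
  up <- matrix(NA_real_, ntot, k)
  up[root, ] <- 1 / k
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    par <- edge[e, 1]; ch <- edge[e, 2]
    sib <- down[par, ] / ifelse(msg[e, ] > 0, msg[e, ], 1)
    # guard zero messages: recompute sibling product explicitly
    if (any(msg[e, ] == 0)) {
      sib <- rep(1, k)
      for (e2 in which(edge[, 1] == par)) {
        if (e2 != e) sib <- sib * msg[e2, ]
      }
    }
    up[ch, ] <- drop(t(Plist[[e]]) %*% (up[par, ] * sib))
    s <- sum(up[ch, ])
    if (s > 0) up[ch, ] <- up[ch, ] / s
  }
  anc <- matrix(NA_real_, nnode, k)
  for (nd in (n + seq_len(nnode))) {
    pr <- down[nd, ] * up[nd, ]
    anc[nd - n, ] <- pr / sum(pr)
  }
  colnames(anc) <- levels(states)
  list(loglik = ll, anc = anc)
}

er_fit <- function(tree, states) {
  height <- max(ape::node.depth.edgelength(tree))
  opt <- stats::optimize(function(lr) {
    er_pruning(tree, states, exp(lr))$loglik
  }, interval = log(c(1e-4 / height, 100 / height)), maximum = TRUE,
  tol = 1e-3)
  rate <- exp(opt$maximum)
  pr <- er_pruning(tree, states, rate, marginals = TRUE)
  list(rate = rate, loglik = pr$loglik, anc = pr$anc)
}

delta_from_states <- function(tree, states) {
  fit <- er_fit(tree, states)
  k <- nlevels(states)
  h <- apply(fit$anc, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }) / log(k)                         # normalised node entropies in [0, 1]
  eps <- 1e-8
  h <- pmin(pmax(h, eps), 1 - eps)
  mean(1 - h) / mean(h)               # certainty-to-uncertainty ratio
}

#' Entropy-based (delta) phylogenetic signal for a categorical trait
#'
#' Reconstructs marginal ancestral state probabilities at every internal node
#' by maximum likelihood under an equal-rates Markov model, converts them to
#' normalised Shannon entropies, and summarises signal as the ratio of the
#' mean certainty `1 - h` to the mean uncertainty `h` over nodes: traits that
#' track the phylogeny yield confident reconstructions (low entropy) and a
#' large statistic. The p-value is the fraction of tip-shuffled replicates
#' whose statistic is at least the observed one.
#'
#' @param trait factor (or coercible) over tips, named or tree-ordered.
#' @param tree an `ape::phylo`.
#' @param n_shuffle number of tip permutations for the p-value.
#' @param seed RNG seed.
#' @return list of class `signal_result`: `statistic` (delta), `p_value`,
#'   `method = "delta"`.
#' @export
delta_signal <- function(trait, tree, n_shuffle = 1000L, seed = NULL) {
  if (is.null(names(trait))) {
    stopifnot(length(trait) == length(tree$tip.label))
    names(trait) <- tree$tip.label
  }
  states <- droplevels(factor(trait[tree$tip.label]))
  tab <- table(states)
  if (nlevels(states) < 2L) stop("signal undefined for invariant trait")
  if (any(tab < 2L)) {
    stop("each state needs at least 2 tips; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  obs <- delta_from_states(tree, states)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_shuffle)) {
    perm <- sample(states)
    ge <- ge + (delta_from_states(tree, perm) >= obs)
  }
  p <- (ge + 1) / (n_shuffle + 1)
  structure(list(statistic = obs, p_value = p, method = "delta",
                 n_shuffle = n_shuffle), class = "signal_result")
}

#' Phylogenetic generalised least squares regression
#'
#' GLS regression of `y` on `x` under covariance `C(lambda)` with lambda
#' estimated by ML profile (or fixed). Reports the slope test (t, df n - 2)
#' and a GLS R-squared (1 - RSS / TSS about the GLS intercept-only fit).
#'
#' @param y,x named numeric vectors over tips.
#' @param tree an `ape::phylo`.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @return list of class `pgls_fit`: `slope`, `intercept`, `lambda_hat`,
#'   `R2`, `p_slope`, `loglik`.
#' @export
pgls <- function(y, x, tree, lambda = "ML") {
  y <- align_trait(y, tree)
  x <- align_trait(x, tree)
  ok <- stats::complete.cases(y, x)
  if (sum(ok) < 10L) stop("need at least 10 complete cases")
  if (!all(ok)) {
    tree <- ape::drop.tip(tree, tree$tip.label[!ok])
    y <- y[tree$tip.label]; x <- x[tree$tip.label]
  }
  if (stats::sd(x) == 0) stop("degenerate design: x is constant")
  X <- cbind(1, x)
  C1 <- phylo_covariance(tree, 1, taxa = names(y))
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(lambda_profile_loglik, c(0, 1), y = y, X = X,
                           tree_C = C1, maximum = TRUE, tol = 1e-6)
    ll_ends <- c(lambda_profile_loglik(0, y, X, C1),
                 lambda_profile_loglik(1, y, X, C1))
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, ll_ends)
    lam <- cand[which.max(lls)]
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lam <- lambda
  }
  C <- phylo_covariance(tree, lam, taxa = names(y))
  g <- gls_profile(y, X, C)
  n <- length(y)
  # slope se from the GLS normal equations (unbiased error variance)
  XtX <- crossprod(g$Xw)
  s2 <- g$rss / (n - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tstat <- g$coef[2] / se
  p_slope <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  g0 <- gls_profile(y, matrix(1, n, 1), C)
  structure(list(slope = unname(g$coef[2]), intercept = unname(g$coef[1]),
                 lambda_hat = lam, R2 = 1 - g$rss / g0$rss,
                 p_slope = unname(p_slope), loglik = g$loglik),
            class = "pgls_fit")
}

#' Ecology x body-mass linear models on discriminant-axis coordinates
#'
#' Shifts the coordinates to be strictly positive (adding `|min| + 1`, which
#' keeps order and finite logs), log10-transforms them, and fits
#' `log10(coord) ~ ecology * log10(mass)` on extant taxa. If the interaction
#' is not significant at `alpha` (type-II F test) the model is refit without
#' it; when the ecology main effect is significant, pairwise contrasts of
#' ecology-adjusted means are run with Benjamini-Hochberg correction.
#'
#' @param coords numeric vector of scores on one discriminant axis.
#' @param ecology factor (4 levels in the reference design: semi-aquatic,
#'   terrestrial, fossorial, arboreal).
#' @param mass body mass in grams.
#' @param alpha significance gate for the interaction term.
#' @return list of class `axis_model_report`: `model` (the lm),
#'   `interaction_kept`, `terms` (data frame of type-II F tests),
#'   `posthoc` (data frame or NULL), `flagged_levels` (ecology levels with
#'   fewer than 2 taxa).
#' @export
axis_ecology_models <- function(coords, ecology, mass, alpha = 0.05) {
  stopifnot(length(coords) == length(ecology),
            length(coords) == length(mass))
  ecology <- droplevels(factor(ecology))
  flagged <- names(which(table(ecology) < 2L))
  d <- data.frame(
    y = log10(coords + abs(min(coords)) + 1),
    ecology = ecology,
    logmass = log10(mass)
  )
  if (stats::sd(d$y) < 1e-12) {
    # constant response: nothing to test
    terms <- data.frame(term = c("ecology", "logmass"),
                        F = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    return(structure(list(model = stats::lm(y ~ 1, data = d),
                          interaction_kept = FALSE, terms = terms,
                          posthoc = NULL, flagged_levels = flagged),
                     class = "axis_model_report"))
  }
  full <- stats::lm(y ~ ecology * logmass, data = d)
  a_full <- car::Anova(full, type = 2)
  p_int <- a_full["ecology:logmass", "Pr(>F)"]
  if (!is.na(p_int) && p_int < alpha) {
    model <- full
    keep_int <- TRUE
    a_tab <- a_full
  } else {
    model <- stats::lm(y ~ ecology + logmass, data = d)
    keep_int <- FALSE
    a_tab <- car::Anova(model, type = 2)
  }
  terms <- data.frame(term = rownames(a_tab),
                      F = a_tab$`F value`,
                      p = a_tab$`Pr(>F)`,
                      stringsAsFactors = FALSE)
  terms <- terms[terms$term != "Residuals", ]
  posthoc <- NULL
  p_eco <- terms$p[terms$term == "ecology"]
  if (length(p_eco) == 1L && !is.na(p_eco) && p_eco < alpha) {
    em <- emmeans::emmeans(model, "ecology")
    ph <- as.data.frame(graphics::pairs(em, adjust = "BH"))
    posthoc <- data.frame(contrast = ph$contrast, estimate = ph$estimate,
                          t = ph$t.ratio, p_adjusted = ph$p.value,
                          stringsAsFactors = FALSE)
  }
  structure(list(model = model, interaction_kept = keep_int, terms = terms,
                 posthoc = posthoc, flagged_levels = flagged),
            class = "axis_model_report")
}
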