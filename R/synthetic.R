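# Ground-truth generators: parametric annular bone sections and
# class-structured trait datasets evolved on trees. Every generator returns
# its own ground truth so each measurement and statistic has a recovery test.

#' Generate a parametric bone cross-section
#'
#' Builds a binary section on an elliptical outline (semi-axes
#' `outer_radius` and `outer_radius / axis_ratio`). In direction-normalised
#' radius `u` (0 at the medullary centre, 1 on the outline), the probability
#' that a pixel is bone follows the logistic
#' `1 / (1 + exp((p(theta) - u) / s_true))` with per-direction inner radius
#' `p(theta) = inner_radius + thickness_amp * sin(theta + thickness_phase)`.
#' `s_true = 0` gives a hard annulus. Salt-and-pepper noise flips pixels
#' inside the outline at rate `noise`. Deterministic under `seed`.
#'
#' @param size raster side length in pixels (default 512; large enough that
#'   pixelation error in the closed-form geometry checks is below 1%).
#' @param outer_radius outer semi-major axis, px.
#' @param inner_radius normalised inner radius in \[0, 1).
#' @param axis_ratio ratio of the outline's semi-axes (a/b >= 1).
#' @param thickness_amp,thickness_phase amplitude and phase of the sinusoidal
#'   per-direction modulation of the inner radius.
#' @param s_true logistic transition width in normalised radius (0 = sharp).
#' @param noise salt-and-pepper flip rate inside the outline.
#' @param resolution um/px for the emitted section.
#' @param seed RNG seed for the stochastic layers.
#' @param taxon,bone_length,side metadata for the emitted section.
#' @return list with `section` (a `section_image`) and ground truth:
#'   `C_true` (analytic bone-area fraction inside the outline), `P_true`
#'   (function of theta), `S_true`, and the generating spec.
#' @export
make_section <- function(size = 512L, outer_radius = 200, inner_radius = 0.5,
                         axis_ratio = 1, thickness_amp = 0,
                         thickness_phase = 0, s_true = 0, noise = 0,
                         resolution = 30, seed = 1L,
                         taxon = NA_character_, bone_length = NA_real_,
                         side = "right") {
  stopifnot(inner_radius >= 0, inner_radius < 1, axis_ratio >= 1,
            outer_radius < size / 2)
  a <- outer_radius
  b <- outer_radius / axis_ratio
  cx <- (size + 1) / 2
  cy <- (size + 1) / 2
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- row - cy
  dx <- col - cx
  theta <- atan2(dy, dx)
  # normalised radius on the elliptical outline
  u <- sqrt((dx / a)^2 + (dy / b)^2)
  p_theta <- function(th) inner_radius + thickness_amp * sin(th + thickness_phase)
  p <- p_theta(theta)
  inside <- u <= 1
  if (s_true <= 0) {
    bone <- inside & u >= p
  } else {
    set.seed(seed)
    prob <- 1 / (1 + exp((p - u) / s_true))
    bone <- inside & matrix(stats::runif(size^2), size, size) < prob
  }
  if (noise > 0) {
    set.seed(seed + 1L)
    flip <- inside & matrix(stats::runif(size^2), size, size) < noise
    bone <- xor(bone, flip)
  }
  # analytic global compactness: area fraction of bone inside the outline.
  # With per-direction normalisation the ellipse factors out exactly:
  # C = 1 - (1/2pi) Int p(theta)^2 dtheta for the sharp case; with a logistic
  # transition the radial integral Int_0^1 sigma((u-p)/s) 2u du is evaluated
  # numerically per direction.
  th_grid <- seq(-pi, pi, length.out = 2001L)[-1]
  if (s_true <= 0) {
    c_true <- 1 - mean(pmax(p_theta(th_grid), 0)^2)
  } else {
    u_grid <- seq(0, 1, length.out = 501L)
    du <- u_grid[2] - u_grid[1]
    c_true <- mean(vapply(th_grid, function(th) {
      f <- 1 / (1 + exp((p_theta(th) - u_grid) / s_true))
      sum(f * 2 * u_grid) * du
    }, numeric(1)))
  }
  sec <- section_image(bone * 1L, resolution, side = side, taxon = taxon,
                       bone_length = bone_length)
  list(section = sec, C_true = c_true, P_true = p_theta, S_true = s_true,
       spec = list(size = size, outer_radius = outer_radius,
                   inner_radius = inner_radius, axis_ratio = axis_ratio,
                   thickness_amp = thickness_amp,
                   thickness_phase = thickness_phase,
                   s_true = s_true, noise = noise, seed = seed))
}

#' Simulate a pure-birth time tree
#'
#' Pure-birth (Yule) ultrametric tree with `n` tips, depth normalised to 1,
#' tip labels `t1..tn`. Deterministic under `seed`.
#'
#' @param n number of tips (>= 3).
#' @param seed RNG seed.
#' @return an `ape::phylo`.
#' @export
make_tree <- function(n, seed = 1L) {
  stopifnot(n >= 3)
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

#' Simulate a class-structured trait dataset on a tree
#'
#' Each variable is simulated as
#' `class mean shift + lambda-transformed Brownian deviation + iid noise`.
#' Class labels are either assigned by clade (the `n_classes` deepest
#' subtrees, giving maximal phylogenetic clustering) or uniformly at random.
#' The output is a trait table directly consumable by the discriminant and
#' comparative-statistics functions.
#'
#' @param tree an `ape::phylo`; if `NULL`, `make_tree(n_tips, seed)` is used.
#' @param n_tips tips for the generated tree when `tree` is `NULL`.
#' @param n_classes number of classes (default 3, mirroring the three
#'   locomotor modes).
#' @param class_mode `"clade"` or `"random"` label assignment.
#' @param shifts numeric matrix `n_classes x n_vars` of per-class mean
#'   shifts, or a single number applied to all variables for class 2..K
#'   (class 1 stays at 0); default 0 (no class signal).
#' @param n_vars number of trait variables (columns `V1..Vn`).
#' @param sigma2 Brownian rate.
#' @param lambda Pagel lambda of the phylogenetic deviation.
#' @param noise sd of the iid observation noise.
#' @param seed RNG seed.
#' @return list with `data` (data.frame: `taxon`, `class`, `role`, `V*`),
#'   `tree`, and the per-class `shifts` matrix actually used.
#' @export
make_trait_dataset <- function(tree = NULL, n_tips = 48L, n_classes = 3L,
                               class_mode = c("clade", "random"),
                               shifts = 0, n_vars = 4L, sigma2 = 1,
                               lambda = 1, noise = 0.05, seed = 1L) {
  class_mode <- match.arg(class_mode)
  if (is.null(tree)) tree <- make_tree(n_tips, seed)
  n <- length(tree$tip.label)
  set.seed(seed + 1000L)
  cls <- switch(class_mode,
    clade = clade_classes(tree, n_classes),
    random = sample(rep_len(seq_len(n_classes), n))
  )
  if (is.matrix(shifts)) {
    stopifnot(nrow(shifts) == n_classes, ncol(shifts) == n_vars)
    sh <- shifts
  } else {
    sh <- matrix(0, n_classes, n_vars)
    if (n_classes > 1) sh[2:n_classes, ] <- shifts * (seq_len(n_classes - 1))
  }
  X <- matrix(NA_real_, n, n_vars)
  for (v in seq_len(n_vars)) {
    bm <- simulate_bm(tree, sigma2 = sigma2, lambda = lambda,
                      root_state = 0, seed = seed + 7L * v)
    set.seed(seed + 7L * v + 3L)
    X[, v] <- sh[cls, v] + bm + stats::rnorm(n, sd = noise)
  }
  colnames(X) <- paste0("V", seq_len(n_vars))
  data <- data.frame(taxon = tree$tip.label,
                     class = factor(paste0("c", cls)),
                     role = "training",
                     X, stringsAsFactors = FALSE)
  list(data = data, tree = tree, shifts = sh)
}

# Split the tips into k groups by clade: repeatedly split the largest group
# at its root-most internal division.
clade_classes <- function(tree, k) {
  n <- length(tree$tip.label)
  groups <- list(seq_len(n))
  subtrees <- ape::prop.part(tree)
  # children of the root give the first split; recurse greedily on size
  while (length(groups) < k) {
    sizes <- lengths(groups)
    gi <- which.max(sizes)
    g <- groups[[gi]]
    # largest proper subset of g among clades
    cand <- Filter(function(p) length(p) < length(g) && all(p %in% g),
                   subtrees)
    if (length(cand) == 0L) break
    best <- cand[[which.max(lengths(cand))]]
    groups[[gi]] <- setdiff(g, best)
    groups[[length(groups) + 1L]] <- best
  }
  cls <- integer(n)
  for (i in seq_along(groups)) cls[groups[[i]]] <- i
  cls
}

#' Write a self-contained synthetic analysis bundle
#'
#' Generates a small class-structured trait dataset on a population of trees
#' (the last `n_fossils` taxa flagged for inference, their classes blanked),
#' writes `trait.csv`, `trees.nwk` and `config.yaml` into `dir`, and returns
#' the config path. The bundle is directly runnable with [run_pipeline()]
#' and is what the test suite and the documentation walkthrough use.
#'
#' @param dir output directory (created if needed).
#' @param n_taxa total taxa including fossils.
#' @param n_fossils trailing taxa treated as extinct inference targets.
#' @param n_classes classes for the discriminant problem.
#' @param n_trees trees in the population.
#' @param n_vars trait variables (`V1..Vn`; `V1`, `V2` carry the class
#'   signal).
#' @param shift class mean shift planted on `V1` (+) and `V2` (-).
#' @param seed RNG seed.
#' @return path to the written `config.yaml`.
#' @export
simulate_bundle <- function(dir, n_taxa = 28L, n_fossils = 2L,
                            n_classes = 2L, n_trees = 3L, n_vars = 4L,
                            shift = 2.5, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trees <- lapply(seq_len(n_trees), function(i) make_tree(n_taxa, seed + i))
  class(trees) <- "multiPhylo"
  d <- make_trait_dataset(tree = trees[[1]], n_classes = n_classes,
                          class_mode = "random", shifts = 0,
                          n_vars = n_vars, lambda = 1, noise = 0.1,
                          seed = seed)
  cls <- as.integer(d$data$class)
  d$data$V1 <- d$data$V1 + shift * (cls - 1)
  d$data$V2 <- d$data$V2 - shift * (cls - 1)
  tt <- d$data
  fossil <- seq(n_taxa - n_fossils + 1L, n_taxa)
  tt$role[fossil] <- "inference"
  tt$class <- as.character(tt$class)
  tt$class[fossil] <- NA
  set.seed(seed + 99L)
  tt$mass_g <- round(10^stats::rnorm(n_taxa, 3, 0.8), 2)
  tt$ecology <- sample(c("Aq", "Te", "Fo", "Ar"), n_taxa, replace = TRUE)
  utils::write.csv(tt, file.path(dir, "trait.csv"), row.names = FALSE)
  write_timetrees(trees, file.path(dir, "trees.nwk"))
  cfg <- list(trait_table = file.path(dir, "trait.csv"),
              tree_file = file.path(dir, "trees.nwk"),
              class_column = "class",
              variables = paste0("V", seq_len(n_vars)),
              log_transform = FALSE,
              lambda_step = 0.1,
              n_sim = 200L,
              seed = seed,
              output_dir = file.path(dir, "out"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
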