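# Tree I/O and the shared phylogenetic machinery: covariance matrices with
# Pagel-lambda scaling, fossil tip grafting at stated divergence ages, and
# seeded Brownian simulation. Trees are ape::phylo objects; branch lengths
# are in Ma and trees need not be ultrametric (fossil tips have positive
# ages).

#' Read a population of time trees
#'
#' Reads one or more Newick trees (one per line or a multi-tree file) and
#' normalises tip labels (spaces to underscores) so they match trait-table
#' taxa by exact string comparison.
#'
#' @param path Newick file.
#' @return a `multiPhylo` (even for a single tree).
#' @export
read_timetrees <- function(path) {
  if (!file.exists(path)) stop("no such tree file: ", path)
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  for (i in seq_along(trees)) {
    trees[[i]]$tip.label <- gsub(" ", "_", trees[[i]]$tip.label)
  }
  trees
}

#' Write trees to Newick
#'
#' @param trees a `phylo` or `multiPhylo`.
#' @param path output file.
#' @export
write_timetrees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}

# node ages (Ma before present): root age is the maximum root-to-node path
# length, assuming at least one tip is extant (age 0); every node's age is
# root age minus its depth.
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Phylogenetic covariance matrix with Pagel-lambda scaling
#'
#' `C[i, j]` is the shared path length (Ma) from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' Off-diagonal entries are multiplied by `lambda`; the diagonal is left
#' untouched, so `lambda = 0` gives independent tips with their original
#' variances and `lambda = 1` the Brownian expectation.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param lambda Pagel multiplier in \[0, 1\].
#' @param taxa optional character vector giving the row/column order (must
#'   all be tips of `tree`).
#' @return a symmetric positive semi-definite matrix with dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1, taxa = NULL) {
  stopifnot(lambda >= 0, lambda <= 1 + 1e-8)
  C <- ape::vcv(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) {
      stop("taxa absent from tree: ", paste(missing, collapse = ", "))
    }
    C <- C[taxa, taxa, drop = FALSE]
  }
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

#' Graft fossil tips onto a time tree
#'
#' Adds each fossil at its stated divergence age on the stem of an
#' attachment clade. `placements` is a data frame with columns `taxon`,
#' `attachment` (a tip label, or several labels separated by `;` whose MRCA
#' anchors the clade, or `"root"` for the root edge), `divergence_ma` and
#' `tip_age_ma`. The divergence age must fall inside the attachment edge's
#' age interval (for the root, at or above the root age: the root edge is
#' extended as needed); the fossil tip's branch length is
#' `divergence_ma - tip_age_ma`. The input tree is not modified; grafting is
#' recomputed per tree so fossil branch lengths track each tree's internal
#' ages.
#'
#' @param tree an `ape::phylo`.
#' @param placements data frame as described; see
#'   `system.file("extdata", "example_fossil_placements.csv",
#'   package = "osteopose")` for the CSV layout.
#' @return a new `phylo` containing the fossil tips.
#' @export
graft_fossils <- function(tree, placements) {
  req <- c("taxon", "attachment", "divergence_ma", "tip_age_ma")
  if (!all(req %in% names(placements))) {
    stop("placements must have columns: ", paste(req, collapse = ", "))
  }
  for (i in seq_len(nrow(placements))) {
    taxon <- gsub(" ", "_", placements$taxon[i])
    div <- placements$divergence_ma[i]
    tip_age <- placements$tip_age_ma[i]
    if (tip_age > div) {
      stop("placement ", taxon, ": tip age ", tip_age,
           " exceeds divergence age ", div)
    }
    att <- placements$attachment[i]
    ages <- node_ages(tree)
    root <- length(tree$tip.label) + 1L
    if (identical(att, "root")) {
      node <- root
    } else {
      labs <- gsub(" ", "_", strsplit(att, ";")[[1]])
      missing <- setdiff(labs, tree$tip.label)
      if (length(missing)) {
        stop("placement ", taxon, ": attachment tips absent from tree: ",
             paste(missing, collapse = ", "))
      }
      node <- if (length(labs) == 1L) {
        match(labs, tree$tip.label)
      } else {
        ape::getMRCA(tree, labs)
      }
    }
    node_age <- ages[node]
    if (node == root) {
      if (div < node_age) {
        stop("placement ", taxon, ": divergence ", div,
             " is younger than the root age ", node_age)
      }
      position <- 0  # bind at root; root edge handled below
    } else {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      parent_age <- ages[parent]
      if (div <= node_age || div > parent_age + 1e-9) {
        stop("placement ", taxon, ": divergence ", div,
             " outside the attachment edge interval (",
             round(node_age, 3), ", ", round(parent_age, 3), "]")
      }
      position <- div - node_age
    }
    if (node == root && div > node_age) {
      # extend the root: bind a 2-tip scaffold is avoided by rooting trick
      tree$root.edge <- div - node_age
      tree <- phytools::bind.tip(tree, taxon,
                                 edge.length = div - tip_age,
                                 where = root,
                                 position = div - node_age)
    } else {
      tree <- phytools::bind.tip(tree, taxon,
                                 edge.length = div - tip_age,
                                 where = node, position = position)
    }
  }
  tree
}

#' Simulate Brownian motion on a tree
#'
#' Draws one multivariate normal sample over the tips with covariance
#' `sigma2 * C(lambda)`; seeded and reproducible.
#'
#' @param tree an `ape::phylo`.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Pagel lambda of the covariance.
#' @param root_state value added to every tip (the root state).
#' @param seed optional RNG seed.
#' @return named numeric vector over the tips.
#' @export
simulate_bm <- function(tree, sigma2 = 1, lambda = 1, root_state = 0,
                        seed = NULL) {
  stopifnot(sigma2 > 0)
  C <- phylo_covariance(tree, lambda)
  L <- chol(C + diag(1e-12 * mean(diag(C)), nrow(C)))
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(nrow(C))
  out <- root_state + sqrt(sigma2) * drop(crossprod(L, z))
  names(out) <- rownames(C)
  out
}
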