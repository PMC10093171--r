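# Shared fixture builders. All randomness is seeded by the caller.

# star phylogeny with unit branch lengths
star_tree <- function(n, depth = 1) {
  st <- ape::stree(n, "star")
  st$edge.length <- rep(depth, n)
  st$tip.label <- paste0("t", seq_len(n))
  st
}

# class dataset whose signal lives jointly in V1 and V2: both share a
# strong Brownian trend and the class shift sits in their contrast
# (V1 + shift, V2 - shift), so neither variable separates the classes alone
# and the top-ranked subset must contain the pair; remaining variables are
# pure lambda=1 Brownian noise
planted_dataset <- function(seed, n = 32, n_vars = 5, shift = 1.5,
                            trend_sigma2 = 4) {
  d <- make_trait_dataset(n_tips = n, n_classes = 2, class_mode = "random",
                          shifts = 0, n_vars = n_vars, lambda = 1,
                          sigma2 = 1, noise = 0.1, seed = seed)
  cls <- as.integer(d$data$class)
  trend <- simulate_bm(d$tree, sigma2 = trend_sigma2, lambda = 1,
                       seed = seed + 5)
  d$data$V1 <- d$data$V1 + trend + shift * (cls - 1)
  d$data$V2 <- d$data$V2 + trend - shift * (cls - 1)
  d
}

# brute-force medulla oracle: BFS flood fill from the border over non-bone
# pixels; remaining non-bone components are enclosed; centroid of the
# largest. Independent of the package's labelling code.
medulla_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  open <- mask == 0L
  reach <- matrix(FALSE, nr, nc)
  queue <- which(open & (row(mask) %in% c(1L, nr) | col(mask) %in% c(1L, nc)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- (queue - 1L) %% nr + 1L
    j <- (queue - 1L) %/% nr + 1L
    nb <- c(queue[i > 1L] - 1L, queue[i < nr] + 1L,
            queue[j > 1L] - nr, queue[j < nc] + nr)
    nb <- unique(nb[open[nb] & !reach[nb]])
    reach[nb] <- TRUE
    queue <- nb
  }
  enclosed <- open & !reach
  if (!any(enclosed)) return(NULL)
  # split enclosed pixels into components by BFS, keep the largest
  comp <- matrix(0L, nr, nc)
  k <- 0L
  for (s in which(enclosed)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- (queue - 1L) %% nr + 1L
      j <- (queue - 1L) %/% nr + 1L
      nb <- c(queue[i > 1L] - 1L, queue[i < nr] + 1L,
              queue[j > 1L] - nr, queue[j < nc] + nr)
      nb <- unique(nb[enclosed[nb] & comp[nb] == 0L])
      comp[nb] <- k
      queue <- nb
    }
  }
  sizes <- tabulate(comp[comp > 0L])
  idx <- which(comp == which.max(sizes), arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

rotate90 <- function(mask) t(mask)[, rev(seq_len(nrow(mask))), drop = FALSE]
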