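# Small character sets and specimen generators used across the suite.

tiny_characters <- function() {
  colour_characters(
    name = c("cap", "stripe", "band"),
    body_region = c("head", "mesosoma", "metasoma_terga"),
    modalities = list(
      c("light", "dark"),
      c("yellow", "mixed", "black"),
      c("m0", "m1", "m2", "m3")
    )
  )
}

# uniform random modality assignments over a character set
random_specimens <- function(characters, n, seed) {
  withr::with_seed(seed, {
    sp <- tibble::tibble(id = sprintf("s%04d", seq_len(n)))
    for (k in seq_len(nrow(characters))) {
      sp[[characters$name[k]]] <-
        sample(characters$modalities[[k]], n, replace = TRUE)
    }
    sp
  })
}

# specimens driven by a single latent melanisation factor with noise
latent_factor_specimens <- function(characters, n, seed, noise_sd = 0.4) {
  withr::with_seed(seed, {
    m <- runif(n)
    sp <- tibble::tibble(id = sprintf("s%04d", seq_len(n)))
    for (k in seq_len(nrow(characters))) {
      nm <- characters$n_modalities[k]
      r <- pmin(nm - 1, pmax(0, round(m * (nm - 1) + rnorm(n, 0, noise_sd))))
      sp[[characters$name[k]]] <- characters$modalities[[k]][r + 1]
    }
    sp
  })
}

# random additive tree and its exact path-length distance matrix
random_additive_distances <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 1))
    tree$tip.label <- paste0("t", seq_len(n_taxa))
    list(tree = ape::unroot(tree),
         d = dist_matrix(ape::cophenetic.phylo(tree)))
  })
}

# a symmetric positive random "distance" matrix, almost surely
# non-Euclidean (uniform off-diagonal entries)
random_nonmetric_distances <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.5, 2)
    m <- m + t(m)
    rownames(m) <- colnames(m) <- paste0("x", seq_len(n))
    dist_matrix(m)
  })
}

# brute-force chi-square statistic of a contingency-style table
chisq_bruteforce <- function(X) {
  N <- sum(X)
  rs <- rowSums(X)
  cs <- colSums(X)
  stat <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      e <- rs[i] * cs[j] / N
      stat <- stat + (X[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# brute-force chi-square distances between row profiles
chisq_row_distances <- function(X) {
  P <- X / sum(X)
  prof <- P / rowSums(P)
  cm <- colSums(P)
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cm))
    }
  }
  d
}
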