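#' Gower double-centering of a distance matrix
#'
#' Computes `-1/2 J D^2 J` with `J` the centering projector, the matrix whose
#' eigen-decomposition underlies principal coordinates analysis; eigenvalues
#' are reported signed (negative values diagnose non-Euclidean distances).
#'
#' @param d A `dist_matrix` (or coercible).
#' @return List with elements `G` (centered matrix) and `eigenvalues`
#'   (descending, signed).
#' @export
gower_center <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  A <- -0.5 * unclass(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  list(G = G, eigenvalues = eigen(G, symmetric = TRUE,
                                  only.values = TRUE)$values)
}

#' Lingoes correction for non-Euclidean distance matrices
#'
#' If the smallest Gower eigenvalue is negative beyond tolerance, every
#' squared off-diagonal distance is increased by twice its magnitude
#' (`D'_ij = sqrt(D_ij^2 + 2c)`, `c = -lambda_min`), the smallest additive
#' constant making the matrix Euclidean-embeddable. Already-Euclidean input
#' is returned unchanged.
#'
#' @param d A `dist_matrix`.
#' @param tol Relative eigenvalue tolerance.
#' @return A `dist_matrix` with attribute `lingoes_constant` (0 when no
#'   correction was needed).
#' @export
lingoes_correction <- function(d, tol = 1e-8) {
  d <- as_dist_matrix(d)
  ev <- gower_center(d)$eigenvalues
  lambda_max <- max(ev, 0)
  if (min(ev) >= -tol * max(lambda_max, 1)) {
    attr(d, "lingoes_constant") <- 0
    return(d)
  }
  cc <- -min(ev)
  m <- sqrt(unclass(d)^2 + 2 * cc)
  diag(m) <- 0
  out <- dist_matrix(m)
  attr(out, "lingoes_constant") <- cc
  out
}

#' Principal coordinates analysis
#'
#' Embeds a Euclidean-embeddable distance matrix: coordinates are Gower
#' eigenvectors scaled by the square root of their (positive) eigenvalues,
#' ordered by descending eigenvalue, so that pairwise Euclidean distances
#' between coordinate rows reproduce the input.
#'
#' @param d A `dist_matrix`; apply [lingoes_correction()] first if it is not
#'   Euclidean-embeddable.
#' @param tol Relative eigenvalue tolerance.
#' @return An object of class `coordinate_set`: `ids`, `coordinates`
#'   (matrix with columns `Axis1`, ...), `eigenvalues` (positive ones kept).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as_dist_matrix(d)
  gc <- gower_center(d)
  eg <- eigen(gc$G, symmetric = TRUE)
  lambda_max <- max(eg$values, 0)
  if (min(eg$values) < -tol * max(lambda_max, 1)) {
    abort(paste0("distance matrix is not Euclidean-embeddable ",
                 "(negative Gower eigenvalues); apply lingoes_correction()"))
  }
  keep <- which(eg$values > tol * max(lambda_max, 1))
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), length(keep))
  colnames(coords) <- paste0("Axis", seq_along(keep))
  rownames(coords) <- rownames(d)
  coordinate_set(rownames(d), coords, eg$values[keep])
}

#' Build a coordinate set
#'
#' Container for labelled ordination scores fed into RV comparisons: rows
#' are individuals (or populations), columns are axes ordered by descending
#' eigenvalue when available.
#'
#' @param ids Character vector of row labels.
#' @param coordinates Numeric matrix, one row per id.
#' @param eigenvalues Optional eigenvalues, one per column.
#' @return Object of class `coordinate_set`.
#' @export
coordinate_set <- function(ids, coordinates, eigenvalues = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(length(ids) == nrow(coordinates))
  if (anyDuplicated(ids)) abort("coordinate set ids must be unique")
  rownames(coordinates) <- ids
  structure(list(ids = as.character(ids), coordinates = coordinates,
                 eigenvalues = eigenvalues),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("<coordinate_set: %d rows, %d axes>\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' @method as_tibble coordinate_set
#' @export
as_tibble.coordinate_set <- function(x, ...) {
  tibble(id = x$ids, !!!as.data.frame(x$coordinates))
}

# internal: accept coordinate_set, id-first tibble, or plain matrix
coord_matrix <- function(x) {
  if (inherits(x, "coordinate_set")) return(x$coordinates)
  if (is.data.frame(x)) return(table_matrix(x))
  m <- as.matrix(x)
  if (is.null(rownames(m))) abort("coordinates must carry row labels")
  m
}

# internal: align y's rows to x's; error on mismatch
align_coords <- function(x, y) {
  X <- coord_matrix(x)
  Y <- coord_matrix(y)
  if (!setequal(rownames(X), rownames(Y))) {
    orphans <- c(setdiff(rownames(X), rownames(Y)),
                 setdiff(rownames(Y), rownames(X)))
    abort(paste0("coordinate sets have mismatched ids: ",
                 paste(head(orphans, 10L), collapse = ", ")))
  }
  list(X = X, Y = Y[rownames(X), , drop = FALSE])
}

#' RV coefficient between two coordinate sets
#'
#' The RV coefficient is the multivariate analogue of a squared correlation
#' between two sets of variables measured on the same individuals:
#' `RV = trace(XX'YY') / sqrt(trace((XX')^2) trace((YY')^2))` after column
#' centering. It lies in `[0, 1]` and is invariant to orthogonal rotation
#' and global rescaling of either set.
#'
#' @param x,y `coordinate_set` objects (or id-first tibbles / labelled
#'   matrices) over the same ids.
#' @return A number in `[0, 1]`.
#' @export
rv_coefficient <- function(x, y) {
  al <- align_coords(x, y)
  X <- scale(al$X, center = TRUE, scale = FALSE)
  Y <- scale(al$Y, center = TRUE, scale = FALSE)
  Sx <- tcrossprod(X)
  Sy <- tcrossprod(Y)
  den <- sqrt(sum(Sx^2) * sum(Sy^2))
  if (den == 0) abort("RV undefined for a zero-variance coordinate set")
  sum(Sx * Sy) / den
}

#' Permutation test of the RV coefficient
#'
#' Monte-Carlo test: the rows of `y` are permuted `n_permutations` times and
#' the RV recomputed; the p-value uses the add-one estimator
#' `(1 + #{perm >= observed}) / (1 + n_permutations)`. Deterministic for a
#' given seed.
#'
#' @inheritParams rv_coefficient
#' @param n_permutations Number of permutations (>= 99; default 9999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `rv_test`: `rv`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
rv_test <- function(x, y, n_permutations = 9999L, seed = 1L) {
  if (n_permutations < 99L) abort("use at least 99 permutations")
  al <- align_coords(x, y)
  X <- scale(al$X, center = TRUE, scale = FALSE)
  Y <- scale(al$Y, center = TRUE, scale = FALSE)
  Sx <- tcrossprod(X)
  Sy <- tcrossprod(Y)
  den <- sqrt(sum(Sx^2) * sum(Sy^2))
  if (den == 0) abort("RV undefined for a zero-variance coordinate set")
  obs <- sum(Sx * Sy) / den
  n <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  perm_rv <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    sum(Sx * Sy[p, p]) / den
  }, numeric(1))
  structure(
    list(rv = obs,
         p_value = (1 + sum(perm_rv >= obs)) / (1 + n_permutations),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "rv_test"
  )
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf("<rv_test: RV = %.4f, p = %.4g (%d permutations, seed %d)>\n",
              x$rv, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' @method tidy rv_test
#' @export
tidy.rv_test <- function(x, ...) {
  tibble(rv = x$rv, p_value = x$p_value,
         n_permutations = x$n_permutations, seed = x$seed)
}

#' @method glance rv_test
#' @export
glance.rv_test <- function(x, ...) tidy(x)

#' Pairwise RV tests over several coordinate sets
#'
#' Runs [rv_test()] for every pair of named coordinate sets and returns a
#' tidy table; the attribute `matrix` holds the square layout with RV in the
#' lower triangle and p-values in the upper triangle.
#'
#' @param coord_sets Named list of `coordinate_set` objects over shared ids.
#' @inheritParams rv_test
#' @return Tibble with columns `set1`, `set2`, `rv`, `p_value`.
#' @export
rv_table <- function(coord_sets, n_permutations = 9999L, seed = 1L) {
  stopifnot(is.list(coord_sets), length(coord_sets) >= 2L,
            !is.null(names(coord_sets)))
  nms <- names(coord_sets)
  pairs <- combn(nms, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    tst <- rv_test(coord_sets[[a]], coord_sets[[b]],
                   n_permutations = n_permutations, seed = seed + k)
    tibble(set1 = a, set2 = b, rv = tst$rv, p_value = tst$p_value)
  })
  out <- bind_rows(rows)
  m <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (k in seq_len(nrow(out))) {
    m[out$set2[k], out$set1[k]] <- out$rv[k]       # lower triangle: RV
    m[out$set1[k], out$set2[k]] <- out$p_value[k]  # upper triangle: p
  }
  attr(out, "matrix") <- m
  out
}

#' Aggregate individual-level data layers to population level
#'
#' Colour and climate scores are averaged per population and compared by
#' Euclidean distance between mean score vectors; coordinates are averaged
#' and compared by great-circle distance; genotypic (DAS) and haplotype
#' distances are averaged over all between-population individual pairs
#' (diagonal zero). Populations missing a data layer are excluded from that
#' layer with a warning.
#'
#' @param membership Tibble with columns `id` and `population`.
#' @param colour Optional tibble of colour-space row coordinates
#'   (`id` + dimensions) or `coordinate_set`.
#' @param climate Optional [climate_distances()] object or score tibble.
#' @param localities Optional tibble `id`, `lat`, `lon`.
#' @param das,haplotype Optional individual-level `dist_matrix` objects.
#' @return Named list of population-level `dist_matrix` objects (elements
#'   among `colour`, `climate`, `geodesic`, `das`, `haplotype`).
#' @export
population_aggregate <- function(membership, colour = NULL, climate = NULL,
                                 localities = NULL, das = NULL,
                                 haplotype = NULL) {
  stopifnot(is.data.frame(membership),
            all(c("id", "population") %in% names(membership)))
  pop_of <- setNames(as.character(membership$population),
                     as.character(membership$id))
  out <- list()

  mean_scores_dist <- function(scores) {
    M <- coord_matrix(scores)
    ids <- intersect(rownames(M), names(pop_of))
    skipped <- setdiff(rownames(M), names(pop_of))
    if (length(skipped)) {
      warn(sprintf("%d id(s) without population membership excluded",
                   length(skipped)))
    }
    M <- M[ids, , drop = FALSE]
    pops <- sort(unique(pop_of[ids]))
    mu <- do.call(rbind, lapply(pops, function(p) {
      colMeans(M[pop_of[ids] == p, , drop = FALSE])
    }))
    rownames(mu) <- pops
    dist_matrix(as.matrix(dist(mu)))
  }

  if (!is.null(colour)) out$colour <- mean_scores_dist(colour)
  if (!is.null(climate)) {
    scores <- if (inherits(climate, "climate_distances")) climate$scores
              else climate
    out$climate <- mean_scores_dist(scores)
  }
  if (!is.null(localities)) {
    ids <- intersect(as.character(localities$id), names(pop_of))
    loc <- localities[match(ids, localities$id), ]
    mu <- loc |>
      mutate(population = pop_of[ids]) |>
      group_by(.data$population) |>
      summarise(lat = mean(.data$lat), lon = mean(.data$lon),
                .groups = "drop") |>
      arrange(.data$population)
    out$geodesic <- geodesic_distances(
      tibble(id = mu$population, lat = mu$lat, lon = mu$lon))
  }
  mean_cross_dist <- function(d) {
    d <- as_dist_matrix(d, allow_na = TRUE)
    ids <- intersect(rownames(d), names(pop_of))
    d <- unclass(d)[ids, ids, drop = FALSE]
    pops <- sort(unique(pop_of[ids]))
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)) {
      for (j in seq_along(pops)) {
        if (i < j) {
          block <- d[pop_of[ids] == pops[i], pop_of[ids] == pops[j],
                     drop = FALSE]
          m[i, j] <- m[j, i] <- mean(block, na.rm = TRUE)
        }
      }
    }
    dist_matrix(m)
  }
  if (!is.null(das)) out$das <- mean_cross_dist(das)
  if (!is.null(haplotype)) out$haplotype <- mean_cross_dist(haplotype)
  if (!length(out)) abort("no data layer supplied")
  out
}

#' Congruence tree over data structures
#'
#' Pairwise RV coefficients between named coordinate sets are converted to
#' the dissimilarity `1 - RV^2` and summarised by a neighbor-joining tree,
#' visualising which data structures (colour, genetic, geographic,
#' climatic) resemble each other.
#'
#' @param coord_sets Named list (>= 3) of `coordinate_set` objects over
#'   shared ids.
#' @return Object of class `congruence_tree`: `tree` (`phylo`), `rv`
#'   (matrix), `dissimilarity` (`dist_matrix`).
#' @export
congruence_tree <- function(coord_sets) {
  stopifnot(is.list(coord_sets), !is.null(names(coord_sets)))
  if (length(coord_sets) < 3L) abort("need at least 3 coordinate sets")
  nms <- names(coord_sets)
  k <- length(nms)
  rv <- matrix(1, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      rv[i, j] <- rv[j, i] <- rv_coefficient(coord_sets[[i]],
                                             coord_sets[[j]])
    }
  }
  diss <- dist_matrix(1 - rv^2)
  structure(list(tree = neighbor_joining(diss), rv = rv,
                 dissimilarity = diss),
            class = "congruence_tree")
}

#' @export
print.congruence_tree <- function(x, ...) {
  cat("<congruence_tree over:", paste(rownames(x$rv), collapse = ", "),
      ">\n")
  invisible(x)
}

#' Per-individual distance-profile correlations
#'
#' Entry `(i, j)` is the Pearson correlation between individual `i`'s
#' distance profile in `d1` and individual `j`'s profile in `d2`, both
#' profiles taken over all other individuals (the pair's own distances are
#' excluded from both profiles). Row and column dendrograms come from
#' complete-linkage clustering of the two raw distance matrices. High,
#' block-structured correlations indicate congruent structures.
#'
#' @param d1,d2 `dist_matrix` objects over the same ids.
#' @return Object of class `profile_correlation`: `correlation` (matrix,
#'   rows follow `d1`), `hclust_rows`, `hclust_cols`, `n_undefined`.
#' @export
distance_profile_correlation <- function(d1, d2) {
  d1 <- as_dist_matrix(d1)
  d2 <- as_dist_matrix(d2)
  if (!setequal(rownames(d1), rownames(d2))) {
    abort("distance matrices must share the same ids")
  }
  d2 <- dist_matrix(unclass(d2)[rownames(d1), rownames(d1)])
  n <- nrow(d1)
  ids <- rownames(d1)
  C <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  m1 <- unclass(d1)
  m2 <- unclass(d2)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      keep <- setdiff(seq_len(n), c(i, j))
      x <- m1[i, keep]
      y <- m2[j, keep]
      if (sd(x) == 0 || sd(y) == 0) next  # flagged NA: constant profile
      C[i, j] <- cor(x, y)
    }
  }
  n_undef <- sum(is.na(C))
  if (n_undef) warn(sprintf("%d cell(s) undefined (constant profile)",
                            n_undef))
  structure(
    list(correlation = C,
         hclust_rows = hclust(as.dist(m1), method = "complete"),
         hclust_cols = hclust(as.dist(m2), method = "complete"),
         n_undefined = n_undef),
    class = "profile_correlation"
  )
}

#' @method autoplot profile_correlation
#' @export
autoplot.profile_correlation <- function(object, ...) {
  ro <- object$hclust_rows$order
  co <- object$hclust_cols$order
  m <- object$correlation[ro, co]
  df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(df) <- c("row", "col", "correlation")
  df$row <- factor(df$row, levels = rownames(m))
  df$col <- factor(df$col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = "profiles in d2", y = "profiles in d1")
}
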