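# Core correspondence-analysis engine shared by CA and MCA. X is a
# non-negative numeric matrix with rownames (ids) and colnames (variables).
ca_engine <- function(X, tol = 1e-10) {
  if (any(X < 0)) abort("correspondence analysis requires non-negative input")
  if (any(rowSums(X) == 0)) abort("input has all-zero row(s)")
  if (nrow(unique(as.data.frame(X))) == 1L) {
    # a single distinct row carries no variation: degenerate, not an error
    return(structure(
      list(eigenvalues = numeric(0), inertia_proportions = numeric(0),
           total_inertia = 0, n_dimensions = 0L, degenerate = TRUE,
           row_coordinates = tibble(id = rownames(X)),
           column_coordinates = tibble(variable = colnames(X)),
           row_masses = setNames(rep(1 / nrow(X), nrow(X)), rownames(X)),
           column_masses = setNames(colSums(X) / sum(X), colnames(X)),
           tol = tol),
      class = "colour_space"
    ))
  }
  if (any(colSums(X) == 0)) abort("input has all-zero column(s)")
  N <- sum(X)
  P <- X / N
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  d_max <- sv$d[1L]
  keep <- if (d_max <= 0) integer(0) else which(sv$d > tol * d_max)
  n_dim <- length(keep)
  eig <- sv$d[keep]^2
  total_inertia <- sum(sv$d^2)

  dims <- paste0("Dim", seq_len(n_dim))
  if (n_dim > 0L) {
    Frow <- sweep(sv$u[, keep, drop = FALSE], 1L, sqrt(r), "/") %*%
      diag(sv$d[keep], n_dim)
    Gcol <- sweep(sv$v[, keep, drop = FALSE], 1L, sqrt(cm), "/") %*%
      diag(sv$d[keep], n_dim)
    colnames(Frow) <- colnames(Gcol) <- dims
  } else {
    Frow <- matrix(0, nrow(X), 0L)
    Gcol <- matrix(0, ncol(X), 0L)
  }
  structure(
    list(
      eigenvalues = eig,
      inertia_proportions = if (total_inertia > 0) eig / total_inertia
                            else numeric(0),
      total_inertia = total_inertia,
      n_dimensions = n_dim,
      degenerate = n_dim == 0L,
      row_coordinates = tibble(id = rownames(X), !!!as.data.frame(Frow)),
      column_coordinates = tibble(variable = colnames(X),
                                  !!!as.data.frame(Gcol)),
      row_masses = setNames(r, rownames(X)),
      column_masses = setNames(cm, colnames(X)),
      tol = tol
    ),
    class = "colour_space"
  )
}

# Pull a numeric matrix (rownames = ids) out of an id-first tibble.
table_matrix <- function(x, id_col = "id") {
  stopifnot(is.data.frame(x), id_col %in% names(x))
  num <- x[setdiff(names(x), id_col)]
  ok <- vapply(num, is.numeric, logical(1))
  m <- as.matrix(num[ok])
  rownames(m) <- as.character(x[[id_col]])
  m
}

#' Correspondence analysis of a fuzzy-coded colour matrix
#'
#' Builds the "colour space": the correspondence table is formed by dividing
#' by the grand total, standardized residuals are decomposed by singular
#' value decomposition, squared singular values are returned as eigenvalues
#' and rows/columns are placed at mass-scaled principal coordinates.
#' Dimensions whose singular value is below `tol` times the largest are
#' dropped as trivial. A degenerate input (no variation) yields zero
#' non-trivial dimensions, flagged, not an error.
#'
#' Because the paired light/dark coding gives every specimen the same row
#' margin, specimens are equally weighted, and each character contributes at
#' most one dimension (the centered dark column is the negation of the
#' centered light column), so a matrix over K variable characters spans K
#' dimensions.
#'
#' @param coded A [encode_specimens()] tibble (or any id-first non-negative
#'   numeric tibble).
#' @param tol Relative singular-value tolerance for trivial dimensions.
#' @return An object of class `colour_space` with elements `eigenvalues`,
#'   `inertia_proportions`, `total_inertia`, `n_dimensions`, `degenerate`,
#'   `row_coordinates`, `column_coordinates`, `row_masses`, `column_masses`.
#' @export
#' @examples
#' study <- simulate_study(scenario_config(seed = 1))
#' coded <- encode_specimens(study$specimens, study$characters)
#' space <- correspondence_analysis(coded)
#' glance(space)
correspondence_analysis <- function(coded, tol = 1e-10) {
  X <- table_matrix(coded)
  space <- ca_engine(X, tol = tol)
  attr(space, "characters") <- attr(coded, "characters")
  space
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Applies the same algorithm as [correspondence_analysis()] to the one-hot
#' indicator matrix from [build_indicator_matrix()], treating each modality
#' as its own variable.
#'
#' @param indicator An indicator tibble from [build_indicator_matrix()].
#' @inheritParams correspondence_analysis
#' @return A `colour_space` object.
#' @export
multiple_correspondence_analysis <- function(indicator, tol = 1e-10) {
  X <- table_matrix(indicator)
  if (!all(X %in% c(0, 1))) abort("indicator matrix must be binary")
  space <- ca_engine(X, tol = tol)
  attr(space, "characters") <- attr(indicator, "characters")
  space
}

#' @export
print.colour_space <- function(x, ...) {
  cat(sprintf("<colour_space: %d specimens, %d variables, %d dimensions>\n",
              nrow(x$row_coordinates), nrow(x$column_coordinates),
              x$n_dimensions))
  if (x$degenerate) cat("  degenerate: no non-trivial variation\n")
  else cat(sprintf("  total inertia %.4g; first axis %.2f%% of inertia\n",
                   x$total_inertia, 100 * x$inertia_proportions[1L]))
  invisible(x)
}

#' @method tidy colour_space
#' @export
tidy.colour_space <- function(x, ...) {
  tibble(
    dimension = seq_len(x$n_dimensions),
    eigenvalue = x$eigenvalues,
    inertia_proportion = x$inertia_proportions,
    cumulative_proportion = cumsum(x$inertia_proportions)
  )
}

#' @method glance colour_space
#' @export
glance.colour_space <- function(x, ...) {
  tibble(
    n_specimens = nrow(x$row_coordinates),
    n_variables = nrow(x$column_coordinates),
    n_dimensions = x$n_dimensions,
    total_inertia = x$total_inertia,
    first_axis_proportion = if (x$n_dimensions) x$inertia_proportions[1L]
                            else NA_real_
  )
}

#' @method autoplot colour_space
#' @export
autoplot.colour_space <- function(object, dims = c(1L, 2L), colour = NULL,
                                  ...) {
  if (object$n_dimensions < max(dims)) {
    abort("requested dimensions exceed the colour space dimensionality")
  }
  dn <- paste0("Dim", dims)
  df <- object$row_coordinates
  if (!is.null(colour)) df$.colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[dn[1L]]], .data[[dn[2L]]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", dn[1L],
                  100 * object$inertia_proportions[dims[1L]]),
      y = sprintf("%s (%.1f%%)", dn[2L],
                  100 * object$inertia_proportions[dims[2L]])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour)) +
    ggplot2::labs(colour = NULL)
}

#' Leave-one-out canonical variate cross-validation of colour morphs
#'
#' For each specimen in turn, a canonical variate discriminant is fitted on
#' all other specimens (group centroids with pooled within-group covariance,
#' ridge-regularized when singular) and the held-out specimen is assigned to
#' the nearest group centroid in canonical space, which is equivalent to
#' nearest-centroid assignment under the pooled Mahalanobis metric. Morphs
#' represented by a single specimen are excluded with a warning; ties are
#' broken towards the alphabetically first morph.
#'
#' @param space A `colour_space` object.
#' @param morphs Either a data frame with columns `id` and `morph`, or a
#'   vector of morph labels aligned with `space$row_coordinates$id`.
#' @param n_dims Number of leading dimensions to use (default: all
#'   non-trivial dimensions).
#' @return An object of class `morph_cv`: `accuracy`, `n_correct`,
#'   `n_misclassified`, `n_total`, `confusion` (tibble of true x predicted
#'   counts), `n_dims`.
#' @export
crossvalidate_morphs <- function(space, morphs, n_dims = NULL) {
  scores <- table_matrix(space$row_coordinates)
  ids <- space$row_coordinates$id
  if (is.data.frame(morphs)) {
    stopifnot(all(c("id", "morph") %in% names(morphs)))
    lab <- morphs$morph[match(ids, morphs$id)]
    if (anyNA(lab)) abort("morph labels missing for some specimens")
  } else {
    if (length(morphs) != length(ids)) {
      abort("morph vector length must match the number of specimens")
    }
    lab <- as.character(morphs)
  }
  n_dims <- n_dims %||% ncol(scores)
  if (n_dims > ncol(scores)) abort("n_dims exceeds available dimensions")
  scores <- scores[, seq_len(n_dims), drop = FALSE]

  singletons <- names(which(table(lab) < 2L))
  if (length(singletons)) {
    warn(paste0("excluding morph(s) with a single specimen: ",
                paste(singletons, collapse = ", ")))
    keep <- !lab %in% singletons
    scores <- scores[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  groups <- sort(unique(lab))
  if (length(groups) < 2L) abort("need at least two morphs with >= 2 specimens")

  n <- nrow(scores)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- scores[-i, , drop = FALSE]
    gl <- lab[-i]
    mu <- do.call(rbind, lapply(groups, function(g) {
      colMeans(tr[gl == g, , drop = FALSE])
    }))
    resid <- tr - mu[match(gl, groups), , drop = FALSE]
    W <- crossprod(resid) / (nrow(tr) - length(groups))
    # ridge-regularize ill-conditioned pooled covariance (lambda =
    # 1e-8 trace/dim), not only exactly singular ones
    ew <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    if (min(ew) <= 1e-10 * max(ew, 0)) {
      lambda <- 1e-8 * max(sum(diag(W)), .Machine$double.eps) / ncol(W)
      W <- W + diag(lambda, ncol(W))
    }
    Winv <- solve(W)
    d2 <- vapply(seq_along(groups), function(g) {
      v <- scores[i, ] - mu[g, ]
      drop(v %*% Winv %*% v)
    }, numeric(1))
    pred[i] <- groups[which.min(d2)]  # which.min: first (sorted) on ties
  }
  confusion <- as_tibble(as.data.frame(table(true = lab, predicted = pred),
                                       stringsAsFactors = FALSE)) |>
    rename(n = "Freq")
  structure(
    list(
      accuracy = mean(pred == lab),
      n_correct = sum(pred == lab),
      n_misclassified = sum(pred != lab),
      n_total = n,
      confusion = confusion,
      n_dims = n_dims
    ),
    class = "morph_cv"
  )
}

#' @export
print.morph_cv <- function(x, ...) {
  cat(sprintf(
    "<morph_cv: %d/%d specimens correctly assigned (%.2f%%), %d misassigned>\n",
    x$n_correct, x$n_total, 100 * x$accuracy, x$n_misclassified))
  invisible(x)
}

#' @method tidy morph_cv
#' @export
tidy.morph_cv <- function(x, ...) x$confusion

#' @method glance morph_cv
#' @export
glance.morph_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_correct = x$n_correct,
         n_misclassified = x$n_misclassified, n_total = x$n_total,
         n_dims = x$n_dims)
}

#' Correlations between character vectors in the colour space
#'
#' Each character's direction of melanisation variation is taken as the
#' column principal-coordinate vector of its light variable across all
#' non-trivial dimensions (light and dark vectors of a character being
#' antipodal, one of the pair suffices). Pairwise Pearson correlations (or
#' cosine similarities) of these vectors quantify how coordinated the
#' melanisation of body parts is.
#'
#' @param space A `colour_space` built from a fuzzy-coded matrix (columns
#'   named `<character>.light` / `<character>.dark`).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return An object of class `character_correlations`: a symmetric K x K
#'   correlation matrix with character names as dimnames.
#' @export
character_vector_correlations <- function(space,
                                          method = c("pearson", "cosine")) {
  method <- match.arg(method)
  G <- table_matrix(space$column_coordinates, id_col = "variable")
  light <- grep("\\.light$", rownames(G), value = TRUE)
  if (length(light) < 2L) {
    abort("colour space has fewer than two `.light` variables")
  }
  L <- G[light, , drop = FALSE]
  rownames(L) <- sub("\\.light$", "", rownames(L))
  if (ncol(L) < 2L) abort("need at least two non-trivial dimensions")
  V <- if (method == "pearson") {
    cor(t(L))
  } else {
    nrm <- sqrt(rowSums(L^2))
    tcrossprod(L / nrm)
  }
  diag(V) <- 1
  structure(V, class = c("character_correlations", "matrix"))
}

#' @method tidy character_correlations
#' @export
tidy.character_correlations <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) |>
    setNames(c("character1", "character2", "correlation")) |>
    as_tibble()
}

#' Summarise phenotypic integration from character correlations
#'
#' Integration of melanisation over the body shows as a predominance of
#' positive correlations among the light-character vectors. The fraction is
#' counted over the strict upper triangle.
#'
#' @param corr A [character_vector_correlations()] matrix.
#' @return A list of class `integration_summary`: `fraction_positive`,
#'   `n_pairs`, `negative_pairs` (tibble of character pairs with negative
#'   correlation).
#' @export
integration_summary <- function(corr) {
  stopifnot(inherits(corr, "character_correlations"))
  m <- unclass(corr)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[ut]
  neg <- ut[vals < 0, , drop = FALSE]
  structure(
    list(
      fraction_positive = mean(vals > 0),
      n_pairs = length(vals),
      negative_pairs = tibble(
        character1 = rownames(m)[neg[, 1L]],
        character2 = colnames(m)[neg[, 2L]],
        correlation = m[neg]
      )
    ),
    class = "integration_summary"
  )
}

#' @export
print.integration_summary <- function(x, ...) {
  cat(sprintf("<integration: %.2f%% of %d character pairs positively correlated>\n",
              100 * x$fraction_positive, x$n_pairs))
  if (nrow(x$negative_pairs)) {
    cat(sprintf("  %d negative pair(s)\n", nrow(x$negative_pairs)))
  }
  invisible(x)
}

#' Partition characters into colour modules
#'
#' Hierarchical clustering (average linkage) of characters on the
#' dissimilarity `1 - correlation`, cut into the requested number of
#' modules. Deterministic given its inputs.
#'
#' @param corr A [character_vector_correlations()] matrix.
#' @param n_modules Number of modules, between 1 and the number of
#'   characters.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return Tibble with columns `character` and `module`.
#' @export
modularity_clusters <- function(corr, n_modules, linkage = "average") {
  stopifnot(inherits(corr, "character_correlations"))
  K <- nrow(corr)
  if (n_modules < 1L || n_modules > K) {
    abort(sprintf("n_modules must be between 1 and %d", K))
  }
  hc <- hclust(as.dist(1 - unclass(corr)), method = linkage)
  tibble(
    character = rownames(corr),
    module = unname(cutree(hc, k = n_modules)[rownames(corr)])
  )
}
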