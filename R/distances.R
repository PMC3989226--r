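#' Construct a labelled distance matrix
#'
#' Light wrapper validating the shared contract of all pairwise distance
#' structures in the package: square, symmetric, non-negative, zero
#' diagonal, labelled. `NA` entries are allowed only when `allow_na = TRUE`
#' (permissive missing-pair modes).
#'
#' @param values Square numeric matrix.
#' @param labels Optional character labels (default: rownames).
#' @param allow_na Allow missing pairwise entries.
#' @return A matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = NULL, allow_na = FALSE) {
  m <- as.matrix(values)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  labels <- labels %||% rownames(m)
  if (is.null(labels)) abort("distance matrix must be labelled")
  if (length(labels) != nrow(m) || anyDuplicated(labels)) {
    abort("labels must be unique and match the matrix dimension")
  }
  dimnames(m) <- list(labels, labels)
  if (anyNA(m) && !allow_na) abort("distance matrix contains missing values")
  if (any(m < 0, na.rm = TRUE)) abort("distances must be non-negative")
  if (any(abs(m - t(m)) > 1e-8, na.rm = TRUE)) {
    abort("distance matrix must be symmetric")
  }
  if (any(abs(diag(m)) > 1e-12)) abort("diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d labels, range [%.4g, %.4g]>\n",
              nrow(x), min(x[upper.tri(x)], na.rm = TRUE),
              max(x[upper.tri(x)], na.rm = TRUE)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' @method tidy dist_matrix
#' @export
tidy.dist_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    item1 = rownames(m)[idx[, 1L]],
    item2 = colnames(m)[idx[, 2L]],
    distance = m[idx]
  )
}

#' @method autoplot dist_matrix
#' @export
autoplot.dist_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(df) <- c("item1", "item2", "distance")
  ggplot2::ggplot(df, ggplot2::aes(.data$item1, .data$item2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

# internal: coerce matrix-like / dist input to dist_matrix
as_dist_matrix <- function(x, allow_na = FALSE) {
  if (inherits(x, "dist_matrix")) return(x)
  if (inherits(x, "dist")) x <- as.matrix(x)
  dist_matrix(x, allow_na = allow_na)
}
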