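EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distances between localities
#'
#' Haversine distances on a sphere of mean radius 6371.0088 km, numerically
#' stable near antipodal points.
#'
#' @param localities Tibble with columns `id`, `lat` (decimal degrees in
#'   `[-90, 90]`) and `lon` (in `[-180, 180]`).
#' @return A `dist_matrix` in kilometres.
#' @export
#' @examples
#' geodesic_distances(tibble::tibble(id = c("a", "b"),
#'                                   lat = c(0, 0), lon = c(0, 1)))
geodesic_distances <- function(localities) {
  stopifnot(is.data.frame(localities),
            all(c("id", "lat", "lon") %in% names(localities)))
  lat <- localities$lat
  lon <- localities$lon
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180)) {
    abort("coordinates must satisfy |lat| <= 90, |lon| <= 180")
  }
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2,
                                                   r = EARTH_RADIUS_KM)
                        })
  rownames(m) <- colnames(m) <- as.character(localities$id)
  dist_matrix(m)
}

#' Climatic dissimilarities from a climate table
#'
#' Each variable is centred and scaled by its standard deviation, a
#' principal component analysis is run, and Euclidean distances between
#' score vectors over all retained components are returned (over all
#' components this equals standardized Euclidean distance on the
#' variables). Constant variables are dropped with a warning.
#'
#' @param climate Tibble with an `id` column and numeric climate variables
#'   (eight BIOCLIM-style variables in the reference design; any number
#'   works).
#' @return An object of class `climate_distances`: `distances`
#'   (`dist_matrix`), `scores` (tibble of component scores), `pca`
#'   (tibble with `component`, `sdev`, `variance_proportion`,
#'   `cumulative_proportion`).
#' @export
climate_distances <- function(climate) {
  X <- table_matrix(climate)
  if (nrow(X) < 2L) abort("need at least two climate rows")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant climate variable(s): ",
                paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x
  d <- as.matrix(dist(scores))
  rownames(d) <- colnames(d) <- rownames(X)
  vp <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      distances = dist_matrix(d),
      scores = tibble(id = rownames(X), !!!as.data.frame(scores)),
      pca = tibble(component = colnames(scores), sdev = pc$sdev,
                   variance_proportion = vp,
                   cumulative_proportion = cumsum(vp))
    ),
    class = "climate_distances"
  )
}

#' @export
print.climate_distances <- function(x, ...) {
  cat(sprintf("<climate_distances: %d localities, %d components>\n",
              nrow(x$scores), nrow(x$pca)))
  invisible(x)
}

#' @method tidy climate_distances
#' @export
tidy.climate_distances <- function(x, ...) x$pca
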