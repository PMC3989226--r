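#' Run the full colour / genetic / geographic / climatic pipeline
#'
#' Chains every stage on a study (a [simulate_study()] object, a
#' [read_study()] list, or any list with the same layers): fuzzy coding and
#' correspondence analysis of the colour characters, morph cross-validation,
#' character-vector correlations with integration and modularity summaries,
#' DAS / haplotype / geodesic / climatic distance matrices, population-level
#' aggregation, Lingoes-corrected PCoA, pairwise RV tests, the RV-based
#' congruence tree, and (for moderate sample sizes) the per-individual
#' distance-profile correlation between haplotype and colour distances.
#'
#' Layers that are absent (`NULL`) are skipped with a message; ids present
#' in a data layer but unknown to the specimen table abort the run listing
#' the orphans. When `outdir` is given all results are also written as
#' TSV/CSV/newick files with a provenance header.
#'
#' @param study List with elements `specimens`, `characters`, and optionally
#'   `alignment`, `genotypes`, `localities`, `climate`.
#' @param outdir Optional output directory.
#' @param n_permutations Permutations per RV test.
#' @param seed Seed for the RV permutation streams.
#' @param cva_dims Dimensions used in morph cross-validation (default all).
#' @param n_modules Modules to cut the character clustering into.
#' @param profile_max_n Skip the O(n^3) distance-profile correlation above
#'   this number of individuals.
#' @return A list of class `melanospace_analysis` with the fitted objects.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(scenario_config(seed = 1))
#' res <- analyze_study(study, n_permutations = 199)
#' res$rv_population
#' }
analyze_study <- function(study, outdir = NULL, n_permutations = 999L,
                          seed = 1L, cva_dims = NULL, n_modules = 2L,
                          profile_max_n = 150L) {
  stopifnot(is.list(study), !is.null(study$specimens),
            !is.null(study$characters))
  specimens <- study$specimens
  ids <- as.character(specimens$id)

  check_ids <- function(layer_ids, layer) {
    orphans <- setdiff(as.character(layer_ids), ids)
    if (length(orphans)) {
      abort(paste0("ids in ", layer, " unknown to the specimen table: ",
                   paste(head(orphans, 10L), collapse = ", ")))
    }
  }

  res <- list(seed = seed)

  ## colour space
  res$coded <- encode_specimens(specimens, study$characters)
  res$space <- correspondence_analysis(res$coded)
  if ("morph" %in% names(specimens) &&
      length(unique(specimens$morph)) >= 2L) {
    res$cva <- crossvalidate_morphs(res$space,
                                    specimens[c("id", "morph")],
                                    n_dims = cva_dims)
  } else {
    inform("morph labels absent or single morph: cross-validation skipped")
  }
  res$character_correlations <- character_vector_correlations(res$space)
  res$integration <- integration_summary(res$character_correlations)
  res$modules <- modularity_clusters(res$character_correlations, n_modules)
  colour_scores <- res$space$row_coordinates
  colour_dist <- dist_matrix(as.matrix(dist(table_matrix(colour_scores))))

  ## individual-level distance layers
  ind <- list(colour = colour_dist)
  if (!is.null(study$genotypes)) {
    check_ids(study$genotypes$id, "genotypes")
    ind$das <- das_distance(study$genotypes)
  } else inform("genotypes absent: DAS distances skipped")
  if (!is.null(study$alignment)) {
    check_ids(study$alignment$id, "alignment")
    ind$haplotype <- haplotype_distance(study$alignment)
  } else inform("alignment absent: haplotype distances skipped")
  if (!is.null(study$localities)) {
    check_ids(study$localities$id, "localities")
    ind$geodesic <- geodesic_distances(study$localities)
  } else inform("localities absent: geodesic distances skipped")
  clim <- NULL
  if (!is.null(study$climate)) {
    check_ids(study$climate$id, "climate")
    clim <- climate_distances(study$climate)
    ind$climate <- clim$distances
  } else inform("climate absent: climatic distances skipped")
  res$individual_distances <- ind
  res$climate_pca <- if (!is.null(clim)) clim$pca

  ## population aggregation and congruence
  if ("population" %in% names(specimens)) {
    membership <- specimens[c("id", "population")]
    res$population_distances <- population_aggregate(
      membership,
      colour = colour_scores,
      climate = clim,
      localities = study$localities,
      das = ind$das,
      haplotype = ind$haplotype
    )
    coord_sets <- lapply(res$population_distances, function(d) {
      pcoa(lingoes_correction(d))
    })
    res$rv_population <- rv_table(coord_sets,
                                  n_permutations = n_permutations,
                                  seed = seed)
    if (length(coord_sets) >= 3L) {
      res$congruence_tree <- congruence_tree(coord_sets)
    }
  } else inform("population column absent: aggregation skipped")

  ## Fig-9-style heatmap on individuals (costly above profile_max_n)
  if (!is.null(ind$haplotype)) {
    if (length(ids) <= profile_max_n) {
      res$profile_correlation <-
        distance_profile_correlation(ind$haplotype, colour_dist)
    } else {
      inform(sprintf(
        "%d individuals > profile_max_n = %d: profile correlation skipped",
        length(ids), profile_max_n))
    }
  }

  class(res) <- "melanospace_analysis"
  if (!is.null(outdir)) write_analysis(res, outdir)
  res
}

#' @export
print.melanospace_analysis <- function(x, ...) {
  cat("<melanospace_analysis>\n")
  print(x$space)
  if (!is.null(x$cva)) print(x$cva)
  if (!is.null(x$integration)) print(x$integration)
  if (!is.null(x$rv_population)) {
    cat("population-level RV tests:\n")
    print(as.data.frame(x$rv_population))
  }
  invisible(x)
}

# Write the full report set of an analysis to a directory.
write_analysis <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- res$seed
  out <- function(name) file.path(outdir, name)
  write_commented_table(res$coded, out("coded_matrix.tsv"), "\t", seed)
  write_commented_table(tidy(res$space), out("eigenvalues.tsv"), "\t", seed)
  write_commented_table(res$space$row_coordinates, out("scores.tsv"),
                        "\t", seed)
  write_commented_table(res$space$column_coordinates,
                        out("variable_coordinates.tsv"), "\t", seed)
  if (!is.null(res$cva)) {
    write_commented_table(glance(res$cva), out("crossvalidation.tsv"),
                          "\t", seed)
    write_commented_table(res$cva$confusion, out("confusion.tsv"), "\t", seed)
  }
  write_commented_table(tidy(res$character_correlations),
                        out("character_correlations.tsv"), "\t", seed)
  write_commented_table(
    tibble(fraction_positive = res$integration$fraction_positive,
           n_pairs = res$integration$n_pairs),
    out("integration.tsv"), "\t", seed)
  write_commented_table(res$modules, out("modules.csv"), ",", seed)
  for (nm in names(res$individual_distances)) {
    write_distance_matrix(res$individual_distances[[nm]],
                          out(paste0("dist_individual_", nm, ".tsv")), seed)
  }
  for (nm in names(res$population_distances)) {
    write_distance_matrix(res$population_distances[[nm]],
                          out(paste0("dist_population_", nm, ".tsv")), seed)
  }
  if (!is.null(res$rv_population)) {
    write_commented_table(res$rv_population, out("rv_tests.tsv"), "\t", seed)
    m <- attr(res$rv_population, "matrix")
    write_commented_table(tibble(set = rownames(m),
                                 !!!as.data.frame(m)),
                          out("rv_matrix.tsv"), "\t", seed)
  }
  if (!is.null(res$congruence_tree)) {
    ape::write.tree(res$congruence_tree$tree, out("congruence_tree.nwk"))
  }
  if (!is.null(res$profile_correlation)) {
    C <- res$profile_correlation$correlation
    write_commented_table(tibble(id = rownames(C), !!!as.data.frame(C)),
                          out("profile_correlation.tsv"), "\t", seed)
  }
  invisible(outdir)
}
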