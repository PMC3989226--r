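# All tabular I/O is CSV/TSV with explicit id columns; writers prepend a
# "#"-prefixed provenance header that the readers skip.

ms_header <- function(seed = NULL) {
  paste0("# melanospace ",
         as.character(utils::packageVersion("melanospace")),
         if (!is.null(seed)) paste0(" | seed ", seed))
}

write_commented_table <- function(x, path, delim, seed = NULL) {
  writeLines(ms_header(seed), path)
  readr::write_delim(x, path, delim = delim, append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Read and write colour character definitions
#'
#' CSV with columns `name`, `body_region`, `modalities` (pipe-separated,
#' ordered lightest to darkest).
#'
#' @param path File path.
#' @return [read_characters()] returns a `colour_characters` tibble.
#' @export
read_characters <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  colour_characters(df$name, df$body_region,
                    strsplit(df$modalities, "|", fixed = TRUE))
}

#' @rdname read_characters
#' @param characters A `colour_characters` tibble.
#' @export
write_characters <- function(characters, path) {
  df <- tibble(
    name = characters$name,
    body_region = characters$body_region,
    modalities = vapply(characters$modalities, paste, character(1),
                        collapse = "|")
  )
  write_commented_table(df, path, ",")
}

#' Read and write specimen coding tables
#'
#' CSV with one row per specimen: `id`, optional `population` / `morph` /
#' `caste`, and one modality-label column per character.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_specimens <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_specimens
#' @param specimens Specimen tibble.
#' @param seed Optional seed recorded in the file header.
#' @export
write_specimens <- function(specimens, path, seed = NULL) {
  write_commented_table(specimens, path, ",", seed)
}

#' Read and write labelled square distance matrices as TSV
#'
#' @param path File path.
#' @return A `dist_matrix`.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  dist_matrix(m, allow_na = anyNA(m))
}

#' @rdname read_distance_matrix
#' @param d A `dist_matrix`.
#' @param seed Optional seed recorded in the file header.
#' @export
write_distance_matrix <- function(d, path, seed = NULL) {
  d <- as_dist_matrix(d, allow_na = TRUE)
  df <- tibble(id = rownames(d), !!!as.data.frame(unclass(d)))
  write_commented_table(df, path, "\t", seed)
}

#' Read and write genotype tables
#'
#' CSV with `id` plus `<locus>.a1` / `<locus>.a2` columns; missing alleles
#' empty.
#'
#' @param path File path.
#' @return A tibble of character columns.
#' @export
read_genotypes <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_genotypes
#' @param genotypes Genotype tibble.
#' @param seed Optional seed recorded in the file header.
#' @export
write_genotypes <- function(genotypes, path, seed = NULL) {
  write_commented_table(genotypes, path, ",", seed)
}

#' Read and write aligned sequences as FASTA
#'
#' The alignment is validated for equal sequence lengths on read.
#'
#' @param path File path.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_alignment_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(bin), paste, character(1),
                         collapse = ""))
  out <- tibble(id = names(bin), sequence = unname(seqs))
  alignment_matrix(out)  # validates length and alphabet
  out
}

#' @rdname read_alignment_fasta
#' @param alignment Tibble with columns `id` and `sequence`.
#' @export
write_alignment_fasta <- function(alignment, path) {
  lines <- as.vector(rbind(paste0(">", alignment$id), alignment$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Writes every data layer in the formats the readers consume
#' (`specimens.csv`, `characters.csv`, `sequences.fasta`, `genotypes.csv`,
#' `localities.csv`, `climate.csv`) plus the ground-truth scenario
#' parameters (`truth.yaml`), making simulate-then-analyze a pure round
#' trip through the public interfaces. Byte-identical for identical
#' configs.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- study$truth$seed
  write_specimens(study$specimens, file.path(dir, "specimens.csv"), seed)
  write_characters(study$characters, file.path(dir, "characters.csv"))
  write_alignment_fasta(study$alignment, file.path(dir, "sequences.fasta"))
  write_genotypes(study$genotypes, file.path(dir, "genotypes.csv"), seed)
  write_commented_table(study$localities, file.path(dir, "localities.csv"),
                        ",", seed)
  write_commented_table(study$climate, file.path(dir, "climate.csv"),
                        ",", seed)
  truth <- study$truth
  yaml::write_yaml(
    list(seed = truth$seed,
         convergence_mode = truth$convergence_mode,
         lineage_divergence_mutations = truth$lineage_divergence_mutations,
         within_lineage_mutations = truth$within_lineage_mutations,
         n_loci = truth$n_loci, allele_pool_size = truth$allele_pool_size,
         fst_like_drift = truth$fst_like_drift,
         climate_geography_coupling = truth$climate_geography_coupling,
         seq_length = truth$seq_length,
         dark_level = truth$dark_level, light_level = truth$light_level,
         profile_sigma = truth$profile_sigma,
         populations = lapply(seq_len(nrow(truth$populations)), function(i) {
           as.list(truth$populations[i, ])
         })),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory path.
#' @return A list with the same layers as a `synthetic_study` (`truth` is
#'   the parsed YAML list, or `NULL` when absent).
#' @export
read_study <- function(dir) {
  need <- file.path(dir, "specimens.csv")
  if (!file.exists(need)) abort(paste0("missing file: ", need))
  truth_path <- file.path(dir, "truth.yaml")
  layers <- list(
    specimens = read_specimens(file.path(dir, "specimens.csv")),
    characters = read_characters(file.path(dir, "characters.csv")),
    alignment = read_alignment_fasta(file.path(dir, "sequences.fasta")),
    genotypes = read_genotypes(file.path(dir, "genotypes.csv")),
    localities = readr::read_csv(file.path(dir, "localities.csv"),
                                 comment = "#", show_col_types = FALSE),
    climate = readr::read_csv(file.path(dir, "climate.csv"),
                              comment = "#", show_col_types = FALSE),
    truth = if (file.exists(truth_path)) yaml::read_yaml(truth_path)
  )
  layers
}
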