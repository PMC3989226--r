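#' Define a set of ordered colour characters
#'
#' A colour character describes the discrete melanic patterns ("modalities")
#' of one body part, ordered from the lightest to the darkest state. The
#' character table is the reference against which specimen codings are
#' validated and fuzzy-coded.
#'
#' @param name Character vector of unique character labels.
#' @param body_region Character vector (recycled) naming the body region of
#'   each character; one of `"head"`, `"mesosoma"`, `"legs"`,
#'   `"metasoma_terga"`, `"metasoma_sterna"`.
#' @param modalities List of character vectors, one per character, giving the
#'   modality labels ordered from lightest to darkest.
#' @param max_modalities Upper bound on the number of modalities per
#'   character (default 5).
#'
#' @return A tibble of class `colour_characters` with columns `name`,
#'   `body_region`, `modalities` (list column) and `n_modalities`.
#' @export
#' @examples
#' colour_characters(
#'   name = c("vertex", "scutellum"),
#'   body_region = c("head", "mesosoma"),
#'   modalities = list(c("yellow", "banded", "black"), c("yellow", "black"))
#' )
colour_characters <- function(name, body_region, modalities,
                              max_modalities = 5L) {
  stopifnot(is.character(name), is.list(modalities))
  if (anyDuplicated(name)) {
    abort("character names must be unique")
  }
  regions <- c("head", "mesosoma", "legs", "metasoma_terga", "metasoma_sterna")
  body_region <- rep_len(as.character(body_region), length(name))
  bad_region <- setdiff(unique(body_region), regions)
  if (length(bad_region)) {
    abort(paste0("unknown body_region: ", paste(bad_region, collapse = ", ")))
  }
  n_mod <- vapply(modalities, length, integer(1))
  if (any(n_mod < 2L) || any(n_mod > max_modalities)) {
    abort(sprintf("each character needs between 2 and %d modalities",
                  max_modalities))
  }
  dup <- vapply(modalities, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    abort(paste0("duplicated modality labels in character(s): ",
                 paste(name[dup], collapse = ", ")))
  }
  out <- tibble(
    name = name,
    body_region = body_region,
    modalities = unname(lapply(modalities, as.character)),
    n_modalities = n_mod
  )
  class(out) <- c("colour_characters", class(out))
  out
}

#' The 23 colour characters of the *Vespa velutina* worker
#'
#' Reference character set covering head (4 characters), mesosoma (5),
#' legs (3), metasomal terga (7) and metasomal sterna (4), with two to five
#' modalities each (72 modalities in total). Modality labels are generic
#' rank labels ordered lightest to darkest.
#'
#' @return A `colour_characters` tibble with 23 rows.
#' @export
#' @examples
#' velutina_characters()
velutina_characters <- function() {
  def <- list(
    upper_gena        = c("head", 3L),
    vertex            = c("head", 3L),
    ocellar_area      = c("head", 3L),
    scape_dorsal      = c("head", 3L),
    prothorax         = c("mesosoma", 4L),
    mesoscutum        = c("mesosoma", 5L),
    scutellum         = c("mesosoma", 3L),
    metanotum         = c("mesosoma", 4L),
    mesepisternum     = c("mesosoma", 2L),
    profemur          = c("legs", 3L),
    protibia          = c("legs", 3L),
    metatibia_apex    = c("legs", 2L),
    tergum1           = c("metasoma_terga", 4L),
    tergum2_base      = c("metasoma_terga", 2L),
    tergum2_apex      = c("metasoma_terga", 3L),
    tergum3           = c("metasoma_terga", 4L),
    tergum4           = c("metasoma_terga", 4L),
    tergum5           = c("metasoma_terga", 3L),
    tergum6           = c("metasoma_terga", 2L),
    sternum2          = c("metasoma_sterna", 4L),
    sternum3          = c("metasoma_sterna", 3L),
    sternum4          = c("metasoma_sterna", 3L),
    sternum5_6        = c("metasoma_sterna", 2L)
  )
  colour_characters(
    name = names(def),
    body_region = vapply(def, `[`, character(1), 1L),
    modalities = lapply(def, function(x) {
      n <- as.integer(x[2L])
      paste0("m", seq_len(n) - 1L)  # m0 lightest ... m(n-1) darkest
    })
  )
}

#' Fuzzy-code an ordered modality rank
#'
#' Maps the rank of a modality in the light-to-dark ordination onto
#' `[0, 1]` as `rank / (n_modalities - 1)`, where rank 0 is the extreme
#' modality *not* described by the variable, so that the two extreme
#' modalities map exactly onto 0 and 1 and intermediate modalities are
#' equally spaced.
#'
#' @param rank Integer vector of modality ranks, `0 <= rank <= n - 1`.
#' @param n_modalities Integer vector (recycled) of modality counts, `>= 2`.
#' @param character Optional character name used in error messages.
#' @return Numeric vector of membership values in `[0, 1]`.
#' @export
#' @examples
#' fuzzy_code(0:3, 4)  # 0, 1/3, 2/3, 1
fuzzy_code <- function(rank, n_modalities, character = NULL) {
  n <- as.integer(n_modalities)
  r <- as.integer(rank)
  if (any(n < 2L)) abort("n_modalities must be >= 2")
  bad <- which(r < 0L | r > rep_len(n, length(r)) - 1L)
  if (length(bad)) {
    abort(sprintf(
      "rank out of range for character %s: rank %s with %s modalities",
      if (is.null(character)) "<unnamed>" else character,
      r[bad[1L]], rep_len(n, length(r))[bad[1L]]
    ))
  }
  r / (rep_len(n, length(r)) - 1L)
}

# Validate specimen table against a character set; returns the character
# columns as a matrix of modality labels. Shared by the two encoders.
check_specimens <- function(specimens, characters,
                            on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(specimens), inherits(characters, "colour_characters"))
  if (!"id" %in% names(specimens)) abort("specimens must have an `id` column")
  if (anyDuplicated(specimens$id)) abort("specimen ids must be unique")
  missing_chars <- setdiff(characters$name, names(specimens))
  if (length(missing_chars)) {
    abort(paste0("specimens lack columns for character(s): ",
                 paste(missing_chars, collapse = ", ")))
  }
  codes <- as.matrix(specimens[characters$name])
  storage.mode(codes) <- "character"
  rownames(codes) <- specimens$id

  incomplete <- rownames(codes)[rowSums(is.na(codes) | codes == "") > 0L]
  if (length(incomplete)) {
    if (on_missing == "error") {
      abort(paste0("incomplete modality codes for specimen(s): ",
                   paste(head(incomplete, 10L), collapse = ", "),
                   if (length(incomplete) > 10L) ", ..."))
    }
    inform(sprintf("dropped %d specimen(s) with incomplete codings",
                   length(incomplete)))
    codes <- codes[setdiff(rownames(codes), incomplete), , drop = FALSE]
  }
  for (k in seq_len(nrow(characters))) {
    mods <- characters$modalities[[k]]
    bad <- which(!codes[, k] %in% mods)
    if (length(bad)) {
      abort(sprintf(
        "unknown modality for character %s in specimen(s): %s",
        characters$name[k],
        paste(head(rownames(codes)[bad], 10L), collapse = ", ")
      ))
    }
  }
  codes
}

#' Encode specimens as a dual-extreme fuzzy-coded matrix
#'
#' Each character becomes two complementary variables: the membership in its
#' lightest extreme (`<character>.light`) and in its darkest extreme
#' (`<character>.dark`), with `light + dark = 1` for every cell. Intermediate
#' modalities take the equally spaced fuzzy values given by [fuzzy_code()].
#' Because the pair sums to one, every specimen has the same row margin
#' (the number of characters) and hence the same weight in a correspondence
#' analysis of the matrix.
#'
#' @param specimens Data frame with an `id` column and one column per
#'   character holding modality labels; extra columns (`population`, `morph`,
#'   `caste`, ...) are ignored.
#' @param characters A [colour_characters()] table.
#' @param on_missing `"error"` (default) rejects specimens with missing
#'   codes; `"drop"` removes them with a message.
#' @return A tibble of class `coded_matrix`: column `id` followed by
#'   `2 * K` numeric columns in character order, light before dark.
#' @export
#' @examples
#' chars <- velutina_characters()
#' sp <- simulate_study(scenario_config(seed = 1))$specimens[1:5, ]
#' encode_specimens(sp, chars)
encode_specimens <- function(specimens, characters,
                             on_missing = c("error", "drop")) {
  codes <- check_specimens(specimens, characters, on_missing)
  K <- nrow(characters)
  cols <- vector("list", 2L * K)
  nms <- character(2L * K)
  for (k in seq_len(K)) {
    mods <- characters$modalities[[k]]
    n <- length(mods)
    idx <- match(codes[, k], mods) - 1L        # 0 = lightest ... n-1 = darkest
    light <- fuzzy_code(n - 1L - idx, n, characters$name[k])
    cols[[2L * k - 1L]] <- light
    cols[[2L * k]] <- 1 - light
    nms[2L * k - 1L] <- paste0(characters$name[k], ".light")
    nms[2L * k] <- paste0(characters$name[k], ".dark")
  }
  out <- tibble(id = rownames(codes), !!!setNames(cols, nms))
  attr(out, "characters") <- characters
  class(out) <- c("coded_matrix", class(out))
  out
}

#' Build the one-hot indicator matrix of modalities
#'
#' The disjunctive (indicator) coding used for multiple correspondence
#' analysis: one binary column per modality, exactly one 1 per character per
#' specimen, columns named `<character>.<modality>`.
#'
#' @inheritParams encode_specimens
#' @return A tibble: `id` followed by one 0/1 column per modality.
#' @export
build_indicator_matrix <- function(specimens, characters,
                                   on_missing = c("error", "drop")) {
  codes <- check_specimens(specimens, characters, on_missing)
  cols <- list()
  for (k in seq_len(nrow(characters))) {
    mods <- characters$modalities[[k]]
    for (m in mods) {
      cols[[paste0(characters$name[k], ".", m)]] <-
        as.numeric(codes[, k] == m)
    }
  }
  out <- tibble(id = rownames(codes), !!!cols)
  attr(out, "characters") <- characters
  out
}

#' Report per-character variant frequencies for filtering
#'
#' Body parts with (nearly) constant coloration or with variants rarer than a
#' frequency threshold are usually excluded before ordination. This utility
#' reports, for each character, the frequency of specimens deviating from the
#' most common modality, and flags characters passing the threshold. No
#' filtering is applied silently; subset the character table on `keep`.
#'
#' @inheritParams encode_specimens
#' @param threshold Minimum variant frequency to keep a character
#'   (default 0.05).
#' @return Tibble with columns `name`, `n_observed_modalities`,
#'   `variant_frequency`, `keep`.
#' @export
character_frequency_filter <- function(specimens, characters,
                                       threshold = 0.05) {
  codes <- check_specimens(specimens, characters, on_missing = "error")
  res <- lapply(seq_len(nrow(characters)), function(k) {
    x <- codes[, k]
    tab <- table(x)
    tibble(
      name = characters$name[k],
      n_observed_modalities = length(tab),
      variant_frequency = 1 - max(tab) / length(x)
    )
  })
  bind_rows(res) |> mutate(keep = .data$variant_frequency >= threshold)
}
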