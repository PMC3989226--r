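#' Reference population layout for synthetic studies
#'
#' Eighteen populations in two deep mitochondrial lineages (a mainland
#' lineage and an Indonesian island lineage), with per-population sample
#' sizes between 1 and 68 (448 specimens in total) and approximate regional
#' centroids, mirroring the sampling shape of the reference study.
#'
#' @return Tibble with columns `name`, `n_specimens`, `lineage`, `lat`,
#'   `lon`, `spread_km`.
#' @export
velutina_populations <- function() {
  tribble(
    ~name,        ~n_specimens, ~lineage,    ~lat,  ~lon,
    "Kashmir",     9L,  "mainland",   34.0,  75.0,
    "Nepal",      68L,  "mainland",   28.0,  84.0,
    "Assam",       3L,  "mainland",   26.0,  92.0,
    "Yunnan",     33L,  "mainland",   25.0, 101.0,
    "Guangdong",   2L,  "mainland",   23.0, 113.0,
    "Zhejiang",   63L,  "mainland",   29.0, 120.0,
    "Taiwan",      2L,  "mainland",   24.0, 121.0,
    "Thailand",   34L,  "mainland",   18.0, 100.0,
    "Vietnam",    10L,  "mainland",   11.0, 107.0,
    "Kra",         1L,  "mainland",   10.0,  99.0,
    "Malaysia",   34L,  "mainland",    3.0, 102.0,
    "Sumatra",    25L,  "indonesia",   0.0, 101.0,
    "Java",       54L,  "indonesia",  -7.0, 110.0,
    "Lombok",     40L,  "indonesia",  -8.6, 116.3,
    "Flores",     25L,  "indonesia",  -8.6, 121.0,
    "Sumba",      27L,  "indonesia",  -9.7, 120.0,
    "Sulawesi",   10L,  "indonesia",  -2.0, 120.0,
    "Timor",       8L,  "indonesia",  -9.5, 125.0
  ) |> mutate(spread_km = 30)
}

# Deterministic per-population melanisation targets and morph labels.
population_melanisation <- function(populations, convergence_mode,
                                    dark_level, light_level) {
  lineages <- unique(populations$lineage)
  mu <- numeric(nrow(populations))
  for (ln in lineages) {
    idx <- which(populations$lineage == ln)
    if (convergence_mode) {
      # plant the same dark and light profiles in both lineages
      mu[idx] <- ifelse(seq_along(idx) %% 2L == 1L, dark_level, light_level)
    } else {
      base <- if (ln == lineages[1L]) dark_level else light_level
      jitter <- if (length(idx) > 1L)
        seq(-0.08, 0.08, length.out = length(idx)) else 0
      mu[idx] <- pmin(0.95, pmax(0.05, base + jitter))
    }
  }
  tibble(name = populations$name, mu = mu,
         morph = ifelse(mu >= 0.5, "morph_dark", "morph_light"))
}

# Modality probability vector for one character at melanisation target mu:
# a Gaussian kernel over the equally spaced light-to-dark positions.
modality_profile <- function(n_modalities, mu, sigma = 0.2) {
  pos <- (seq_len(n_modalities) - 1L) / (n_modalities - 1L)  # 0 light, 1 dark
  w <- exp(-(pos - mu)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Configure a synthetic study scenario
#'
#' Bundles and validates all ground-truth parameters of a simulated
#' dataset: the populations with their lineages and centroids, the colour
#' characters, per-population modality profiles, mitochondrial divergence
#' (more mutations between than within lineages), microsatellite drift,
#' and the coupling of climate to geography.
#'
#' If `morph_profiles` is not supplied it is derived deterministically:
#' in the default (congruent) mode each lineage gets a distinct
#' melanisation level (dark mainland, light islands, with a small
#' within-lineage gradient); with `convergence_mode = TRUE` one dark and
#' one light profile are planted alternately in populations of *both*
#' lineages, emulating convergent colour morphs.
#'
#' @param seed Integer seed; all layers derive independent streams from it.
#' @param populations Tibble as [velutina_populations()].
#' @param characters A [colour_characters()] table.
#' @param morph_profiles Optional named list (per population) of named
#'   lists (per character) of modality probability vectors.
#' @param lineage_divergence_mutations Mutations separating the two lineage
#'   ancestors (default 16, emulating a deep split of more than 15).
#' @param within_lineage_mutations Maximum mutational divergence within a
#'   lineage (default 11; must be smaller than the between-lineage count).
#' @param n_loci,allele_pool_size Microsatellite loci and alleles per locus.
#' @param fst_like_drift Drift of population allele frequencies from the
#'   common pool, in `[0, 1)`; Dirichlet concentration `(1 - f) / f`.
#' @param climate_geography_coupling In `[0, 1]`: correlation of each
#'   climate variable with its geographic gradient.
#' @param convergence_mode Plant the same morph profiles in both lineages.
#' @param seq_length Alignment length (default 658 bp).
#' @param dark_level,light_level Melanisation targets of the dark and light
#'   profiles.
#' @param profile_sigma Width of the modality kernel (larger = more labile
#'   within-population colour variation).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            populations = velutina_populations(),
                            characters = velutina_characters(),
                            morph_profiles = NULL,
                            lineage_divergence_mutations = 16L,
                            within_lineage_mutations = 11L,
                            n_loci = 13L,
                            allele_pool_size = 8L,
                            fst_like_drift = 0.15,
                            climate_geography_coupling = 0.8,
                            convergence_mode = FALSE,
                            seq_length = 658L,
                            dark_level = 0.8,
                            light_level = 0.2,
                            profile_sigma = 0.2) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(is.data.frame(populations),
            all(c("name", "n_specimens", "lineage", "lat", "lon",
                  "spread_km") %in% names(populations)))
  if (anyDuplicated(populations$name)) abort("population names must be unique")
  if (length(unique(populations$lineage)) != 2L) {
    abort("exactly two lineages are required")
  }
  if (lineage_divergence_mutations <= within_lineage_mutations) {
    abort("between-lineage mutations must exceed within-lineage mutations")
  }
  if (fst_like_drift < 0 || fst_like_drift >= 1) {
    abort("fst_like_drift must be in [0, 1)")
  }
  if (climate_geography_coupling < 0 || climate_geography_coupling > 1) {
    abort("climate_geography_coupling must be in [0, 1]")
  }
  stopifnot(inherits(characters, "colour_characters"))

  mel <- population_melanisation(populations, convergence_mode,
                                 dark_level, light_level)
  if (is.null(morph_profiles)) {
    morph_profiles <- lapply(seq_len(nrow(populations)), function(p) {
      setNames(lapply(characters$n_modalities, modality_profile,
                      mu = mel$mu[p], sigma = profile_sigma),
               characters$name)
    })
    names(morph_profiles) <- populations$name
  }
  for (p in names(morph_profiles)) {
    sums <- vapply(morph_profiles[[p]], sum, numeric(1))
    if (any(abs(sums - 1) > 1e-8)) {
      abort(sprintf("modality probabilities of population %s do not sum to 1",
                    p))
    }
  }
  # site budget: lineage split + per-population blocks + one private site
  # per specimen
  pop_block <- max(1L, floor(within_lineage_mutations / 2))
  needed <- lineage_divergence_mutations +
    nrow(populations) * pop_block + sum(populations$n_specimens)
  if (seq_length < needed) {
    abort(sprintf("seq_length %d too short for the mutation budget (%d)",
                  seq_length, needed))
  }
  structure(
    list(seed = as.integer(seed), populations = populations,
         characters = characters, morph_profiles = morph_profiles,
         population_morphs = mel,
         lineage_divergence_mutations = as.integer(lineage_divergence_mutations),
         within_lineage_mutations = as.integer(within_lineage_mutations),
         n_loci = as.integer(n_loci),
         allele_pool_size = as.integer(allele_pool_size),
         fst_like_drift = fst_like_drift,
         climate_geography_coupling = climate_geography_coupling,
         convergence_mode = isTRUE(convergence_mode),
         seq_length = as.integer(seq_length),
         dark_level = dark_level, light_level = light_level,
         profile_sigma = profile_sigma),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config: %d populations (%d specimens), %d characters, seed %d%s>\n",
    nrow(x$populations), sum(x$populations$n_specimens),
    nrow(x$characters), x$seed,
    if (x$convergence_mode) ", convergent morphs" else ""))
  invisible(x)
}

# independent, reproducible sub-seed per data layer (kept below 2^31)
layer_seed <- function(seed, k) {
  as.integer((abs(seed) * 2654435.0 + k * 97561.0) %% 2147483629 + 1)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a full synthetic study
#'
#' Generates every data layer the analysis pipeline consumes, each from its
#' own seeded random stream (so changing the colour scenario leaves
#' genetics untouched): colour modalities drawn per character from the
#' population's morph profile; a 658 bp mitochondrial alignment mutated
#' along a two-lineage star topology (between-lineage divergence exceeding
#' any within-lineage divergence); microsatellite genotypes drawn by random
#' union of gametes from Dirichlet-drifted population allele frequencies;
#' coordinates scattered around population centroids; and climate variables
#' as geographic gradients mixed with noise.
#'
#' @param config A [scenario_config()].
#' @return Object of class `synthetic_study`: tibbles `specimens`,
#'   `alignment`, `genotypes`, `localities`, `climate`, plus `characters`
#'   and `truth` (the config). Regeneration with the same config is
#'   bit-identical.
#' @export
#' @examples
#' study <- simulate_study(scenario_config(seed = 42))
#' dplyr::count(study$specimens, population, morph)
simulate_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  pops <- config$populations
  chars <- config$characters
  pop_idx <- rep(seq_len(nrow(pops)), pops$n_specimens)
  ids <- unlist(lapply(seq_len(nrow(pops)), function(p) {
    sprintf("%s_%03d", pops$name[p], seq_len(pops$n_specimens[p]))
  }))
  n <- length(ids)

  ## colour layer
  set.seed(layer_seed(config$seed, 1L))
  colour_cols <- lapply(seq_len(nrow(chars)), function(k) {
    mods <- chars$modalities[[k]]
    vapply(pop_idx, function(p) {
      prof <- config$morph_profiles[[pops$name[p]]][[chars$name[k]]]
      sample(mods, 1L, prob = prof)
    }, character(1))
  })
  names(colour_cols) <- chars$name
  specimens <- tibble(
    id = ids,
    population = pops$name[pop_idx],
    morph = config$population_morphs$morph[pop_idx],
    caste = "worker",
    !!!colour_cols
  )

  ## mitochondrial layer: star topology within two lineages
  set.seed(layer_seed(config$seed, 2L))
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  mutate_at <- function(seq, sites) {
    for (s in sites) seq[s] <- sample(setdiff(bases, seq[s]), 1L)
    seq
  }
  B <- config$lineage_divergence_mutations
  pop_block <- max(1L, floor(config$within_lineage_mutations / 2))
  lineages <- unique(pops$lineage)
  anc <- list(root, mutate_at(root, seq_len(B)))
  names(anc) <- lineages
  next_site <- B + 1L
  pop_hap <- vector("list", nrow(pops))
  for (p in seq_len(nrow(pops))) {
    k_p <- sample.int(pop_block + 1L, 1L) - 1L        # 0..pop_block mutations
    sites <- if (k_p > 0L) next_site:(next_site + k_p - 1L) else integer(0)
    pop_hap[[p]] <- mutate_at(anc[[pops$lineage[p]]], sites)
    next_site <- next_site + pop_block
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- pop_hap[[pop_idx[i]]]
    if (runif(1) < 0.2) s <- mutate_at(s, next_site + i - 1L)  # private site
    seqs[i] <- paste(s, collapse = "")
  }
  alignment <- tibble(id = ids, sequence = seqs)

  ## microsatellite layer
  set.seed(layer_seed(config$seed, 3L))
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  allele_labels <- as.character(100 + 2 * (seq_len(config$allele_pool_size) - 1))
  f <- config$fst_like_drift
  conc <- if (f > 0) (1 - f) / f else Inf
  geno_cols <- list()
  for (loc in loci) {
    pool <- rdirichlet1(rep(1, config$allele_pool_size))
    pop_freq <- lapply(seq_len(nrow(pops)), function(p) {
      if (is.finite(conc)) rdirichlet1(pool * conc) else pool
    })
    a1 <- character(n); a2 <- character(n)
    for (i in seq_len(n)) {
      al <- sample(allele_labels, 2L, replace = TRUE,
                   prob = pop_freq[[pop_idx[i]]])
      a1[i] <- al[1L]; a2[i] <- al[2L]
    }
    geno_cols[[paste0(loc, ".a1")]] <- a1
    geno_cols[[paste0(loc, ".a2")]] <- a2
  }
  genotypes <- tibble(id = ids, !!!geno_cols)

  ## geographic layer
  set.seed(layer_seed(config$seed, 4L))
  km_per_deg <- 111.195
  lat <- pops$lat[pop_idx] +
    rnorm(n, sd = pops$spread_km[pop_idx] / km_per_deg)
  lon <- pops$lon[pop_idx] +
    rnorm(n, sd = pops$spread_km[pop_idx] /
            (km_per_deg * pmax(cos(pops$lat[pop_idx] * pi / 180), 0.2)))
  localities <- tibble(id = ids, lat = pmin(90, pmax(-90, lat)),
                       lon = ((lon + 180) %% 360) - 180)

  ## climate layer: gradients in geography mixed with noise
  set.seed(layer_seed(config$seed, 5L))
  g_temp <- as.numeric(scale(-abs(localities$lat)))   # hot near the equator
  g_lon <- as.numeric(scale(localities$lon))
  rho <- config$climate_geography_coupling
  clim_var <- function(mean, sdv, a, b) {
    det <- (a * g_temp + b * g_lon) / sqrt(a^2 + b^2)
    mean + sdv * (rho * det + sqrt(max(0, 1 - rho^2)) * rnorm(n))
  }
  climate <- tibble(
    id = ids,
    annual_mean_temperature = clim_var(24, 4, 1, 0),
    temperature_seasonality = clim_var(30, 12, -1, 0.2),
    max_annual_temperature = clim_var(32, 3, 1, 0.1),
    min_annual_temperature = clim_var(14, 6, 1, -0.1),
    annual_precipitation = clim_var(1800, 500, 0.4, 1),
    max_monthly_precipitation = clim_var(320, 90, 0.3, 1),
    min_monthly_precipitation = clim_var(40, 25, 0.5, -1),
    precipitation_seasonality = clim_var(60, 20, -0.4, -1)
  )

  structure(
    list(specimens = specimens, characters = chars, alignment = alignment,
         genotypes = genotypes, localities = localities, climate = climate,
         truth = config),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study: %d specimens, %d populations, %d characters, %d loci, %d bp>\n",
    nrow(x$specimens), nrow(x$truth$populations), nrow(x$characters),
    x$truth$n_loci, x$truth$seq_length))
  invisible(x)
}

#' Paired congruent / convergent synthetic studies
#'
#' Returns two studies that differ only in the colour scenario: the
#' *congruent* study assigns distinct morph profiles to the two lineages
#' (colour tracks the deep genetic split), while the *convergent* study
#' plants the same dark and light profiles in populations of both lineages
#' (colour similarity arises independently of ancestry). Genetics,
#' geography and climate share identical random streams, so their data
#' layers are identical between the two studies.
#'
#' @param config A base [scenario_config()] (its `convergence_mode` is
#'   overridden).
#' @return List with elements `congruent` and `convergent`.
#' @export
make_congruent_and_convergent_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  remake <- function(mode) {
    scenario_config(
      seed = config$seed, populations = config$populations,
      characters = config$characters,
      lineage_divergence_mutations = config$lineage_divergence_mutations,
      within_lineage_mutations = config$within_lineage_mutations,
      n_loci = config$n_loci, allele_pool_size = config$allele_pool_size,
      fst_like_drift = config$fst_like_drift,
      climate_geography_coupling = config$climate_geography_coupling,
      convergence_mode = mode, seq_length = config$seq_length,
      dark_level = config$dark_level, light_level = config$light_level,
      profile_sigma = config$profile_sigma
    )
  }
  list(congruent = simulate_study(remake(FALSE)),
       convergent = simulate_study(remake(TRUE)))
}
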