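#' Shared-allele distance (DAS) between multilocus genotypes
#'
#' For each pair of individuals and each locus scored in both, the number of
#' shared alleles is the sum over allele labels of the smaller count carried
#' by each individual (0, 1 or 2 for diploids); the locus similarity is
#' `shared / 2` and the distance is one minus its mean over the commonly
#' scored loci (pairwise deletion of missing loci).
#'
#' @param genotypes Tibble with an `id` column and two columns per locus
#'   named `<locus>.a1` and `<locus>.a2`; missing alleles as `NA` or `""`.
#' @param on_no_shared_locus `"error"` (default) fails when a pair has no
#'   commonly scored locus; `"na"` flags that pair's distance as missing.
#' @return A `dist_matrix` of DAS values in `[0, 1]`.
#' @export
#' @examples
#' g <- tibble::tibble(id = c("a", "b"),
#'                     L1.a1 = c("120", "120"), L1.a2 = c("120", "124"))
#' das_distance(g)  # 1 - 1/2 = 0.5
das_distance <- function(genotypes, on_no_shared_locus = c("error", "na")) {
  on_no_shared_locus <- match.arg(on_no_shared_locus)
  stopifnot(is.data.frame(genotypes), "id" %in% names(genotypes))
  ids <- as.character(genotypes$id)
  if (anyDuplicated(ids)) abort("genotype ids must be unique")
  a1_cols <- grep("\\.a1$", names(genotypes), value = TRUE)
  loci <- sub("\\.a1$", "", a1_cols)
  if (!length(loci) || !all(paste0(loci, ".a2") %in% names(genotypes))) {
    abort("genotypes need paired `<locus>.a1` / `<locus>.a2` columns")
  }
  n <- length(ids)
  shared_sum <- matrix(0, n, n)
  n_loci_common <- matrix(0L, n, n)
  for (loc in loci) {
    a1 <- as.character(genotypes[[paste0(loc, ".a1")]])
    a2 <- as.character(genotypes[[paste0(loc, ".a2")]])
    a1[a1 == ""] <- NA
    a2[a2 == ""] <- NA
    scored <- !(is.na(a1) | is.na(a2))
    hom <- scored & (a1 == a2)
    m11 <- outer(a1, a1, "==")
    m12 <- outer(a1, a2, "==")
    m21 <- outer(a2, a1, "==")
    m22 <- outer(a2, a2, "==")
    het_shared <- (m11 | m12) + (m21 | m22)
    hom_shared <- m11 + m12
    s <- ifelse(matrix(hom, n, n), hom_shared, het_shared)
    ok <- outer(scored, scored, "&")
    s[!ok] <- 0
    shared_sum <- shared_sum + (s / 2)
    n_loci_common <- n_loci_common + ok
  }
  no_common <- n_loci_common == 0L
  diag(no_common) <- FALSE
  if (any(no_common)) {
    if (on_no_shared_locus == "error") {
      idx <- which(no_common, arr.ind = TRUE)[1L, ]
      abort(sprintf("no commonly scored locus for pair %s / %s",
                    ids[idx[1L]], ids[idx[2L]]))
    }
    warn(sprintf("%d pair(s) without a commonly scored locus set to NA",
                 sum(no_common) / 2L))
  }
  d <- 1 - shared_sum / pmax(n_loci_common, 1L)
  d[no_common] <- NA
  diag(d) <- 0
  rownames(d) <- colnames(d) <- ids
  dist_matrix(d, allow_na = any(no_common))
}

#' Per-locus missingness report
#'
#' Fraction of individuals with an incomplete genotype at each locus, to
#' support wholesale locus filtering before [das_distance()].
#'
#' @inheritParams das_distance
#' @return Tibble with columns `locus`, `n_missing`, `missing_fraction`.
#' @export
locus_missingness <- function(genotypes) {
  a1_cols <- grep("\\.a1$", names(genotypes), value = TRUE)
  loci <- sub("\\.a1$", "", a1_cols)
  purrr::map_dfr(loci, function(loc) {
    a1 <- as.character(genotypes[[paste0(loc, ".a1")]])
    a2 <- as.character(genotypes[[paste0(loc, ".a2")]])
    miss <- is.na(a1) | is.na(a2) | a1 == "" | a2 == ""
    tibble(locus = loc, n_missing = sum(miss),
           missing_fraction = mean(miss))
  })
}

# internal: tibble(id, sequence) -> integer matrix (A,C,G,T = 1..4; else NA)
alignment_matrix <- function(sequences) {
  if (is.character(sequences) && !is.null(names(sequences))) {
    sequences <- tibble(id = names(sequences), sequence = unname(sequences))
  }
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  seqs <- toupper(sequences$sequence)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("all sequences must have the same (aligned) length")
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  bad <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(paste0("invalid alignment symbol(s): ", paste(bad, collapse = ", ")))
  }
  code <- match(chars, c("A", "C", "G", "T"))
  dim(code) <- dim(chars)
  rownames(code) <- as.character(sequences$id)
  code
}

#' Pairwise haplotype distances on an alignment
#'
#' Counts differing sites over the positions where both sequences carry an
#' unambiguous base (`A`, `C`, `G`, `T`); gaps and `N` are treated as
#' missing with pairwise deletion. `mode = "p"` divides by the number of
#' compared positions.
#'
#' @param sequences Tibble with columns `id` and `sequence` (equal-length
#'   aligned strings over `A,C,G,T,N,-`), or a named character vector.
#' @param mode `"count"` (default) for the raw number of differences, `"p"`
#'   for the proportion of differing compared sites.
#' @return A `dist_matrix`; attribute `compared_sites` holds the matrix of
#'   pairwise comparable-site counts.
#' @export
haplotype_distance <- function(sequences, mode = c("count", "p")) {
  mode <- match.arg(mode)
  code <- alignment_matrix(sequences)
  n <- nrow(code)
  if (anyDuplicated(rownames(code))) abort("sequence ids must be unique")
  valid <- !is.na(code)
  matches <- matrix(0, n, n)
  for (b in 1:4) {
    B <- (code == b) & valid
    storage.mode(B) <- "double"
    matches <- matches + tcrossprod(B)
  }
  V <- tcrossprod(matrix(as.double(valid), n))
  diff <- V - matches
  d <- if (mode == "count") diff else diff / pmax(V, 1)
  if (any(V[upper.tri(V)] == 0)) {
    warn("some pairs share no comparable site; distance set to NA")
    d[V == 0] <- NA
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(code)
  out <- dist_matrix(d, allow_na = anyNA(d))
  attr(out, "compared_sites") <- V
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch lengths are
#' clamped to zero with the excess transferred to the longest adjacent
#' branch so that path lengths through the node are preserved as far as
#' possible (reported with a message).
#'
#' @param d A `dist_matrix` (or square labelled matrix / `dist`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 3L) abort("neighbor joining requires at least 3 labels")
  tree <- ape::nj(as.dist(unclass(d)))
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    inform(sprintf("clamped %d negative branch length(s) to zero",
                   length(neg)))
    for (e in order(tree$edge.length)) {
      len <- tree$edge.length[e]
      if (len >= 0) next
      child <- tree$edge[e, 2L]
      parent <- tree$edge[e, 1L]
      adj <- which((tree$edge[, 1L] %in% c(child, parent) |
                    tree$edge[, 2L] %in% c(child, parent)) &
                   seq_along(tree$edge.length) != e)
      if (length(adj)) {
        target <- adj[which.max(tree$edge.length[adj])]
        tree$edge.length[target] <- max(0, tree$edge.length[target] + len)
      }
      tree$edge.length[e] <- 0
    }
  }
  tree
}
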