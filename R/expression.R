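#' Renormalize RPKM columns to transcripts per million (TPM)
#'
#' Rescales every sample column so its values sum to one million: TPM is
#' obtained from RPKM by dividing each gene's value by the column total and
#' multiplying by 1e6, which makes expression comparable across samples
#' with different total transcript output. Gene order is preserved.
#'
#' @param table Tibble or data frame whose first column is `gene_id` and
#'   whose remaining columns are nonnegative RPKM values, or a numeric
#'   matrix with genes in rows.
#' @return The same shape with TPM values; every sample column sums to 1e6
#'   (relative tolerance 1e-6). The `unit_tag` attribute is set to
#'   `"TPM"`.
#' @examples
#' rpkm_to_tpm(data.frame(gene_id = c("a", "b", "c"), s1 = c(1, 1, 2)))
#' @export
rpkm_to_tpm <- function(table) {
  if (is.matrix(table)) {
    sums <- colSums(table)
    bad <- which(sums <= 0)
    if (length(bad)) {
      stop("sample column(s) with nonpositive sum: ",
           paste(colnames(table)[bad] %||% bad, collapse = ", "),
           call. = FALSE)
    }
    out <- sweep(table, 2, sums / 1e6, "/")
    attr(out, "unit_tag") <- "TPM"
    return(out)
  }
  table <- tibble::as_tibble(table)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  for (s in num) {
    tot <- sum(table[[s]])
    if (!is.finite(tot) || tot <= 0) {
      stop(sprintf("sample '%s' has nonpositive sum; cannot renormalize", s),
           call. = FALSE)
    }
    table[[s]] <- table[[s]] * (1e6 / tot)
  }
  attr(table, "unit_tag") <- "TPM"
  table
}

#' Join per-species expression tables on a reference ortholog map
#'
#' Resolves every species' gene ids to reference-species gene ids through
#' an ortholog map (rows of `reference_gene_id`, `species`,
#' `species_gene_id`, at most one assignment per gene and species) and
#' returns one row per reference gene. With `complete_cases = TRUE` (the
#' default, required for cross-species operations) a gene is kept only if
#' an ortholog is resolvable in *every* supplied table: if one species of
#' the set has no assignment for a gene, that gene is not considered.
#'
#' @param tables Named list of per-species expression tibbles (first column
#'   `gene_id` holding species gene ids).
#' @param map Ortholog map tibble.
#' @param reference_species Species whose ids key the output.
#' @param complete_cases Drop genes missing in any species?
#' @return Tibble keyed by `gene_id` (reference ids) with each species'
#'   sample columns prefixed `species.`.
#' @export
ortholog_join <- function(tables, map, reference_species,
                          complete_cases = TRUE) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(c("reference_gene_id", "species", "species_gene_id") %in%
                  names(map)))
  if (!reference_species %in% map$species) {
    stop("reference species not present in the ortholog map", call. = FALSE)
  }
  if (anyDuplicated(map[, c("reference_gene_id", "species")])) {
    stop("ortholog map has duplicate (gene, species) assignments",
         call. = FALSE)
  }
  joined <- NULL
  for (sp in names(tables)) {
    m <- map[map$species == sp, c("reference_gene_id", "species_gene_id")]
    tbl <- tibble::as_tibble(tables[[sp]])
    tbl <- dplyr::inner_join(m, tbl, by = c(species_gene_id = "gene_id"))
    tbl$species_gene_id <- NULL
    num <- setdiff(names(tbl), "reference_gene_id")
    names(tbl)[match(num, names(tbl))] <- paste(sp, num, sep = ".")
    joined <- if (is.null(joined)) tbl else {
      if (complete_cases) {
        dplyr::inner_join(joined, tbl, by = "reference_gene_id")
      } else {
        dplyr::full_join(joined, tbl, by = "reference_gene_id")
      }
    }
  }
  dplyr::rename(joined, gene_id = "reference_gene_id")
}

#' Cluster species by global expression profile
#'
#' Computes the Spearman rank correlation between species' expression
#' profiles (per-species replicate means by default), turns it into the
#' dissimilarity `d = 1 - rho`, and clusters agglomeratively with the
#' classic Ward criterion applied to that dissimilarity matrix as given
#' (`hclust` method `"ward.D"`, the legacy behavior of the `"Ward"`
#' option; `"ward.D2"` is available for the squared-distance variant).
#' Being rank-based, the result is invariant to any monotone transform of
#' the expression values. Pairwise least-squares R-squared values of the
#' mean profiles are returned alongside for heatmap display.
#'
#' @param table Ortholog-joined expression tibble ([ortholog_join()]
#'   output: `gene_id` plus `species.sample` columns) with complete cases
#'   only.
#' @param species_means Average replicates within species before
#'   correlating (default), or use concatenated replicate columns.
#' @param linkage `"ward.D"` (default) or `"ward.D2"`.
#' @return Object of class `expr_clust`: `hclust` (the dendrogram),
#'   `dissimilarity` (matrix `1 - rho`), `spearman_rho`, `r_squared`
#'   (pairwise R^2 of mean profiles), `species`.
#' @export
expression_cluster <- function(table, species_means = TRUE,
                               linkage = c("ward.D", "ward.D2")) {
  linkage <- match.arg(linkage)
  num <- setdiff(names(table), "gene_id")
  sp <- sub("\\..*$", "", num)
  species <- unique(sp)
  if (length(species) < 2) stop("need >= 2 species", call. = FALSE)

  means <- vapply(species, function(s) {
    rowMeans(as.matrix(table[, num[sp == s], drop = FALSE]))
  }, numeric(nrow(table)))
  const <- apply(means, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("constant expression profile (correlation undefined) for: ",
         paste(species[const], collapse = ", "), call. = FALSE)
  }

  profiles <- if (species_means) means else {
    ## concatenated replicates: stack each species' replicate columns into
    ## one long vector (requires equal replicate counts across species)
    reps <- table(sp)
    if (length(unique(reps)) != 1) {
      stop("concatenated-replicate mode needs equal replicate counts; ",
           "use species_means = TRUE", call. = FALSE)
    }
    vapply(species, function(s) {
      as.vector(as.matrix(table[, num[sp == s], drop = FALSE]))
    }, numeric(nrow(table) * reps[1]))
  }
  rho <- stats::cor(profiles, method = "spearman")
  d <- 1 - rho
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  r2 <- stats::cor(means)^2
  structure(
    list(hclust = hc, dissimilarity = d, spearman_rho = rho,
         r_squared = r2, species = species, linkage = linkage),
    class = "expr_clust"
  )
}

#' @export
print.expr_clust <- function(x, ...) {
  cat(sprintf("<expr_clust> %d species, %s linkage on 1 - Spearman rho\n",
              length(x$species), x$linkage))
  print(x$hclust$merge)
  invisible(x)
}

#' Consensus differential-expression call across pairwise comparisons
#'
#' A gene is called differentially expressed in the focal species relative
#' to a species set when (a) its adjusted p-value is at or below `alpha` in
#' *every* pairwise comparison against the set, and (b) an ortholog
#' assignment exists for that gene in every species of the set — a gene
#' with a missing assignment in any set member is not considered,
#' regardless of its p-values. The call direction is the sign of the log2
#' fold change; genes whose direction disagrees across comparisons are
#' retained but flagged.
#'
#' @param records Named list (one element per non-focal species) of tibbles
#'   with columns `gene_id` (reference ids), `log2fc`, `padj`.
#' @param map Ortholog map tibble (see [ortholog_join()]).
#' @param species_set Character vector of the species that must all carry
#'   an ortholog (typically the focal species plus the comparison set).
#' @param alpha Significance threshold on `padj`, default 0.05.
#' @param universe Optional explicit gene universe; defaults to all
#'   reference genes with orthologs in every `species_set` member.
#' @return Object of class `de_set`: tibble `gene_id`, `direction`
#'   (+1/-1), `direction_conflict`, with attributes `universe` and
#'   `alpha`.
#' @export
consensus_de <- function(records, map, species_set, alpha = 0.05,
                         universe = NULL) {
  stopifnot(is.list(records), length(records) >= 1, !is.null(names(records)))
  ## genes with an ortholog in every species of the set
  with_orth <- purrr::map(species_set, function(sp) {
    map$reference_gene_id[map$species == sp]
  })
  eligible <- Reduce(intersect, with_orth)
  universe <- universe %||% eligible

  tested <- purrr::map(records, function(r) r$gene_id[!is.na(r$padj)])
  in_any <- Reduce(union, tested)
  in_all <- Reduce(intersect, tested)
  partial <- intersect(setdiff(in_any, in_all), eligible)
  if (length(partial)) {
    stop("gene(s) tested in some pairwise comparisons but missing padj in ",
         "others despite full ortholog coverage: ",
         paste(utils::head(partial, 5), collapse = ", "), call. = FALSE)
  }

  sig <- purrr::map(records, function(r) {
    r$gene_id[!is.na(r$padj) & r$padj <= alpha]
  })
  called <- intersect(Reduce(intersect, sig), eligible)

  dirs <- purrr::map_dfr(records, function(r) {
    r[r$gene_id %in% called, c("gene_id", "log2fc")]
  }) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      direction = sign(.data$log2fc[1]),
      direction_conflict = length(unique(sign(.data$log2fc))) > 1,
      .groups = "drop"
    )
  out <- dirs[match(called, dirs$gene_id), ]
  class(out) <- c("de_set", class(out))
  attr(out, "universe") <- universe
  attr(out, "alpha") <- alpha
  out
}

#' Permutation test for the overlap of two gene sets
#'
#' Draws `|setA|` genes uniformly without replacement from the universe,
#' counts the overlap with set B, and repeats `n_perm` times; the p-value
#' uses the add-one estimator `(1 + #(null >= observed)) / (n_perm + 1)`,
#' which can bound but never reach zero — an overlap larger than every
#' permutation reports `p < 1/(n_perm)` territory rather than an exact
#' zero. The analytic reference for this null is the hypergeometric tail.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of
#'   `universe`); a `de_set` is accepted and its `gene_id` column used.
#' @param universe Character vector of all candidate genes.
#' @param n_perm Number of permutation draws, default 10000.
#' @param seed Integer seed; fixed seed gives identical results.
#' @return One-row tibble of class `overlap_test`: `observed_overlap`,
#'   `p_value`, `null_mean`, `null_sd`, `n_perm`, `universe_size`,
#'   `size_a`, `size_b`.
#' @export
overlap_permutation <- function(set_a, set_b, universe, n_perm = 10000,
                                seed = 1) {
  if (inherits(set_a, "de_set")) set_a <- set_a$gene_id
  if (inherits(set_b, "de_set")) set_b <- set_b$gene_id
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(set_a) > length(universe)) {
    stop("|set_a| exceeds the universe size", call. = FALSE)
  }
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  observed <- length(intersect(set_a, set_b))
  in_b <- universe %in% set_b
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(in_b[sample.int(length(universe), length(set_a))])
    }, integer(1))
  })
  out <- tibble::tibble(
    observed_overlap = observed,
    p_value = (1 + sum(null >= observed)) / (n_perm + 1),
    null_mean = mean(null), null_sd = stats::sd(null),
    n_perm = as.integer(n_perm),
    universe_size = length(universe),
    size_a = length(set_a), size_b = length(set_b)
  )
  class(out) <- c("overlap_test", class(out))
  out
}

#' Cross-species table of socialization-driven expression changes
#'
#' Builds the per-gene matrix of log2 fold changes between socially reared
#' and socially naive flies across species, masked to significant entries
#' (`padj <= alpha`; non-significant entries are `NA`), together with the
#' count of species in which each gene responds. Helper filters implement
#' the inclusion criteria used to shortlist conserved responses: a gene is
#' kept if it is significantly altered in (1) both of two core species,
#' (2) a prior-study flag plus either core species, or (3) at least
#' `min_species` of the assayed species.
#'
#' @param records Named list (one element per species) of tibbles
#'   `gene_id`, `log2fc`, `padj` for the socialized-vs-naive comparison.
#' @param alpha Significance threshold, default 0.05.
#' @return Tibble of class `socialization_response`: `gene_id`, one
#'   `lfc_<species>` column per species (NA where not significant),
#'   `n_species_significant`.
#' @export
socialization_response_table <- function(records, alpha = 0.05) {
  stopifnot(is.list(records), length(records) >= 2, !is.null(names(records)))
  genes <- sort(unique(unlist(purrr::map(records, "gene_id"))))
  out <- tibble::tibble(gene_id = genes)
  for (sp in names(records)) {
    r <- records[[sp]]
    lfc <- r$log2fc[match(genes, r$gene_id)]
    padj <- r$padj[match(genes, r$gene_id)]
    lfc[is.na(padj) | padj > alpha] <- NA_real_
    out[[paste0("lfc_", sp)]] <- lfc
  }
  sig <- as.matrix(!is.na(out[, paste0("lfc_", names(records))]))
  out$n_species_significant <- unname(rowSums(sig))
  class(out) <- c("socialization_response", class(out))
  attr(out, "species") <- names(records)
  attr(out, "alpha") <- alpha
  out
}

#' Shortlist conserved socialization responses
#'
#' Filters a [socialization_response_table()] to genes satisfying at least
#' one inclusion criterion: (1) significant in both `core_species`; (2)
#' flagged in a supplied external comparison *and* significant in either
#' core species; (3) significant in at least `min_species` species.
#'
#' @param tbl A `socialization_response` tibble.
#' @param core_species Length-2 character vector of the core species.
#' @param external_flags Optional character vector of gene ids flagged by a
#'   prior study (criterion 2); `NULL` disables that criterion.
#' @param min_species Minimum species count for criterion 3, default 3.
#' @return The filtered tibble with a `criteria` list-column naming which
#'   criteria each gene met.
#' @export
filter_shared_response <- function(tbl, core_species,
                                   external_flags = NULL, min_species = 3) {
  stopifnot(length(core_species) == 2)
  cols <- paste0("lfc_", core_species)
  stopifnot(all(cols %in% names(tbl)))
  sig_core <- !is.na(tbl[[cols[1]]]) | !is.na(tbl[[cols[2]]])
  c1 <- !is.na(tbl[[cols[1]]]) & !is.na(tbl[[cols[2]]])
  c2 <- if (is.null(external_flags)) rep(FALSE, nrow(tbl)) else {
    tbl$gene_id %in% external_flags & sig_core
  }
  c3 <- tbl$n_species_significant >= min_species
  keep <- c1 | c2 | c3
  out <- tbl[keep, ]
  out$criteria <- purrr::pmap(list(c1[keep], c2[keep], c3[keep]),
                              function(a, b, c) {
                                c("both_core", "external_plus_core",
                                  "min_species")[c(a, b, c)]
                              })
  out
}
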