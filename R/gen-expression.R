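#' Generate multi-species orthologous expression data with planted structure
#'
#' Simulates head-transcriptome-like expression tables for several species
#' whose between-species correlation follows a planted block structure
#' (species in the same block share a latent gene-effect component at
#' correlation `within_block_rho`), together with planted differentially
#' expressed (DE) gene sets between a "social" and a "naive" rearing
#' condition, and a FlyBase-style ortholog map with configurable per-species
#' dropout. Everything a downstream stage estimates — the block tree, the
#' planted DE sets and their cross-species overlap — is recorded in the
#' `truth` element for parameter-recovery tests.
#'
#' Per gene g and species s the log2 mean is
#' `mu_g + sqrt(rho) * z_block + sqrt(1 - rho) * z_species`, so species in
#' one block are exchangeable draws around a common profile; replicate
#' values add log-normal measurement noise. DE genes shift the naive
#' condition by `lfc_scale` log2 units with a random (but cross-species
#' consistent, for the shared pool) sign.
#'
#' @param n_genes Number of reference genes.
#' @param blocks Named list of character vectors: the planted grouping of
#'   species into correlation blocks; every species appears exactly once.
#' @param within_block_rho Latent-effect correlation within a block, `[0,1]`.
#' @param n_replicates Biological replicates per species and condition.
#' @param de_fraction Fraction of genes planted as DE per species.
#' @param shared_de_fraction Fraction of each species' DE set drawn from a
#'   pool common to all species (controls the planted cross-species overlap).
#' @param lfc_scale Absolute planted log2 fold change of DE genes.
#' @param rep_noise_sd Log2-scale replicate noise standard deviation.
#' @param dropout Fraction of genes, per non-reference species, dropped from
#'   the ortholog map (exercises the missing-ortholog exclusion rule).
#' @param reference_species Species whose gene ids key the ortholog map;
#'   defaults to the first species listed.
#' @param seed Integer seed.
#' @return A list of class `expression_sim`: `tables` (named list of
#'   RPKM-unit expression tibbles keyed by species gene ids), `ortholog_map`
#'   (tibble `reference_gene_id`, `species`, `species_gene_id`),
#'   `de_records` (named list of per-species social-vs-naive DE tibbles with
#'   `gene_id`, `log2fc`, `padj`), and `truth` (planted DE sets, block
#'   structure, pairwise DE-set overlaps).
#' @export
gen_expression <- function(n_genes, blocks, within_block_rho = 0.9,
                           n_replicates = 3, de_fraction = 0.05,
                           shared_de_fraction = 0.5, lfc_scale = 2,
                           rep_noise_sd = 0.25, dropout = 0,
                           reference_species = NULL, seed = 1) {
  species <- unlist(blocks, use.names = FALSE)
  stopifnot(n_genes >= 2, length(species) >= 1, !anyDuplicated(species),
            within_block_rho >= 0, within_block_rho <= 1,
            de_fraction >= 0, de_fraction <= 1, lfc_scale >= 0,
            dropout >= 0, dropout < 1, n_replicates >= 1)
  if (de_fraction > 0 && de_fraction * n_genes < 1) {
    stop("`de_fraction` too small: de_fraction * n_genes must be >= 1",
         call. = FALSE)
  }
  reference_species <- reference_species %||% species[1]
  stopifnot(reference_species %in% species)

  with_seed(seed, {
    ref_ids <- sprintf("FBgn%07d", seq_len(n_genes))
    mu <- stats::rnorm(n_genes, mean = 6, sd = 2)
    rho <- within_block_rho

    block_of <- rep(names(blocks) %||% as.character(seq_along(blocks)),
                    lengths(blocks))
    names(block_of) <- species
    z_block <- matrix(stats::rnorm(n_genes * length(blocks)), ncol = length(blocks),
                      dimnames = list(NULL, unique(block_of)))

    n_de <- round(de_fraction * n_genes)
    n_shared <- round(shared_de_fraction * n_de)
    shared_pool <- if (n_de > 0) sample(ref_ids, max(n_shared, 0)) else character(0)
    shared_sign <- stats::setNames(sample(c(-1, 1), length(shared_pool), TRUE),
                                   shared_pool)

    tables <- list(); de_sets <- list(); de_records <- list()
    map_rows <- list()
    for (sp in species) {
      z_sp <- stats::rnorm(n_genes)
      l2 <- mu + sqrt(rho) * z_block[, block_of[[sp]]] + sqrt(1 - rho) * z_sp

      if (n_de > 0) {
        own <- sample(setdiff(ref_ids, shared_pool), n_de - length(shared_pool))
        de <- c(shared_pool, own)
        sgn <- c(shared_sign[shared_pool],
                 stats::setNames(sample(c(-1, 1), length(own), TRUE), own))
      } else {
        de <- character(0); sgn <- numeric(0)
      }
      de_sets[[sp]] <- de

      lfc <- stats::setNames(rep(0, n_genes), ref_ids)
      lfc[de] <- sgn[de] * lfc_scale

      sp_ids <- sprintf("%s_g%06d", sp, seq_len(n_genes))
      samples <- list(gene_id = sp_ids)
      for (cond in c("social", "naive")) {
        shift <- if (cond == "naive") lfc else rep(0, n_genes)
        for (r in seq_len(n_replicates)) {
          eps <- if (rep_noise_sd > 0) stats::rnorm(n_genes, 0, rep_noise_sd) else 0
          samples[[sprintf("%s_rep%d", cond, r)]] <- 2^(l2 + shift + eps)
        }
      }
      tbl <- tibble::as_tibble(samples)
      attr(tbl, "unit_tag") <- "RPKM"
      tables[[sp]] <- tbl

      keep <- rep(TRUE, n_genes)
      if (dropout > 0 && sp != reference_species) {
        keep[sample.int(n_genes, round(dropout * n_genes))] <- FALSE
      }
      map_rows[[sp]] <- tibble::tibble(
        reference_gene_id = ref_ids[keep], species = sp,
        species_gene_id = sp_ids[keep]
      )

      is_de <- ref_ids %in% de
      de_records[[sp]] <- tibble::tibble(
        gene_id = ref_ids,
        log2fc = lfc + stats::rnorm(n_genes, 0, 0.05),
        padj = ifelse(is_de, stats::runif(n_genes, 0, 0.01),
                      stats::runif(n_genes, 0.051, 1))
      )
    }

    overlaps <- NULL
    if (length(species) >= 2) {
      prs <- utils::combn(species, 2)
      overlaps <- tibble::tibble(
        species_a = prs[1, ], species_b = prs[2, ],
        overlap = purrr::map2_int(prs[1, ], prs[2, ], function(a, b) {
          length(intersect(de_sets[[a]], de_sets[[b]]))
        })
      )
    }

    structure(
      list(
        tables = tables,
        ortholog_map = dplyr::bind_rows(map_rows),
        de_records = de_records,
        truth = list(
          reference_gene_ids = ref_ids, de_sets = de_sets,
          shared_pool = shared_pool, blocks = blocks,
          block_of = block_of, within_block_rho = rho,
          pairwise_overlap = overlaps
        ),
        params = list(n_genes = n_genes, n_replicates = n_replicates,
                      de_fraction = de_fraction, lfc_scale = lfc_scale,
                      dropout = dropout, reference_species = reference_species,
                      seed = as.integer(seed))
      ),
      class = "expression_sim"
    )
  })
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf(
    "<expression_sim> %d genes x %d species, %d planted DE genes/species\n",
    x$params$n_genes, length(x$tables),
    length(x$truth$de_sets[[1]])
  ))
  invisible(x)
}
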