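test_that("TPM renormalization scales every sample to one million", {
  out <- rpkm_to_tpm(data.frame(gene_id = c("a", "b", "c"), s1 = c(1, 1, 2)))
  expect_equal(out$s1, c(250000, 250000, 500000))
  expect_equal(rpkm_to_tpm(data.frame(gene_id = "a", s1 = 5))$s1, 1e6)

  set.seed(1)
  tbl <- data.frame(gene_id = sprintf("g%d", 1:50),
                    s1 = rexp(50), s2 = rexp(50) * 100)
  tpm <- rpkm_to_tpm(tbl)
  expect_equal(sum(tpm$s1), 1e6, tolerance = 1e-6)
  expect_equal(sum(tpm$s2), 1e6, tolerance = 1e-6)
  expect_equal(attr(tpm, "unit_tag"), "TPM")
  expect_equal(tpm$gene_id, tbl$gene_id)  # gene order preserved

  bad <- data.frame(gene_id = "a", s1 = 0)
  expect_error(rpkm_to_tpm(bad), "s1")
})

test_that("ortholog join keeps complete cases and flags bad maps", {
  blocks <- list(b1 = c("spA", "spB"), b2 = "spC")
  sim <- gen_expression(100, blocks, dropout = 0.1, de_fraction = 0, seed = 4)
  joined <- ortholog_join(sim$tables, sim$ortholog_map, "spA")

  ## brute-force set intersection over the map
  m <- sim$ortholog_map
  expected <- Reduce(intersect, lapply(c("spA", "spB", "spC"), function(s) {
    m$reference_gene_id[m$species == s]
  }))
  expect_setequal(joined$gene_id, expected)

  full <- gen_expression(50, blocks, dropout = 0, de_fraction = 0, seed = 5)
  j2 <- ortholog_join(full$tables, full$ortholog_map, "spA")
  expect_equal(nrow(j2), 50)

  dup <- rbind(sim$ortholog_map, sim$ortholog_map[1, ])
  expect_error(ortholog_join(sim$tables, dup, "spA"), "duplicate")
  expect_error(ortholog_join(sim$tables, sim$ortholog_map, "nope"),
               "reference species")
})

test_that("expression clustering: extremes, invariances and errors", {
  mk <- function(...) {
    vals <- list(...)
    tbl <- tibble::tibble(gene_id = sprintf("g%d", seq_along(vals[[1]])))
    for (nm in names(vals)) tbl[[nm]] <- vals[[nm]]
    tbl
  }
  ## identical ranking -> d = 0 and first merge; anti-ranked pair -> d = 2
  x <- c(1, 5, 2, 9, 4, 7, 3, 8, 6, 10)
  tbl <- mk("spA.s1" = x, "spB.s1" = x * 3 + 1, "spC.s1" = 11 - x)
  cl <- expression_cluster(tbl)
  expect_equal(cl$dissimilarity["spA", "spB"], 0)
  expect_equal(cl$dissimilarity["spA", "spC"], 2)
  expect_setequal(abs(cl$hclust$merge[1, ]),
                  abs(which(cl$species %in% c("spA", "spB"))))

  ## rank-based: invariant to monotone transforms and to gene order
  cl_log <- expression_cluster(mk("spA.s1" = log1p(x),
                                  "spB.s1" = (x * 3 + 1)^2,
                                  "spC.s1" = 11 - x))
  expect_equal(cl_log$dissimilarity, cl$dissimilarity)
  perm <- sample(seq_along(x))
  cl_perm <- expression_cluster(tbl[perm, ])
  expect_equal(cl_perm$dissimilarity, cl$dissimilarity)

  ## heights are non-decreasing along merges
  expect_true(all(diff(cl$hclust$height) >= -1e-12))

  expect_error(
    expression_cluster(mk("spA.s1" = rep(1, 10), "spB.s1" = x)), "spA")
  expect_error(expression_cluster(tbl[, 1:2]), ">= 2 species")
})

test_that("planted two-block structure is recovered by the dendrogram", {
  blocks <- list(inner = c("spA", "spB"), outer = "spC")
  hits <- 0L
  for (seed in 1:100) {
    sim <- gen_expression(150, blocks, within_block_rho = 0.9,
                          de_fraction = 0, seed = seed)
    tpm <- lapply(sim$tables, rpkm_to_tpm)
    joined <- ortholog_join(tpm, sim$ortholog_map, "spA")
    cl <- expression_cluster(joined)
    first <- sort(cl$species[-cl$hclust$merge[1, ]])
    if (identical(first, c("spA", "spB"))) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("consensus DE requires significance in all pairs and full ortholog coverage", {
  map <- tibble::tibble(
    reference_gene_id = c("g1", "g2", "g3", "g1", "g2", "g3", "g1", "g3"),
    species = c(rep("mel", 3), rep("sim", 3), rep("yak", 2)),
    species_gene_id = paste0("x", 1:8)
  )
  rec <- function(p1, p2, p3, lfc = c(1, 1, 1)) {
    tibble::tibble(gene_id = c("g1", "g2", "g3"), log2fc = lfc,
                   padj = c(p1, p2, p3))
  }
  records <- list(sim = rec(0.01, 0.01, 0.04), yak = rec(0.03, 0.01, 0.03))
  out <- consensus_de(records, map, species_set = c("mel", "sim", "yak"))
  ## g2 has no yak ortholog, so only g1 and g3 are considered
  expect_setequal(out$gene_id, c("g1", "g3"))

  ## one padj above alpha excludes the gene
  records2 <- list(sim = rec(0.01, 0.01, 0.06), yak = rec(0.03, 0.01, 0.03))
  out2 <- consensus_de(records2, map, species_set = c("mel", "sim", "yak"))
  expect_equal(out2$gene_id, "g1")

  ## direction conflicts are flagged, not dropped
  records3 <- list(sim = rec(0.01, 0.5, 0.01, lfc = c(2, 0, -1)),
                   yak = rec(0.01, 0.5, 0.01, lfc = c(2, 0, 1)))
  out3 <- consensus_de(records3, map, species_set = c("mel", "sim", "yak"))
  g3 <- out3[out3$gene_id == "g3", ]
  expect_true(g3$direction_conflict)
  expect_false(out3$direction_conflict[out3$gene_id == "g1"])

  ## monotone in alpha: raising alpha never removes a gene
  loose <- consensus_de(records2, map, species_set = c("mel", "sim", "yak"),
                        alpha = 0.1)
  expect_true(all(out2$gene_id %in% loose$gene_id))

  ## tested-in-some-pairs-only with full coverage is a data-integrity error
  records4 <- list(sim = rec(0.01, 0.01, 0.04),
                   yak = tibble::tibble(gene_id = c("g1", "g3"),
                                        log2fc = c(1, 1),
                                        padj = c(0.01, NA)))
  expect_error(consensus_de(records4, map,
                            species_set = c("mel", "sim")), "missing padj")
})

test_that("overlap permutation matches the hypergeometric tail", {
  universe <- sprintf("g%d", 1:10)
  a <- universe[1:3]
  res <- overlap_permutation(a, a, universe, n_perm = 10000, seed = 1)
  expect_equal(res$observed_overlap, 3)
  p_exact <- 1 / choose(10, 3)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 2 / 10001)

  ## disjoint halves: overlap 0 is certain to be matched or beaten
  u6 <- sprintf("g%d", 1:6)
  res0 <- overlap_permutation(u6[1:3], u6[4:6], u6, n_perm = 500, seed = 2)
  expect_equal(res0$observed_overlap, 0)
  expect_equal(res0$p_value, 1)

  expect_error(overlap_permutation(sprintf("g%d", 1:11), a, universe),
               "universe")
  ## determinism
  r1 <- overlap_permutation(a, universe[2:5], universe, n_perm = 200, seed = 3)
  r2 <- overlap_permutation(a, universe[2:5], universe, n_perm = 200, seed = 3)
  expect_identical(r1, r2)
})

test_that("socialization response table counts species and filters criteria", {
  rec <- function(genes, lfc, padj) {
    tibble::tibble(gene_id = genes, log2fc = lfc, padj = padj)
  }
  g <- c("g1", "g2", "g3", "g4")
  records <- list(
    mel = rec(g, c(-2, 1, 0.5, 0.1), c(0.01, 0.01, 0.2, 0.8)),
    ere = rec(g, c(-1, 2, 0.5, 0.2), c(0.04, 0.2, 0.01, 0.9)),
    sim = rec(g, c(-1, 1, 0.5, 0.3), c(0.01, 0.01, 0.01, 0.9)),
    yak = rec(g, c(-2, 1, 0.5, 0.4), c(0.01, 0.2, 0.2, 0.9))
  )
  tbl <- socialization_response_table(records)
  expect_equal(tbl$n_species_significant,
               c(4, 2, 2, 0)[match(tbl$gene_id, g)])
  ## non-significant entries are masked
  expect_true(is.na(tbl$lfc_ere[tbl$gene_id == "g2"]))
  expect_equal(tbl$lfc_mel[tbl$gene_id == "g1"], -2)

  ## criterion 1 (both core), criterion 3 (>= 3 species)
  kept <- filter_shared_response(tbl, core_species = c("mel", "ere"))
  expect_true("g1" %in% kept$gene_id)     # all 4 species
  expect_false("g2" %in% kept$gene_id)    # mel+sim only, not both core
  expect_false("g4" %in% kept$gene_id)
  ## criterion 2: external flag plus either core species
  kept2 <- filter_shared_response(tbl, core_species = c("mel", "ere"),
                                  external_flags = "g2")
  expect_true("g2" %in% kept2$gene_id)
})

test_that("planted DE inputs reproduce generator sharing counts", {
  blocks <- list(b = c("m", "e", "s", "y"))
  sim <- gen_expression(200, blocks, de_fraction = 0.1,
                        shared_de_fraction = 0.6, seed = 6)
  tbl <- socialization_response_table(sim$de_records)
  truth_counts <- vapply(tbl$gene_id, function(g) {
    sum(vapply(sim$truth$de_sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  expect_equal(tbl$n_species_significant, unname(truth_counts))
})
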