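#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cooperativity fit
#'
#' One row per regression term, broom-style.
#'
#' @param x A `coop_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std_error`, `p_value`.
#' @method tidy coop_fit
#' @export
tidy.coop_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = c("intercept", "density"),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    p_value = if (ncol(sm) >= 4) unname(sm[, 4]) else NA_real_
  )
}

#' One-row summary of a cooperativity fit
#'
#' @param x A `coop_fit`.
#' @param ... Unused.
#' @return Tibble `slope` (the cooperativity coefficient, min/fly),
#'   `intercept`, `r_squared`, `n_densities`.
#' @method glance coop_fit
#' @export
glance.coop_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared,
                 n_densities = length(x$densities_used))
}

#' Per-agent arrival table of a search simulation
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return Tibble `agent`, `arrival_tick` (`NA` if never arrived),
#'   `arrived`.
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) {
  tibble::tibble(agent = seq_along(x$arrival_ticks),
                 arrival_tick = x$arrival_ticks,
                 arrived = !is.na(x$arrival_ticks))
}

#' One-row summary of a search simulation
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return Tibble `n_flies`, `n_arrived`, `t40_ticks`, `cooperativity`,
#'   `max_ticks`.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(n_flies = x$params$n_flies,
                 n_arrived = sum(!is.na(x$arrival_ticks)),
                 t40_ticks = x$t40_ticks,
                 cooperativity = x$params$cooperativity,
                 max_ticks = x$params$max_ticks)
}

#' Merge table of an expression dendrogram
#'
#' @param x An `expr_clust`.
#' @param ... Unused.
#' @return Tibble `step`, `cluster_a`, `cluster_b`, `height`; negative
#'   entries index species, positive entries earlier merges (the `hclust`
#'   convention, with species named where applicable).
#' @method tidy expr_clust
#' @export
tidy.expr_clust <- function(x, ...) {
  lab <- function(i) {
    vapply(i, function(k) {
      if (k < 0) x$hclust$labels[-k] else paste0("merge_", k)
    }, character(1))
  }
  tibble::tibble(
    step = seq_len(nrow(x$hclust$merge)),
    cluster_a = lab(x$hclust$merge[, 1]),
    cluster_b = lab(x$hclust$merge[, 2]),
    height = x$hclust$height
  )
}

#' One-row summary of an expression clustering
#'
#' @param x An `expr_clust`.
#' @param ... Unused.
#' @return Tibble `n_species`, `linkage`, `min_rho`, `max_rho`.
#' @method glance expr_clust
#' @export
glance.expr_clust <- function(x, ...) {
  off <- x$spearman_rho[upper.tri(x$spearman_rho)]
  tibble::tibble(n_species = length(x$species), linkage = x$linkage,
                 min_rho = min(off), max_rho = max(off))
}

#' One-row summary of a consensus DE set
#'
#' @param x A `de_set`.
#' @param ... Unused.
#' @return Tibble `n_genes`, `n_up`, `n_down`, `n_conflict`,
#'   `universe_size`, `alpha`.
#' @method glance de_set
#' @export
glance.de_set <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(x$direction > 0), n_down = sum(x$direction < 0),
    n_conflict = sum(x$direction_conflict),
    universe_size = length(attr(x, "universe")),
    alpha = attr(x, "alpha")
  )
}
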