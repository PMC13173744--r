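#' Decompose a circulating DNA concentration into tumor and non-tumor parts
#'
#' Exact identity split of a total concentration by tumor fraction:
#' `tumor = total * tf`, `nontumor = total - tumor`. Works on a data frame
#' (tidy-eval columns) so it pipes on per-sample metadata.
#'
#' @param data Tibble of per-sample measurements.
#' @param total Column holding the total concentration (ng/mL).
#' @param tf Column holding the tumor fraction in `[0, 1]`.
#' @param prefix Prefix for the added columns.
#' @return `data` with `<prefix>_tumor` and `<prefix>_nontumor` columns.
#' @examples
#' tibble::tibble(cfdna = 100, tf = 0.3) |>
#'   decompose_concentration(cfdna, tf, prefix = "cfdna")
#' @export
decompose_concentration <- function(data, total, tf, prefix = "conc") {
  tot <- dplyr::pull(data, {{ total }})
  tfv <- dplyr::pull(data, {{ tf }})
  if (any(tfv < 0 | tfv > 1, na.rm = TRUE)) {
    abort("tumor fractions must lie in [0, 1]")
  }
  if (any(tot < 0, na.rm = TRUE)) abort("totals must be non-negative")
  data[[paste0(prefix, "_tumor")]] <- tot * tfv
  data[[paste0(prefix, "_nontumor")]] <- tot - tot * tfv
  data
}

#' Naive coverage-ratio tumor-fraction estimator
#'
#' A deliberately simple analytic estimator for synthetic end-to-end tests
#' (real-data tumor fractions are consumed as inputs from a dedicated CNA
#' caller). On a toy genome with known segment copy states and genome-wide
#' mean copy 2, the expected per-bp coverage of a segment with tumor copy
#' `c` relative to neutral segments is `(2 + tf * (c - 2)) / 2`, so a
#' single-copy gain gives `tf = 2 * (r - 1)` and a single-copy loss
#' `tf = 2 * (1 - r)`. Estimates from all altered segments are averaged.
#'
#' @param fragments Fragment tibble (`sample_id`, `chrom`).
#' @param genome Toy genome tibble with `chrom`, `length`, `copy_state`.
#' @return Tibble with `sample_id`, `tf_hat` (`NA` if the genome has no
#'   altered or no neutral segments).
#' @export
naive_tf_estimate <- function(fragments, genome) {
  if (!all(fragments$chrom %in% genome$chrom)) {
    abort("fragments reference contigs absent from the toy genome")
  }
  fragments |>
    group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      cov <- df |>
        count(.data$chrom) |>
        left_join(genome, by = "chrom") |>
        mutate(density = .data$n / .data$length)
      cov <- tidyr::complete(cov, chrom = genome$chrom,
                             fill = list(n = 0L)) |>
        mutate(length = genome$length[match(.data$chrom, genome$chrom)],
               copy_state = genome$copy_state[match(.data$chrom, genome$chrom)],
               density = .data$n / .data$length)
      neutral <- filter(cov, .data$copy_state == 2L)
      altered <- filter(cov, .data$copy_state != 2L)
      if (nrow(altered) == 0 || nrow(neutral) == 0) {
        return(tibble(sample_id = key$sample_id, tf_hat = NA_real_))
      }
      d0 <- sum(neutral$n) / sum(neutral$length)
      est <- 2 * (altered$density / d0 - 1) / (altered$copy_state - 2)
      tibble(sample_id = key$sample_id, tf_hat = mean(est))
    }) |>
    list_rbind()
}

#' Fragment-length-stratified tumor-fraction enrichment
#'
#' Fold enrichment of the tumor fraction measured in short fragments
#' (75-145 bp) over the one measured in mononucleosome-sized fragments
#' (75-200 bp): `fold = tf_short / tf_mono`. Values near 1 mean tumor- and
#' blood-derived DNA are similarly fragmented; folds > 1 indicate
#' tumor-specific shortening.
#'
#' @param tf_short,tf_mono Tumor fractions in `[0, 1]` (vectorized);
#'   `tf_mono` must be positive for a defined fold.
#' @return Numeric fold vector; `NA` where `tf_mono` is 0.
#' @export
length_stratified_tf_enrichment <- function(tf_short, tf_mono) {
  if (any(c(tf_short, tf_mono) < 0, na.rm = TRUE) ||
      any(c(tf_short, tf_mono) > 1, na.rm = TRUE)) {
    abort("tumor fractions must lie in [0, 1]")
  }
  ifelse(tf_mono > 0, tf_short / tf_mono, NA_real_)
}

#' Hierarchical feature clustering on Spearman distance
#'
#' Pairwise Spearman correlation over samples between per-sample features
#' (pairwise-complete observations), distance `1 - rho`, agglomerative
#' clustering, and a cut into `n_clusters` groups. Constant features have no
#' defined rank correlation and are masked out with a warning.
#'
#' @param features Tibble: `sample_id` plus numeric feature columns.
#' @param n_clusters Number of clusters for the tree cut.
#' @param linkage Agglomeration method (default `"average"`).
#' @return Object of class `feature_clustering`: `rho` (correlation matrix),
#'   `tree` (hclust), `clusters` (named integer vector), `linkage`.
#' @export
feature_cluster <- function(features, n_clusters = 2, linkage = "average") {
  x <- select(features, -dplyr::any_of("sample_id"))
  if (ncol(x) < 3) abort("need at least 3 features")
  if (nrow(x) < 5) abort("need at least 5 samples")
  constant <- vapply(x, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) <= 1
  }, logical(1))
  if (any(constant)) {
    warn(paste("masking constant feature(s):",
               paste(names(x)[constant], collapse = ", ")))
    x <- x[!constant]
  }
  rho <- cor(as.matrix(x), method = "spearman",
             use = "pairwise.complete.obs")
  tree <- hclust(as.dist(1 - rho), method = linkage)
  clusters <- cutree(tree, k = min(n_clusters, ncol(x)))
  structure(list(rho = rho, tree = tree, clusters = clusters,
                 linkage = linkage),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("Feature clustering (%s linkage on 1 - Spearman rho): %d features, %d clusters\n",
              x$linkage, ncol(x$rho), length(unique(x$clusters))))
  print(split(names(x$clusters), x$clusters))
  invisible(x)
}

#' @rdname tidy.feature_clustering
#' @export
glance.feature_clustering <- function(x, ...) {
  tibble(n_features = ncol(x$rho), n_clusters = length(unique(x$clusters)),
         linkage = x$linkage,
         mean_abs_rho = mean(abs(x$rho[upper.tri(x$rho)])))
}

#' Tidy feature-clustering results
#'
#' `tidy()` gives one row per feature with its cluster; `glance()` a one-row
#' summary.
#'
#' @param x A `feature_clustering` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.feature_clustering <- function(x, ...) {
  tibble(feature = names(x$clusters), cluster = unname(x$clusters))
}

#' Export a feature-clustering tree as newick text
#'
#' @param x A `feature_clustering` object.
#' @return Newick string.
#' @export
cluster_newick <- function(x) {
  ape::write.tree(ape::as.phylo(x$tree))
}

#' Heatmap of the feature correlation matrix
#'
#' @param object A `feature_clustering` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_clustering <- function(object, ...) {
  ord <- object$tree$labels[object$tree$order]
  df <- as_tibble(object$rho, rownames = "f1") |>
    tidyr::pivot_longer(-"f1", names_to = "f2", values_to = "rho") |>
    mutate(f1 = factor(.data$f1, levels = ord),
           f2 = factor(.data$f2, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
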