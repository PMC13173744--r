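#' Fragment-length distributions on the log grid
#'
#' Bins each sample's fragment lengths onto a [log_bin_grid()] and returns,
#' per bin, the fragment proportion (bin count over total fragments) and the
#' DNA proportion (bin base-pair total over total base pairs). Both vectors
#' sum to 1 per sample. Lengths outside the grid are clamped to the terminal
#' bins.
#'
#' @param fragments Fragment tibble with columns `sample_id` and `length`.
#' @param grid A [log_bin_grid()].
#' @return Long tibble with one row per sample and bin: `sample_id`, `bin`,
#'   `center`, `fragment_proportion`, `dna_proportion`, `n_fragments`,
#'   `total_bp`. Samples with no fragments are absent.
#' @examples
#' frags <- tibble::tibble(sample_id = "s1", length = c(100L, 100L, 200L))
#' p <- length_profile(frags)
#' sum(p$dna_proportion) # 1
#' @export
length_profile <- function(fragments, grid = log_bin_grid()) {
  if (nrow(fragments) == 0) {
    return(tibble(sample_id = character(), bin = integer(), center = numeric(),
                  fragment_proportion = numeric(), dna_proportion = numeric(),
                  n_fragments = integer(), total_bp = numeric()))
  }
  nb <- nrow(grid)
  fragments |>
    mutate(.bin = bin_assign(.data$length, grid)) |>
    group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      counts <- tabulate(df$.bin, nbins = nb)
      bp <- numeric(nb)
      agg <- rowsum(as.numeric(df$length), df$.bin)
      bp[as.integer(rownames(agg))] <- agg[, 1]
      tibble(sample_id = key$sample_id, bin = grid$bin, center = grid$center,
             fragment_proportion = counts / nrow(df),
             dna_proportion = bp / sum(bp),
             n_fragments = nrow(df), total_bp = sum(bp))
    }) |>
    list_rbind()
}

#' Wide sample-by-bin profile matrix
#'
#' @param profiles Long profile tibble from [length_profile()].
#' @param value Which proportion to spread: `"dna_proportion"` (default, the
#'   representation used for PCA classification) or `"fragment_proportion"`.
#' @return Wide tibble: `sample_id` plus one numeric column per bin, named
#'   `x<exponent>`.
#' @export
profile_matrix <- function(profiles, value = c("dna_proportion",
                                               "fragment_proportion")) {
  value <- match.arg(value)
  profiles |>
    mutate(bin_name = sprintf("x%.2f", log10(.data$center)),
           bin_value = .data[[value]]) |>
    select("sample_id", "bin_name", "bin_value") |>
    tidyr::pivot_wider(names_from = "bin_name", values_from = "bin_value",
                       values_fill = 0)
}

profile_bin_centers <- function(profile_tbl) {
  10^as.numeric(sub("^x", "", setdiff(names(profile_tbl), "sample_id")))
}

#' Fraction of DNA in a fragment-length range
#'
#' Base-pair-weighted proportion of each sample's DNA carried by fragments
#' whose raw length lies in the closed interval `[min_bp, max_bp]`. Computed
#' from raw lengths, not from grid bins, so it carries no quantization error.
#'
#' @param fragments Fragment tibble (`sample_id`, `length`).
#' @param min_bp,max_bp Closed interval bounds in bp (`max_bp` may be `Inf`).
#' @return Tibble with `sample_id`, `frac_dna`.
#' @export
frac_dna_in_range <- function(fragments, min_bp, max_bp = Inf) {
  if (min_bp > max_bp) abort("min_bp must not exceed max_bp")
  fragments |>
    group_by(.data$sample_id) |>
    summarise(frac_dna = sum(.data$length[.data$length >= min_bp &
                                            .data$length <= max_bp]) /
                sum(.data$length),
              .groups = "drop")
}

#' Fraction of fragments longer than a threshold
#'
#' Count-based (not base-pair-weighted) proportion of fragments with
#' `length > threshold_bp`, per sample.
#'
#' @param fragments Fragment tibble (`sample_id`, `length`).
#' @param threshold_bp Length threshold in bp (strict).
#' @return Tibble with `sample_id`, `frac_fragments`.
#' @export
frac_fragments_over <- function(fragments, threshold_bp) {
  fragments |>
    group_by(.data$sample_id) |>
    summarise(frac_fragments = mean(.data$length > threshold_bp),
              .groups = "drop")
}

#' Quintile binning of samples by a fragmentation metric
#'
#' Sorts samples ascending by the metric (ties broken by `sample_id`
#' lexicographic order) and splits them into `n_bins` near-equal bins whose
#' sizes differ by at most one (earlier bins take the remainder). With the
#' default metric — fraction of DNA in 900-4,300 bp fragments — bin 1 holds
#' the most hyperfragmented samples and bin `n_bins` the most hypofragmented.
#'
#' @param data Tibble with a `sample_id` column.
#' @param metric Column (tidy-eval) holding the per-sample metric.
#' @param n_bins Number of bins (default 5).
#' @return `data` with an added integer `quintile` column, input order
#'   preserved.
#' @export
quintile_bins <- function(data, metric, n_bins = 5) {
  if (nrow(data) < n_bins) {
    abort(sprintf("need at least %d samples for %d bins", n_bins, n_bins))
  }
  m <- dplyr::pull(data, {{ metric }})
  ord <- order(m, data$sample_id)
  sizes <- rep(nrow(data) %/% n_bins, n_bins) +
    c(rep(1L, nrow(data) %% n_bins), rep(0L, n_bins - nrow(data) %% n_bins))
  q <- integer(nrow(data))
  q[ord] <- rep(seq_len(n_bins), sizes)
  mutate(data, quintile = q)
}
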