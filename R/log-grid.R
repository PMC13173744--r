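#' Logarithmic fragment-length bin grid
#'
#' Builds the fixed log10 grid used for all fragment-length distributions:
#' bin centers at `10^x` for `x` running in exact steps of `log10_step`
#' (default 0.01) between the grid endpoints, which are the multiples of the
#' step nearest to `log10(min_bp)` and `log10(max_bp)`. With the defaults
#' (50 bp to 50,000 bp) the grid has 301 bins spanning exponents 1.70-4.70.
#'
#' @param min_bp,max_bp Grid limits in base pairs. Fragment lengths outside
#'   the limits are clamped to the terminal bins by [bin_assign()].
#' @param log10_step Exponent increment between adjacent bins.
#'
#' @return A tibble of class `log_bin_grid` with one row per bin and columns
#'   `bin` (1-based index), `exponent`, and `center` (bp, `10^exponent`).
#' @examples
#' grid <- log_bin_grid()
#' nrow(grid) # 301
#' @export
log_bin_grid <- function(min_bp = 50, max_bp = 50000, log10_step = 0.01) {
  stopifnot(min_bp > 0, max_bp > min_bp, log10_step > 0)
  # work in integer units of the step so the grid is exact under rounding
  lo <- round(log10(min_bp) / log10_step)
  hi <- round(log10(max_bp) / log10_step)
  ex <- (lo:hi) * log10_step
  out <- tibble(bin = seq_along(ex), exponent = ex, center = 10^ex)
  class(out) <- c("log_bin_grid", class(out))
  attr(out, "log10_step") <- log10_step
  out
}

#' Assign fragment lengths to log-grid bins
#'
#' A length `L` maps to the bin whose exponent is `log10(L)` rounded to the
#' nearest multiple of the grid step; lengths falling outside the grid are
#' clamped to the first or last bin.
#'
#' @param length_bp Integer vector of fragment lengths (bp), all positive.
#' @param grid A [log_bin_grid()].
#' @return Integer vector of bin indices (1-based) into `grid`.
#' @examples
#' grid <- log_bin_grid()
#' bin_assign(100, grid) # exponent 2.00
#' @export
bin_assign <- function(length_bp, grid = log_bin_grid()) {
  if (any(length_bp <= 0) || anyNA(length_bp)) {
    abort("fragment lengths must be positive and non-missing")
  }
  step <- attr(grid, "log10_step")
  lo <- round(grid$exponent[1] / step)
  idx <- round(log10(length_bp) / step) - lo + 1L
  pmin(pmax(as.integer(idx), 1L), nrow(grid))
}
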