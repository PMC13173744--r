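pc_length_windows <- list(
  hypofragmented = list(c(900, 4300)),
  ultralong = list(c(7500, Inf)),
  hyperfragmented = list(c(75, 145), c(245, 295))
)

#' Build a healthy reference from length profiles
#'
#' Per-bin mean and standard deviation of the DNA proportion across a
#' designated reference sample set, used for z-normalization of all
#' profiles. Zero-SD bins are flagged (they get the SD floor during
#' normalization).
#'
#' @param profile_tbl Wide profile tibble from [profile_matrix()].
#' @param reference_ids Sample ids forming the reference; atypical samples
#'   (e.g. unspun aliquots) should be excluded here.
#' @return Tibble of class `healthy_reference` (`bin_name`, `center`,
#'   `mean`, `sd`, `zero_sd`) with attribute `n_reference`.
#' @export
build_reference <- function(profile_tbl, reference_ids) {
  sub <- filter(profile_tbl, .data$sample_id %in% reference_ids)
  if (nrow(sub) < 2) abort("need at least 2 reference samples")
  x <- as.matrix(select(sub, -"sample_id"))
  out <- tibble(bin_name = colnames(x),
                center = 10^as.numeric(sub("^x", "", colnames(x))),
                mean = colMeans(x),
                sd = apply(x, 2, sd))
  out$zero_sd <- out$sd == 0
  class(out) <- c("healthy_reference", class(out))
  attr(out, "n_reference") <- nrow(sub)
  out
}

#' Z-normalize length profiles against a healthy reference
#'
#' Per bin: `z = (value - mean) / max(sd, sd_floor)`. The floor keeps
#' zero-variance bins finite; its default is `1e-6` times the largest bin SD
#' (absolute `1e-6` if all SDs are zero).
#'
#' @param profile_tbl Wide profile tibble ([profile_matrix()]).
#' @param ref A [build_reference()] result on the same grid.
#' @param sd_floor Optional explicit SD floor.
#' @return Wide tibble of z-scores, same shape as `profile_tbl`.
#' @export
znormalize <- function(profile_tbl, ref, sd_floor = NULL) {
  bins <- setdiff(names(profile_tbl), "sample_id")
  if (!identical(bins, ref$bin_name)) {
    abort("profile bins do not match the reference grid")
  }
  sd_floor <- sd_floor %||% max(1e-6 * max(ref$sd), 1e-6)
  x <- as.matrix(profile_tbl[bins])
  z <- sweep(sweep(x, 2, ref$mean), 2, pmax(ref$sd, sd_floor), "/")
  dplyr::bind_cols(profile_tbl["sample_id"], as_tibble(z))
}

#' Fit a PCA of z-normalized fragment-length profiles
#'
#' PCA of the samples-by-bins z-matrix. Because every profile is already
#' expressed as deviation from the healthy reference mean (in reference-SD
#' units), the decomposition is run uncentered: components are directions
#' of departure from the healthy state, and reference samples score near
#' zero on every component. Components are sign-oriented so that the bin
#' with the largest absolute loading has a positive loading — "high" scores
#' then mean an excess of that component's signature lengths.
#'
#' @param z_tbl Wide z-score tibble from [znormalize()].
#' @param n_components Number of components retained (default 3).
#' @return Object of class `frag_pca`: oriented loadings, per-sample scores,
#'   explained variance, bin centers, and the fitted center vector. A
#'   zero-variance matrix yields all-zero scores with a warning.
#' @export
fit_fragment_pca <- function(z_tbl, n_components = 3) {
  bins <- setdiff(names(z_tbl), "sample_id")
  x <- as.matrix(z_tbl[bins])
  if (nrow(x) < n_components + 1) {
    abort("need at least n_components + 1 samples")
  }
  k <- as.integer(n_components)
  centers <- 10^as.numeric(sub("^x", "", bins))
  if (all(apply(x, 2, sd) == 0)) {
    warn("profiles have zero variance; all scores set to 0")
    loadings <- matrix(0, nrow = k, ncol = ncol(x),
                       dimnames = list(paste0("PC", 1:k), bins))
    scores <- matrix(0, nrow = nrow(x), ncol = k,
                     dimnames = list(NULL, paste0("PC", 1:k)))
    ev <- rep(0, k)
  } else {
    fit <- prcomp(x, center = FALSE, scale. = FALSE)
    k <- min(k, ncol(fit$rotation))
    rot <- fit$rotation[, 1:k, drop = FALSE]
    sc <- fit$x[, 1:k, drop = FALSE]
    for (j in 1:k) {
      if (rot[which.max(abs(rot[, j])), j] < 0) {
        rot[, j] <- -rot[, j]
        sc[, j] <- -sc[, j]
      }
    }
    loadings <- t(rot)
    scores <- sc
    ev <- (fit$sdev^2 / sum(fit$sdev^2))[1:k]
  }
  structure(list(loadings = loadings,
                 scores = dplyr::bind_cols(z_tbl["sample_id"],
                                           as_tibble(scores)),
                 explained_variance = ev,
                 bin_names = bins, centers = centers,
                 n_components = k),
            class = "frag_pca")
}

#' @export
print.frag_pca <- function(x, ...) {
  cat(sprintf("Fragment-length PCA: %d samples, %d bins, %d components\n",
              nrow(x$scores), length(x$bin_names), x$n_components))
  cat("explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Map principal components to fragmentation classes
#'
#' Each component is matched to the fragmentation class whose diagnostic
#' length window (hypofragmented 900-4,300 bp; ultra-long > 7.5 kb;
#' hyperfragmented 75-145 and 245-295 bp) captures the largest share of its
#' positive loading mass; assignment is greedy and one-to-one.
#'
#' @param model A [fit_fragment_pca()] model.
#' @return Named character vector, `PCk -> class`.
#' @export
pc_class_map <- function(model) {
  pcs <- rownames(model$loadings)
  mass <- sapply(names(pc_length_windows), function(cl) {
    inwin <- Reduce(`|`, map(pc_length_windows[[cl]], function(w) {
      model$centers >= w[1] & model$centers <= w[2]
    }))
    vapply(pcs, function(pc) {
      pos <- pmax(model$loadings[pc, ], 0)
      if (sum(pos) == 0) 0 else sum(pos[inwin]) / sum(pos)
    }, numeric(1))
  })
  mass <- matrix(mass, nrow = length(pcs),
                 dimnames = list(pcs, names(pc_length_windows)))
  out <- setNames(rep(NA_character_, length(pcs)), pcs)
  repeat {
    if (all(mass < 0) || !any(is.na(out))) break
    best <- which(mass == max(mass), arr.ind = TRUE)[1, ]
    if (max(mass) <= 0) break
    out[best["row"]] <- colnames(mass)[best["col"]]
    mass[best["row"], ] <- -1
    mass[, best["col"]] <- -1
  }
  out
}

#' Dominant length range of a principal component
#'
#' Bins where the oriented loading exceeds `loading_quantile` times its
#' maximum define the component's length range.
#'
#' @param model A `frag_pca` model.
#' @param pc Component index.
#' @param loading_quantile Fraction of the maximum loading (default 0.5).
#' @return Logical vector over bins (TRUE = in range).
#' @keywords internal
pc_range_bins <- function(model, pc, loading_quantile = 0.5) {
  load <- model$loadings[pc, ]
  if (max(load) <= 0) {
    warn(sprintf("PC%d has no positive loading; empty range", pc))
    return(rep(FALSE, length(load)))
  }
  load > loading_quantile * max(load)
}

#' Fraction of DNA in a component's length range
#'
#' The percentage of each sample's sequenced DNA falling in the length range
#' defined by a principal component ([pc_range_bins()]): the sum of the
#' sample's DNA proportions over those bins.
#'
#' @param profile_tbl Wide DNA-proportion profile tibble.
#' @param model A `frag_pca` model fitted on the matching grid.
#' @param pc Component index.
#' @param loading_quantile Passed to [pc_range_bins()].
#' @return Tibble with `sample_id`, `pc`, `frac_dna`.
#' @export
frac_dna_in_pc <- function(profile_tbl, model, pc, loading_quantile = 0.5) {
  bins <- pc_range_bins(model, pc, loading_quantile)
  x <- as.matrix(profile_tbl[model$bin_names])
  tibble(sample_id = profile_tbl$sample_id, pc = paste0("PC", pc),
         frac_dna = if (any(bins)) rowSums(x[, bins, drop = FALSE]) else 0)
}

#' Assign fragmentation classes from PCA scores
#'
#' In the default reference-relative mode, a sample is high on a component
#' when its score exceeds `z_threshold` standard deviations of the reference
#' samples' scores on that component; in absolute mode a fixed score cutoff
#' is used (the single-component re-analysis convention: score <= cutoff is
#' typical, score > cutoff is hyperfragmented-like for that component's
#' class). When several components exceed their threshold the largest
#' standardized score wins; samples high on none are `healthy_like`.
#'
#' @param model A `frag_pca` model.
#' @param reference_ids Reference sample ids (required in
#'   `mode = "reference"`).
#' @param z_threshold Reference-SD multiplier (default 3).
#' @param mode `"reference"` or `"absolute"`.
#' @param cutoff Absolute score cutoff (absolute mode, default 5).
#' @param class_map Optional named `PC -> class` vector; defaults to
#'   [pc_class_map()].
#' @return Tibble with `sample_id`, `label`, the PC scores, and
#'   `threshold_used`.
#' @export
assign_classes <- function(model, reference_ids = NULL, z_threshold = 3,
                           mode = c("reference", "absolute"), cutoff = 5,
                           class_map = NULL) {
  mode <- match.arg(mode)
  class_map <- class_map %||% pc_class_map(model)
  pcs <- rownames(model$loadings)
  sc <- as.matrix(model$scores[pcs])
  if (mode == "reference") {
    if (is.null(reference_ids)) {
      abort("reference_ids is required in reference-relative mode")
    }
    ref_sc <- sc[model$scores$sample_id %in% reference_ids, , drop = FALSE]
    if (nrow(ref_sc) < 2) abort("need at least 2 reference samples' scores")
    mus <- colMeans(ref_sc)
    sds <- pmax(apply(ref_sc, 2, sd), 1e-12)
    sc <- sweep(sc, 2, mus)
    thr <- z_threshold * sds
    std <- sweep(sc, 2, sds, "/")
  } else {
    thr <- setNames(rep(cutoff, length(pcs)), pcs)
    std <- sc
  }
  label <- vapply(seq_len(nrow(sc)), function(i) {
    high <- which(sc[i, ] > thr & !is.na(class_map))
    if (length(high) == 0) return("healthy_like")
    unname(class_map[high[which.max(std[i, high])]])
  }, character(1))
  dplyr::bind_cols(model$scores,
                   tibble(label = label,
                          threshold_used = paste(sprintf("%s>%.3g", pcs, thr),
                                                 collapse = ",")))
}

#' Tumor-fraction quality bins
#'
#' `below_lod` for tumor fraction < 0.02, `low_purity` for 0.02-0.1
#' (both bounds inclusive), `pass` for > 0.1.
#'
#' @param tumor_fraction Numeric vector in `[0, 1]`.
#' @return Factor with levels `below_lod`, `low_purity`, `pass`.
#' @export
tf_bin <- function(tumor_fraction) {
  if (any(is.na(tumor_fraction)) || any(tumor_fraction < 0) ||
      any(tumor_fraction > 1)) {
    abort("tumor fractions must lie in [0, 1]")
  }
  factor(ifelse(tumor_fraction < 0.02, "below_lod",
                ifelse(tumor_fraction <= 0.1, "low_purity", "pass")),
         levels = c("below_lod", "low_purity", "pass"))
}

#' @rdname tidy.frag_pca
#' @export
glance.frag_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_bins = length(x$bin_names),
         n_components = x$n_components,
         var_explained = sum(x$explained_variance))
}

#' Tidy fragment-PCA fits
#'
#' `tidy()` returns per-sample scores (`matrix = "scores"`) or per-bin
#' loadings in long form (`matrix = "loadings"`); `glance()` returns a
#' one-row model summary.
#'
#' @param x A `frag_pca` model.
#' @param matrix Which matrix to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.frag_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    return(tidyr::pivot_longer(x$scores, -"sample_id", names_to = "pc",
                               values_to = "score"))
  }
  as_tibble(t(x$loadings)) |>
    mutate(center = x$centers, .before = 1) |>
    tidyr::pivot_longer(-"center", names_to = "pc", values_to = "loading")
}

#' Plot fragment-PCA loadings along the length axis
#'
#' @param object A `frag_pca` model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frag_pca <- function(object, ...) {
  tidy(object, matrix = "loadings") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$center, y = .data$loading,
                                 colour = .data$pc)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fragment length (bp)", y = "PC loading",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
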