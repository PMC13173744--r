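#' @include log-grid.R
NULL

frag_class_levels <- c("healthy_like", "hypofragmented", "hyperfragmented",
                       "ultralong")

rand_kmer <- function(n, k = 5) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, asplit(m, 2))
}

# 5' end motifs with exact CC- and CCCA-prefix probabilities.
# Branches: CCCA + 1 random base; CC + 3-mer not starting "CA"; 5-mer not
# starting "CC". Rejection keeps the configured prefix fractions exact.
draw_end_motifs <- function(n, p_cc, p_ccca) {
  if (n == 0) return(character(0))
  u <- runif(n)
  out <- character(n)
  i_ccca <- u < p_ccca
  i_cc <- !i_ccca & u < p_cc
  i_bg <- !(i_ccca | i_cc)
  out[i_ccca] <- paste0("CCCA", rand_kmer(sum(i_ccca), 1))
  if (any(i_cc)) {
    tail3 <- rand_kmer(sum(i_cc), 3)
    repeat {
      bad <- startsWith(tail3, "CA")
      if (!any(bad)) break
      tail3[bad] <- rand_kmer(sum(bad), 3)
    }
    out[i_cc] <- paste0("CC", tail3)
  }
  if (any(i_bg)) {
    k5 <- rand_kmer(sum(i_bg), 5)
    repeat {
      bad <- startsWith(k5, "CC")
      if (!any(bad)) break
      k5[bad] <- rand_kmer(sum(bad), 5)
    }
    out[i_bg] <- k5
  }
  out
}

#' Fragment-length mixture component
#'
#' One component of a fragmentation class's length mixture. Three kinds are
#' supported: `gaussian_peak` (a normal peak, e.g. the ~167 bp mononucleosome),
#' `nucleosome_ladder` (lengths `n * unit + jitter` with `n` uniform on
#' `n_min:n_max`, emulating phased multi-nucleosome fragments in the 1-4 kb
#' range), and `log_uniform` (log-uniform lengths, used for ultra-long
#' lysis-derived fragments > 7.5 kb).
#'
#' @param kind One of `"gaussian_peak"`, `"nucleosome_ladder"`, `"log_uniform"`.
#' @param weight Mixture weight as a share of total DNA mass (base pairs);
#'   weights of a class's components must sum to 1. DNA-mass shares are the
#'   natural scale for mixed short/long fragment populations (a 45% ladder
#'   share by mass is only a few percent of fragment counts) and are
#'   converted internally to per-fragment draw probabilities using each
#'   component's mean length.
#' @param mean,sd Peak mean and SD in bp (`gaussian_peak`).
#' @param unit,n_min,n_max,jitter_sd Ladder parameters: nucleosome repeat
#'   length (bp), nucleosome count range, and Gaussian length jitter SD (bp).
#' @param min_bp,max_bp Range for `log_uniform`.
#' @param tumor_share Relative propensity of tumor-origin fragments in this
#'   component (0 = never tumor-derived, as for ex vivo ladder and lysis
#'   fragments).
#' @param motif One of `"class"` (use the class's CC/CCCA motif model, i.e.
#'   nuclease-processed ends) or `"background"` (uniform-random 5-mers, as for
#'   lysis fragments never exposed to circulating nucleases).
#' @return A `length_component` list.
#' @export
length_component <- function(kind = c("gaussian_peak", "nucleosome_ladder",
                                      "log_uniform"),
                             weight,
                             mean = NULL, sd = NULL,
                             unit = 167, n_min = 5, n_max = 25, jitter_sd = 25,
                             min_bp = NULL, max_bp = NULL,
                             tumor_share = 1,
                             motif = c("class", "background")) {
  kind <- match.arg(kind)
  motif <- match.arg(motif)
  if (kind == "gaussian_peak" && (is.null(mean) || is.null(sd))) {
    abort("gaussian_peak components need `mean` and `sd`")
  }
  if (kind == "log_uniform" && (is.null(min_bp) || is.null(max_bp))) {
    abort("log_uniform components need `min_bp` and `max_bp`")
  }
  structure(list(kind = kind, weight = weight, mean = mean, sd = sd,
                 unit = unit, n_min = n_min, n_max = n_max,
                 jitter_sd = jitter_sd, min_bp = min_bp, max_bp = max_bp,
                 tumor_share = tumor_share, motif = motif),
            class = "length_component")
}

#' Fragmentation class profile
#'
#' The generative model of one fragmentation class: a fragment-length mixture
#' plus a 5' end-motif model (probability that an end starts with CC, and with
#' CCCA specifically — the DNASE1L3 cleavage signature).
#'
#' @param name Class name, one of `healthy_like`, `hypofragmented`,
#'   `hyperfragmented`, `ultralong`.
#' @param components List of [length_component()]s; weights must sum to 1.
#' @param p_cc_start,p_ccca_start End-motif prefix probabilities for
#'   nuclease-processed (`motif = "class"`) components; must satisfy
#'   `0 <= p_ccca_start <= p_cc_start <= 1`.
#' @return A `class_profile` list.
#' @export
class_profile <- function(name, components, p_cc_start, p_ccca_start) {
  name <- match.arg(name, frag_class_levels)
  w <- sum(map_dbl(components, "weight"))
  if (abs(w - 1) > 1e-8) {
    abort(sprintf("component weights of class '%s' sum to %.4f, not 1", name, w))
  }
  if (!(p_ccca_start >= 0 && p_ccca_start <= p_cc_start && p_cc_start <= 1)) {
    abort("need 0 <= p_ccca_start <= p_cc_start <= 1")
  }
  structure(list(name = name, components = components,
                 p_cc_start = p_cc_start, p_ccca_start = p_ccca_start),
            class = "class_profile")
}

#' Default fragmentation class profiles
#'
#' The four generative class models used throughout: `healthy_like`
#' (mono/di-nucleosome peaks at ~167/~334 bp), `hypofragmented` (an added
#' nucleosome-phased ladder spanning ~0.9-4.3 kb, never tumor-derived),
#' `hyperfragmented` (excess sub-mononucleosomal 75-145 bp and short
#' di-nucleosome 245-295 bp peaks, with reduced CC/CCCA motif levels), and
#' `ultralong` (a log-uniform > 7.5 kb lysis component carrying
#' uniform-random end motifs, never tumor-derived).
#'
#' @param hyper_short_tumor_bias Multiplier on the tumor propensity of the
#'   hyperfragmented class's short (sub-mononucleosomal) component. The
#'   default 1 encodes the null model in which tumor- and blood-derived DNA
#'   share one length distribution; values > 1 inject tumor-specific
#'   shortening.
#' @param ultralong_max_bp Upper length bound of the lysis component (bp).
#' @return Named list of [class_profile()]s.
#' @export
default_class_profiles <- function(hyper_short_tumor_bias = 1,
                                   ultralong_max_bp = 50000) {
  list(
    healthy_like = class_profile(
      "healthy_like",
      list(length_component("gaussian_peak", weight = 0.88, mean = 167, sd = 10),
           length_component("gaussian_peak", weight = 0.12, mean = 334, sd = 20)),
      p_cc_start = 0.30, p_ccca_start = 0.10),
    hypofragmented = class_profile(
      "hypofragmented",
      list(length_component("nucleosome_ladder", weight = 0.45,
                            unit = 167, n_min = 5, n_max = 25, jitter_sd = 25,
                            tumor_share = 0),
           length_component("gaussian_peak", weight = 0.45, mean = 167, sd = 10),
           length_component("gaussian_peak", weight = 0.10, mean = 334, sd = 20)),
      p_cc_start = 0.30, p_ccca_start = 0.10),
    hyperfragmented = class_profile(
      "hyperfragmented",
      list(length_component("gaussian_peak", weight = 0.45, mean = 110, sd = 18,
                            tumor_share = hyper_short_tumor_bias),
           length_component("gaussian_peak", weight = 0.15, mean = 270, sd = 13),
           length_component("gaussian_peak", weight = 0.40, mean = 167, sd = 10)),
      p_cc_start = 0.18, p_ccca_start = 0.04),
    ultralong = class_profile(
      "ultralong",
      list(length_component("log_uniform", weight = 0.50, min_bp = 7500,
                            max_bp = ultralong_max_bp,
                            tumor_share = 0, motif = "background"),
           length_component("gaussian_peak", weight = 0.44, mean = 167, sd = 10),
           length_component("gaussian_peak", weight = 0.06, mean = 334, sd = 20)),
      p_cc_start = 0.30, p_ccca_start = 0.10)
  )
}

#' Toy diploid genome with known copy-number segments
#'
#' Default: four 10-Mb contigs, one whole-contig single-copy gain (copy 3)
#' and one single-copy loss (copy 1), balanced so the genome-wide mean copy
#' number is exactly 2 (which makes the naive coverage-ratio tumor-fraction
#' estimator unbiased).
#'
#' @param contig_length Length of each contig in bp.
#' @param copy_state Integer copy number per contig in tumor cells.
#' @return Tibble with columns `chrom`, `length`, `copy_state`.
#' @export
toy_genome <- function(contig_length = 1e7, copy_state = c(2L, 3L, 1L, 2L)) {
  tibble(chrom = paste0("chr", seq_along(copy_state)),
         length = as.integer(rep(contig_length, length(copy_state))),
         copy_state = as.integer(copy_state))
}

#' Synthetic cohort specification
#'
#' All parameters of a synthetic cfDNA cohort. Validation happens here, before
#' any simulation output is produced.
#'
#' @param n_samples_per_class Named integer vector, samples per class.
#' @param fragments_per_sample Fragments generated for each sample.
#' @param class_profiles Named list of [class_profile()]s (defaults to
#'   [default_class_profiles()]).
#' @param genome Toy genome tibble ([toy_genome()]).
#' @param tumor_fraction Either `NULL` (per-class defaults: 0 for healthy-like
#'   and ultralong, Uniform(0, 0.05) for hypofragmented, Uniform(0.05, 0.3)
#'   for hyperfragmented), a single number applied to every sample, or a
#'   named numeric vector per class.
#' @param cfdna_meanlog Named per-class log-mean of the lognormal cfDNA
#'   concentration model (ng/mL). Defaults encode elevated concentrations for
#'   the hypofragmented, hyperfragmented, and ultralong classes.
#' @param cfdna_sdlog Lognormal log-SD, shared across classes.
#' @param h3_slope Slope of the H3.1 nucleosome concentration on cfDNA.
#' @param h3_r2_target Target population R-squared of the H3.1-cfDNA
#'   relationship (default 0.73).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples_per_class = c(healthy_like = 17,
                                                hypofragmented = 10,
                                                hyperfragmented = 10,
                                                ultralong = 3),
                        fragments_per_sample = 20000,
                        class_profiles = default_class_profiles(),
                        genome = toy_genome(),
                        tumor_fraction = NULL,
                        cfdna_meanlog = c(healthy_like = log(7),
                                          hypofragmented = log(35),
                                          hyperfragmented = log(35),
                                          ultralong = log(30)),
                        cfdna_sdlog = 0.5,
                        h3_slope = 5,
                        h3_r2_target = 0.73,
                        seed = 1L) {
  if (!all(names(n_samples_per_class) %in% frag_class_levels)) {
    abort("unknown class names in n_samples_per_class")
  }
  if (!all(names(n_samples_per_class) %in% names(class_profiles))) {
    abort("missing class_profiles for some requested classes")
  }
  if (nrow(genome) == 0) abort("toy genome must be non-empty")
  if (is.numeric(tumor_fraction) &&
      (any(tumor_fraction < 0) || any(tumor_fraction > 1))) {
    abort("tumor_fraction must lie in [0, 1]")
  }
  if (!(h3_r2_target > 0 && h3_r2_target <= 1)) {
    abort("h3_r2_target must lie in (0, 1]")
  }
  for (cp in class_profiles) {
    stopifnot(inherits(cp, "class_profile"))
  }
  structure(list(n_samples_per_class = n_samples_per_class,
                 fragments_per_sample = as.integer(fragments_per_sample),
                 class_profiles = class_profiles,
                 genome = genome,
                 tumor_fraction = tumor_fraction,
                 cfdna_meanlog = cfdna_meanlog,
                 cfdna_sdlog = cfdna_sdlog,
                 h3_slope = h3_slope,
                 h3_r2_target = h3_r2_target,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_component_lengths <- function(comp, n) {
  len <- switch(comp$kind,
    gaussian_peak = round(rnorm(n, comp$mean, comp$sd)),
    nucleosome_ladder = round(sample(comp$n_min:comp$n_max, n, replace = TRUE) *
                                comp$unit + rnorm(n, 0, comp$jitter_sd)),
    log_uniform = round(10^runif(n, log10(comp$min_bp), log10(comp$max_bp))))
  # truncate the tails: fragments below 30 bp are not observable
  repeat {
    bad <- len < 30
    if (!any(bad)) break
    len[bad] <- draw_component_lengths(comp, sum(bad))
  }
  as.integer(len)
}

draw_positions <- function(lengths, origin, genome) {
  n <- length(lengths)
  p_blood <- genome$length / sum(genome$length)
  p_tumor <- genome$length * genome$copy_state
  p_tumor <- p_tumor / sum(p_tumor)
  seg <- integer(n)
  is_t <- origin == "tumor"
  seg[is_t] <- sample.int(nrow(genome), sum(is_t), replace = TRUE,
                          prob = p_tumor)
  seg[!is_t] <- sample.int(nrow(genome), sum(!is_t), replace = TRUE,
                           prob = p_blood)
  # resample fragments longer than their contig (logged, never silently kept)
  n_resampled <- 0L
  repeat {
    bad <- lengths > genome$length[seg]
    if (!any(bad)) break
    feasible <- genome$length > max(lengths[bad])
    if (!any(feasible)) abort("fragment longer than every toy-genome contig")
    n_resampled <- n_resampled + sum(bad)
    seg[bad] <- sample(which(feasible), sum(bad), replace = TRUE)
  }
  if (n_resampled > 0) {
    message(sprintf("resampled %d fragments exceeding their contig", n_resampled))
  }
  start <- as.integer(floor(runif(n) * (genome$length[seg] - lengths)))
  tibble(chrom = genome$chrom[seg], start = start,
         end = start + as.integer(lengths))
}

mean_component_length <- function(comp) {
  switch(comp$kind,
    gaussian_peak = comp$mean,
    nucleosome_ladder = comp$unit * (comp$n_min + comp$n_max) / 2,
    # mean of a log-uniform variable
    log_uniform = (comp$max_bp - comp$min_bp) / log(comp$max_bp / comp$min_bp))
}

# component weights are DNA-mass shares; convert to per-fragment draw
# probabilities by dividing by the component's mean fragment length
component_count_weights <- function(cp) {
  w <- map_dbl(cp$components, "weight") /
    map_dbl(cp$components, mean_component_length)
  w / sum(w)
}

simulate_sample_fragments <- function(sample_id, cp, n, tf, genome) {
  w <- component_count_weights(cp)
  comp_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  kinds <- map_chr(cp$components, "kind")
  lengths <- integer(n)
  for (ci in seq_along(cp$components)) {
    sel <- comp_idx == ci
    if (any(sel)) lengths[sel] <- draw_component_lengths(cp$components[[ci]],
                                                         sum(sel))
  }
  # per-component tumor propensity, scaled so the overall tumor share is tf
  m <- map_dbl(cp$components, "tumor_share")
  z <- sum(w * m)
  p_tumor <- if (tf == 0 || z == 0) rep(0, n) else pmin(tf * m[comp_idx] / z, 1)
  origin <- if_else(runif(n) < p_tumor, "tumor", "blood")
  pos <- draw_positions(lengths, origin, genome)
  motif_regime <- map_chr(cp$components, "motif")[comp_idx]
  bg <- motif_regime == "background"
  left <- character(n); right <- character(n)
  left[bg] <- rand_kmer(sum(bg), 5)
  right[bg] <- rand_kmer(sum(bg), 5)
  left[!bg] <- draw_end_motifs(sum(!bg), cp$p_cc_start, cp$p_ccca_start)
  right[!bg] <- draw_end_motifs(sum(!bg), cp$p_cc_start, cp$p_ccca_start)
  tibble(sample_id = sample_id, class = cp$name,
         component = kinds[comp_idx],
         chrom = pos$chrom, start = pos$start, end = pos$end,
         length = as.integer(lengths), mapq = 60L,
         read_qs = round(pmax(rnorm(n, 20, 3), 12), 1),
         is_duplicate = FALSE, flags = 0L,
         left_motif = left, right_motif = right, origin = origin)
}

default_tumor_fraction <- function(class) {
  switch(class,
         healthy_like = 0,
         ultralong = 0,
         hypofragmented = runif(1, 0, 0.05),
         hyperfragmented = runif(1, 0.05, 0.3))
}

#' Simulate a synthetic cfDNA cohort
#'
#' Draws, per sample, fragment lengths from the class mixture, 5' end motifs
#' from the class motif model (uniform-random for lysis components), genomic
#' positions from the toy genome (tumor-origin fragments proportional to copy
#' state), tumor/blood origin labels at the sample's tumor fraction, and
#' correlated cfDNA / H3.1 concentrations. Deterministic under the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cfdna_cohort` with elements `fragments` (tibble,
#'   one row per fragment, including ground-truth `class`, `component`, and
#'   `origin` columns), `samples` (per-sample metadata: class, tumor fraction,
#'   concentrations, true motif probabilities), and `spec`.
#' @examples
#' spec <- cohort_spec(n_samples_per_class = c(healthy_like = 2),
#'                     fragments_per_sample = 500, seed = 7)
#' cohort <- simulate_cohort(spec)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    classes <- rep(names(spec$n_samples_per_class), spec$n_samples_per_class)
    ids <- unlist(map(names(spec$n_samples_per_class), function(cl) {
      sprintf("%s_%02d", cl, seq_len(spec$n_samples_per_class[[cl]]))
    }))
    tf <- map_dbl(seq_along(ids), function(i) {
      cl <- classes[i]
      if (is.null(spec$tumor_fraction)) default_tumor_fraction(cl)
      else if (length(spec$tumor_fraction) == 1 &&
               is.null(names(spec$tumor_fraction))) spec$tumor_fraction
      else if (cl %in% names(spec$tumor_fraction)) spec$tumor_fraction[[cl]]
      else 0
    })
    conc <- simulate_concentrations(classes,
                                    cfdna_meanlog = spec$cfdna_meanlog,
                                    cfdna_sdlog = spec$cfdna_sdlog,
                                    h3_slope = spec$h3_slope,
                                    h3_r2_target = spec$h3_r2_target)
    samples <- tibble(sample_id = ids, class = classes, tumor_fraction = tf,
                      cfdna_ng_ml = conc$cfdna_ng_ml,
                      h3_ng_ml = conc$h3_ng_ml,
                      p_cc_start = map_dbl(classes,
                                           ~ spec$class_profiles[[.x]]$p_cc_start),
                      p_ccca_start = map_dbl(classes,
                                             ~ spec$class_profiles[[.x]]$p_ccca_start))
    fragments <- list_rbind(map(seq_along(ids), function(i) {
      simulate_sample_fragments(ids[i], spec$class_profiles[[classes[i]]],
                                spec$fragments_per_sample, tf[i], spec$genome)
    }))
    structure(list(fragments = fragments, samples = samples, spec = spec),
              class = "cfdna_cohort")
  })
}

#' Simulate correlated cfDNA and H3.1 nucleosome concentrations
#'
#' cfDNA concentrations are lognormal per class; H3.1 is a linear response
#' `h3 = slope * cfdna + e` with Gaussian noise whose variance is chosen
#' analytically from the lognormal mixture moments so that the population
#' R-squared equals `h3_r2_target`.
#'
#' @param classes Character vector of class labels, one per sample.
#' @inheritParams cohort_spec
#' @return Tibble with columns `cfdna_ng_ml`, `h3_ng_ml`.
#' @examples
#' x <- simulate_concentrations(rep("healthy_like", 100), h3_r2_target = 1)
#' cor(x$cfdna_ng_ml, x$h3_ng_ml)^2 # exactly 1
#' @export
simulate_concentrations <- function(classes,
                                    cfdna_meanlog = c(healthy_like = log(7),
                                                      hypofragmented = log(35),
                                                      hyperfragmented = log(35),
                                                      ultralong = log(30)),
                                    cfdna_sdlog = 0.5,
                                    h3_slope = 5,
                                    h3_r2_target = 0.73) {
  if (!(h3_r2_target > 0 && h3_r2_target <= 1)) {
    abort("h3_r2_target must lie in (0, 1]")
  }
  if (!all(classes %in% names(cfdna_meanlog))) {
    abort("cfdna_meanlog missing for some classes")
  }
  mu <- cfdna_meanlog[classes]
  cfdna <- exp(rnorm(length(classes), mu, cfdna_sdlog))
  # analytic mixture variance of the lognormal cfDNA model
  w <- table(classes) / length(classes)
  mk <- exp(cfdna_meanlog[names(w)] + cfdna_sdlog^2 / 2)
  vk <- (exp(cfdna_sdlog^2) - 1) * exp(2 * cfdna_meanlog[names(w)] + cfdna_sdlog^2)
  mix_var <- sum(w * (vk + mk^2)) - sum(w * mk)^2
  noise_var <- h3_slope^2 * mix_var * (1 - h3_r2_target) / h3_r2_target
  h3 <- h3_slope * cfdna + rnorm(length(classes), 0, sqrt(noise_var))
  tibble(cfdna_ng_ml = cfdna, h3_ng_ml = h3)
}

#' Simulate the post-thaw high-speed spin
#'
#' Removes a configured proportion of lysis-derived (log-uniform component)
#' fragments from a fragment table, emulating the high-speed centrifugation
#' step that depletes ultra-long genomic contamination.
#'
#' @param fragments Fragment tibble from [simulate_cohort()] (needs the
#'   ground-truth `component` column).
#' @param proportion Removal proportion among lysis-component fragments.
#' @return Filtered fragment tibble.
#' @export
apply_high_speed_spin <- function(fragments, proportion = 0.85) {
  stopifnot(proportion >= 0, proportion <= 1)
  if (!"component" %in% names(fragments)) {
    abort("`fragments` must carry the ground-truth `component` column")
  }
  drop <- fragments$component == "log_uniform" & runif(nrow(fragments)) < proportion
  fragments[!drop, ]
}
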