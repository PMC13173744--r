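default_config <- function() {
  list(
    seed = 1L,
    grid = list(min_bp = 50, max_bp = 50000, log10_step = 0.01),
    filter = list(min_read_qs = 10, min_mapq = 20),
    motif = list(min_baseq = 20, adapter_tail = "CACCT"),
    pca = list(n_components = 3, z_threshold = 3, loading_quantile = 0.5),
    spin = list(apply = FALSE, proportion = 0.85),
    simulator = list(
      n_samples_per_class = list(healthy_like = 17, hypofragmented = 10,
                                 hyperfragmented = 10, ultralong = 3),
      fragments_per_sample = 20000,
      h3_r2_target = 0.73)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in ", path) else "",
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "simulator") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], k)
    } else if (k == "simulator") {
      unknown <- setdiff(names(user[[k]]),
                         c(names(defaults[[k]]), "tumor_fraction"))
      if (length(unknown)) {
        abort(sprintf("unknown config key(s) in simulator: %s",
                      paste(unknown, collapse = ", ")))
      }
      defaults[[k]][names(user[[k]])] <- user[[k]]
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds and validates the full pipeline configuration from defaults plus
#' overrides. Unknown keys are rejected. Sections: `seed`, `grid`
#' (log-grid parameters), `filter` (read filter policy), `motif` (end-motif
#' caller), `pca` (classification), `spin` (simulated high-speed spin),
#' `simulator` (synthetic cohort).
#'
#' @param ... Named overrides, possibly nested lists (e.g.
#'   `grid = list(min_bp = 50)`).
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, user)
}

write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

cohort_from_config <- function(config) {
  sim <- config$simulator
  spec <- cohort_spec(
    n_samples_per_class = unlist(sim$n_samples_per_class),
    fragments_per_sample = sim$fragments_per_sample,
    tumor_fraction = sim$tumor_fraction,
    h3_r2_target = sim$h3_r2_target,
    seed = config$seed)
  simulate_cohort(spec)
}

#' Run the full fragmentomics pipeline on a synthetic cohort
#'
#' Executes the stages in order — simulate, profile, end motifs, classify,
#' cohort features — and writes every stage artifact plus a run manifest to
#' `out_dir`. Reruns with an identical configuration produce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- cohort_from_config(config)
  fragments <- cohort$fragments
  if (isTRUE(config$spin$apply)) {
    fragments <- withr::with_seed(config$seed + 1L,
      apply_high_speed_spin(fragments, config$spin$proportion))
  }
  grid <- log_bin_grid(config$grid$min_bp, config$grid$max_bp,
                       config$grid$log10_step)
  profiles <- length_profile(fragments, grid)
  prof_tbl <- profile_matrix(profiles)

  calls <- fragment_motif_calls(fragments)
  motifs <- motif_fractions(calls)

  reference_ids <- cohort$samples$sample_id[cohort$samples$class == "healthy_like"]
  ref <- build_reference(prof_tbl, reference_ids)
  z <- znormalize(prof_tbl, ref)
  model <- fit_fragment_pca(z, config$pca$n_components)
  assignments <- assign_classes(model, reference_ids,
                                z_threshold = config$pca$z_threshold)

  frac_short <- frac_dna_in_range(fragments, 0, 150) |>
    rename(frac_dna_under_150 = "frac_dna")
  frac_long <- frac_dna_in_range(fragments, 900, 4300) |>
    rename(frac_dna_900_4300 = "frac_dna")
  tf_est <- naive_tf_estimate(fragments, cohort$spec$genome)
  features <- cohort$samples |>
    select("sample_id", "class", "tumor_fraction", "cfdna_ng_ml",
           "h3_ng_ml") |>
    # the additive assay-noise model can dip below zero; report such values
    # as 0, as an immunoassay clips below its detection limit
    mutate(h3_ng_ml = pmax(.data$h3_ng_ml, 0)) |>
    left_join(model$scores, by = "sample_id") |>
    left_join(motifs, by = "sample_id") |>
    left_join(frac_short, by = "sample_id") |>
    left_join(frac_long, by = "sample_id") |>
    left_join(tf_est, by = "sample_id") |>
    decompose_concentration(.data$cfdna_ng_ml, .data$tumor_fraction,
                            prefix = "cfdna") |>
    decompose_concentration(.data$h3_ng_ml, .data$tumor_fraction,
                            prefix = "h3")
  clustering <- feature_cluster(
    select(features, "sample_id", dplyr::starts_with("PC"), "ccca_frac",
           "frac_dna_under_150", "tumor_fraction", "cfdna_ng_ml", "h3_ng_ml"),
    n_clusters = 3)

  paths <- c(
    metadata = write_tsv_file(cohort$samples,
                              file.path(out_dir, "metadata.tsv")),
    profiles = write_tsv_file(
      setNames(prof_tbl, c("sample_id",
                           format(profile_bin_centers(prof_tbl),
                                  trim = TRUE))),
      file.path(out_dir, "profiles.tsv")),
    motifs = write_tsv_file(motifs, file.path(out_dir, "motif_summary.tsv")),
    scores = write_tsv_file(model$scores, file.path(out_dir, "scores.tsv")),
    loadings = write_tsv_file(
      tidy(model, matrix = "loadings"), file.path(out_dir, "loadings.tsv")),
    assignments = write_tsv_file(assignments,
                                 file.path(out_dir, "assignments.tsv")),
    features = write_tsv_file(features, file.path(out_dir, "features.tsv")),
    rho = write_tsv_file(as_tibble(clustering$rho, rownames = "feature"),
                         file.path(out_dir, "feature_rho.tsv")),
    tree = {
      p <- file.path(out_dir, "feature_tree.newick")
      writeLines(cluster_newick(clustering), p)
      p
    })
  manifest <- list(
    package = "cffrag",
    version = as.character(utils::packageVersion("cffrag")),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(unname(paths))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, profiles = profiles, model = model,
                 assignments = assignments, features = features,
                 clustering = clustering, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}

#' Plot fragment-length profiles
#'
#' DNA-weighted (or fragment-count) length distributions on the log grid,
#' one line per sample.
#'
#' @param profiles Long profile tibble from [length_profile()].
#' @param value Which proportion to draw.
#' @return A ggplot.
#' @export
plot_length_profiles <- function(profiles, value = c("dna_proportion",
                                                     "fragment_proportion")) {
  value <- match.arg(value)
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$center, y = .data[[value]],
                               group = .data$sample_id,
                               colour = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fragment length (bp)",
                  y = gsub("_", " ", value)) +
    ggplot2::theme_minimal()
}
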