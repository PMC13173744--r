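make_planted <- function(seed, fragments_per_sample = 3000) {
  spec <- cohort_spec(n_samples_per_class = c(healthy_like = 17,
                                              hypofragmented = 10,
                                              hyperfragmented = 10,
                                              ultralong = 3),
                      fragments_per_sample = fragments_per_sample,
                      seed = seed)
  cohort <- simulate_cohort(spec)
  pm <- profile_matrix(length_profile(cohort$fragments))
  ref_ids <- cohort$samples$sample_id[cohort$samples$class == "healthy_like"]
  list(cohort = cohort, pm = pm, ref_ids = ref_ids)
}

test_that("reference statistics and flags follow their definitions", {
  pm <- tibble::tibble(sample_id = c("a", "b", "c"),
                       x1 = c(0.5, 0.5, 0.1), x2 = c(0.5, 0.5, 0.9))
  ref <- build_reference(pm, c("a", "b"))
  expect_equal(attr(ref, "n_reference"), 2)
  expect_true(all(ref$sd == 0))       # identical profiles
  expect_true(all(ref$zero_sd))
  ref3 <- build_reference(pm, c("a", "b", "c"))
  expect_equal(attr(ref3, "n_reference"), 3)
  expect_false(any(ref3$zero_sd))
  expect_error(build_reference(pm, "a"), "at least 2")
})

test_that("z-normalization is exact and floored on zero-SD bins", {
  pm <- tibble::tibble(sample_id = c("a", "b", "q"),
                       x1 = c(0.4, 0.6, 0.5), x2 = c(0.6, 0.4, 0.9))
  ref <- build_reference(pm, c("a", "b"))
  z <- znormalize(pm, ref)
  # profile equal to the reference mean -> zero z
  expect_equal(as.numeric(z[z$sample_id == "q", "x1"]), 0)
  # value = mean + 2 SD -> z = 2 (sd over a,b in x2 is sqrt(2)*0.1...)
  s <- sd(c(0.6, 0.4))
  expect_equal(as.numeric(z[z$sample_id == "q", "x2"]), (0.9 - 0.5) / s)
  # zero-SD bins stay finite under the floor
  pm0 <- tibble::tibble(sample_id = c("a", "b", "q"),
                        x1 = c(0.5, 0.5, 0.7), x2 = c(0.5, 0.5, 0.3))
  z0 <- znormalize(pm0, build_reference(pm0, c("a", "b")), sd_floor = 1e-6)
  expect_true(all(is.finite(as.matrix(z0[-1]))))
  bad <- dplyr::rename(pm, y1 = x1)
  expect_error(znormalize(bad, ref), "match")
})

test_that("degenerate inputs give zero scores with a warning", {
  pm <- tibble::tibble(sample_id = letters[1:5],
                       x1 = rep(0.5, 5), x2 = rep(0.5, 5))
  ref <- build_reference(pm, letters[1:2])
  z <- znormalize(pm, ref)
  expect_warning(model <- fit_fragment_pca(z, 2), "zero variance")
  expect_true(all(as.matrix(model$scores[-1]) == 0))
  expect_equal(model$explained_variance, c(0, 0))
})

test_that("planted classes are recovered and PCs map to their length windows", {
  pl <- make_planted(seed = 41)
  ref <- build_reference(pl$pm, pl$ref_ids)
  model <- fit_fragment_pca(znormalize(pl$pm, ref), 3)
  cmap <- pc_class_map(model)
  expect_setequal(unname(cmap),
                  c("hypofragmented", "hyperfragmented", "ultralong"))
  # dominant loading range of each signature PC overlaps its window
  hypo_pc <- as.integer(sub("PC", "", names(cmap)[cmap == "hypofragmented"]))
  hyper_pc <- as.integer(sub("PC", "", names(cmap)[cmap == "hyperfragmented"]))
  hypo_rng <- model$centers[cffrag:::pc_range_bins(model, hypo_pc)]
  hyper_rng <- model$centers[cffrag:::pc_range_bins(model, hyper_pc)]
  expect_true(any(hypo_rng >= 900 & hypo_rng <= 4300))
  expect_true(any(hyper_rng >= 75 & hyper_rng <= 145))
  asg <- assign_classes(model, pl$ref_ids)
  truth <- pl$cohort$samples$class[match(asg$sample_id,
                                         pl$cohort$samples$sample_id)]
  expect_gte(mean(asg$label == truth), 0.9)
})

test_that("reference samples score near zero on every component", {
  pl <- make_planted(seed = 42)
  ref <- build_reference(pl$pm, pl$ref_ids)
  model <- fit_fragment_pca(znormalize(pl$pm, ref), 3)
  sc <- as.matrix(model$scores[-1])
  ref_rows <- model$scores$sample_id %in% pl$ref_ids
  for (j in 1:3) {
    expect_lt(abs(mean(sc[ref_rows, j])), 0.2 * sd(sc[, j]))
  }
})

test_that("sample order permutations permute scores identically", {
  pl <- make_planted(seed = 43, fragments_per_sample = 1000)
  ref <- build_reference(pl$pm, pl$ref_ids)
  z <- znormalize(pl$pm, ref)
  model <- fit_fragment_pca(z, 3)
  perm <- withr::with_seed(44, sample(nrow(z)))
  model_p <- fit_fragment_pca(z[perm, ], 3)
  expect_equal(model_p$scores$sample_id, model$scores$sample_id[perm])
  expect_equal(as.matrix(model_p$scores[-1]),
               as.matrix(model$scores[perm, -1]), tolerance = 1e-8)
})

test_that("duplicating a healthy sample leaves existing labels unchanged", {
  pl <- make_planted(seed = 45, fragments_per_sample = 2000)
  ref <- build_reference(pl$pm, pl$ref_ids)
  base <- assign_classes(fit_fragment_pca(znormalize(pl$pm, ref), 3),
                         pl$ref_ids)
  dup <- pl$pm[pl$pm$sample_id == pl$ref_ids[1], ]
  dup$sample_id <- "healthy_dup"
  pm2 <- dplyr::bind_rows(pl$pm, dup)
  aug <- assign_classes(fit_fragment_pca(znormalize(pm2, ref), 3),
                        pl$ref_ids)
  merged <- merge(base[c("sample_id", "label")], aug[c("sample_id", "label")],
                  by = "sample_id")
  expect_true(all(merged$label.x == merged$label.y))
  expect_equal(aug$label[aug$sample_id == "healthy_dup"], "healthy_like")
})

test_that("frac_dna_in_pc is a proportion ordered by class severity", {
  pl <- make_planted(seed = 46)
  ref <- build_reference(pl$pm, pl$ref_ids)
  model <- fit_fragment_pca(znormalize(pl$pm, ref), 3)
  cmap <- pc_class_map(model)
  hypo_pc <- as.integer(sub("PC", "", names(cmap)[cmap == "hypofragmented"]))
  fd <- frac_dna_in_pc(pl$pm, model, hypo_pc)
  expect_true(all(fd$frac_dna >= 0 & fd$frac_dna <= 1))
  cls <- pl$cohort$samples$class[match(fd$sample_id,
                                       pl$cohort$samples$sample_id)]
  expect_gt(min(fd$frac_dna[cls == "hypofragmented"]),
            max(fd$frac_dna[cls == "healthy_like"]))
  # one-hot loading: range collapses to that bin
  toy <- model
  toy$loadings[hypo_pc, ] <- 0
  toy$loadings[hypo_pc, 100] <- 1
  expect_equal(sum(cffrag:::pc_range_bins(toy, hypo_pc)), 1)
})

test_that("absolute single-component mode applies the printed cutoff strictly", {
  pl <- make_planted(seed = 47, fragments_per_sample = 1000)
  ref <- build_reference(pl$pm, pl$ref_ids)
  model <- fit_fragment_pca(znormalize(pl$pm, ref), 3)
  # forge scores at the boundary to pin the > 5 rule
  model$scores[2:4] <- 0
  model$scores[[2]][1:2] <- c(5.0, 5.01)
  asg <- assign_classes(model, mode = "absolute", cutoff = 5,
                        class_map = c(PC1 = "hyperfragmented",
                                      PC2 = NA, PC3 = NA))
  expect_equal(asg$label[1], "healthy_like")      # 5.00 is typical
  expect_equal(asg$label[2], "hyperfragmented")   # 5.01 exceeds the cutoff
  expect_true(all(asg$label[-(1:2)] == "healthy_like"))
})

test_that("tumor-fraction bins honour the printed boundaries", {
  expect_equal(as.character(tf_bin(c(0, 0.019, 0.02, 0.05, 0.1, 0.101, 0.55))),
               c("below_lod", "below_lod", "low_purity", "low_purity",
                 "low_purity", "pass", "pass"))
  expect_error(tf_bin(1.2), "\\[0, 1\\]")
  expect_error(tf_bin(-0.1), "\\[0, 1\\]")
})

test_that("tidy and glance expose scores, loadings, and fit summary", {
  pl <- make_planted(seed = 48, fragments_per_sample = 1000)
  ref <- build_reference(pl$pm, pl$ref_ids)
  model <- fit_fragment_pca(znormalize(pl$pm, ref), 3)
  sc <- tidy(model)
  expect_setequal(unique(sc$pc), c("PC1", "PC2", "PC3"))
  expect_equal(nrow(sc), 40 * 3)
  ld <- tidy(model, matrix = "loadings")
  expect_equal(nrow(ld), 301 * 3)
  g <- glance(model)
  expect_equal(g$n_samples, 40)
  expect_lte(g$var_explained, 1)
  expect_s3_class(autoplot(model), "ggplot")
})
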