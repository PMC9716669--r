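# end-to-end helper: network, hubs, archetypes, markers on a small dataset
run_sex_pipeline <- function(ds) {
  expr <- ds$expression
  s <- spearman_correlation(log2(expr + 1))
  a <- signed_adjacency(s, 15)
  mods <- detect_modules(topological_overlap(a)$diss, min_module_size = 10)
  kin <- intramodular_connectivity(a, mods)
  hubs <- select_hubs(kin, mods)
  arch <- classify_archetype(module_eigengene(expr, mods), ds$design)
  markers <- suppressWarnings(
    select_sex_markers(hubs, expr, ds$design, arch))
  cl <- cluster_samples(expr[markers, , drop = FALSE])
  list(markers = markers, hubs = hubs, arch = arch,
       timing = assign_early_sex(cl, ds$design))
}

test_that("marker selection screens hubs by the between-sex test at 45 dpf", {
  ds <- small_dataset(seed = 3)
  res <- run_sex_pipeline(ds)
  sex_mods <- res$arch$module[res$arch$archetype %in%
                                c("male_specific", "female_specific")]
  expect_length(sex_mods, 2)
  # markers are hub genes of the sex-specific modules only
  hub_genes <- res$hubs$gene[res$hubs$is_hub &
                               res$hubs$module %in% sex_mods]
  expect_true(all(res$markers %in% hub_genes))
  expect_gt(length(res$markers), 0)

  # a gene identical in both sexes cannot be a marker: force one hub flat
  expr2 <- ds$expression
  flat_gene <- res$markers[1]
  expr2[flat_gene, ] <- 100
  arch <- res$arch
  m2 <- suppressWarnings(
    select_sex_markers(res$hubs, expr2, ds$design, arch))
  expect_false(flat_gene %in% m2)

  # per-module cap binds when more hubs are significant than top_n
  m3 <- suppressWarnings(
    select_sex_markers(res$hubs, ds$expression, ds$design, arch, top_n = 2))
  expect_lte(length(m3), 4)
  no_sex <- res$arch[res$arch$archetype == "gonad_forming", , drop = FALSE]
  expect_error(select_sex_markers(res$hubs, ds$expression, ds$design,
                                  no_sex),
               "male-specific")
})

test_that("sample clustering separates planted groups and handles edges", {
  set.seed(44)
  centers <- matrix(rnorm(30 * 3, sd = 4), 30, 3)
  x <- centers[, rep(1:3, each = 6)] + rnorm(30 * 18, sd = 0.3)
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:18))
  cl <- cluster_samples(x, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl, rep(1:3, each = 6)), 1)

  # a duplicated sample lands in its twin's cluster
  x2 <- cbind(x, dup = x[, "s1"])
  cl2 <- cluster_samples(x2, k = 3)
  expect_equal(unname(cl2["dup"]), unname(cl2["s1"]))

  expect_equal(length(unique(cluster_samples(x, k = 18))), 18)
  expect_error(cluster_samples(x, k = 1), "k must be")
  expect_error(cluster_samples(x[0, ], k = 2), "marker")
})

test_that("early-sample sex assignment votes by sexed cluster members", {
  design <- gonad_design()
  # construct clusters by true latent sex: all early samples assignable
  sex_eff <- ifelse(design$sex == "U", design$latent_sex, design$sex)
  cl <- setNames(ifelse(sex_eff == "M", 1L, 2L), design$sample_id)
  out <- assign_early_sex(cl, design)
  expect_equal(out$ratios$ratio, c(1, 1))
  calls <- out$sample_calls
  early <- calls$timepoint <= 40
  lat <- design$latent_sex[match(calls$sample_id, design$sample_id)]
  expect_equal(calls$inferred_sex[early], lat[early])

  # a cluster without sexed members stays undifferentiated
  cl3 <- cl
  cl3[design$timepoint <= 40] <- 3L
  out3 <- assign_early_sex(cl3, design)
  expect_true(all(out3$sample_calls$inferred_sex[
    out3$sample_calls$timepoint <= 40] == "unresolved"))
  expect_equal(out3$ratios$ratio, c(0, 0))

  # tied vote: undifferentiated with a warning
  cl4 <- setNames(rep(1L, 40), design$sample_id)
  expect_warning(out4 <- assign_early_sex(cl4, design), "tied")
  expect_true(all(out4$sample_calls$inferred_sex[
    out4$sample_calls$timepoint <= 40] == "unresolved"))
})

test_that("molecular divergence at 35 dpf lets early samples be sexed", {
  n_ok <- 0
  for (seed in 1:5) {
    ds <- small_dataset(seed = seed, divergence_tp = 35)
    res <- run_sex_pipeline(ds)
    calls <- res$timing$sample_calls
    early <- calls$timepoint <= 40
    lat <- ds$design$latent_sex[match(calls$sample_id,
                                      ds$design$sample_id)]
    assigned <- early & calls$inferred_sex %in% c("M", "F")
    acc <- mean(calls$inferred_sex[assigned] == lat[assigned])
    if (any(assigned) && acc >= 0.8) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 4)
})

test_that("later divergence shows up as a lower 35 dpf assignment ratio", {
  n_ok <- 0
  for (seed in 1:5) {
    ds <- small_dataset(seed = seed, divergence_tp = 40)
    r <- run_sex_pipeline(ds)$timing$ratios
    if (r$ratio[r$timepoint == 40] >= r$ratio[r$timepoint == 35])
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 4)
})

test_that("sample PCA returns orthonormal components and sane fractions", {
  # data varying along a single direction
  v <- c(1, -1, 2, 0.5, -2)
  x <- outer(c(1, 2, 3), v)
  dimnames(x) <- list(paste0("g", 1:3), paste0("s", 1:5))
  res <- sample_pca(x)
  expect_equal(res$variance_explained[1], 1, tolerance = 1e-12)

  # three clean sample classes: undifferentiated, testis, ovary
  ds <- small_dataset(seed = 9, divergence_tp = 45)
  pc <- sample_pca(log2(ds$expression + 1))
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(pc$variance_explained >= 0))
  # separation of the three sample classes on PC1-2: mean silhouette
  d <- ds$design
  cls <- ifelse(d$timepoint <= 40, "U", d$sex)
  sc <- pc$scores[, 1:2]
  sil <- vapply(seq_len(nrow(sc)), function(i) {
    own <- colMeans(sc[cls == cls[i] & seq_len(nrow(sc)) != i, , drop = FALSE])
    a <- sqrt(sum((sc[i, ] - own)^2))
    b <- min(vapply(setdiff(unique(cls), cls[i]), function(cc) {
      sqrt(sum((sc[i, ] - colMeans(sc[cls == cc, , drop = FALSE]))^2))
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  flat <- matrix(3, 3, 4, dimnames = list(paste0("g", 1:3),
                                          paste0("s", 1:4)))
  expect_error(suppressWarnings(sample_pca(flat)), "non-degenerate")
})
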