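test_that("hypergeometric upper tail equals exhaustive pmf summation", {
  # hand-worked case: universe 10, 5 DEGs, module of 2 fully DEG
  mods <- setNames(c("M1", "M1", rep("unassigned", 8)),
                   sprintf("g%02d", 1:10))
  degs <- sprintf("g%02d", 1:5)
  out <- module_overrepresentation(mods, degs, names(mods))
  expect_equal(out$hyper_p, 10 / 45, tolerance = 1e-12)

  # zero overlap has p = 1
  mods2 <- setNames(c("M1", "M1", rep("unassigned", 8)),
                    sprintf("g%02d", 1:10))
  out2 <- module_overrepresentation(mods2, sprintf("g%02d", 5:8),
                                    names(mods2))
  expect_equal(out2$hyper_p, 1)

  # exhaustive oracle sweep over small universes
  for (N in c(4, 9, 17, 33, 60)) {
    for (K in unique(c(0, 1, N %/% 3, N %/% 2, N))) {
      for (n in unique(c(1, N %/% 4 + 1, N %/% 2))) {
        for (k in 0:min(K, n)) {
          expect_equal(gonadnet:::.hyper_upper(k, K, N, n),
                       hyper_tail_bruteforce(k, K, N, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("module overrepresentation flags DEG-rich modules", {
  set.seed(30)
  genes <- sprintf("g%04d", 1:500)
  mods <- setNames(rep("unassigned", 500), genes)
  mods[1:50] <- "rich"     # fully DEG
  mods[51:100] <- "poor"   # DEG-free
  degs <- c(genes[1:50], sample(genes[101:500], 20))
  out <- module_overrepresentation(mods, degs, genes)
  expect_equal(out$module[1], "rich")
  expect_true(out$is_related[out$module == "rich"])
  expect_false(out$is_related[out$module == "poor"])
  expect_equal(out$deg_fraction[out$module == "rich"], 1)
  expect_true(all(out$n_deg_in_module <=
                    pmin(out$module_size, out$n_deg_total)))
  expect_warning(module_overrepresentation(mods, character(0), genes),
                 "empty DEG")
  expect_error(module_overrepresentation(mods, "not_there", genes),
               "subset")
})

test_that("intramodular connectivity sums within-module adjacency", {
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a["a", "b"] <- a["b", "a"] <- 0.5
  a["a", "c"] <- a["c", "a"] <- 0.25
  a["b", "c"] <- a["c", "b"] <- 0.1
  a["a", "d"] <- a["d", "a"] <- 0.9   # d is outside the module
  mods <- c(a = "M1", b = "M1", c = "M1", d = "unassigned")
  kin <- intramodular_connectivity(a, mods)
  expect_equal(unname(kin[c("a", "b", "c")]), c(0.75, 0.6, 0.35))
  expect_equal(unname(kin["d"]), 0)

  full <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(full) <- 0
  expect_equal(unname(intramodular_connectivity(
    full, setNames(rep("M1", 3), letters[1:3]))), rep(2, 3))

  lone <- setNames(c("M1", "M2", "M2"), letters[1:3])
  expect_equal(unname(intramodular_connectivity(full, lone)["a"]), 0)
})

test_that("hub selection takes ceil(fraction * size) with deterministic ties", {
  kin <- setNames(c(4, 3, 2, 1), c("d", "c", "b", "a"))
  mods <- setNames(rep("M1", 4), names(kin))
  out <- select_hubs(kin, mods, fraction = 0.25)
  expect_equal(out$gene[out$is_hub], "d")

  # ceil rule across module sizes, exhaustively
  for (size in c(1, 7, 10, 15, 100, 999)) {
    genes <- sprintf("g%04d", seq_len(size))
    k <- setNames(rev(seq_len(size)), genes)
    hubs <- select_hubs(k, setNames(rep("M1", size), genes))
    expect_equal(sum(hubs$is_hub), ceiling(0.15 * size))
    expect_gte(min(hubs$K_in[hubs$is_hub]),
               max(c(hubs$K_in[!hubs$is_hub], -Inf)))
    expect_equal(sum(hubs$is_top50), min(50, size))
  }

  # equal K_in: ties broken by lexicographic gene id
  tied <- setNames(rep(1, 4), c("g4", "g2", "g3", "g1"))
  out2 <- select_hubs(tied, setNames(rep("M1", 4), names(tied)),
                      fraction = 0.5)
  expect_equal(sort(out2$gene[out2$is_hub]), c("g1", "g2"))
  expect_error(select_hubs(tied, setNames(rep("M1", 4), names(tied)),
                           fraction = 0), "fraction")
})

test_that("module eigengenes summarize member profiles", {
  # identical profiles: the eigengene explains everything
  x <- matrix(rep(c(1, 5, 2, 8), each = 3), 3, 4, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  x <- rbind(x[1, ] + 0, x[1, ] + 1, x[1, ] * 2)
  rownames(x) <- paste0("g", 1:3)
  eg <- module_eigengene(x, setNames(rep("M1", 3), rownames(x)))
  expect_equal(unname(eg$variance_explained["M1"]), 1, tolerance = 1e-12)
  expect_equal(sum(eg$eigengenes["M1", ]^2), 1)

  # two-gene spectra follow the 2x2 gram-matrix eigenvalues: perfectly
  # anticorrelated z-profiles are rank one (eigenvalues {2, 0}, the
  # sign-flipped eigengene carries everything); orthogonal profiles split
  # the spectrum evenly ({1, 1})
  y <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  colnames(y) <- paste0("s", 1:4)
  eg2 <- module_eigengene(y, setNames(rep("M1", 2), rownames(y)))
  expect_equal(unname(eg2$variance_explained["M1"]), 1)

  orth <- rbind(g1 = c(1, 1, -1, -1), g2 = c(1, -1, 1, -1))
  colnames(orth) <- paste0("s", 1:4)
  zo <- t(scale(t(orth)))
  ev <- eigen(tcrossprod(zo))$values     # oracle: 2x2 gram spectrum
  eg4 <- module_eigengene(orth, setNames(rep("M1", 2), rownames(orth)))
  expect_equal(unname(eg4$variance_explained["M1"]), ev[1] / sum(ev))
  expect_equal(unname(eg4$variance_explained["M1"]), 0.5)

  # orientation: mean correlation with member z-profiles is non-negative
  set.seed(5)
  z <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  eg3 <- module_eigengene(z, setNames(rep("M1", 6), rownames(z)))
  zc <- t(scale(t(z)))
  expect_gte(mean(cor(eg3$eigengenes["M1", ], t(zc))), 0)

  withflat <- rbind(z, flat = rep(3, 10))
  expect_warning(module_eigengene(withflat,
                                  setNames(rep("M1", 7),
                                           rownames(withflat))),
                 "zero-variance")
})

test_that("archetype classification recovers the planted patterns", {
  for (seed in 1:5) {
    ds <- small_dataset(seed = seed)
    truth <- truth_assignment(ds)
    eg <- module_eigengene(ds$expression, truth)
    arch <- classify_archetype(eg, ds$design)
    calls <- setNames(arch$archetype, arch$module)
    expect_equal(unname(calls["gonadA"]), "gonad_forming")
    expect_equal(unname(calls["testisA"]), "male_specific")
    expect_equal(unname(calls["ovaryA"]), "female_specific")
  }

  # design-independent eigengenes are usually left unrelated
  n_unrelated <- 0
  for (seed in 1:10) {
    set.seed(seed)
    design <- gonad_design()
    e <- matrix(rnorm(40), 1, 40, dimnames = list("Mx", design$sample_id))
    e <- e / sqrt(sum(e^2))
    if (classify_archetype(e, design)$archetype == "unrelated")
      n_unrelated <- n_unrelated + 1
  }
  expect_gte(n_unrelated, 9)
})

test_that("shared archetype requires a rising trend in both sexes", {
  design <- gonad_design()
  e <- matrix((design$timepoint - 47.5) / 25, 1, 40,
              dimnames = list("Ms", design$sample_id))
  e <- e + rnorm(40, 0, 0.02)
  expect_equal(classify_archetype(e, design)$archetype, "shared")
})

test_that("term enrichment ranks a planted term first and handles edges", {
  genes <- sprintf("g%03d", 1:300)
  module_genes <- genes[1:40]
  ann <- simulate_annotation(genes, n_terms = 30,
                             planted = list(list(term = "TARGET",
                                                 genes = module_genes,
                                                 fold = Inf)),
                             seed = 12)
  enr <- term_enrichment(module_genes, ann, genes)
  expect_equal(enr$term[1], "TARGET")
  expect_true(enr$significant[1])

  allg <- term_enrichment(genes, ann, genes)
  expect_true(all(allg$p_value == 1))
  expect_equal(nrow(term_enrichment(character(0), ann, genes)), 0)

  orphan <- list(ONLY_OUTSIDE = c("zz1", "zz2"))
  expect_message(out <- term_enrichment(module_genes, orphan, genes),
                 "skipped")
  expect_equal(nrow(out), 0)
})
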