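# Module characterization: DEG overrepresentation, intramodular
# connectivity and hub ranking, module eigengenes, archetype classification,
# and generic term enrichment.

# upper-tail hypergeometric P(X >= k) for overlap k, |set| K, universe N,
# draw n
.hyper_upper <- function(k, K, N, n) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric DEG overrepresentation of modules
#'
#' Tests each module (the reserved `"unassigned"` label is excluded) for
#' overrepresentation of differentially expressed genes with an upper-tail
#' hypergeometric test, adjusts across modules with [qvalues()] (which
#' equals Benjamini-Hochberg for the few hypotheses involved), and flags
#' modules with `q < q_threshold` (strict) as related to gonadal
#' development.
#'
#' @param modules Named character vector gene -> module label, as from
#'   [detect_modules()].
#' @param degs Character vector of DEG ids (subset of `universe`).
#' @param universe Character vector, the tested gene universe.
#' @param q_threshold Strict q-value threshold (default 0.1).
#' @return data.frame with one row per module: sizes, overlap counts,
#'   `deg_fraction`, `hyper_p`, `q`, `is_related`.
#' @export
module_overrepresentation <- function(modules, degs, universe,
                                      q_threshold = 0.1) {
  if (!all(degs %in% universe))
    stop("degs must be a subset of the universe", call. = FALSE)
  modules <- modules[names(modules) %in% universe]
  if (!length(degs)) warning("empty DEG set; all p-values are 1")
  labs <- setdiff(sort(unique(modules)), "unassigned")
  N <- length(universe)
  K <- length(degs)
  rows <- lapply(labs, function(lab) {
    members <- names(modules)[modules == lab]
    k <- sum(members %in% degs)
    data.frame(module = lab, module_size = length(members),
               n_deg_in_module = k, universe_size = N, n_deg_total = K,
               deg_fraction = k / length(members),
               hyper_p = .hyper_upper(k, K, N, length(members)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(0), module_size = integer(0),
                      n_deg_in_module = integer(0), universe_size = integer(0),
                      n_deg_total = integer(0), deg_fraction = numeric(0),
                      hyper_p = numeric(0), q = numeric(0),
                      is_related = logical(0)))
  out$q <- as.numeric(qvalues(out$hyper_p))
  out$is_related <- out$q < q_threshold
  out[order(out$hyper_p, out$module), , drop = FALSE]
}

#' Intramodular connectivity
#'
#' `K_in(g)` is the sum of a gene's signed adjacency to the other genes of
#' its own module — its connection strength within the module. Unassigned
#' genes get `K_in = 0`.
#'
#' @param adj Adjacency matrix from [signed_adjacency()] (zero diagonal).
#' @param modules Named character vector gene -> module label.
#' @return Named numeric vector of `K_in` per gene.
#' @export
intramodular_connectivity <- function(adj, modules) {
  genes <- rownames(adj)
  stopifnot(!is.null(genes), all(genes %in% names(modules)))
  lab <- modules[genes]
  kin <- numeric(length(genes))
  names(kin) <- genes
  for (m in setdiff(unique(lab), "unassigned")) {
    idx <- which(lab == m)
    kin[idx] <- rowSums(adj[idx, idx, drop = FALSE])
  }
  kin
}

#' Rank hub genes within each module
#'
#' Within each module the `ceil(fraction * size)` genes with highest
#' intramodular connectivity are the hub genes (top 15% by default). Ties
#' at the boundary are broken deterministically by lexicographic gene id.
#' `is_top50` marks the `min(top_n_heatmap, size)` best-connected genes,
#' the set conventionally visualized as the module heatmap.
#'
#' @param kin Named `K_in` vector from [intramodular_connectivity()].
#' @param modules Named character vector gene -> module label.
#' @param fraction Hub fraction in `(0, 1]` (default 0.15).
#' @param top_n_heatmap Size of the heatmap set (default 50).
#' @return data.frame over assigned genes: `gene`, `module`, `K_in`,
#'   `rank`, `is_hub`, `is_top50`.
#' @export
select_hubs <- function(kin, modules, fraction = 0.15, top_n_heatmap = 50L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  modules <- modules[names(kin)]
  rows <- lapply(setdiff(sort(unique(modules)), "unassigned"), function(m) {
    genes <- names(kin)[modules == m]
    ord <- genes[order(-kin[genes], genes)]
    n_hub <- ceiling(fraction * length(ord))
    data.frame(gene = ord, module = m, K_in = unname(kin[ord]),
               rank = seq_along(ord),
               is_hub = seq_along(ord) <= n_hub,
               is_top50 = seq_along(ord) <= min(top_n_heatmap, length(ord)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Module eigengenes
#'
#' Each module is summarized by its eigengene: genes are z-scored across
#' samples and the first right singular vector over samples is taken, with
#' its sign oriented so the mean correlation with member gene profiles is
#' non-negative. `variance_explained` is the share of the module's
#' (standardized) variance captured by the eigengene.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param modules Named character vector gene -> module label; modules need
#'   at least 2 genes. Zero-variance member genes are dropped with a
#'   warning.
#' @return List with `eigengenes` (module-by-sample matrix, unit-norm rows)
#'   and `variance_explained` (named vector in `[0,1]`).
#' @export
module_eigengene <- function(expr, modules) {
  labs <- setdiff(sort(unique(modules)), "unassigned")
  eg <- matrix(NA_real_, length(labs), ncol(expr),
               dimnames = list(labs, colnames(expr)))
  ve <- setNames(numeric(length(labs)), labs)
  for (m in labs) {
    members <- intersect(names(modules)[modules == m], rownames(expr))
    if (length(members) < 2)
      stop("module ", m, " has fewer than 2 genes in the matrix",
           call. = FALSE)
    z <- expr[members, , drop = FALSE]
    sds <- apply(z, 1L, sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " zero-variance gene(s) from ",
              "module ", m)
      z <- z[sds > 0, , drop = FALSE]
    }
    z <- t(scale(t(z)))
    sv <- svd(z)
    e <- sv$v[, 1L]
    if (mean(cor(e, t(z))) < 0) e <- -e
    eg[m, ] <- e
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, variance_explained = ve)
}

# pooled within-group standard deviation of two sample vectors
.pooled_sd <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
}

#' Classify module expression archetypes
#'
#' Formalizes the visual classification of module heatmap patterns into
#' archetypes, applying rules in order:
#' 1. `gonad_forming` — the eigengene's mean over the early (35-40 dpf,
#'    pre-differentiation) samples exceeds its mean over the mature (55-60
#'    dpf) samples by at least `early_margin` pooled SDs, and the peak
#'    timepoint is 35 or 40 dpf.
#' 2. `male_specific` / `female_specific` — the absolute Cohen's d between
#'    male and female samples (45-60 dpf) reaches `sex_d_threshold`; the
#'    sign gives the direction.
#' 3. `shared` — the eigengene rises with age (Spearman rho vs dpf at least
#'    `trend_rho_threshold`) within both sexes.
#' 4. `unrelated` otherwise.
#'
#' @param eigengenes Module-by-sample matrix from [module_eigengene()] (the
#'   `eigengenes` element, or the full list).
#' @param design Sample design covering the eigengene columns.
#' @param early_margin Early-vs-mature contrast threshold in pooled-SD
#'   units (default 0.5).
#' @param sex_d_threshold Cohen's d threshold for sex specificity
#'   (default 1.5).
#' @param trend_rho_threshold Spearman threshold for a shared maturity
#'   trend (default 0.5).
#' @return data.frame with `module`, `archetype`, and supporting statistics
#'   (`early_contrast`, `sex_cohens_d`, `trend_rho_M`, `trend_rho_F`).
#' @export
classify_archetype <- function(eigengenes, design, early_margin = 0.5,
                               sex_d_threshold = 1.5,
                               trend_rho_threshold = 0.5) {
  if (is.list(eigengenes) && !is.null(eigengenes$eigengenes))
    eigengenes <- eigengenes$eigengenes
  stopifnot(all(colnames(eigengenes) %in% design$sample_id))
  d <- design[match(colnames(eigengenes), design$sample_id), ]
  early <- d$timepoint %in% c(35, 40)
  mature <- d$timepoint %in% c(55, 60)
  sexed <- d$timepoint >= 45 & d$sex %in% c("M", "F")
  if (!any(early) || !any(sexed))
    stop("design must contain early undifferentiated and sexed samples",
         call. = FALSE)

  rows <- lapply(rownames(eigengenes), function(m) {
    e <- eigengenes[m, ]
    tp_means <- tapply(e, d$timepoint, mean)
    psd_early <- .pooled_sd(e[early], e[mature])
    contrast <- (mean(e[early]) - mean(e[mature])) / max(psd_early, 1e-12)
    peak_early <- as.numeric(names(tp_means)[which.max(tp_means)]) <= 40

    eM <- e[sexed & d$sex == "M"]
    eF <- e[sexed & d$sex == "F"]
    cd <- (mean(eM) - mean(eF)) / max(.pooled_sd(eM, eF), 1e-12)
    rho_M <- suppressWarnings(
      cor(eM, d$timepoint[sexed & d$sex == "M"], method = "spearman"))
    rho_F <- suppressWarnings(
      cor(eF, d$timepoint[sexed & d$sex == "F"], method = "spearman"))

    arch <- if (contrast >= early_margin && peak_early) {
      "gonad_forming"
    } else if (abs(cd) >= sex_d_threshold) {
      if (cd > 0) "male_specific" else "female_specific"
    } else if (!is.na(rho_M) && !is.na(rho_F) &&
               rho_M >= trend_rho_threshold && rho_F >= trend_rho_threshold) {
      "shared"
    } else {
      "unrelated"
    }
    data.frame(module = m, archetype = arch, early_contrast = contrast,
               sex_cohens_d = cd, trend_rho_M = rho_M, trend_rho_F = rho_F,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric term enrichment of a gene set
#'
#' Flat upper-tail hypergeometric enrichment of each annotation term in a
#' gene set against a universe, with Benjamini-Hochberg adjustment across
#' terms. Terms with no member in the universe are skipped with a note.
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param annotation Named list term -> gene ids (e.g. from [read_gmt()] or
#'   [simulate_annotation()]).
#' @param universe Character vector, the annotated gene universe.
#' @param q_threshold Strict significance threshold on the adjusted q
#'   (default 0.1).
#' @return data.frame ordered by p: `term`, `term_size`, `overlap`,
#'   `p_value`, `q_value`, `significant`. Empty gene sets or annotations
#'   give an empty table.
#' @export
term_enrichment <- function(gene_set, annotation, universe,
                            q_threshold = 0.1) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe", call. = FALSE)
  empty <- data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0))
  if (!length(annotation) || !length(gene_set)) return(empty)
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(annotation[[term]], universe)
    if (!length(tg)) {
      message("term ", term, " has no genes in the universe; skipped")
      return(NULL)
    }
    k <- sum(gene_set %in% tg)
    data.frame(term = term, term_size = length(tg), overlap = k,
               p_value = .hyper_upper(k, length(tg), N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < q_threshold
  out[order(out$p_value, out$term), , drop = FALSE]
}
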