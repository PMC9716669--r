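# Dating molecular sex differentiation: choose sex-marker hub genes at the
# first morphologically sexed timepoint, cluster all samples on those
# markers, assign a sex to the early undifferentiated samples, and report
# per-timepoint assignment ratios. Also the global sample PCA.

#' Select sex-differentiation marker genes from sex-specific modules
#'
#' From each module classified `male_specific` or `female_specific`, takes
#' its hub genes, keeps those differentially expressed between males and
#' females at the first sexed timepoint (two-sided Welch t-test on
#' `log2(TPM + 1)`, `p < alpha`), ranks them by intramodular connectivity,
#' and returns up to `top_n` markers per module (union over modules).
#'
#' @param hubs Hub table from [select_hubs()].
#' @param expr Gene-by-sample TPM matrix.
#' @param design Sample design; both sexes must be present at `timepoint`.
#' @param archetypes Archetype table from [classify_archetype()]; at least
#'   one male-specific and one female-specific module are required.
#' @param timepoint Testing timepoint in dpf (default 45, the first
#'   morphologically sexed stage).
#' @param alpha Strict per-gene p-value threshold (default 0.05).
#' @param top_n Per-module marker cap (default 40).
#' @return Character vector of marker genes, with the per-module candidate
#'   table in attribute `detail`.
#' @export
select_sex_markers <- function(hubs, expr, design, archetypes,
                               timepoint = 45, alpha = 0.05, top_n = 40L) {
  sex_mods <- archetypes$module[archetypes$archetype %in%
                                  c("male_specific", "female_specific")]
  if (!any(archetypes$archetype == "male_specific") ||
      !any(archetypes$archetype == "female_specific"))
    stop("need at least one male-specific and one female-specific module",
         call. = FALSE)
  d <- design[match(colnames(expr), design$sample_id), ]
  m_idx <- which(d$timepoint == timepoint & d$sex == "M")
  f_idx <- which(d$timepoint == timepoint & d$sex == "F")
  if (!length(m_idx) || !length(f_idx))
    stop("both sexes must be present at ", timepoint, " dpf", call. = FALSE)

  logx <- log2(expr + 1)
  detail <- list()
  markers <- character(0)
  for (mod in sex_mods) {
    cand <- hubs[hubs$module == mod & hubs$is_hub, , drop = FALSE]
    p <- vapply(cand$gene, function(g) {
      tryCatch(t.test(logx[g, m_idx], logx[g, f_idx])$p.value,
               error = function(e) 1)  # constant in both sexes: no evidence
    }, numeric(1))
    keep <- cand[p < alpha, , drop = FALSE]
    keep$p_value <- p[p < alpha]
    if (!nrow(keep)) {
      warning("module ", mod, " contributes no significant hub markers")
      next
    }
    keep <- keep[order(-keep$K_in, keep$gene), , drop = FALSE]
    keep <- head(keep, top_n)
    detail[[mod]] <- keep
    markers <- c(markers, keep$gene)
  }
  markers <- unique(markers)
  attr(markers, "detail") <- do.call(rbind, detail)
  markers
}

#' Cluster samples on marker-gene expression profiles
#'
#' Marker genes are z-scored across samples; samples are clustered by
#' average-linkage hierarchical clustering on the correlation distance
#' `1 - Pearson(r)` between their marker profiles, and the tree is cut into
#' `k` clusters.
#'
#' @param expr Gene-by-sample matrix restricted to the marker genes.
#' @param k Number of clusters (default 3: testes, ovaries,
#'   undifferentiated).
#' @return Named integer vector sample -> cluster id, with the `hclust`
#'   object in attribute `dendrogram`.
#' @export
cluster_samples <- function(expr, k = 3L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (!nrow(expr)) stop("no marker genes supplied", call. = FALSE)
  if (ncol(expr) < k)
    stop("fewer samples than clusters", call. = FALSE)
  z <- t(scale(t(expr)))
  z <- z[apply(expr, 1L, sd) > 0, , drop = FALSE]
  d <- as.dist(1 - cor(z))
  h <- hclust(d, method = "average")
  cl <- cutree(h, k = k)
  attr(cl, "dendrogram") <- h
  cl
}

#' Assign a sex to early undifferentiated samples from marker clustering
#'
#' Each cluster is labelled male, female, or undifferentiated by majority
#' vote of its morphologically sexed (45-60 dpf) members; clusters without
#' sexed members, or with a tied vote, stay undifferentiated. Early (35/40
#' dpf) samples inherit their cluster's label; those in an undifferentiated
#' cluster remain `"unresolved"`. The per-timepoint assignment ratio —
#' assigned early samples over all early samples at that timepoint — is the
#' quantity used to date molecular sex differentiation.
#'
#' @param clusters Named cluster ids from [cluster_samples()].
#' @param design Sample design covering the clustered samples.
#' @return List of class `sex_timing`: `sample_calls` (per sample: cluster,
#'   inferred sex), `ratios` (per early timepoint: `n_assigned`, `n_total`,
#'   `ratio`), and `cluster_labels`.
#' @export
assign_early_sex <- function(clusters, design) {
  d <- design[match(names(clusters), design$sample_id), ]
  labels <- vapply(sort(unique(clusters)), function(cl) {
    sx <- d$sex[clusters == cl & d$timepoint >= 45 & d$sex %in% c("M", "F")]
    if (!length(sx)) return("U")
    votes <- table(sx)
    if (length(votes) > 1 && votes["M"] == votes["F"]) {
      warning("tied sex vote in cluster ", cl, "; left undifferentiated")
      return("U")
    }
    names(votes)[which.max(votes)]
  }, character(1))
  names(labels) <- as.character(sort(unique(clusters)))

  inferred <- labels[as.character(clusters)]
  inferred[!inferred %in% c("M", "F")] <- "unresolved"
  calls <- data.frame(sample_id = names(clusters),
                      timepoint = d$timepoint, sex = d$sex,
                      cluster = as.integer(clusters),
                      inferred_sex = unname(inferred),
                      stringsAsFactors = FALSE)

  early_tps <- sort(unique(d$timepoint[d$sex == "U"]))
  ratios <- do.call(rbind, lapply(early_tps, function(tp) {
    idx <- d$timepoint == tp & d$sex == "U"
    n_assigned <- sum(idx & inferred %in% c("M", "F"))
    data.frame(timepoint = tp, n_assigned = n_assigned,
               n_total = sum(idx), ratio = n_assigned / sum(idx))
  }))
  structure(list(sample_calls = calls, ratios = ratios,
                 cluster_labels = labels),
            class = "sex_timing")
}

#' Principal component analysis of samples
#'
#' Genes are z-scored across samples (zero-variance genes dropped with a
#' warning) and the sample-by-gene matrix is decomposed by SVD. Scores are
#' the sample projections; `variance_explained` fractions sum to 1 over the
#' retained components.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param genes Optional gene subset (default: all genes).
#' @return List with `scores` (samples x components, columns `PC1..`) and
#'   `variance_explained`.
#' @export
sample_pca <- function(expr, genes = NULL) {
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), ,
                                    drop = FALSE]
  if (ncol(expr) < 2) stop("at least 2 samples are required", call. = FALSE)
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2)
    stop("fewer than 2 non-degenerate genes", call. = FALSE)
  m <- scale(t(expr))                # samples x genes, genes z-scored
  sv <- svd(m)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(expr)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  list(scores = scores, variance_explained = sv$d^2 / sum(sv$d^2))
}
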