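# Signed weighted co-expression network construction: Spearman correlation,
# signed soft-thresholded adjacency, scale-free topology diagnostics,
# topological overlap, and module detection on the TOM dissimilarity.

#' Gene-gene Spearman correlation matrix
#'
#' Pairwise Spearman rank correlation between gene expression profiles, with
#' average-rank tie handling. Genes with zero variance across samples get
#' correlation 0 to all other genes (so downstream matrices keep stable
#' dimensions) and are reported in the `zero_variance` attribute.
#'
#' @param expr Gene-by-sample numeric matrix with at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal; attributes
#'   `method = "spearman"` and `zero_variance` (character vector).
#' @export
spearman_correlation <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3)
    stop("at least 3 samples are required", call. = FALSE)
  s <- suppressWarnings(cor(t(expr), method = "spearman"))
  zv <- rownames(expr)[apply(expr, 1L, function(v) var(v) == 0)]
  if (length(zv)) {
    s[is.na(s)] <- 0
  }
  diag(s) <- 1
  attr(s, "method") <- "spearman"
  attr(s, "zero_variance") <- zv
  s
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + s_ij) / 2)^beta`: strong positive correlation maps near 1,
#' strong negative correlation near 0, so the sign of co-expression is
#' preserved. The diagonal is stored as 0 (self-connections are excluded
#' from all connectivity sums).
#'
#' @param cor_mat Correlation matrix, as from [spearman_correlation()].
#' @param beta Positive integer soft-thresholding power (default 15).
#' @return Adjacency matrix in `[0,1]` with zero diagonal and attribute
#'   `beta`.
#' @export
signed_adjacency <- function(cor_mat, beta = 15L) {
  if (length(beta) != 1 || beta < 1)
    stop("beta must be a positive integer", call. = FALSE)
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  attr(a, "beta") <- as.integer(beta)
  attr(a, "signed") <- TRUE
  a
}

# least squares of y on x returning R^2 and slope
.ols_fit <- function(x, y) {
  fit <- lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2L]))
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins whole-network connectivities `k` into `n_bins` equal-width bins,
#' and regresses `log10` of the bin frequency on `log10` of the bin mean
#' connectivity. Approximate scale-free topology shows as a high R-squared
#' with a negative slope.
#'
#' @param connectivities Positive connectivity values (row sums of the
#'   adjacency matrix).
#' @param n_bins Number of equal-width bins (default 10); empty bins are
#'   dropped and at least 2 occupied bins are required.
#' @return List with `r_squared`, `slope`, and the per-bin `fit_table`
#'   (`k_mean`, `freq`).
#' @export
scale_free_fit <- function(connectivities, n_bins = 10L) {
  k <- connectivities[is.finite(connectivities)]
  if (length(k) < 2 || diff(range(k)) == 0)
    stop("degenerate connectivity distribution", call. = FALSE)
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  k_mean <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  occ <- !is.na(k_mean) & k_mean > 0
  if (sum(occ) < 2)
    stop("degenerate connectivity distribution", call. = FALSE)
  fit <- .ols_fit(log10(k_mean[occ]), log10(freq[occ]))
  c(fit, list(fit_table = data.frame(k_mean = as.numeric(k_mean[occ]),
                                     freq = as.numeric(freq[occ]))))
}

#' Choose the soft-thresholding power for approximate scale-free topology
#'
#' Evaluates the scale-free fit of the signed adjacency over candidate
#' powers and returns the smallest power whose fit reaches `target_r2` with
#' a negative slope. If no candidate qualifies, the candidate with maximal
#' R-squared is returned with a warning.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param candidates Candidate integer powers (default 1..20).
#' @param target_r2 Required model fitting index R-squared (default 0.75).
#' @param n_bins Passed to [scale_free_fit()].
#' @return The chosen power (integer) with the per-candidate fit table in
#'   attribute `fits`.
#' @export
pick_soft_power <- function(expr, candidates = 1:20, target_r2 = 0.75,
                            n_bins = 10L) {
  if (!length(candidates)) stop("no candidate powers", call. = FALSE)
  s <- spearman_correlation(expr)
  fits <- data.frame(power = as.integer(candidates), r_squared = NA_real_,
                     slope = NA_real_)
  for (i in seq_along(candidates)) {
    a <- signed_adjacency(s, candidates[i])
    f <- tryCatch(scale_free_fit(rowSums(a), n_bins), error = function(e) NULL)
    if (!is.null(f)) {
      fits$r_squared[i] <- f$r_squared
      fits$slope[i] <- f$slope
    }
  }
  ok <- !is.na(fits$r_squared) & fits$r_squared >= target_r2 & fits$slope < 0
  if (any(ok)) {
    power <- fits$power[which(ok)[1L]]
  } else {
    if (all(is.na(fits$r_squared)))
      stop("scale-free fit failed for every candidate power", call. = FALSE)
    power <- fits$power[which.max(fits$r_squared)]
    warning("no candidate power reaches R^2 >= ", target_r2,
            " with negative slope; returning the best-fitting power ", power)
  }
  attr(power, "fits") <- fits
  power
}

#' Topological overlap matrix and dissimilarity
#'
#' For adjacency `a` with connectivities `k_i = sum_j a_ij`, the topological
#' overlap is
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over third genes `u`, and `w_ii = 1`. Two genes
#' overlap strongly when they are connected and share neighbours. The
#' clustering dissimilarity is `1 - w`.
#'
#' @param adj Adjacency matrix from [signed_adjacency()] (zero diagonal).
#' @return List with `tom` (the overlap matrix) and `diss` (`1 - tom`).
#' @export
topological_overlap <- function(adj) {
  a <- as.matrix(adj)
  if (any(a < 0 | a > 1)) stop("adjacency outside [0,1]", call. = FALSE)
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                     # diagonal of a is 0, so u != i, j terms only
  denom <- outer(k, k, pmin) + 1 - a
  w <- (l + a) / denom
  diag(w) <- 1
  if (any(w < -1e-10 | w > 1 + 1e-10))
    stop("internal consistency error: TOM outside [0,1]", call. = FALSE)
  w[w < 0] <- 0
  w[w > 1] <- 1
  dimnames(w) <- dimnames(a)
  list(tom = w, diss = 1 - w)
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' topological-overlap dissimilarity and modules are identified by dynamic
#' branch decomposition of the dendrogram: a subtree is a module when it
#' completes below `detect_cut_height`, contains at least
#' `min_module_size` genes, and is separated from its surroundings by a
#' clear merge-height gap — the height at which it joins the rest of the
#' tree exceeds its own top internal merge by at least `min_branch_gap`.
#' Maximal such subtrees are taken, so a tight branch is reported whole.
#' This adaptive rule is needed because in TOM dendrograms nearly all genes
#' eventually merge just below any practical cut height; a plain static cut
#' returns one giant cluster (which is why dynamic tree cutting is the
#' field's standard). Modules are relabelled `M1..Mk` in order of
#' decreasing size; all remaining genes receive the reserved label
#' `"unassigned"` (the grey genes).
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal, as
#'   `topological_overlap(adj)$diss`.
#' @param min_module_size Minimum module size (default 100).
#' @param detect_cut_height Maximum merge height for a module branch
#'   (default 0.99).
#' @param min_branch_gap Minimum separation, in dissimilarity units,
#'   between a branch's completion height and its attachment to the rest of
#'   the tree (default 0.02). Real module branches in TOM trees separate by
#'   an order of magnitude more; unclustered genes merge in a near
#'   continuum with gaps an order of magnitude smaller.
#' @return Named character vector gene -> module label, with attributes
#'   `dendrogram` (the `hclust` object), `min_module_size` and
#'   `detect_cut_height`.
#' @export
detect_modules <- function(diss, min_module_size = 100L,
                           detect_cut_height = 0.99,
                           min_branch_gap = 0.02) {
  d <- as.matrix(diss)
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-8))
    stop("dissimilarity must be symmetric with zero diagonal", call. = FALSE)
  genes <- rownames(d)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(d)))
  n <- nrow(d)
  h <- hclust(as.dist(d), method = "average")
  labels <- rep("unassigned", n)
  names(labels) <- genes

  if (min_module_size > n) {
    warning("min_module_size exceeds the number of genes; all unassigned")
  } else {
    n_nodes <- nrow(h$merge)
    leaves <- vector("list", n_nodes)   # leaf indices under each merge node
    size <- integer(n_nodes)
    parent_h <- rep(Inf, n_nodes)       # height at which node joins the rest
    for (i in seq_len(n_nodes)) {
      kids <- h$merge[i, ]
      leaves[[i]] <- unlist(lapply(kids, function(k)
        if (k < 0) -k else leaves[[k]]))
      size[i] <- length(leaves[[i]])
      for (k in kids[kids > 0]) parent_h[k] <- h$height[i]
    }
    qualifies <- h$height <= detect_cut_height &
      size >= min_module_size &
      (parent_h - h$height) >= min_branch_gap
    # keep maximal qualifying subtrees: drop nodes with a qualifying
    # ancestor (parents always carry a larger index than their children)
    flagged <- rep(FALSE, n_nodes)
    for (i in rev(seq_len(n_nodes))) {
      kids <- h$merge[i, ][h$merge[i, ] > 0]
      flagged[kids] <- flagged[i] | qualifies[i]
    }
    chosen <- which(qualifies & !flagged)
    if (length(chosen)) {
      ord <- chosen[order(-size[chosen],
                          vapply(leaves[chosen], min, numeric(1)))]
      for (i in seq_along(ord)) {
        labels[leaves[[ord[i]]]] <- sprintf("M%d", i)
      }
    }
  }
  attr(labels, "dendrogram") <- h
  attr(labels, "min_module_size") <- as.integer(min_module_size)
  attr(labels, "detect_cut_height") <- detect_cut_height
  attr(labels, "min_branch_gap") <- min_branch_gap
  labels
}
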