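# Per-gene one-way ANOVA across sample groups and q-value FDR control.

#' Vectorized per-gene one-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA of each gene's expression values
#' across the sample groups, computed row-wise:
#' `F = (SSB / (g - 1)) / (SSW / (n - g))`, with the p-value from the upper
#' tail of the F distribution. Values are analysed as provided; apply any
#' variance-stabilizing transform (e.g. `log2(TPM + 1)`) beforehand.
#'
#' Degenerate rows are handled explicitly: zero between-group variation
#' gives `F = 0, p = 1`; zero within-group variation with between-group
#' signal gives the smallest representable positive p and is flagged.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @return data.frame with `gene`, `F_statistic`, `p_value`, `degenerate`.
#' @export
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 2, 3, 4))
#' anova_per_gene(x, rep(c("A", "B"), each = 3))
anova_per_gene <- function(expr, groups) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(expr))
  tab <- table(groups)
  if (length(tab) < 2) stop("at least 2 groups are required", call. = FALSE)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)

  n <- ncol(expr)
  g <- length(tab)
  design <- outer(groups, names(tab), "==") * 1  # n x g indicator
  n_j <- colSums(design)
  grand <- rowMeans(expr)
  means <- (expr %*% design) / matrix(n_j, nrow(expr), g, byrow = TRUE)
  ssb <- rowSums(sweep(means, 1L, grand, "-")^2 *
                   matrix(n_j, nrow(expr), g, byrow = TRUE))
  sstot <- rowSums(sweep(expr, 1L, grand, "-")^2)
  ssw <- pmax(sstot - ssb, 0)

  Fstat <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- pf(Fstat, g - 1, n - g, lower.tail = FALSE)
  degenerate <- ssw <= .Machine$double.eps * pmax(sstot, 1) & ssb > 0
  no_signal <- ssb <= .Machine$double.eps * pmax(sstot, 1)
  Fstat[no_signal] <- 0
  p[no_signal] <- 1
  p[degenerate] <- .Machine$double.xmin
  Fstat[degenerate] <- Inf

  data.frame(gene = rownames(expr), F_statistic = Fstat, p_value = p,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' q-values for false discovery rate control
#'
#' `method = "storey"` estimates the proportion of true nulls `pi0` by the
#' cubic-spline smoother over the tuning grid `lambda = 0.05, ..., 0.95`
#' and sets `q_i = min over p_j >= p_i of pi0 * m * p_j / rank_j`, clipped
#' to `[0,1]`. With fewer than 100 p-values the spline is unstable, so
#' `pi0` falls back to 1 and the result equals the Benjamini-Hochberg
#' adjustment. `method = "bh"` is the standard step-up adjustment
#' (delegated to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0,1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Tuning grid for the `pi0` smoother.
#' @return q-values in input order; for `"storey"` the `pi0` estimate is
#'   attached as an attribute.
#' @export
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh")
qvalues <- function(p_values, method = c("storey", "bh"),
                    lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  if (method == "bh") return(p.adjust(p, method = "BH"))

  m <- length(p)
  if (m < 100) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    ss <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(ss, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- pmin(cummin(pi0 * m * p[ord] / rank(p, ties.method = "max")[ord]), 1)
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially expressed genes at a q-value threshold
#'
#' @param results data.frame with columns `gene` and `q_value`.
#' @param q_threshold Strict threshold: a gene is a DEG iff `q < q_threshold`
#'   (default 0.01).
#' @return List with `genes` (character vector) and `n`.
#' @export
call_degs <- function(results, q_threshold = 0.01) {
  stopifnot(all(c("gene", "q_value") %in% names(results)))
  genes <- results$gene[results$q_value < q_threshold]
  list(genes = genes, n = length(genes))
}

#' Per-gene differential expression across design groups
#'
#' Convenience wrapper: transforms TPM, runs [anova_per_gene()] on the
#' design groups, attaches q-values and the DEG call.
#'
#' @param expr Gene-by-sample TPM matrix.
#' @param design Sample design (needs `sample_id`, `group`).
#' @param transform `"log2p1"` (default, `log2(TPM + 1)`) or `"none"`.
#' @param method q-value method, see [qvalues()].
#' @param q_threshold DEG threshold on the q-value (strict, default 0.01).
#' @return data.frame with `gene`, `F_statistic`, `p_value`, `q_value`,
#'   `is_deg`.
#' @export
differential_expression <- function(expr, design,
                                    transform = c("log2p1", "none"),
                                    method = c("storey", "bh"),
                                    q_threshold = 0.01) {
  transform <- match.arg(transform)
  stopifnot(all(colnames(expr) %in% design$sample_id))
  x <- if (transform == "log2p1") log2(expr + 1) else expr
  groups <- design$group[match(colnames(expr), design$sample_id)]
  res <- anova_per_gene(x, groups)
  res$q_value <- as.numeric(qvalues(res$p_value, method = match.arg(method)))
  res$is_deg <- res$q_value < q_threshold
  res$degenerate <- NULL
  res
}
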