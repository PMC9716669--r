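#' Default gonadal time-course sampling design
#'
#' Builds the 40-sample design used throughout the package: six timepoints
#' (35-60 dpf every 5 days), sexually undifferentiated gonads at 35 and 40
#' dpf (6 replicates each), and sexed testis/ovary samples at 45-60 dpf
#' (3 replicates per sex at 45/50/55 dpf, 5 per sex at 60 dpf). Each
#' timepoint-by-sex combination is one of 10 sample groups.
#'
#' Undifferentiated samples additionally carry a `latent_sex` column: the
#' (unobserved) genetic sex the simulator uses once molecular divergence has
#' started. It is balanced 3 male / 3 female within each early timepoint.
#'
#' @return A data.frame with columns `sample_id`, `timepoint` (dpf), `sex`
#'   (`"M"`, `"F"` or `"U"`), `replicate`, `group`, and `latent_sex`.
#' @export
#' @examples
#' design <- gonad_design()
#' table(design$group)
gonad_design <- function() {
  rows <- list()
  for (tp in c(35L, 40L)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%ddpf_U%d", tp, 1:6),
      timepoint = tp, sex = "U", replicate = 1:6,
      group = sprintf("%ddpf", tp),
      latent_sex = rep(c("M", "F"), 3L),
      stringsAsFactors = FALSE
    )
  }
  for (tp in c(45L, 50L, 55L, 60L)) {
    n <- if (tp == 60L) 5L else 3L
    for (sx in c("M", "F")) {
      suff <- if (sx == "M") "T" else "O"
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%ddpf_%s%d", tp, suff, seq_len(n)),
        timepoint = tp, sex = sx, replicate = seq_len(n),
        group = sprintf("%ddpf_%s", tp, suff),
        latent_sex = sx,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

.archetypes <- c("gonad_forming", "testis_specific", "ovary_specific",
                 "shared", "unrelated")

#' Default planted-module specification
#'
#' One module per archetype, sized within the range typical of gonadal
#' co-expression modules: an early gonad-forming module, a testis-specific
#' and an ovary-specific module diverging at `divergence_tp`, a sexually
#' shared module rising with maturity, and a co-expressed module unrelated
#' to gonadal development.
#'
#' @param effect_size Template amplitude in log2-expression units.
#' @param divergence_tp Timepoint (dpf) at which the sex-specific templates
#'   separate; 35 dpf by default, i.e. molecular sex divergence precedes
#'   morphological sexing at 45 dpf.
#' @return A list of module specifications (`module_id`, `n_genes`,
#'   `archetype`, `effect_size`, `divergence_tp`).
#' @export
default_modules <- function(effect_size = 4, divergence_tp = 35) {
  base <- list(
    list(module_id = "gonad1",  n_genes = 150L, archetype = "gonad_forming"),
    list(module_id = "testis1", n_genes = 140L, archetype = "testis_specific"),
    list(module_id = "ovary1",  n_genes = 140L, archetype = "ovary_specific"),
    list(module_id = "shared1", n_genes = 160L, archetype = "shared"),
    list(module_id = "noise1",  n_genes = 130L, archetype = "unrelated")
  )
  lapply(base, function(m) {
    m$effect_size <- effect_size
    m$divergence_tp <- divergence_tp
    m
  })
}

# Piecewise-constant archetype template on the log2 scale, per sample.
# Templates are zero-centered deviations in [-1/2, +1/2], so effect_size is
# the peak-to-trough log2 amplitude and planted signal redistributes
# transcriptome mass rather than adding it (TPM is compositional; one-sided
# templates would shift whole-sample column sums by group and distort every
# background gene). Sex-specific templates use the latent sex of
# undifferentiated samples.
.template_value <- function(archetype, timepoint, sex_eff, divergence_tp) {
  switch(archetype,
    gonad_forming = ifelse(timepoint <= 40, 0.5, -0.5),
    testis_specific = ifelse(timepoint >= divergence_tp,
                             ifelse(sex_eff == "M", 0.5, -0.5), 0),
    ovary_specific = ifelse(timepoint >= divergence_tp,
                            ifelse(sex_eff == "F", 0.5, -0.5), 0),
    shared = (timepoint - 35) / 25 - 0.5,
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

#' Simulate a gonadal time-course expression dataset with planted modules
#'
#' Generates a gene-by-sample TPM matrix over the supplied design, with
#' planted co-expression modules of five archetypes and full ground truth.
#' Each planted gene's log2 expression is
#' `baseline + effect_size * template(timepoint, sex) + N(0, noise_sd)`;
#' background genes are noise around a gene-specific baseline. Templates are
#' piecewise-constant over timepoints and zero-centered, with `effect_size`
#' the peak-to-trough log2 amplitude: gonad-forming modules are high at
#' 35-40 dpf and low after; sex-specific modules are flat before
#' `divergence_tp` and split by (latent) sex afterwards; shared modules ramp
#' up monotonically with age in both sexes. The `unrelated` archetype is
#' driven by a per-sample latent factor drawn independently of the design,
#' so it forms a genuine co-expression module carrying no developmental
#' signal. Values are exponentiated to the linear scale and each sample is
#' rescaled to sum to 1e6 (TPM).
#'
#' @param design Sampling design, as from [gonad_design()].
#' @param modules Planted-module specification, as from [default_modules()].
#'   Each element needs `module_id`, `archetype`, `effect_size`, and either
#'   `n_genes` or an explicit character vector `genes`; sex-specific
#'   archetypes also use `divergence_tp`.
#' @param n_background Number of template-free background genes; the default
#'   tops the universe up to 2,000 genes.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   dataset bit-for-bit.
#' @param baseline_mean,baseline_sd Per-gene baseline log2-TPM distribution.
#' @return A list of class `gonad_dataset`: `expression` (genes x samples,
#'   TPM), `design`, `truth` (module specs with `member_genes` filled in),
#'   and `seed`.
#' @export
#' @examples
#' ds <- simulate_expression(seed = 1)
#' dim(ds$expression)
simulate_expression <- function(design = gonad_design(),
                                modules = default_modules(),
                                n_background = NULL,
                                noise_sd = 0.5,
                                seed = 1L,
                                baseline_mean = 5,
                                baseline_sd = 2) {
  stopifnot(is.data.frame(design), nrow(design) >= 2)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  for (m in modules) {
    if (!m$archetype %in% .archetypes)
      stop("unknown archetype: ", m$archetype, call. = FALSE)
    n_m <- if (!is.null(m$genes)) length(m$genes) else m$n_genes
    if (n_m < 2) stop("module sizes must be >= 2", call. = FALSE)
  }

  n_mod_genes <- sum(vapply(modules, function(m)
    if (!is.null(m$genes)) length(m$genes) else as.integer(m$n_genes),
    integer(1)))
  if (is.null(n_background)) n_background <- max(0L, 2000L - n_mod_genes)

  # assign gene ids: explicit ids kept, the rest drawn from a g%04d series
  explicit <- unlist(lapply(modules, function(m) m$genes))
  if (anyDuplicated(explicit))
    stop("overlapping module gene ids", call. = FALSE)
  auto_needed <- sum(vapply(modules, function(m)
    if (is.null(m$genes)) as.integer(m$n_genes) else 0L, integer(1))) +
    n_background
  auto_ids <- setdiff(sprintf("g%05d", seq_len(auto_needed + length(explicit))),
                      explicit)[seq_len(auto_needed)]
  nxt <- 1L
  truth <- list()
  for (m in modules) {
    if (is.null(m$genes)) {
      m$genes <- auto_ids[nxt:(nxt + m$n_genes - 1L)]
      nxt <- nxt + m$n_genes
    }
    m$n_genes <- length(m$genes)
    truth[[m$module_id]] <- m
  }
  background <- if (n_background > 0) auto_ids[nxt:(nxt + n_background - 1L)]
                else character(0)
  all_ids <- unlist(lapply(truth, function(m) m$genes), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("overlapping module gene ids", call. = FALSE)
  genes <- c(all_ids, background)
  n_genes <- length(genes)
  n_samp <- nrow(design)
  sex_eff <- ifelse(design$sex == "U", design$latent_sex, design$sex)

  set.seed(as.integer(seed))
  baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
  names(baseline) <- genes
  logx <- matrix(baseline, n_genes, n_samp)

  for (m in truth) {
    idx <- match(m$genes, genes)
    if (m$archetype == "unrelated") {
      # sample-level latent factor, design-independent, amplitude-matched
      # to the other archetypes
      tmpl <- rnorm(n_samp, sd = 0.5)
    } else {
      tmpl <- .template_value(m$archetype, design$timepoint, sex_eff,
                              m$divergence_tp)
    }
    logx[idx, ] <- logx[idx, ] +
      matrix(m$effect_size * tmpl, length(idx), n_samp, byrow = TRUE)
  }
  logx <- logx + matrix(rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp)

  x <- 2^logx
  x <- sweep(x, 2L, colSums(x) / 1e6, "/")
  dimnames(x) <- list(genes, design$sample_id)
  attr(x, "unit") <- "TPM"

  structure(list(expression = x, design = design, truth = truth,
                 seed = as.integer(seed)),
            class = "gonad_dataset")
}

#' Planted module assignment from simulation ground truth
#'
#' @param dataset A `gonad_dataset` from [simulate_expression()].
#' @return Named character vector mapping every gene to its planted module
#'   id, with background genes labelled `"unassigned"`.
#' @export
truth_assignment <- function(dataset) {
  genes <- rownames(dataset$expression)
  lab <- rep("unassigned", length(genes))
  names(lab) <- genes
  for (m in dataset$truth) lab[m$genes] <- m$module_id
  lab
}

#' Simulate FASTQ reads with planted QC failures
#'
#' Produces `n_reads` random reads of which exactly
#' `round(n_reads * frac_with_N)` contain at least one undetermined base
#' (`N`) and exactly `round(n_reads * frac_lowq_excess)` N-free reads carry
#' 11 positions with Phred quality < 20 (one more than the filter's default
#' allowance). All remaining reads pass [filter_reads()] at its defaults.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (>= 12 when low-quality reads are
#'   planted).
#' @param frac_with_N,frac_lowq_excess Planted failure fractions in `[0,1]`,
#'   summing to at most 1.
#' @param seed Integer seed.
#' @return A data.frame with columns `read_id`, `sequence`, and `quality`
#'   (Phred+33 string), plus a `planted` column giving each read's status
#'   (`"pass"`, `"with_N"`, `"lowq"`).
#' @export
simulate_fastq <- function(n_reads, read_len = 150L, frac_with_N = 0,
                           frac_lowq_excess = 0, seed = 1L) {
  stopifnot(n_reads >= 1, read_len >= 1)
  if (frac_with_N < 0 || frac_with_N > 1 ||
      frac_lowq_excess < 0 || frac_lowq_excess > 1 ||
      frac_with_N + frac_lowq_excess > 1)
    stop("planted fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (read_len < 12 && frac_lowq_excess > 0)
    stop("read_len < 12: cannot plant 11 low-quality positions",
         call. = FALSE)

  n_N <- round(n_reads * frac_with_N)
  n_low <- round(n_reads * frac_lowq_excess)
  set.seed(as.integer(seed))
  status <- sample(rep(c("with_N", "lowq", "pass"),
                       c(n_N, n_low, n_reads - n_N - n_low)))

  bases <- c("A", "C", "G", "T")
  seqs <- quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- sample(bases, read_len, replace = TRUE)
    q <- sample(25:40, read_len, replace = TRUE)  # passes both rules
    if (status[i] == "with_N") {
      s[sample.int(read_len, sample(1:3, 1))] <- "N"
    } else if (status[i] == "lowq") {
      q[sample.int(read_len, 11L)] <- sample(2:19, 11L, replace = TRUE)
    }
    seqs[i] <- paste(s, collapse = "")
    quals[i] <- intToUtf8(q + 33L)
  }
  data.frame(read_id = sprintf("read_%05d", seq_len(n_reads)),
             sequence = seqs, quality = quals, planted = status,
             stringsAsFactors = FALSE)
}

#' Simulate a gene-to-term annotation map
#'
#' Builds a GMT-writable term-to-gene map over a gene universe. Unplanted
#' terms sample genes uniformly; each planted term over-samples its target
#' subset with the stated enrichment fold (sampling weight `fold` for target
#' genes, 1 elsewhere).
#'
#' @param genes Character vector, the gene universe.
#' @param n_terms Number of background terms.
#' @param planted List of planted terms, each a list with `term`, `genes`
#'   (subset of the universe), `fold` (>= 1; `Inf` takes exactly the
#'   subset), and optionally `size` (defaults to the subset size).
#' @param term_size_range Size range for background terms.
#' @param seed Integer seed.
#' @return Named list mapping term ids to gene-id vectors.
#' @export
simulate_annotation <- function(genes, n_terms, planted = list(),
                                term_size_range = c(10L, 50L), seed = 1L) {
  for (p in planted) {
    if (!all(p$genes %in% genes))
      stop("planted subset is not contained in the gene universe",
           call. = FALSE)
    if (is.null(p$fold) || p$fold < 1)
      stop("enrichment fold must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- list()
  if (n_terms > 0) {
    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms,
                    replace = TRUE)
    for (i in seq_len(n_terms)) {
      out[[sprintf("TERM%04d", i)]] <- sort(sample(genes, sizes[i]))
    }
  }
  for (p in planted) {
    size <- if (is.null(p$size)) length(p$genes) else p$size
    if (is.infinite(p$fold)) {
      out[[p$term]] <- sort(p$genes)
    } else {
      w <- ifelse(genes %in% p$genes, p$fold, 1)
      out[[p$term]] <- sort(sample(genes, size, prob = w))
    }
  }
  out
}
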