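#' Simulation configuration for planted pathway-crosstalk data
#'
#' Describes a synthetic expression experiment with two latent pathway
#' activity signals z1 and z2 of length `n_samples`: pathway-k genes follow
#' `loading * zk` plus gene-level Gaussian noise; planted shared
#' intermediaries follow `loading * (z1 + z2)/sqrt(2)` (unit-variance additive
#' load on both signals); single-signal intermediaries load on one signal
#' only; noise genes are independent standard normal. Three conditions are
#' produced: `"WT"` with both signals and `"KO1"`/`"KO2"` in which the
#' corresponding signal is abolished — each affected gene's signal component
#' is replaced by its own independent standard-normal series, so the
#' coherence the signal induced collapses.
#'
#' @param n_samples number of samples T (columns); at least 6 recommended.
#' @param n_pathway1,n_pathway2 pathway gene counts.
#' @param n_shared planted intermediaries loading on both signals.
#' @param n_p1_only,n_p2_only intermediaries loading on one signal.
#' @param n_noise independent noise genes.
#' @param loading signal coefficient.
#' @param noise_sd standard deviation of gene-level noise added to every
#'   signal-bearing gene.
#' @param signal_model `"smooth_curve"` (random spline over ordered samples,
#'   emulating a stimulation time course) or `"ar1"` (autoregressive series
#'   with coefficient 0.8, emulating unordered population samples).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 30, n_pathway1 = 10, n_pathway2 = 10,
                       n_shared = 15, n_p1_only = 5, n_p2_only = 5,
                       n_noise = 300, loading = 1, noise_sd = 0.25,
                       signal_model = c("smooth_curve", "ar1"), seed = 1) {
  signal_model <- match.arg(signal_model)
  cfg <- list(n_samples = as.integer(n_samples),
              n_pathway1 = as.integer(n_pathway1),
              n_pathway2 = as.integer(n_pathway2),
              n_shared = as.integer(n_shared),
              n_p1_only = as.integer(n_p1_only),
              n_p2_only = as.integer(n_p2_only),
              n_noise = as.integer(n_noise),
              loading = loading, noise_sd = noise_sd,
              signal_model = signal_model, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_pathway1", "n_pathway2", "n_shared", "n_p1_only",
                         "n_p2_only", "n_noise")])
  stopifnot(cfg$n_samples >= 3, all(counts >= 0), cfg$noise_sd >= 0,
            cfg$n_pathway1 >= 1, cfg$n_pathway2 >= 1)
  if (sum(counts) == 0) stop("degenerate config: all gene counts zero")
  structure(cfg, class = "sim_config")
}

# one latent signal, standardized to mean 0 / sd 1 over the T samples
draw_signal <- function(T, model) {
  s <- switch(model,
    smooth_curve = {
      k <- max(4, min(8, floor(T / 4)))
      stats::spline(seq(1, T, length.out = k), stats::rnorm(k),
                    xout = seq_len(T))$y
    },
    ar1 = {
      phi <- 0.8
      e <- stats::rnorm(T)
      x <- numeric(T)
      x[1] <- e[1] / sqrt(1 - phi^2)
      for (t in seq_len(T)[-1]) x[t] <- phi * x[t - 1] + e[t]
      x
    })
  if (stats::sd(s) == 0) s <- s + stats::rnorm(T, sd = 1e-6)
  (s - mean(s)) / stats::sd(s)
}

#' Simulate expression matrices with planted crosstalk structure
#'
#' Generates one z-scored [expression_matrix()] per condition (`WT`, `KO1`,
#' `KO2`) plus the ground truth of the planted structure. All randomness
#' derives from `config$seed` through an isolated RNG stream; the caller's
#' RNG state is untouched and the same config always yields bit-identical
#' matrices.
#'
#' @param config a [sim_config()].
#' @return list with `matrices` (named list of [expression_matrix()]) and
#'   `truth` (a `synthetic_truth`: gene-id sets `pathway1_genes`,
#'   `pathway2_genes`, `planted_shared`, `planted_p1_only`,
#'   `planted_p2_only`, `noise_genes`, and the `config`).
#' @export
simulate_crosstalk <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  T <- config$n_samples
  z1 <- draw_signal(T, config$signal_model)
  z2 <- draw_signal(T, config$signal_model)

  ids <- list(
    pathway1_genes  = sprintf("P1_%03d", seq_len(config$n_pathway1)),
    pathway2_genes  = sprintf("P2_%03d", seq_len(config$n_pathway2)),
    planted_shared  = if (config$n_shared) sprintf("SH_%03d", seq_len(config$n_shared)) else character(),
    planted_p1_only = if (config$n_p1_only) sprintf("I1_%03d", seq_len(config$n_p1_only)) else character(),
    planted_p2_only = if (config$n_p2_only) sprintf("I2_%03d", seq_len(config$n_p2_only)) else character(),
    noise_genes     = if (config$n_noise) sprintf("NS_%03d", seq_len(config$n_noise)) else character())

  # per-gene loadings on (z1, z2)
  w <- rbind(
    matrix(rep(c(1, 0), each = config$n_pathway1), ncol = 2),
    matrix(rep(c(0, 1), each = config$n_pathway2), ncol = 2),
    matrix(rep(c(1, 1) / sqrt(2), each = config$n_shared), ncol = 2),
    matrix(rep(c(1, 0), each = config$n_p1_only), ncol = 2),
    matrix(rep(c(0, 1), each = config$n_p2_only), ncol = 2),
    matrix(rep(c(0, 0), each = config$n_noise), ncol = 2))
  gene_ids <- unlist(ids, use.names = FALSE)
  rownames(w) <- gene_ids

  build_condition <- function(cond, ko) {
    vals <- matrix(0, length(gene_ids), T,
                   dimnames = list(gene_ids, sprintf("S%02d", seq_len(T))))
    for (i in seq_along(gene_ids)) {
      s1 <- if (ko == 1 && w[i, 1] != 0) stats::rnorm(T) else z1
      s2 <- if (ko == 2 && w[i, 2] != 0) stats::rnorm(T) else z2
      signal <- config$loading * (w[i, 1] * s1 + w[i, 2] * s2)
      noise <- if (all(w[i, ] == 0)) stats::rnorm(T)
               else stats::rnorm(T, sd = config$noise_sd)
      vals[i, ] <- signal + noise
    }
    # z-score rows; guard exact duplicates of a constant profile (noise_sd=0
    # leaves signal rows varying, so zero variance cannot occur here)
    sds <- apply(vals, 1, stats::sd)
    vals <- (vals - rowMeans(vals)) / sds
    expression_matrix(vals, condition = cond, stage = "zscore")
  }

  matrices <- list(WT = build_condition("WT", 0),
                   KO1 = build_condition("KO1", 1),
                   KO2 = build_condition("KO2", 2))
  truth <- structure(c(ids, list(config = config)), class = "synthetic_truth")
  list(matrices = matrices, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d+%d pathway, %d shared, %d+%d single-signal, %d noise genes (T=%d, noise_sd=%g, %s)\n",
    length(x$pathway1_genes), length(x$pathway2_genes),
    length(x$planted_shared), length(x$planted_p1_only),
    length(x$planted_p2_only), length(x$noise_genes),
    x$config$n_samples, x$config$noise_sd, x$config$signal_model))
  invisible(x)
}

#' Pathway pair implied by a synthetic truth
#'
#' @param truth a `synthetic_truth`.
#' @return a [build_predictor_pool()] pathway pair over the simulated
#'   universe.
#' @export
truth_pathway_pair <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  universe <- c(truth$pathway1_genes, truth$pathway2_genes,
                truth$planted_shared, truth$planted_p1_only,
                truth$planted_p2_only, truth$noise_genes)
  build_predictor_pool(universe, truth$pathway1_genes, truth$pathway2_genes)
}

#' Score recovery of a planted gene set
#'
#' Precision, recall and F1 of a predicted set against the truth. Degenerate
#' conventions: an empty prediction has precision 1 if the truth is also
#' empty, otherwise 0; recall is 1 when the truth is empty; F1 is 0 when
#' precision + recall is 0.
#'
#' @param predicted,truth_positive character vectors of gene ids, both
#'   subsets of `universe`.
#' @param universe all gene ids under consideration.
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
evaluate_recovery <- function(predicted, truth_positive, universe) {
  predicted <- unique(as.character(predicted))
  truth_positive <- unique(as.character(truth_positive))
  if (length(setdiff(predicted, universe)))
    stop("predicted genes outside the universe")
  if (length(setdiff(truth_positive, universe)))
    stop("truth genes outside the universe")
  tp <- length(intersect(predicted, truth_positive))
  precision <- if (length(predicted) == 0) {
    if (length(truth_positive) == 0) 1 else 0
  } else tp / length(predicted)
  recall <- if (length(truth_positive) == 0) 1 else tp / length(truth_positive)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
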