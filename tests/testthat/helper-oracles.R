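# Independent oracles and fixture builders used across the test files.

# Worst violation of the elastic-net stationarity (KKT) conditions for one
# path point of the objective RSS/(2T) + s*(mix*|w|_1 + (1-mix)/2*|w|_2^2).
kkt_violation <- function(X, y, beta, intercept, s, mixing) {
  T <- length(y)
  r <- as.numeric(y - intercept - X %*% beta)
  g <- as.numeric(crossprod(X, r)) / T
  act <- which(beta != 0)
  ina <- which(beta == 0)
  v <- abs(mean(r)) # intercept stationarity
  if (length(act))
    v <- max(v, max(abs(g[act] - s * (mixing * sign(beta[act]) +
                                        (1 - mixing) * beta[act]))))
  if (length(ina))
    v <- max(v, max(pmax(0, abs(g[ina]) - s * mixing)))
  v
}

# Worst KKT violation over every point of a fitted path.
path_kkt_violation <- function(path, X, y, mixing) {
  max(vapply(seq_along(path$penalties), function(l) {
    kkt_violation(X, y, path$coefficients[, l], path$intercepts[l],
                  path$penalties[l], mixing)
  }, numeric(1)))
}

# T x P design with X'X/T = I and mean-zero columns (for the closed form).
orthonormal_design <- function(T, P) {
  X0 <- scale(matrix(rnorm(T * P), T, P), scale = FALSE)
  sqrt(T) * qr.Q(qr(X0))
}

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

# Exact upper-tail hypergeometric probability by combinatorial enumeration
# (independent of phyper): P(X >= k) with K special among M, n drawn.
hyper_upper_exact <- function(k, K, n, M) {
  j <- seq(from = k, to = min(K, n))
  if (k <= max(0, n - (M - K))) return(1)
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# Small z-scored expression matrix fixture with named genes.
fixture_matrix <- function(genes, T = 8, condition = "WT", seed = 42) {
  set.seed(seed)
  vals <- matrix(rnorm(length(genes) * T), length(genes), T,
                 dimnames = list(genes, paste0("S", seq_len(T))))
  vals <- (vals - rowMeans(vals)) / apply(vals, 1, sd)
  expression_matrix(vals, condition = condition, stage = "zscore")
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
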