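# Independent brute-force oracles used across test files.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws: population 1..N, successes 1..K, draw size n, observed k.
hyper_upper_bruteforce <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Benjamini-Hochberg step-up by direct definition: sort p ascending,
# q_i = p_i * m / i, then enforce monotonicity from the largest rank down.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Small labelled_expression built by hand.
toy_expression <- function(values, labels, biotype = NULL, symbol = NULL) {
  ann <- data.frame(
    feature_id = rownames(values),
    symbol = symbol %||% rownames(values),
    biotype = biotype %||% rep("lncRNA", nrow(values)),
    stringsAsFactors = FALSE
  )
  labelled_expression(values, labels, ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared default-sized simulated study, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_study(synthetic_config(seed = 1))
  }
  .fixture_env$sim
}
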