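# Independent oracles used across the suite.

# BH adjusted p as the smallest alpha at which the step-up procedure rejects,
# scanning the finite candidate set of alpha values (literal definition).
bh_reject_at <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= alpha * seq_len(m) / m + 1e-10)
  if (length(k) == 0L) rep(FALSE, m) else p <= s[max(k)]
}
bh_oracle <- function(p) {
  m <- length(p)
  cand <- sort(unique(pmin(1, as.vector(outer(p * m, seq_len(m), `/`)))))
  vapply(seq_len(m), function(i) {
    min(cand[vapply(cand, function(a) bh_reject_at(p, a)[i], logical(1L))])
  }, numeric(1L))
}

# Upper-tail hypergeometric probability by explicit enumeration.
hyper_upper_oracle <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) choose(K, i) * choose(N - K, n - i),
             numeric(1L))) / choose(N, n)
}

# TOST via two calls to stats::t.test (independent of the package's Welch code).
tost_oracle <- function(a, b, delta) {
  p1 <- stats::t.test(a, b, mu = delta, alternative = "less")$p.value
  p2 <- stats::t.test(a, b, mu = -delta, alternative = "greater")$p.value
  max(p1, p2)
}

# tiny hit-frame builder for hand-constructed cases
make_hits <- function(genome, orf, acc, score = 10, evalue = 1e-20,
                      env_start = 1L, env_end = 50L) {
  data.frame(genome_id = genome, orf_id = orf, model_acc = acc,
             model_name = acc, full_seq_evalue = evalue,
             full_seq_bitscore = score, domain_bitscore = score,
             env_start = env_start, env_end = env_end,
             description = "test", stringsAsFactors = FALSE)
}

# small default-shaped scenario shared by several tests
small_scenario <- function(seed = 1L, ...) {
  simulation_scenario(seed = seed, ...)
}
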