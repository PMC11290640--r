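# Independent oracles and small fixture builders shared across tests.

# Brute-force Mann-Whitney two-sided p by enumerating every assignment of
# the pooled values to the two groups (valid for tie-free data).
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  assignments <- utils::combn(length(pooled), n1)
  us <- apply(assignments, 2L, function(ii)
    u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(obs - mu))
}

# Direct sup-distance between the empirical CDF of x and Normal(mean, sd),
# evaluated at every jump of the ECDF (both sides).
ks_d_direct <- function(x, mean, sd) {
  xs <- sort(x)
  n <- length(xs)
  cdf <- pnorm(xs, mean, sd)
  max(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf))
}

# Two-group samples with a planted location shift delta (in SD units).
shifted_groups <- function(n1, n2, delta, sd = 1) {
  list(x = rnorm(n1, delta * sd, sd), y = rnorm(n2, 0, sd))
}

# A small cohort with one sensitizing EC50 effect and one AUC effect on
# gene G1 / drug D1.
planted_cohort <- function(n = 300, delta = 1.5, freq = 0.3, seed = 1) {
  freqs <- c(G1 = freq, G2 = freq, G3 = freq)
  spec <- cohort_spec(n, freqs, c("D1", "D2"),
                      measures = c("AUC", "EC50"), seed = seed)
  truth <- synthetic_truth(snv_effects = data.frame(
    gene = c("G1", "G1"), drug = c("D1", "D1"),
    measure = c("AUC", "EC50"), delta = delta,
    direction = "sensitizing", stringsAsFactors = FALSE))
  generate_cohort(spec, truth)
}

# One-row comparison stub for map-score tests.
comp_stub <- function(measure, mean_mut, mean_unmut, p_t) {
  data.frame(target = "G", drug = "D", measure = measure,
             n_mut = 10, n_unmut = 10, mean_mut = mean_mut,
             mean_unmut = mean_unmut, p_t = p_t, p_w = p_t, p_m = p_t,
             evaluable = TRUE, stringsAsFactors = FALSE)
}
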