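# Brute-force oracle: exact two-sided Mann-Whitney p by enumerating all
# C(n_a + n_b, n_a) assignments of the pooled ranks to sample a.
mw_exact_oracle <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
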