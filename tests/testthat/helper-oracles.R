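# brute-force BH step-up written independently of bh_adjust(): for each p_i,
# the adjusted value is min over j with p_j >= p_i of m * p_j / rank_j,
# capped at 1
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- m * p / r
    min(1, min(cand[p >= p[i] - 1e-300 & r >= r[i]]))
  }, numeric(1))
}
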