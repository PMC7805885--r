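# Closed-form oracles derived by direct enumeration of one round's four
# realized-action combinations; kept independent of the chain builder.

# Per-round expected reward of one GP facing another GP: both intend to
# cooperate (mutual punishment is unreachable because GP apologies are always
# believed), each realized defection (probability a) is apologized at cost c.
gp_gp_round_reward <- function(a, cost) {
  2 * (1 - a)^2 + 3 * a * (1 - a) + 0 * (1 - a) * a + 1 * a^2 - a * cost
}

# Per-round expected reward of a D facing a D (no apologies ever).
dd_round_reward <- function(a) {
  1 * (1 - a)^2 + 3 * a * (1 - a) + 0 * (1 - a) * a + 2 * a^2
}

default_pairs <- function() {
  expand.grid(s1 = strategy_ids(), s2 = strategy_ids(),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
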