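# Brute-force oracle for the branching model: enumerate every fate
# assignment of a founder's three-cycle decision tree (and the stomatal
# rounds of each terminal 2C leaf) with its probability, and count leaves.
# Independent of the closed form in expected_terminal_counts().

# outcomes of a terminal 2C cell with r stomatal rounds left:
# data.frame(prob, n2); declining a round is terminal
oracle_stomatal <- function(p_s, r) {
  if (r == 0L) return(data.frame(prob = 1, n2 = 1))
  sub <- oracle_stomatal(p_s, r - 1L)
  pairs <- expand.grid(i = seq_len(nrow(sub)), j = seq_len(nrow(sub)))
  divided <- data.frame(
    prob = p_s * sub$prob[pairs$i] * sub$prob[pairs$j],
    n2 = sub$n2[pairs$i] + sub$n2[pairs$j])
  rbind(data.frame(prob = 1 - p_s, n2 = 1), divided)
}

# outcomes of a 2C patterning cell entering cycle k:
# data.frame(prob, n2, n4, n8, n16)
oracle_cell <- function(p, k, rounds) {
  if (k > 3L) {
    s <- oracle_stomatal(p[["p_s"]], rounds)
    return(data.frame(prob = s$prob, n2 = s$n2, n4 = 0, n8 = 0, n16 = 0))
  }
  pk <- p[[c("p1", "p2", "p3")[k]]]
  commit <- data.frame(prob = pk, n2 = 0, n4 = 0, n8 = 0, n16 = 0)
  commit[[c("n16", "n8", "n4")[k]]] <- 1   # commit at k -> 2^(1 + (4 - k)) C
  sub <- oracle_cell(p, k + 1L, rounds)
  pairs <- expand.grid(i = seq_len(nrow(sub)), j = seq_len(nrow(sub)))
  divided <- data.frame(
    prob = (1 - pk) * sub$prob[pairs$i] * sub$prob[pairs$j],
    n2 = sub$n2[pairs$i] + sub$n2[pairs$j],
    n4 = sub$n4[pairs$i] + sub$n4[pairs$j],
    n8 = sub$n8[pairs$i] + sub$n8[pairs$j],
    n16 = sub$n16[pairs$i] + sub$n16[pairs$j])
  rbind(commit, divided)
}

oracle_expected_counts <- function(fate, stomatal_rounds = 1L) {
  out <- oracle_cell(fate, 1L, stomatal_rounds)
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  n <- c(n2 = sum(out$prob * out$n2), n4 = sum(out$prob * out$n4),
         n8 = sum(out$prob * out$n8), n16 = sum(out$prob * out$n16))
  c(n, total = sum(n))
}

oracle_expected_fractions <- function(fate, stomatal_rounds = 1L) {
  n <- oracle_expected_counts(fate, stomatal_rounds)
  n[c("n2", "n4", "n8", "n16")] / n[["total"]]
}

# small helper: a fast-running configuration for engine tests
small_config <- function(...) {
  scenario_config("wildtype", target_cells = 200, seed = 42, ...)
}
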