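# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (brute-force counting,
# closed forms, direct arithmetic) and never share code with the package
# implementation they check.

# Pincus ApEn by direct O(N^2) epoch counting (self-matches, Chebyshev)
apen_bruteforce <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    M <- N - mm + 1
    C <- vapply(seq_len(M), function(i) {
      ti <- x[i:(i + mm - 1)]
      sum(vapply(seq_len(M), function(j) {
        all(abs(ti - x[j:(j + mm - 1)]) <= r)
      }, TRUE))
    }, 0)
    mean(log(C / M))
  }
  phi(m) - phi(m + 1)
}

# entropy in bits of a label vector
entropy_oracle <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# gain ratio of a proposed partition (list of label subsets)
gain_ratio_oracle <- function(labels, parts) {
  n <- length(labels)
  H <- entropy_oracle(labels)
  Hs <- sum(vapply(parts, function(g) length(g) / n * entropy_oracle(g), 0))
  gain <- H - Hs
  si <- entropy_oracle(rep(seq_along(parts), vapply(parts, length, 0L)))
  c(gain = gain, split_info = si, gain_ratio = gain / si)
}

# every candidate numeric split of one feature, scored by the oracle
enumerate_numeric_splits <- function(x, labels) {
  ux <- sort(unique(x))
  if (length(ux) < 2) {
    return(data.frame(threshold = numeric(0), gain = numeric(0),
                      split_info = numeric(0), gain_ratio = numeric(0)))
  }
  thr <- (ux[-1] + ux[-length(ux)]) / 2
  do.call(rbind, lapply(thr, function(t) {
    g <- gain_ratio_oracle(labels, list(labels[x <= t], labels[x > t]))
    data.frame(threshold = t, gain = g[["gain"]],
               split_info = g[["split_info"]],
               gain_ratio = g[["gain_ratio"]])
  }))
}

# tie-aware AUC as the normalized Mann-Whitney U statistic
auc_rank_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  rk <- rank(scores)
  (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small synthetic recording shared by the signal round-trip tests
make_test_recording <- function(duration = 60, seed = 5) {
  generate_recording(synthetic_spec(duration = duration, true_ahi = 0,
                                    noise_sd = 0.02, flow_rate = 200,
                                    thoracic_rate = 10, spo2_rate = 1,
                                    seed = seed))$recording
}

# reduced-rate cohort conditions used by the pipeline tests
cohort_spec <- function(duration = 6 * 3600) {
  synthetic_spec(duration = duration, flow_rate = 8, thoracic_rate = 4,
                 spo2_rate = 1)
}
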