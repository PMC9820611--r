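# shared fixtures, all built in code at test time

# expression matrix straight from a value matrix, default 7x3 design
make_expr <- function(values, n_rep = 3,
                      tp = c(0, 1, 3, 5, 9, 12, 24)[seq_len(ncol(values) / n_rep)]) {
  expression_matrix(values,
                    time_point = rep(tp, each = n_rep),
                    replicate = rep(seq_len(n_rep), times = length(tp)))
}

# a minimal planted chain z1 -> z2 -> {s1, s2} with positive weights
chain_grn <- function() {
  planted_grn("z1", "z2", c("s1", "s2"),
              data.frame(regulator = c("z1", "z2", "z2"),
                         target = c("z2", "s1", "s2"),
                         weight = c(1, 0.8, 1.2)),
              seed = 1)
}

# independent-oracle BH step-up, straight from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent-oracle Pearson r and p from the closed-form definitions
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(t), df = n - 2, lower.tail = FALSE))
}
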