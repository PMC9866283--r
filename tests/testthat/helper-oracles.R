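# Independent brute-force reference implementations used as oracles.
# Deliberately naive (double loops), never shared with package internals.

qn_bruteforce <- function(conc, Vn, Vi, A) {
  n <- length(conc)
  out <- numeric(n)
  for (k in seq_len(n)) {
    removed <- 0
    if (k > 1) for (i in seq_len(k - 1)) removed <- removed + conc[i] * Vi
    out[k] <- (conc[k] * Vn + removed) / A
  }
  out
}

rmsd_bruteforce <- function(frames, sel = seq_len(nrow(frames[[1]]))) {
  nf <- length(frames)
  na <- length(sel)
  ref <- matrix(0, na, 3)
  for (k in seq_len(nf)) ref <- ref + frames[[k]][sel, , drop = FALSE]
  ref <- ref / nf
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    s <- 0
    for (a in seq_len(na)) {
      d <- frames[[k]][sel[a], ] - ref[a, ]
      s <- s + sum(d * d)
    }
    out[k] <- sqrt(s / na)
  }
  out
}

trapz_ref <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

make_ts <- function(time, value, ...) timeseries_table(time, value, ...)
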