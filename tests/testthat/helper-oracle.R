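# Independent brute-force oracle for the urn null: enumerate every ordered
# red/black draw sequence of length s from an urn starting with 1 red and
# k-1 black balls, returning `reinforcement` extra balls of the drawn
# colour after each draw. Exponential in s; only for tiny fixtures.

oracle_urn_pmf <- function(x, k, s, reinforcement) {
  if (s == 0) return(as.numeric(x == 0))
  seqs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), s)))
  total <- 0
  for (i in seq_len(nrow(seqs))) {
    draws <- seqs[i, ]
    if (sum(draws) != x) next
    p <- 1
    reds <- 0L
    for (t in seq_len(s)) {
      denom <- k + reinforcement * (t - 1)
      p_red <- (1 + reinforcement * reds) / denom
      p <- p * if (draws[t] == 1L) p_red else 1 - p_red
      reds <- reds + draws[t]
    }
    total <- total + p
  }
  total
}

oracle_urn_survival <- function(w, k, s, reinforcement) {
  if (w <= 0) return(1)
  sum(vapply(w:s, oracle_urn_pmf, numeric(1),
             k = k, s = s, reinforcement = reinforcement))
}

# equal-weight toy star: hub A (k = 3, s = 4), links A-B (2), A-C/A-D (1)
toy_star <- function() fig1_fixture()

write_tmp_edgelist <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
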