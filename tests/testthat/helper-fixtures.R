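# shared fixtures and independent oracles for the suite

test_ref <- load_reference()

# mean-absolute-difference formulation of the Gini index (independent of the
# rank-formula implementation under test)
gini_mad_oracle <- function(y) {
  n <- length(y)
  sum(abs(outer(y, y, "-"))) / (2 * n^2 * mean(y))
}

# brute-force single-linkage components: all-pairs Hamming + BFS
brute_components <- function(junctions, max_hamming = 1L) {
  n <- length(junctions)
  ch <- strsplit(junctions, "")
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sum(ch[[i]] != ch[[j]]) <= max_hamming) {
        adj[[i]] <- c(adj[[i]], j)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  sum(abs(us - mu) >= abs(u_obs - mu) - 1e-9) / ncol(combos)
}

# brute-force Holm-Sidak step-down
holm_sidak_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, max(1 - (1 - p[o][seq_len(i)])^(m - seq_len(i) + 1)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# random rearrangement records for clustering tests
random_junction_group <- function(n, len, alphabet = LETTERS[1:4]) {
  vapply(seq_len(n), function(i) {
    paste0(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

small_sim_cache <- new.env()

# one small annotated ERA donor, computed once per test run
cached_small_donor <- function() {
  if (is.null(small_sim_cache$donor)) {
    p <- donor_preset("ERA", n_reads = 1500L)
    sim <- simulate_donor(p, seed = 42, reference = test_ref)
    rep <- run_donor_pipeline(sim, test_ref)
    small_sim_cache$donor <- list(sim = sim, rep = rep)
  }
  small_sim_cache$donor
}
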