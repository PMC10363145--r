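# Independent reference implementations ("oracles") used to cross-check the
# package. Deliberately naive: explicit loops, direct definitions, exact
# enumeration. They share no code with the optimized paths they verify.

# --- brute-force DIRAC ------------------------------------------------------
# values: numeric matrix (analytes x samples); groups: named character vector
# (sample -> group). Returns templates, per-sample RMS under every group's
# consensus, and own-consensus RCI, all computed with plain loops.
oracle_dirac <- function(values, groups) {
  ids <- sort(rownames(values), method = "radix")
  samples <- colnames(values)
  m <- length(ids)
  pairs <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
  }
  bit_of <- function(s, pr) as.integer(values[pr[1L], s] > values[pr[2L], s])
  sample_bits <- sapply(samples, function(s) {
    vapply(pairs, function(pr) bit_of(s, pr), integer(1))
  })
  sample_bits <- matrix(sample_bits, nrow = length(pairs),
                        dimnames = list(NULL, samples))
  glabels <- unique(unname(groups))
  templates <- list()
  for (g in glabels) {
    gs <- samples[groups[samples] == g]
    tmpl <- integer(length(pairs))
    for (p in seq_along(pairs)) {
      ones <- sum(sample_bits[p, gs])
      tmpl[p] <- if (ones >= length(gs) / 2) 1L else 0L
    }
    templates[[g]] <- tmpl
  }
  rms <- matrix(NA_real_, length(samples), length(glabels),
                dimnames = list(samples, glabels))
  for (s in samples) {
    for (g in glabels) {
      agree <- 0L
      for (p in seq_along(pairs)) {
        if (sample_bits[p, s] == templates[[g]][p]) agree <- agree + 1L
      }
      rms[s, g] <- agree / length(pairs)
    }
  }
  rci <- vapply(glabels, function(g) {
    gs <- samples[groups[samples] == g]
    mean(rms[gs, g])
  }, numeric(1))
  list(templates = templates, rms = rms, rci = rci)
}

# --- analytic own-consensus null -------------------------------------------
# E[RCI] for i.i.d. continuous data: per pair the template matches
# max(K, n - K) of n samples, K ~ Binomial(n, 1/2); linearity over pairs.
oracle_null_rci <- function(n) {
  k <- 0:n
  sum(pmax(k, n - k) * stats::dbinom(k, n, 0.5)) / n
}

# --- direct-definition Benjamini-Hochberg ----------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# --- exact two-sided Mann-Whitney by enumeration ---------------------------
# Enumerates all C(nx+ny, nx) assignments of the pooled values (tie-free).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2L, function(ii) {
    sum(rank(pooled)[ii]) - nx * (nx + 1) / 2
  })
  mu <- nx * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# --- exact hypergeometric upper tail by enumeration ------------------------
# P(X >= k) where X = |draw of size n from N, K marked| by enumerating all
# C(N, n) draws. Feasible for N <= 12.
oracle_hyper_upper <- function(N, K, n, k) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d %in% marked) >= k))
}

# --- module retention rule, one line ---------------------------------------
oracle_retain <- function(background, measured) {
  measured >= 4 && measured >= ceiling(background / 2)
}

# --- small random study fixture --------------------------------------------
# A random abundance table + metadata with g groups of n samples and one
# module covering all analytes; used by oracle-equivalence loops.
random_instance <- function(m, n, g) {
  groups <- paste0("G", seq_len(g))
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", seq_len(n * g)),
    group = rep(groups, each = n),
    sex = rep_len(c("F", "M"), n * g),
    age_months = rep_len(c("6", "12"), n * g)))
  values <- matrix(stats::rnorm(m * n * g), m, n * g,
                   dimnames = list(paste0("A", seq_len(m)), meta$sample_id))
  list(table = abundance_table(values), meta = meta,
       modules = module_set(list(MOD = rownames(values))),
       groups = stats::setNames(meta$group, meta$sample_id))
}
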