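# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately written as plain loops / closed forms,
# sharing no code with the package implementation.

# textbook two-pass Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# gene x gene correlation by looping over pairs
oracle_cor_matrix <- function(m) {
  n <- nrow(m)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- oracle_pearson(m[i, ], m[j, ])
  }
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

# triple-loop topological overlap on an adjacency with zero diagonal
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    out[i, j] <- if (den == 0 || (a[i, j] == 0 && l == 0)) 0 else (l + a[i, j]) / den
  }
  out
}

# exhaustive three-criterion RSG evaluation on a genes x regions mean matrix;
# returns (gene, region) pairs that are RSGs plus the pairs passing c1
oracle_rsgs <- function(m, fold = 3, other_mean_ratio = 0.5, q = 0.75) {
  qcut <- apply(m, 2, stats::quantile, probs = q, type = 7)
  rsg <- character(0); c1_pairs <- character(0)
  for (g in seq_len(nrow(m))) {
    for (r in seq_len(ncol(m))) {
      c1 <- TRUE
      for (s in seq_len(ncol(m))) {
        if (s != r && !(m[g, r] > fold * m[g, s])) c1 <- FALSE
      }
      if (!c1) next
      c1_pairs <- c(c1_pairs, paste(g, r))
      others <- m[g, -r]
      c2 <- m[g, r] > other_mean_ratio * mean(others)
      c3 <- m[g, r] >= qcut[r]
      if (c2 && c3) rsg <- c(rsg, paste(g, r))
    }
  }
  list(rsg = rsg, c1 = c1_pairs)
}

# two-tailed p of a Pearson r at sample size n via the incomplete beta
# (independent of the pt() path used by the implementation)
oracle_cor_p <- function(r, n) {
  df <- n - 2
  t2 <- r^2 * df / (1 - r^2)
  stats::pbeta(df / (df + t2), df / 2, 1 / 2)
}

# small expression fixture: genes x samples matrix wrapped as a tibble
make_expr <- function(m, unit = "fpkm") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  as_expr_tbl(m, unit = unit)
}

# reduced-size simulation settings for fast structural tests (the default
# config is exercised where recovery quality itself is under test)
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 600, n_rsg_per_region = 3, n_modules = 3,
         module_size = 40, dropout_fraction = 0.3),
    list(...))
  do.call(sim_config, args)
}

# metadata for n_regions x n_reps samples named s1, s2, ...
make_meta <- function(n_regions = 2, n_reps = 3,
                      regions = paste0("R", seq_len(n_regions))) {
  n <- n_regions * n_reps
  tibble::tibble(sample_id = paste0("s", seq_len(n)),
                 region = rep(regions, each = n_reps),
                 replicate = rep(seq_len(n_reps), n_regions),
                 individual = paste0("i", rep(seq_len(n_reps), n_regions)))
}
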