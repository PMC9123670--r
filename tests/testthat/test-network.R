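test_that("correlation_matrix matches a two-pass Pearson loop oracle", {
  set.seed(12)
  m <- matrix(rexp(10 * 8), 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  cc <- correlation_matrix(make_expr(m), transform = "none")
  expect_equal(cc, oracle_cor_matrix(m), tolerance = 1e-12)
  expect_true(all(diag(cc) == 1))
  expect_true(all(abs(cc) <= 1 + 1e-12))
  expect_equal(cc, t(cc))

  # anti-correlated profiles give exactly -1 (transform off)
  x <- rnorm(8)
  m2 <- rbind(g1 = x - min(x) + 1, g2 = max(x) + 1 - x)
  colnames(m2) <- paste0("s", 1:8)
  cc2 <- correlation_matrix(make_expr(m2), transform = "none")
  expect_equal(cc2["g1", "g2"], -1)
})

test_that("zero-variance genes are removed with a warning naming them", {
  m <- rbind(flat = rep(2, 6), ok1 = rexp(6) + 1, ok2 = rexp(6) + 1)
  colnames(m) <- paste0("s", 1:6)
  expect_warning(cc <- correlation_matrix(make_expr(m), transform = "none"), "flat")
  expect_identical(rownames(cc), c("ok1", "ok2"))
})

test_that("adjacency follows the soft-power map with zero diagonal", {
  cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3, 3)
  a <- adjacency_matrix(cc, beta = 5, type = "unsigned")
  expect_equal(a[1, 2], 0.03125)
  expect_equal(a[1, 3], 0.03125)   # |-0.5|^5
  expect_equal(a[2, 3], 1)         # cor 1 is a fixed point for any power
  expect_true(all(diag(a) == 0))
  s <- adjacency_matrix(cc, beta = 5, type = "signed")
  expect_equal(s[1, 3], 0.25^5)

  # monotone non-decreasing in |cor| for the unsigned map
  r <- seq(-1, 1, by = 0.05)
  cc2 <- outer(r, r, function(a, b) a)  # rows sweep the correlation range
  a2 <- adjacency_matrix(cc2, beta = 5, type = "unsigned")
  keep <- setdiff(order(abs(r)), 2)  # skip the structural-zero diagonal cell
  expect_true(all(diff(a2[keep, 2]) >= -1e-15))
})

test_that("tom_similarity matches hand evaluation and the triple-loop oracle", {
  # 3-clique with unit adjacency: TOM_12 = (1 + 1) / (2 + 1 - 1) = 1
  a3 <- matrix(1, 3, 3) - diag(3)
  t3 <- tom_similarity(a3)
  expect_equal(t3[1, 2], 1)

  # two isolated genes
  a0 <- matrix(0, 2, 2)
  expect_equal(tom_similarity(a0)[1, 2], 0)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("soft-threshold selection honours an override and reports the table", {
  set.seed(2)
  meta <- make_meta(5, 6)
  ds <- generate_dataset(small_cfg(dropout_fraction = 0, seed = 2))
  sft <- pick_soft_threshold(ds$expr, powers = 1:8, beta = 5)
  expect_identical(sft$beta, 5)
  expect_true(sft$user_supplied)
  expect_identical(nrow(sft$fit_table), 8L)
  expect_true(all(c("power", "r_squared", "mean_k") %in% names(sft$fit_table)))
  # table is the same whether or not the override is used
  sel <- pick_soft_threshold(ds$expr, powers = 1:8)
  expect_equal(sel$fit_table, sft$fit_table)
  expect_true(sel$beta %in% 1:8)
})

test_that("pure-noise expression does not reach the scale-free cutoff", {
  # under i.i.d. Gaussian noise the connectivity distribution is not
  # scale-free; selection must fall back to the max-R^2 power
  falls_back <- vapply(1:10, function(s) {
    set.seed(100 + s)
    m <- matrix(exp(rnorm(200 * 30)), 200, 30,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:30)))
    sft <- suppressWarnings(pick_soft_threshold(make_expr(m), powers = c(1, 3, 5, 7, 9)))
    all(sft$fit_table$r_squared < 0.80, na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(falls_back), 9)
})

test_that("planted-module data picks a moderate soft power", {
  ds <- generate_dataset(sim_config(seed = 5))
  filt <- filter_expressed(ds$expr, ds$meta)
  sft <- suppressWarnings(pick_soft_threshold(filt, powers = 1:12))
  expect_lte(sft$beta, 10)
})

test_that("detect_modules recovers planted blocks and handles degeneracy", {
  # block-structured TOM: two planted blocks of 50, near-zero elsewhere
  n <- 100
  tom <- matrix(0, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  tom[1:50, 1:50] <- 0.8
  tom[51:100, 51:100] <- 0.8
  diag(tom) <- 1
  asg <- detect_modules(tom, min_module_size = 30)
  expect_identical(max(asg$module), 2L)
  expect_identical(length(unique(asg$module[1:50])), 1L)
  expect_identical(length(unique(asg$module[51:100])), 1L)
  expect_true(all(asg$module > 0))

  # min_module_size larger than the gene count: everything unassigned
  expect_warning(none <- detect_modules(tom, min_module_size = 200))
  expect_true(all(none$module == 0))

  # permuting gene order permutes labels consistently
  perm <- sample(n)
  asg_p <- detect_modules(tom[perm, perm], min_module_size = 30)
  ref <- asg$module[match(asg_p$gene_id, asg$gene_id)]
  expect_identical(mclust::adjustedRandIndex(asg_p$module, ref), 1)
})

test_that("module eigengenes equal the first PC from an SVD oracle", {
  set.seed(77)
  meta <- make_meta(5, 6)
  m <- matrix(rexp(40 * 30, 0.1), 40, 30, dimnames = list(NULL, meta$sample_id))
  expr <- make_expr(m)
  asg <- tibble::tibble(gene_id = paste0("g", 1:40),
                        module = rep(1:2, each = 20))
  me <- module_eigengenes(expr, asg, transform = "log2_plus1")
  ve <- attr(me, "variance_explained")
  for (mod in 1:2) {
    sub <- log2(m[asg$module == mod, ] + 1)
    z <- t(scale(t(sub)))
    sv <- svd(z)                      # independent full SVD
    pc <- sv$v[, 1] / stats::sd(sv$v[, 1])
    got <- unlist(me[me$module == mod, -1])
    agree <- min(sum(abs(got - pc)), sum(abs(got + pc)))
    expect_lt(agree, 1e-10)
    expect_equal(unname(ve[as.character(mod)]), sv$d[1]^2 / sum(sv$d^2))
    # sign convention: non-negative correlation with module mean expression
    expect_gte(stats::cor(got, colMeans(z)), 0)
  }
})

test_that("a rank-1 module explains all variance; constant genes are dropped", {
  meta <- make_meta(2, 4)
  x <- c(1, 5, 2, 8, 3, 9, 4, 7)
  m <- rbind(g1 = x, g2 = x, g3 = x, g4 = rep(2, 8))
  colnames(m) <- meta$sample_id
  expr <- make_expr(m)
  asg <- tibble::tibble(gene_id = paste0("g", 1:4), module = 1L)
  expect_warning(me <- module_eigengenes(expr, asg, transform = "none"), "g4")
  expect_equal(unname(attr(me, "variance_explained")["1"]), 1)
  e <- unlist(me[1, -1])
  expect_equal(abs(stats::cor(e, x)), 1)
  # label-0 background never yields an eigengene
  asg2 <- tibble::tibble(gene_id = paste0("g", 1:4), module = c(1L, 1L, 1L, 0L))
  me2 <- module_eigengenes(expr, asg2, transform = "none")
  expect_identical(me2$module, 1L)
})

test_that("merge_close_modules merges duplicate-profile modules and respects 0", {
  meta <- make_meta(5, 6)
  set.seed(55)
  f <- rnorm(30)
  m <- rbind(matrix(rep(f, 10), 10, byrow = TRUE) + rnorm(300, 0, 0.01),
             matrix(rep(f, 10), 10, byrow = TRUE) + rnorm(300, 0, 0.01),
             matrix(rep(rnorm(30), 10), 10, byrow = TRUE) + rnorm(300, 0, 0.01))
  m <- exp(m)
  colnames(m) <- meta$sample_id
  expr <- make_expr(m)
  asg <- tibble::tibble(gene_id = paste0("g", 1:30), module = rep(1:3, each = 10))
  merged <- merge_close_modules(expr, asg, merge_cut_height = 0.25, transform = "none")
  expect_identical(max(merged$module), 2L)
  # the two near-identical factor modules collapsed into one
  expect_identical(length(unique(merged$module[1:20])), 1L)

  unchanged <- merge_close_modules(expr, asg, merge_cut_height = 0, transform = "none")
  expect_identical(unchanged$module, asg$module)
})

test_that("the network pipeline is deterministic given identical input", {
  ds <- generate_dataset(small_cfg(seed = 9))
  filt <- filter_expressed(ds$expr, ds$meta)
  n1 <- build_network(filt, beta = 5)
  n2 <- build_network(filt, beta = 5)
  expect_identical(n1$assignment, n2$assignment)
  expect_equal(n1$eigengenes, n2$eigengenes)
})

test_that("tidiers summarise a network consistently", {
  ds <- generate_dataset(small_cfg(seed = 10))
  filt <- filter_expressed(ds$expr, ds$meta)
  net <- build_network(filt, beta = 5)
  td <- tidy(net)
  gl <- glance(net)
  expect_identical(nrow(td), gl$n_modules)
  expect_identical(sum(td$n_genes) + gl$n_unassigned, gl$n_genes)
  expect_true(all(td$variance_explained > 0 & td$variance_explained <= 1))
})
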