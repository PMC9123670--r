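fixture_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(sim_config(seed = 6))
      filt <- filter_expressed(ds$expr, ds$meta)
      rsgs <- detect_rsgs(region_means(filt, ds$meta))
      net <- build_network(filt, beta = 5)
      design <- build_design_matrix(ds$meta)
      assoc <- module_trait_correlation(net$eigengenes, design)
      calls <- call_region_specific_modules(assoc)
      kme <- module_membership(filt, net$eigengenes)
      cache <<- list(ds = ds, filt = filt, rsgs = rsgs, net = net,
                     calls = calls, kme = kme)
    }
    cache
  }
})

test_that("merge_candidates unions the two arms with provenance", {
  fx <- fixture_run()
  cands <- merge_candidates(fx$rsgs, fx$calls, fx$net$assignment, fx$kme,
                            top_k_per_module = 10)
  n_rsg <- sum(fx$rsgs$is_rsg)
  n_spec <- sum(fx$calls$is_region_specific)
  expect_lte(nrow(cands), n_rsg + 10 * n_spec)
  expect_identical(anyDuplicated(cands$gene_id), 0L)
  expect_true(all(cands$sources %in% c("rsg", "module", "rsg+module")))
  # provenance invariants
  expect_true(all(!is.na(cands$focal_region[grepl("rsg", cands$sources)])))
  expect_true(all(is.na(cands$focal_region[cands$sources == "module"])))
  expect_true(all(!is.na(cands$module[grepl("module", cands$sources)])))
  # every planted RSG that was detected appears in the candidate list
  planted <- fx$ds$truth$rsg_genes$gene_id
  detected <- fx$rsgs$gene_id[fx$rsgs$is_rsg]
  expect_true(all(intersect(planted, detected) %in% cands$gene_id))

  # top_k = 0 restricts candidates to the RSG arm
  only_rsg <- merge_candidates(fx$rsgs, fx$calls, fx$net$assignment, fx$kme,
                               top_k_per_module = 0)
  expect_setequal(only_rsg$gene_id, detected)
  expect_true(all(only_rsg$sources == "rsg"))
})

test_that("a dual-provenance gene appears once with both sources", {
  fx <- fixture_run()
  # force an overlap: a detected RSG that also sits in a called module
  both <- merge_candidates(fx$rsgs, fx$calls, fx$net$assignment, fx$kme,
                           top_k_per_module = 10000)
  overlap <- both$gene_id[both$sources == "rsg+module"]
  expect_gt(length(overlap), 0)
  expect_identical(anyDuplicated(both$gene_id), 0L)
  row <- both[both$gene_id == overlap[1], ]
  expect_false(is.na(row$focal_region))
  expect_false(is.na(row$module))
})

test_that("delta_delta_ct follows the 2^-ddCt arithmetic", {
  q <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    region = c("cal", "cal", "other", "other"),
    gene = "GX",
    ct_target = c(24, 26, 25, 21),
    ct_reference = c(20, 22, 20, 20))
  out <- delta_delta_ct(q, calibrator = "cal")
  # calibrator mean dCt = 4; sample at the mean has relative expression 1
  expect_equal(out$rel_expr[1], 1)
  # ct 25/20: dCt 5, ddCt 1 -> 0.5
  expect_equal(out$rel_expr[out$sample_id == "s3"], 0.5)
  # ddCt -3 -> 8
  expect_equal(out$rel_expr[out$sample_id == "s4"], 8)

  # shift invariance: adding a constant to all Ct of a gene cancels in ddCt
  q2 <- q; q2$ct_target <- q2$ct_target + 3.7
  out2 <- delta_delta_ct(q2, calibrator = "cal")
  expect_equal(out2$rel_expr, out$rel_expr)

  # minimum-dCt calibrator: the best sample gets relative expression 1
  out3 <- delta_delta_ct(q, calibrator = NULL)
  expect_equal(max(out3$rel_expr), 1)

  qna <- q; qna$ct_reference[2] <- NA
  expect_error(delta_delta_ct(qna), "s2")
  expect_error(delta_delta_ct(q, calibrator = "missing_region"), "missing_region")
})

test_that("cross-platform concordance ranks regions consistently", {
  meta <- make_meta(5, 2)
  m <- matrix(rep(c(1, 2, 4, 8, 16), each = 2), 1, byrow = TRUE)
  m <- rbind(up = rep(c(1, 2, 4, 8, 16), each = 2),
             down = rep(c(16, 8, 4, 2, 1), each = 2))
  colnames(m) <- meta$sample_id
  expr <- make_expr(m)
  # qPCR relative expression with the same (reversed) region ordering
  rel <- tibble::tibble(
    sample_id = rep(meta$sample_id, 2),
    region = rep(meta$region, 2),
    gene = rep(c("up", "down"), each = 10),
    delta_ct = 0, delta_delta_ct = 0,
    rel_expr = c(rep(c(1, 2, 4, 8, 16), each = 2),
                 rep(c(16, 8, 4, 2, 1), each = 2)))
  cc <- cross_platform_concordance(rel, expr, meta)
  expect_equal(cc$rho[cc$gene == "up"], 1)
  expect_equal(cc$rho[cc$gene == "down"], 1)    # both orderings agree per gene
  rel_flip <- rel
  rel_flip$rel_expr[rel_flip$gene == "up"] <- rep(c(16, 8, 4, 2, 1), each = 2)
  cc2 <- cross_platform_concordance(rel_flip, expr, meta)
  expect_equal(cc2$rho[cc2$gene == "up"], -1)
})

test_that("synthetic qPCR round-trips fold changes and stays concordant", {
  fx <- fixture_run()
  genes <- utils::head(fx$ds$truth$rsg_genes$gene_id, 4)
  # noise-free: ddCt on the generated table reproduces (FPKM+1) ratios
  q0 <- generate_qpcr(fx$ds$expr, fx$ds$meta, genes, noise_sd_ct = 0, seed = 2)
  rel0 <- delta_delta_ct(q0, calibrator = "chuck")
  m <- expr_matrix(fx$ds$expr)
  for (g in genes) {
    rg <- rel0[rel0$gene == g, ]
    cal <- fx$ds$meta$sample_id[fx$ds$meta$region == "chuck"]
    expected <- (m[g, rg$sample_id] + 1) / exp(mean(log(m[g, cal] + 1)))
    expect_equal(unname(rg$rel_expr), unname(expected), tolerance = 1e-9)
  }
  # monotone contract: higher FPKM means strictly lower Ct at zero noise
  ord <- order(m[genes[1], ])
  cts <- q0$ct_target[q0$gene == genes[1]][ord]
  expect_true(all(diff(cts) < 0))

  # doubling FPKM + 1 lowers Ct by exactly one cycle at slope -1/ln 2
  f <- c(1, 3)                          # FPKM + 1 = 2 and 4
  mm <- matrix(f, 1, 2, dimnames = list("g", c("s1", "s2")))
  meta2 <- tibble::tibble(sample_id = c("s1", "s2"), region = c("A", "A"),
                          replicate = 1:2, individual = c("i1", "i2"))
  qq <- generate_qpcr(make_expr(mm), meta2, "g", noise_sd_ct = 0, seed = 1)
  expect_equal(unname(qq$ct_target[1] - qq$ct_target[2]), 1)

  # noisy qPCR remains rank-concordant with FPKM
  q1 <- generate_qpcr(fx$ds$expr, fx$ds$meta, genes, noise_sd_ct = 0.3, seed = 5)
  rel1 <- delta_delta_ct(q1, calibrator = "chuck")
  cc <- cross_platform_concordance(rel1, fx$ds$expr, fx$ds$meta, genes)
  expect_true(all(cc$rho > 0.8))
})

test_that("region comparison flags a planted region effect", {
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    meta <- make_meta(5, 6)
    rel <- tibble::tibble(
      sample_id = meta$sample_id, region = meta$region, gene = "g",
      delta_ct = 0, delta_delta_ct = 0,
      rel_expr = exp(rnorm(30, 0, 0.4)) * ifelse(meta$region == "R1", 4, 1))
    compare_regions(rel)$kruskal_p <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)

  # post-hoc contract: symmetric pairwise p matrix with unit diagonal
  meta <- make_meta(3, 6)
  set.seed(1)
  rel <- tibble::tibble(sample_id = meta$sample_id, region = meta$region,
                        gene = "g", delta_ct = 0, delta_delta_ct = 0,
                        rel_expr = rexp(18))
  pw <- compare_regions(rel)$pairwise_p
  expect_equal(pw, t(pw))
  expect_true(all(diag(pw) == 1))
  expect_true(all(pw >= 0 & pw <= 1))
})
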