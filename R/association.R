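# Module-region association: a one-hot design matrix over samples, Pearson
# correlation of each module eigengene with each region indicator, Student-t
# two-tailed p-values, and the region-specific call rule (|r| above a
# magnitude threshold with p below a cutoff).

#' One-hot region design matrix
#'
#' Each row is a sample, each column a region; the entry is 1 when the sample
#' comes from that region and 0 otherwise, so each row sums to exactly 1 and
#' each column sum equals the region's replicate count.
#'
#' @param meta Metadata tibble.
#' @return A tibble `sample_id` + one 0/1 column per region.
#' @export
build_design_matrix <- function(meta) {
  validate_metadata(meta)
  regions <- unique(meta$region)
  if (length(regions) < 2) {
    rlang::abort("design matrix needs >= 2 regions (a single constant column cannot be correlated)")
  }
  if (any(is.na(meta$region))) rlang::abort("sample with unknown region")
  cols <- lapply(regions, function(r) as.integer(meta$region == r))
  names(cols) <- regions
  tibble::tibble(sample_id = meta$sample_id, !!!cols)
}

design_matrix_values <- function(design) {
  X <- as.matrix(design[, -1, drop = FALSE])
  rownames(X) <- design$sample_id
  X
}

#' Correlate module eigengenes with region indicators
#'
#' For every (module, region) pair: Pearson r between the eigengene profile
#' and the one-hot region column (point-biserial correlation is exactly
#' Pearson here), and the two-tailed Student-t p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom.
#' Samples are aligned by id; a perfect |r| = 1 is reported with the smallest
#' representable positive p and `at_machine_limit = TRUE`.
#'
#' @param me Eigengene tibble from [module_eigengenes()].
#' @param design Design tibble from [build_design_matrix()].
#' @return A tibble `module`, `region`, `r`, `p`, `n`, `at_machine_limit`.
#' @export
module_trait_correlation <- function(me, design) {
  M <- me_matrix(me)
  X <- design_matrix_values(design)
  if (!setequal(colnames(M), rownames(X))) {
    rlang::abort("eigengene samples and design samples do not match")
  }
  X <- X[colnames(M), , drop = FALSE]
  n <- ncol(M)
  if (n < 3) rlang::abort("need >= 3 samples for the t-based p-value")
  flat <- apply(M, 1, stats::sd) == 0
  if (any(flat)) {
    rlang::abort(paste0("zero-variance eigengene for module(s): ",
                        paste(rownames(M)[flat], collapse = ", ")))
  }
  grid <- tidyr::expand_grid(module = me$module, region = colnames(X))
  res <- purrr::pmap(grid, function(module, region) {
    r <- stats::cor(M[as.character(module), ], X[, region])
    corr_test_p(r, n)
  })
  grid$r <- vapply(res, `[[`, numeric(1), "r")
  grid$p <- vapply(res, `[[`, numeric(1), "p")
  grid$n <- n
  grid$at_machine_limit <- vapply(res, `[[`, logical(1), "limit")
  grid
}

# two-tailed p for a Pearson r at sample size n via the Student-t transform
corr_test_p <- function(r, n) {
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    return(list(r = r, p = .Machine$double.xmin, limit = TRUE))
  }
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), limit = FALSE)
}

#' Call region-specific modules
#'
#' A (module, region) pair is region-specific when the correlation magnitude
#' exceeds `r_min` and the p-value is below `p_max` (the study thresholds are
#' 0.60 and 1e-2). Negative associations are retained and flagged with
#' `direction = "negative"`; magnitude-based calling (`use_absolute_r = TRUE`,
#' default) is what admits them. No multiple-testing correction is applied to
#' the calls by default; Bonferroni and Benjamini-Hochberg adjusted p-values
#' are reported alongside, and `adjust` switches the calls onto one of them.
#' Near-threshold pairs (within `borderline_margin` of `r_min`, significant
#' p) are flagged `borderline` for manual review.
#'
#' @param assoc Association tibble from [module_trait_correlation()].
#' @param r_min Correlation-magnitude threshold (default 0.60).
#' @param p_max P-value threshold (default 1e-2).
#' @param use_absolute_r Compare |r| (default) rather than signed r.
#' @param adjust `"none"` (default), `"bonferroni"`, or `"BH"` — which
#'   p-value the call uses.
#' @param borderline_margin Width of the borderline band below `r_min`
#'   (default 0.05).
#' @return The association tibble with `p_bonferroni`, `p_bh`,
#'   `is_region_specific`, `direction`, and `borderline` columns.
#' @export
call_region_specific_modules <- function(assoc, r_min = 0.60, p_max = 1e-2,
                                         use_absolute_r = TRUE,
                                         adjust = c("none", "bonferroni", "BH"),
                                         borderline_margin = 0.05) {
  adjust <- match.arg(adjust)
  if (nrow(assoc) == 0) rlang::abort("empty association table")
  stat <- if (use_absolute_r) abs(assoc$r) else assoc$r
  assoc$p_bonferroni <- stats::p.adjust(assoc$p, method = "bonferroni")
  assoc$p_bh <- stats::p.adjust(assoc$p, method = "BH")
  p_used <- switch(adjust, none = assoc$p, bonferroni = assoc$p_bonferroni, BH = assoc$p_bh)
  assoc$is_region_specific <- stat > r_min & p_used < p_max
  assoc$direction <- ifelse(assoc$r >= 0, "positive", "negative")
  assoc$borderline <- !assoc$is_region_specific &
    stat > (r_min - borderline_margin) & p_used < p_max
  assoc
}

#' Module membership (kME) of every gene
#'
#' kME of gene g in module m is the Pearson correlation between g's
#' (transformed) expression profile and module m's eigengene; high |kME|
#' within a region-specific module marks hub genes. Zero-variance genes have
#' undefined kME and are reported as missing.
#'
#' @param expr Expression tibble.
#' @param me Eigengene tibble.
#' @param transform Expression transform matching the network construction.
#' @return A long tibble `gene_id`, `module`, `kme`.
#' @export
module_membership <- function(expr, me, transform = c("log2_plus1", "none")) {
  transform <- match.arg(transform)
  m <- transform_expr(expr_matrix(expr), transform)
  M <- me_matrix(me)
  if (!setequal(colnames(m), colnames(M))) rlang::abort("sample mismatch between expression and eigengenes")
  m <- m[, colnames(M), drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  kme <- matrix(NA_real_, nrow(m), nrow(M), dimnames = list(rownames(m), rownames(M)))
  ok <- sds > 0
  if (any(ok)) kme[ok, ] <- stats::cor(t(m[ok, , drop = FALSE]), t(M))
  out <- tibble::as_tibble(kme, .name_repair = "minimal")
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1)
  tidyr::pivot_longer(out, -"gene_id", names_to = "module", values_to = "kme") %>%
    dplyr::mutate(module = as.integer(.data$module))
}

#' Top hub genes of region-specific modules
#'
#' @param kme Long kME tibble from [module_membership()].
#' @param calls Called association tibble from
#'   [call_region_specific_modules()].
#' @param top_k Hub genes to keep per region-specific module (default 10).
#' @return Tibble `gene_id`, `module`, `kme`, `region`, `direction`, ranked
#'   by |kME| within module.
#' @export
hub_genes <- function(kme, calls, top_k = 10) {
  spec <- calls[calls$is_region_specific, c("module", "region", "direction")]
  if (nrow(spec) == 0 || top_k == 0) {
    return(tibble::tibble(gene_id = character(), module = integer(), kme = numeric(),
                          region = character(), direction = character()))
  }
  dplyr::inner_join(kme, spec, by = "module", relationship = "many-to-many") %>%
    dplyr::filter(!is.na(.data$kme)) %>%
    dplyr::group_by(.data$module, .data$region) %>%
    dplyr::slice_max(abs(.data$kme), n = top_k, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$module, .data$region, dplyr::desc(abs(.data$kme)), .data$gene_id)
}
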