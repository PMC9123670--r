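# Candidate synthesis (RSGs union hub genes of region-specific modules) and
# the qPCR validation arithmetic (2^-ddCt, cross-platform concordance,
# Kruskal-Wallis across regions).

#' Merge RSGs and module hub genes into a candidate list
#'
#' Candidates are the union of all detected RSGs and the top `top_k_per_module`
#' genes by |kME| from each region-specific module; a gene reached by both
#' routes appears once with `sources = "rsg+module"`. Ordering is
#' deterministic: source, region, |kME| descending, gene id.
#'
#' @param rsgs RSG record tibble from [detect_rsgs()].
#' @param calls Called association tibble from
#'   [call_region_specific_modules()].
#' @param assignment Module assignment tibble.
#' @param kme Long kME tibble from [module_membership()].
#' @param top_k_per_module Hub genes per region-specific module (default 10);
#'   0 restricts candidates to RSGs.
#' @return Tibble `gene_id`, `sources`, `focal_region`, `module`, `kme`,
#'   `fold_vs_max_other`.
#' @export
merge_candidates <- function(rsgs, calls, assignment, kme, top_k_per_module = 10) {
  rsg_arm <- rsgs[rsgs$is_rsg, c("gene_id", "focal_region", "fold_vs_max_other")]
  hub <- hub_genes(kme, calls, top_k = top_k_per_module)
  # a hub gene should belong to the module it represents
  hub <- dplyr::semi_join(hub,
                          tibble::tibble(gene_id = assignment$gene_id, module = assignment$module),
                          by = c("gene_id", "module"))
  mod_arm <- hub %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_max(abs(.data$kme), n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", module_region = "region", "module", "kme")
  out <- dplyr::full_join(rsg_arm, mod_arm, by = "gene_id") %>%
    dplyr::mutate(
      sources = dplyr::case_when(
        !is.na(.data$focal_region) & !is.na(.data$module) ~ "rsg+module",
        !is.na(.data$focal_region) ~ "rsg",
        TRUE ~ "module"),
      region = dplyr::coalesce(.data$focal_region, .data$module_region)) %>%
    dplyr::arrange(.data$sources, .data$region,
                   dplyr::desc(dplyr::coalesce(abs(.data$kme), -Inf)), .data$gene_id) %>%
    dplyr::select("gene_id", "sources", "focal_region", "module", "kme",
                  "fold_vs_max_other")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per gene, `dCt = ct_target - ct_reference`; `ddCt` subtracts the mean dCt
#' of the calibrator group for that gene; relative expression is `2^-ddCt`.
#' The calibrator is a named region (recommended) or, when `calibrator` is
#' `NULL`, the per-gene sample with the smallest dCt.
#'
#' @param qpcr Tibble with columns `sample_id`, `region`, `gene`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator Region label, or `NULL` for the per-gene minimum-dCt
#'   sample.
#' @return Tibble `sample_id`, `region`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @export
delta_delta_ct <- function(qpcr, calibrator = NULL) {
  need <- c("sample_id", "region", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, names(qpcr))
  if (length(miss)) rlang::abort(paste0("qPCR table missing column(s): ", paste(miss, collapse = ", ")))
  bad <- !is.finite(qpcr$ct_target) | !is.finite(qpcr$ct_reference)
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf("non-finite Ct for sample '%s', gene '%s'",
                         qpcr$sample_id[i], qpcr$gene[i]))
  }
  if (!is.null(calibrator) && !calibrator %in% qpcr$region) {
    rlang::abort(paste0("calibrator region '", calibrator, "' absent from the qPCR table"))
  }
  qpcr %>%
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_reference) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::mutate(
      cal_mean = if (is.null(calibrator)) min(.data$delta_ct)
                 else mean(.data$delta_ct[.data$region == calibrator]),
      delta_delta_ct = .data$delta_ct - .data$cal_mean,
      rel_expr = 2^(-.data$delta_delta_ct)) %>%
    dplyr::ungroup() %>%
    dplyr::select("sample_id", "region", "gene", "delta_ct", "delta_delta_ct", "rel_expr")
}

#' Concordance between qPCR relative expression and FPKM
#'
#' Per gene, the Spearman rank correlation between region-mean relative
#' expression (2^-ddCt) and region-mean FPKM across the regions common to
#' both tables. A constant vector leaves the correlation undefined (NA).
#'
#' @param relexp Output of [delta_delta_ct()].
#' @param expr Expression tibble (FPKM).
#' @param meta Metadata tibble for `expr`.
#' @param genes Genes to assess; default all genes in `relexp`.
#' @return Tibble `gene`, `rho`, `n_regions`.
#' @export
cross_platform_concordance <- function(relexp, expr, meta, genes = NULL) {
  if (is.null(genes)) genes <- unique(relexp$gene)
  rmeans <- region_means(expr[expr$gene_id %in% genes, , drop = FALSE], meta)
  purrr::map_dfr(genes, function(g) {
    q <- relexp[relexp$gene == g, ] %>%
      dplyr::group_by(.data$region) %>%
      dplyr::summarise(rel = mean(.data$rel_expr), .groups = "drop")
    fv <- unlist(rmeans[rmeans$gene_id == g, -1])
    common <- intersect(q$region, names(fv))
    if (length(common) < 3) rlang::abort("need >= 3 regions in common")
    x <- q$rel[match(common, q$region)]
    y <- fv[common]
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      suppressWarnings(stats::cor(x, y, method = "spearman"))
    tibble::tibble(gene = g, rho = rho, n_regions = length(common))
  })
}

#' Compare relative expression across regions
#'
#' The global test is Kruskal-Wallis on 2^-ddCt relative expression by
#' region, per gene; the post-hoc pairwise comparison is a rank-based
#' pairwise Wilcoxon test with Holm correction, returned as a symmetric
#' region x region p matrix with unit diagonal.
#'
#' @param relexp Output of [delta_delta_ct()].
#' @param gene Gene to test (default: first in the table).
#' @return List with `kruskal_p`, `kruskal_statistic`, and `pairwise_p`.
#' @export
compare_regions <- function(relexp, gene = NULL) {
  if (is.null(gene)) gene <- relexp$gene[1]
  d <- relexp[relexp$gene == gene, ]
  if (length(unique(d$region)) < 2) rlang::abort("need >= 2 regions")
  kw <- stats::kruskal.test(d$rel_expr, factor(d$region))
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(d$rel_expr, factor(d$region), p.adjust.method = "holm"))
  regions <- sort(unique(d$region))
  P <- matrix(1, length(regions), length(regions), dimnames = list(regions, regions))
  for (i in rownames(pw$p.value)) for (j in colnames(pw$p.value)) {
    if (!is.na(pw$p.value[i, j])) P[i, j] <- P[j, i] <- pw$p.value[i, j]
  }
  list(gene = gene, kruskal_p = unname(kw$p.value),
       kruskal_statistic = unname(kw$statistic), pairwise_p = P)
}
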