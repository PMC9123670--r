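# Region-specific gene (RSG) detection: a gene is region-specific when its
# per-region mean expression (i) exceeds a fold multiple of every other
# region's mean, (ii) exceeds a fraction of the other regions' average, and
# (iii) sits in the top expression quantile of its focal region.

#' Per-region mean expression
#'
#' @param expr Expression tibble (FPKM).
#' @param meta Metadata tibble consistent with `expr`.
#' @param aggregator `"mean"` (default) or `"median"` over a region's
#'   replicates.
#' @return A tibble with `gene_id` and one numeric column per region.
#' @export
region_means <- function(expr, meta, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  validate_metadata(meta, expr)
  m <- expr_matrix(expr)
  regions <- unique(meta$region)
  agg <- if (aggregator == "mean") rowMeans else function(x) apply(x, 1, stats::median)
  cols <- lapply(regions, function(r) {
    s <- meta$sample_id[meta$region == r]
    unname(agg(m[, s, drop = FALSE]))
  })
  names(cols) <- regions
  tibble::tibble(gene_id = rownames(m), !!!cols)
}

#' Detect region-specific genes
#'
#' Evaluates the three criteria on a genes x regions mean-expression table.
#' For each gene and candidate focal region r with per-gene means m:
#' criterion 1 holds when `m[r] > fold * m[s]` for every other region s
#' (`c1_aggregate = "each"`, default) or `m[r] > fold * mean(m[-r])`
#' (`"mean"`); criterion 2, read literally, holds when
#' `m[r] > other_mean_ratio * mean(m[-r])` (default `other_mean_ratio` 0.5;
#' the stricter reading `c2_rule = "strict"` requires the focal mean to exceed
#' the others' average by 50%, i.e. ratio > 1 + other_mean_ratio); criterion 3
#' holds when `m[r]` is at or above the `quantile` empirical quantile
#' (type 7, inclusive) of all genes' means in region r. A gene is an RSG when
#' all three hold. Records are emitted for every (gene, focal region) pair
#' passing criterion 1; with `fold > 1` and the `"each"` aggregate a gene can
#' have at most one focal region.
#'
#' @param rm Region-mean tibble from [region_means()].
#' @param fold Fold threshold for criterion 1 (default 3, must be > 1).
#' @param other_mean_ratio Ratio for criterion 2 (default 0.5).
#' @param quantile Quantile for criterion 3 (default 0.75, in (0,1)).
#' @param c1_aggregate Compare against `"each"` other region (default) or
#'   their `"mean"`.
#' @param c2_rule `"literal"` (default) or `"strict"` reading of criterion 2;
#'   both booleans are reported regardless.
#' @return A tibble of RSG records: `gene_id`, `focal_region`, `focal_mean`,
#'   `fold_vs_max_other`, `ratio_vs_other_mean`, `focal_quantile`, `c1`, `c2`,
#'   `c2_literal`, `c2_strict`, `c3`, `is_rsg`. The attribute `n_genes_tested`
#'   records the input size; genes with no focal region are omitted.
#' @export
detect_rsgs <- function(rm, fold = 3, other_mean_ratio = 0.5, quantile = 0.75,
                        c1_aggregate = c("each", "mean"),
                        c2_rule = c("literal", "strict")) {
  c1_aggregate <- match.arg(c1_aggregate)
  c2_rule <- match.arg(c2_rule)
  if (!(quantile > 0 && quantile < 1)) rlang::abort("quantile must be in (0, 1)")
  if (fold <= 1) rlang::abort("fold must be > 1")
  m <- as.matrix(rm[, -1, drop = FALSE])
  rownames(m) <- rm$gene_id
  regions <- colnames(m)
  qcut <- apply(m, 2, stats::quantile, probs = quantile, type = 7)
  recs <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    focal <- unname(m[, ri])
    others <- m[, -ri, drop = FALSE]
    max_other <- unname(apply(others, 1, max))
    mean_other <- unname(rowMeans(others))
    c1 <- if (c1_aggregate == "each") focal > fold * max_other else focal > fold * mean_other
    # all-zero rows: focal 0 is never > 0, so c1 is FALSE without any division
    ratio <- ifelse(mean_other > 0, focal / mean_other, ifelse(focal > 0, Inf, 0))
    c2_literal <- focal > other_mean_ratio * mean_other
    c2_strict <- focal > (1 + other_mean_ratio) * mean_other
    c3 <- focal >= qcut[ri]
    keep <- which(c1)
    if (!length(keep)) next
    c2 <- if (c2_rule == "literal") c2_literal else c2_strict
    pass2 <- c2[keep]
    pass3 <- c3[keep]
    recs[[ri]] <- tibble::tibble(
      gene_id = rownames(m)[keep],
      focal_region = regions[ri],
      focal_mean = focal[keep],
      fold_vs_max_other = ifelse(max_other[keep] > 0, focal[keep] / max_other[keep],
                                 ifelse(focal[keep] > 0, Inf, 0)),
      ratio_vs_other_mean = ratio[keep],
      focal_quantile = vapply(focal[keep], function(v) mean(m[, ri] <= v), numeric(1)),
      c1 = TRUE,
      c2 = pass2,
      c2_literal = c2_literal[keep],
      c2_strict = c2_strict[keep],
      c3 = pass3,
      is_rsg = pass2 & pass3
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), focal_region = character(),
                          focal_mean = numeric(), fold_vs_max_other = numeric(),
                          ratio_vs_other_mean = numeric(), focal_quantile = numeric(),
                          c1 = logical(), c2 = logical(), c2_literal = logical(),
                          c2_strict = logical(), c3 = logical(), is_rsg = logical())
  }
  if (c1_aggregate == "each" && anyDuplicated(out$gene_id)) {
    rlang::abort("internal error: a gene passed criterion 1 for two regions with fold > 1")
  }
  attr(out, "n_genes_tested") <- nrow(m)
  attr(out, "params") <- list(fold = fold, other_mean_ratio = other_mean_ratio,
                              quantile = quantile, c1_aggregate = c1_aggregate,
                              c2_rule = c2_rule)
  out
}

#' Per-region RSG counts
#'
#' @param records RSG record tibble from [detect_rsgs()].
#' @param regions Optional region levels to report (zero-filled).
#' @return A tibble `region`, `n_rsg`, with the grand total as attribute
#'   `total` (always the number of `is_rsg` records).
#' @export
rsg_region_counts <- function(records, regions = NULL) {
  hits <- records[records$is_rsg, , drop = FALSE]
  counts <- dplyr::count(hits, .data$focal_region, name = "n_rsg")
  names(counts)[1] <- "region"
  if (!is.null(regions)) {
    counts <- dplyr::left_join(tibble::tibble(region = regions), counts, by = "region") %>%
      dplyr::mutate(n_rsg = dplyr::coalesce(.data$n_rsg, 0L))
  }
  attr(counts, "total") <- nrow(hits)
  counts
}

#' Clustered RSG expression profile
#'
#' Restricts the expression table to RSGs, applies `log10(FPKM + 1)` by
#' default, and orders rows by average-linkage hierarchical clustering on
#' Euclidean distance so co-regulated RSGs sit together.
#'
#' @param expr Expression tibble (FPKM) containing every RSG.
#' @param records RSG record tibble from [detect_rsgs()].
#' @param transform `"log10_plus1"` (default) or `"none"`.
#' @return A tibble (`gene_id`, `focal_region`, sample columns) in clustered
#'   row order, with the `hclust` tree as attribute `hclust`.
#' @export
rsg_expression_profile <- function(expr, records, transform = c("log10_plus1", "none")) {
  transform <- match.arg(transform)
  hits <- records[records$is_rsg, , drop = FALSE]
  m <- expr_matrix(expr)
  miss <- setdiff(hits$gene_id, rownames(m))
  if (length(miss)) {
    rlang::abort(paste0("RSG gene(s) absent from expression table: ",
                        paste(utils::head(miss, 5), collapse = ", ")))
  }
  sub <- m[hits$gene_id, , drop = FALSE]
  if (transform == "log10_plus1") sub <- log10(sub + 1)
  ord <- seq_len(nrow(sub))
  tree <- NULL
  if (nrow(sub) >= 2) {
    tree <- stats::hclust(stats::dist(sub), method = "average")
    ord <- tree$order
  }
  out <- tibble::as_tibble(sub[ord, , drop = FALSE], .name_repair = "minimal")
  out <- tibble::add_column(out,
                            gene_id = hits$gene_id[ord],
                            focal_region = hits$focal_region[ord], .before = 1)
  attr(out, "hclust") <- tree
  attr(out, "transform") <- transform
  out
}
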