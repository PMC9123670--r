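#' @importFrom rlang .data abort warn :=
#' @importFrom dplyr %>%
NULL

# ---- internal representation helpers ---------------------------------------

#' Convert an expression tibble to a numeric matrix
#'
#' Expression tables in regiospec are tibbles whose first column is `gene_id`
#' and whose remaining columns are numeric per-sample abundances. This helper
#' extracts the numeric part as a genes x samples matrix with gene ids as row
#' names.
#'
#' @param expr An expression tibble (`gene_id` + one numeric column per sample).
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
expr_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Build an expression tibble from a matrix
#'
#' @param m Numeric matrix, genes in rows (row names = gene ids), samples in
#'   columns (column names = sample ids).
#' @param unit Abundance unit, `"counts"` or `"fpkm"`; stored as the `unit`
#'   attribute and persisted by [write_expression()].
#' @return A tibble with a `gene_id` column followed by one column per sample.
#' @export
as_expr_tbl <- function(m, unit = c("fpkm", "counts")) {
  unit <- match.arg(unit)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must carry gene ids as rownames and sample ids as colnames")
  }
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1)
  attr(out, "unit") <- unit
  validate_expression(out)
  out
}

#' Unit tag of an expression tibble
#' @param expr An expression tibble.
#' @return `"counts"`, `"fpkm"`, or `NA` when untagged.
#' @export
expr_unit <- function(expr) {
  u <- attr(expr, "unit", exact = TRUE)
  if (is.null(u)) NA_character_ else u
}

sample_ids <- function(expr) names(expr)[-1]

#' Validate an expression tibble
#'
#' Checks the container invariants: a `gene_id` first column, all-numeric
#' sample columns, no duplicated gene or sample identifiers, no missing
#' entries, and no negative abundances. Missing values are rejected, never
#' imputed.
#'
#' @param expr An expression tibble.
#' @return `expr`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2L || names(expr)[1] != "gene_id") {
    abort("expression table must have a `gene_id` first column and >= 1 sample column")
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g)) {
    abort(paste0("duplicated gene id(s): ", paste(utils::head(dup_g, 5), collapse = ", ")))
  }
  sids <- sample_ids(expr)
  dup_s <- unique(sids[duplicated(sids)])
  if (length(dup_s)) {
    abort(paste0("duplicated sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  vals <- expr[, -1, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    abort(paste0("non-numeric sample column(s): ", paste(sids[not_num], collapse = ", ")))
  }
  for (j in seq_along(vals)) {
    bad <- which(is.na(vals[[j]]))
    if (length(bad)) {
      abort(sprintf("missing value at gene '%s', sample '%s'", expr$gene_id[bad[1]], sids[j]))
    }
    neg <- which(vals[[j]] < 0)
    if (length(neg)) {
      abort(sprintf("negative value at gene '%s', sample '%s'", expr$gene_id[neg[1]], sids[j]))
    }
  }
  invisible(expr)
}

#' Validate a sample metadata table
#'
#' Metadata must hold `sample_id`, `region`, `replicate`, `individual`
#' columns; every region needs at least two samples (downstream Pearson
#' correlations against region indicators require within-region variance).
#' When `expr` is supplied, its sample columns must match `sample_id`
#' one-to-one.
#'
#' @param meta Metadata tibble.
#' @param expr Optional expression tibble to cross-check sample ids against.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, expr = NULL) {
  need <- c("sample_id", "region", "replicate", "individual")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) {
    abort("metadata sample_id values must be unique")
  }
  tab <- table(meta$region)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    abort(paste0("region(s) with fewer than 2 samples: ", paste(small, collapse = ", ")))
  }
  if (!is.null(expr)) {
    sids <- sample_ids(expr)
    if (!setequal(sids, meta$sample_id) || length(sids) != nrow(meta)) {
      abort("expression sample columns and metadata sample_id must match one-to-one")
    }
  }
  invisible(meta)
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# ---- i/o --------------------------------------------------------------------

#' Read an expression matrix from delimited text
#'
#' TSV by default; CSV is auto-detected from the `.csv` extension or forced
#' with `delim`. The table must carry gene identifiers along one margin and
#' sample identifiers along the other; `orientation` says which.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param unit Abundance unit to tag the result with (`"fpkm"` or `"counts"`);
#'   overridden by a `#unit:` header comment written by [write_expression()].
#' @param delim Field delimiter; `NULL` auto-detects from the extension.
#' @return An expression tibble (`gene_id` + sample columns), tagged with its
#'   unit.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "genes_in_columns"),
                            unit = c("fpkm", "counts"), delim = NULL) {
  orientation <- match.arg(orientation)
  unit <- match.arg(unit)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#unit:")) {
    unit <- match.arg(trimws(sub("^#unit:", "", first)), c("fpkm", "counts"))
  }
  raw <- readr::read_delim(path, delim = delim_for(path, delim), comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "gene_id"
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    abort(sprintf("non-numeric values in column '%s' of %s", names(raw)[-1][bad], path))
  }
  rownames(m) <- as.character(raw$gene_id)
  if (orientation == "genes_in_columns") m <- t(m)
  as_expr_tbl(m, unit = unit)
}

#' Write an expression matrix to delimited text
#'
#' Writes genes in rows with a `#unit:` comment line so the unit tag survives
#' a round trip through [read_expression()].
#'
#' @param expr Expression tibble.
#' @param path Output path (`.csv` switches the delimiter to comma).
#' @param delim Field delimiter; `NULL` auto-detects from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = NULL) {
  validate_expression(expr)
  u <- expr_unit(expr)
  writeLines(paste0("#unit: ", if (is.na(u)) "fpkm" else u), path)
  d <- delim_for(path, delim)
  readr::write_delim(expr, path, delim = d, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path Delimited text file with columns `sample_id`, `region`,
#'   `replicate`, `individual`.
#' @param delim Field delimiter; `NULL` auto-detects from the extension.
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path, delim = NULL) {
  meta <- readr::read_delim(path, delim = delim_for(path, delim),
                            show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
  meta
}

# ---- fpkm -------------------------------------------------------------------

#' Compute FPKM from read counts
#'
#' FPKM for gene i in sample j is `1e9 * c[i,j] / (N_j * L_i)` with `N_j` the
#' per-sample library size and `L_i` the gene length in base pairs. By default
#' the library size is the column sum of the count matrix; externally known
#' mapped-read totals can be supplied instead.
#'
#' @param counts Expression tibble in count units.
#' @param lengths Tibble with columns `gene_id` and `length` (bp) covering
#'   every gene of `counts`.
#' @param library_size `NULL` (default; per-sample column sums) or a named
#'   numeric vector of totals covering every sample.
#' @return An expression tibble in FPKM units.
#' @export
compute_fpkm <- function(counts, lengths, library_size = NULL) {
  m <- expr_matrix(counts)
  u <- expr_unit(counts)
  if (!is.na(u) && u != "counts") abort("compute_fpkm expects a counts-unit matrix")
  if (any(lengths$length < 1)) abort("gene lengths must be >= 1 bp")
  miss <- setdiff(rownames(m), lengths$gene_id)
  if (length(miss)) {
    abort(paste0("missing gene length for: ", paste(utils::head(miss, 5), collapse = ", ")))
  }
  L <- lengths$length[match(rownames(m), lengths$gene_id)]
  if (is.null(library_size)) {
    N <- colSums(m)
  } else {
    miss_s <- setdiff(colnames(m), names(library_size))
    if (length(miss_s)) abort(paste0("missing library size for sample(s): ", paste(miss_s, collapse = ", ")))
    N <- library_size[colnames(m)]
  }
  zero <- colnames(m)[N == 0]
  if (length(zero)) abort(paste0("zero library size for sample(s): ", paste(zero, collapse = ", ")))
  fpkm <- sweep(m, 2, N, "/") / L * 1e9
  as_expr_tbl(fpkm, unit = "fpkm")
}

# ---- filtering --------------------------------------------------------------

#' Replicate-consistency expression filter
#'
#' Keeps a gene when its FPKM exceeds `threshold` in all biological replicates
#' of at least one region (default scope, `"any_region_all_reps"`), i.e. the
#' gene is reliably expressed somewhere — region-restricted genes survive. The
#' stricter `"all_samples"` scope requires FPKM above threshold in every
#' sample of the study. Gene order is preserved; filtering is idempotent.
#'
#' @param expr Expression tibble in FPKM units.
#' @param meta Metadata tibble consistent with `expr`.
#' @param threshold FPKM threshold (strictly greater than); default 1.
#' @param scope `"any_region_all_reps"` (default) or `"all_samples"`.
#' @return The filtered expression tibble (a subset of rows of `expr`).
#' @export
filter_expressed <- function(expr, meta, threshold = 1,
                             scope = c("any_region_all_reps", "all_samples")) {
  scope <- match.arg(scope)
  if (threshold < 0) abort("threshold must be >= 0")
  validate_metadata(meta, expr)
  m <- expr_matrix(expr)
  above <- m > threshold
  if (scope == "all_samples") {
    keep <- rowSums(above) == ncol(m)
  } else {
    keep <- rep(FALSE, nrow(m))
    for (r in unique(meta$region)) {
      cols <- meta$sample_id[meta$region == r]
      keep <- keep | rowSums(above[, cols, drop = FALSE]) == length(cols)
    }
  }
  if (!any(keep)) warn("no genes pass the expression filter")
  out <- expr[keep, , drop = FALSE]
  attr(out, "unit") <- expr_unit(expr)
  out
}

# ---- presence summary -------------------------------------------------------

#' Expressed / shared / region-unique gene summary
#'
#' A gene counts as expressed in a sample when its FPKM exceeds
#' `presence_threshold` (default 0). Per region, the expressed set is the
#' union over the region's samples; the shared set is the intersection of the
#' region sets; a region-unique set is the region set minus the union of all
#' other region sets.
#'
#' @param expr Expression tibble in FPKM units.
#' @param meta Metadata tibble consistent with `expr`.
#' @param presence_threshold FPKM above which a gene is called expressed.
#' @return A `presence_summary` list with tibbles `per_sample` (sample_id,
#'   region, n_expressed), `per_region` (region, n_union, mean ± sd of
#'   per-sample counts, n_unique), the `shared` gene vector, and the named
#'   list `unique_sets`.
#' @export
presence_summary <- function(expr, meta, presence_threshold = 0) {
  validate_metadata(meta, expr)
  m <- expr_matrix(expr)
  present <- m > presence_threshold
  per_sample <- tibble::tibble(
    sample_id = colnames(m),
    region = meta$region[match(colnames(m), meta$sample_id)],
    n_expressed = colSums(present)
  )
  regions <- unique(meta$region)
  region_sets <- lapply(regions, function(r) {
    cols <- meta$sample_id[meta$region == r]
    rownames(m)[rowSums(present[, cols, drop = FALSE]) > 0]
  })
  names(region_sets) <- regions
  shared <- Reduce(intersect, region_sets)
  unique_sets <- lapply(seq_along(regions), function(i) {
    setdiff(region_sets[[i]], unique(unlist(region_sets[-i])))
  })
  names(unique_sets) <- regions
  per_region <- per_sample %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(mean_expressed = mean(.data$n_expressed),
                     sd_expressed = stats::sd(.data$n_expressed), .groups = "drop") %>%
    dplyr::left_join(
      tibble::tibble(region = regions,
                     n_union = lengths(region_sets),
                     n_unique = lengths(unique_sets)),
      by = "region")
  structure(list(per_sample = per_sample, per_region = per_region,
                 region_sets = region_sets, shared = shared,
                 unique_sets = unique_sets,
                 presence_threshold = presence_threshold),
            class = "presence_summary")
}

#' @export
print.presence_summary <- function(x, ...) {
  cat("Presence summary (FPKM >", x$presence_threshold, ")\n")
  cat("  shared across all regions:", length(x$shared), "genes\n")
  print(x$per_region)
  invisible(x)
}
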