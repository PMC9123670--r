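# Weighted co-expression network built from first principles: Pearson
# correlation on transformed expression, soft-power adjacency, topological
# overlap, average-linkage module detection, module eigengenes, and
# eigengene-based module merging.

transform_expr <- function(m, transform = c("log2_plus1", "none")) {
  transform <- match.arg(transform)
  if (transform == "log2_plus1") log2(m + 1) else m
}

#' Gene-gene Pearson correlation matrix
#'
#' Expression is log2(FPKM + 1)-transformed by default before correlation.
#' Zero-variance genes have no defined correlation and are removed with a
#' warning naming them.
#'
#' @param expr Expression tibble.
#' @param transform `"log2_plus1"` (default) or `"none"`.
#' @return A symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, transform = c("log2_plus1", "none")) {
  m <- transform_expr(expr_matrix(expr), transform)
  if (ncol(m) < 3) rlang::abort("correlation requires >= 3 samples")
  v <- apply(m, 1, stats::var)
  flat <- v == 0 | !is.finite(v)
  if (any(flat)) {
    rlang::warn(paste0("removing ", sum(flat), " zero-variance gene(s): ",
                       paste(utils::head(rownames(m)[flat], 5), collapse = ", ")))
    m <- m[!flat, , drop = FALSE]
  }
  cc <- stats::cor(t(m))
  diag(cc) <- 1
  cc
}

#' Soft-power adjacency matrix
#'
#' Unsigned: `a_ij = |cor_ij|^beta`; signed: `a_ij = ((1 + cor_ij)/2)^beta`.
#' The diagonal is set to 0 so that connectivity and topological-overlap sums
#' exclude self-edges, per the standard definition.
#'
#' @param cor Correlation matrix from [correlation_matrix()].
#' @param beta Soft-thresholding power (integer >= 1; the study value is 5).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return Adjacency matrix in \[0,1\] with zero diagonal.
#' @export
adjacency_matrix <- function(cor, beta = 5, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) rlang::abort("beta must be >= 1")
  a <- if (type == "unsigned") abs(cor)^beta else ((1 + cor) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for i != j, with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours u and `k_i = sum_u a_iu`
#' the connectivity; `TOM_ii = 1`. A fully isolated pair (zero adjacency and
#' zero connectivity) gets TOM 0 by convention rather than 0/0.
#'
#' @param adj Adjacency matrix with zero diagonal, entries in \[0,1\].
#' @return Symmetric TOM matrix, entries in \[0,1\], unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (any(diag(adj) != 0)) rlang::abort("adjacency diagonal must be zero")
  k <- rowSums(adj)
  l <- adj %*% adj            # zero diagonal makes this exactly sum_{u != i,j}
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - adj
  tom <- (l + adj) / denom
  tom[denom == 0] <- 0
  tom[adj == 0 & l == 0] <- 0 # isolated pairs
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power the adjacency connectivities `k_i` are binned;
#' the scale-free fit statistic is the squared Pearson correlation between
#' `log10` bin frequency and `log10` mean bin connectivity over occupied
#' bins. The chosen power is the smallest one reaching `r2_cutoff`
#' (default 0.80), falling back to the power with the best fit. Supplying
#' `beta` bypasses selection but still reports the per-power table.
#'
#' @param expr Expression tibble.
#' @param powers Candidate powers (default 1:20).
#' @param r2_cutoff Scale-free fit threshold (default 0.8).
#' @param beta Optional user-fixed power (e.g. 5) that bypasses selection.
#' @param type,transform Passed to [adjacency_matrix()] / [correlation_matrix()].
#' @param n_bins Number of connectivity bins (default 10); if fewer than 10
#'   bins are occupied the count is reduced with a warning, to a minimum of 5.
#' @return A `soft_threshold_fit` list: `beta`, `user_supplied`, and
#'   `fit_table` (power, r_squared, slope, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cutoff = 0.8, beta = NULL,
                                type = c("unsigned", "signed"),
                                transform = c("log2_plus1", "none"),
                                n_bins = 10) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  cc <- correlation_matrix(expr, transform)
  rows <- purrr::map(powers, function(p) {
    a <- adjacency_matrix(cc, beta = p, type = type)
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins = n_bins)
    tibble::tibble(power = p, r_squared = fit$r_squared, slope = fit$slope,
                   mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(beta)) {
    chosen <- beta
    user <- TRUE
  } else {
    ok <- which(tab$r_squared >= r2_cutoff)
    chosen <- if (length(ok)) tab$power[ok[1]] else tab$power[which.max(tab$r_squared)]
    user <- FALSE
  }
  structure(list(beta = chosen, user_supplied = user, r2_cutoff = r2_cutoff,
                 fit_table = tab),
            class = "soft_threshold_fit")
}

# Scale-free topology fit of a connectivity vector: R^2 of the log-log
# frequency vs mean-connectivity relation over occupied bins. Bins are
# log-spaced (a power law is linear in log k), which keeps the heavily
# right-skewed connectivity distributions of high powers from collapsing
# into a single occupied bin.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3 || min(k) == max(k)) {
    return(list(r_squared = NA_real_, slope = NA_real_))
  }
  repeat {
    breaks <- 10^seq(log10(min(k)), log10(max(k)), length.out = n_bins + 1)
    bin <- cut(k, breaks = breaks, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    meank <- tapply(k, bin, mean)
    occupied <- !is.na(freq) & freq > 0 & meank > 0
    if (sum(occupied) >= min(10, n_bins) || n_bins <= 5) break
    n_bins <- max(5, sum(occupied))
    rlang::warn(sprintf("fewer than 10 occupied connectivity bins; reducing to %d bins", n_bins))
  }
  x <- log10(meank[occupied])
  y <- log10(freq[occupied] / sum(freq[occupied]))
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r_squared = r^2, slope = r * stats::sd(y) / stats::sd(x))
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat("Soft threshold: beta =", x$beta,
      if (x$user_supplied) "(user-supplied)\n" else "(selected)\n")
  print(x$fit_table, n = Inf)
  invisible(x)
}

#' Detect modules by hierarchical clustering of the TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed fraction of the maximum merge height. Branches smaller than
#' `min_module_size` fall into the unassigned background (label 0); module
#' labels are renumbered by decreasing size, 1..M.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Cut at `cut_height * max(tree height)` (default 0.99).
#' @return A tibble `gene_id`, `module` (integer, 0 = unassigned), with the
#'   `hclust` tree and cut parameters as attributes.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  # average linkage is monotone; exact ties can still leave epsilon-scale
  # inversions that cutree rejects, so enforce monotone heights
  tree$height <- cummax(tree$height)
  h <- cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  relabelled <- renumber_modules(raw, min_module_size)
  if (all(relabelled == 0)) rlang::warn("no branch meets min_module_size; all genes unassigned")
  out <- tibble::tibble(gene_id = rownames(tom), module = relabelled)
  attr(out, "hclust") <- tree
  attr(out, "cut_height") <- h
  attr(out, "min_module_size") <- min_module_size
  out
}

# keep clusters of size >= min size; relabel 1..M by decreasing size (ties by
# first appearance), everything else 0
renumber_modules <- function(labels, min_module_size) {
  tab <- table(labels)
  big <- names(tab)[tab >= min_module_size]
  sizes <- sort(tab[big], decreasing = TRUE)
  new <- integer(length(labels))
  for (i in seq_along(sizes)) {
    new[labels == names(sizes)[i]] <- i
  }
  new
}

#' Module eigengenes
#'
#' Each module's expression submatrix is standardised per gene (zero mean,
#' unit variance across samples; constant genes are dropped with a warning)
#' and decomposed by SVD; the eigengene is the first right-singular vector —
#' the module's first principal component across samples — rescaled to unit
#' variance and sign-anchored so it correlates non-negatively with the
#' module's mean standardised expression. `variance_explained` is the first
#' squared singular value over the total.
#'
#' @param expr Expression tibble covering every assigned gene.
#' @param assignment Module assignment tibble from [detect_modules()].
#' @param transform Expression transform applied before standardisation;
#'   `"log2_plus1"` (default) matches the network construction.
#' @return An `eigengene_tbl`: tibble with `module` and one column per
#'   sample; attributes `variance_explained` (named numeric) and `n_genes`.
#' @export
module_eigengenes <- function(expr, assignment, transform = c("log2_plus1", "none")) {
  transform <- match.arg(transform)
  m <- transform_expr(expr_matrix(expr), transform)
  mods <- sort(unique(assignment$module[assignment$module > 0]))
  if (!length(mods)) rlang::abort("no modules to summarise (all genes unassigned)")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(m),
               dimnames = list(as.character(mods), colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), as.character(mods))
  ng <- stats::setNames(integer(length(mods)), as.character(mods))
  for (i in seq_along(mods)) {
    genes <- assignment$gene_id[assignment$module == mods[i]]
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) rlang::abort(paste0("assigned gene(s) absent from expression: ",
                                          paste(utils::head(miss, 3), collapse = ", ")))
    sub <- m[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      rlang::warn(paste0("dropping constant gene(s) from module ", mods[i], ": ",
                         paste(utils::head(genes[sds == 0], 3), collapse = ", ")))
      sub <- sub[sds > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2) rlang::abort(paste0("module ", mods[i], " has < 2 usable genes"))
    z <- t(scale(t(sub)))  # per-gene standardisation
    sv <- svd(z)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[i, ] <- e / stats::sd(e)
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    ng[i] <- nrow(sub)
  }
  out <- tibble::as_tibble(me, .name_repair = "minimal")
  out <- tibble::add_column(out, module = mods, .before = 1)
  attr(out, "variance_explained") <- ve
  attr(out, "n_genes") <- ng
  class(out) <- c("eigengene_tbl", class(out))
  out
}

me_matrix <- function(me) {
  m <- as.matrix(me[, -1, drop = FALSE])
  rownames(m) <- as.character(me$module)
  m
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene dissimilarity
#' `1 - Pearson r` falls below `merge_cut_height`, recomputing eigengenes
#' after each merge, until no pair qualifies. Labels are renumbered by
#' decreasing module size.
#'
#' @param expr Expression tibble.
#' @param assignment Module assignment tibble.
#' @param merge_cut_height Eigengene dissimilarity below which modules merge
#'   (default 0.25); 0 leaves the assignment unchanged.
#' @param transform Expression transform, as in [module_eigengenes()].
#' @return A module assignment tibble of the same shape.
#' @export
merge_close_modules <- function(expr, assignment, merge_cut_height = 0.25,
                                transform = c("log2_plus1", "none")) {
  transform <- match.arg(transform)
  if (merge_cut_height < 0 || merge_cut_height > 1) {
    rlang::abort("merge_cut_height must be in [0, 1]")
  }
  labels <- assignment$module
  if (merge_cut_height == 0) return(assignment)
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    asg <- tibble::tibble(gene_id = assignment$gene_id, module = labels)
    me <- me_matrix(module_eigengenes(expr, asg, transform))
    diss <- 1 - stats::cor(t(me))
    diag(diss) <- Inf
    if (min(diss) >= merge_cut_height) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    a <- mods[idx[1]]; b <- mods[idx[2]]
    labels[labels == max(a, b)] <- min(a, b)
  }
  sizes <- table(labels[labels > 0])
  ord <- names(sort(sizes, decreasing = TRUE))
  new <- integer(length(labels))
  for (i in seq_along(ord)) new[labels == as.integer(ord[i])] <- i
  out <- tibble::tibble(gene_id = assignment$gene_id, module = new)
  attr(out, "merge_cut_height") <- merge_cut_height
  out
}

#' Build a weighted co-expression network end to end
#'
#' Convenience wrapper: correlation, soft-power adjacency (fixed `beta` or
#' scale-free selection), TOM, module detection, eigengene merging, and final
#' eigengenes.
#'
#' @param expr Filtered expression tibble (FPKM).
#' @param beta Soft power; `NULL` selects by scale-free fit. The study's
#'   value is 5.
#' @param type Network type, `"unsigned"` (default) or `"signed"`.
#' @param transform Expression transform (default `"log2_plus1"`).
#' @param min_module_size,cut_height,merge_cut_height Module-detection
#'   parameters, see [detect_modules()] and [merge_close_modules()].
#' @param powers Candidate powers when `beta` is `NULL`.
#' @return A `coexpression_network` list: `assignment`, `eigengenes`,
#'   `soft_threshold` (fit object or NULL), `params`.
#' @export
build_network <- function(expr, beta = 5, type = c("unsigned", "signed"),
                          transform = c("log2_plus1", "none"),
                          min_module_size = 30, cut_height = 0.99,
                          merge_cut_height = 0.25, powers = 1:20) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  sft <- NULL
  if (is.null(beta)) {
    sft <- pick_soft_threshold(expr, powers = powers, type = type, transform = transform)
    beta <- sft$beta
  }
  cc <- correlation_matrix(expr, transform)
  kept <- rownames(cc)
  adj <- adjacency_matrix(cc, beta = beta, type = type)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, min_module_size = min_module_size,
                               cut_height = cut_height)
  assignment <- merge_close_modules(expr[expr$gene_id %in% kept, , drop = FALSE],
                                    assignment, merge_cut_height, transform)
  me <- module_eigengenes(expr, assignment, transform)
  structure(list(assignment = assignment, eigengenes = me, soft_threshold = sft,
                 params = list(beta = beta, type = type, transform = transform,
                               min_module_size = min_module_size,
                               cut_height = cut_height,
                               merge_cut_height = merge_cut_height)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  n_mod <- max(x$assignment$module)
  cat("Co-expression network: beta =", x$params$beta, ", type =", x$params$type, "\n")
  cat("  ", n_mod, "modules over", nrow(x$assignment), "genes (",
      sum(x$assignment$module == 0), "unassigned )\n")
  invisible(x)
}
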