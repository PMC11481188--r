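#' Soft-thresholded adjacency matrix
#'
#' Unsigned weighted-network adjacency: `|pearson_r|^power` between all
#' transcript pairs, with the diagonal set to 1. Soft thresholding at the
#' conventional power of 12 suppresses weak correlations while keeping the
#' network weighted. Constant transcripts have undefined correlations; their
#' adjacencies are set to 0 with a warning.
#'
#' @param expr A `normalized_expression` object or a transcripts x samples
#'   matrix with >= 4 samples.
#' @param power Soft-threshold exponent (default 12).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(expr, power = 12) {
  mat <- if (inherits(expr, "normalized_expression")) expr$matrix else expr
  assert_matrix(mat, "expression")
  if (ncol(mat) < 4) stop_invalid("adjacency needs >= 4 samples")
  r <- suppressWarnings(cor(t(mat)))
  if (anyNA(r)) {
    warning("constant transcripts present; their adjacencies were set to 0")
    r[is.na(r)] <- 0
  }
  a <- abs(r)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, where the
#' sum runs over shared neighbours `u != i, j` and `k` is the connectivity
#' (row sum excluding the diagonal). Measures how much two transcripts share
#' neighbours in addition to their direct adjacency; `1 - TOM` is the
#' clustering dissimilarity.
#'
#' @param adjacency Symmetric matrix with entries in `[0, 1]`.
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  assert_matrix(adjacency, "adjacency")
  if (nrow(adjacency) != ncol(adjacency) ||
      max(abs(adjacency - t(adjacency))) > 1e-8)
    stop_invalid("adjacency must be symmetric")
  if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12)
    stop_invalid("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                     # u = i and u = j terms vanish (diag 0)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage clustering on `1 - TOM`, cut at a static height
#' `0.99 * max(h) - deep_split * 0.05 * range(h)` - a documented
#' simplification of dynamic hybrid tree cutting in which larger
#' `deep_split` values cut deeper and split more finely. Clusters smaller
#' than `min_module_size` are assigned label 0 (unassigned); surviving
#' modules are relabelled 1..K by decreasing size.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param deep_split Split depth level (default 2).
#' @return Integer vector of module labels, named by transcript.
#' @export
detect_modules <- function(tom, min_module_size = 30, deep_split = 2) {
  assert_matrix(tom, "TOM")
  n <- nrow(tom)
  labels <- setNames(integer(n), rownames(tom))
  if (n < min_module_size) {
    warning("fewer transcripts than min_module_size; all unassigned")
    return(labels)
  }
  h <- hclust(as.dist(1 - tom), method = "average")
  rng <- range(h$height)
  cut_h <- 0.99 * rng[2] - deep_split * 0.05 * diff(rng)
  raw <- cutree(h, h = max(cut_h, 0))
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-transcript standardized submatrix: the single per-sample profile that
#' explains the largest share of the module's variance. Each eigengene is
#' sign-aligned so it correlates non-negatively with the module's mean
#' expression profile, and scaled to unit variance.
#'
#' @param expr A `normalized_expression` object or matrix (transcripts x
#'   samples).
#' @param labels Module labels from [detect_modules()]; label 0 is ignored.
#' @return Matrix, samples x modules, columns named `M<id>`.
#' @export
module_eigengenes <- function(expr, labels) {
  mat <- if (inherits(expr, "normalized_expression")) expr$matrix else expr
  assert_matrix(mat, "expression")
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop_degenerate("no assigned modules")
  out <- matrix(NA_real_, ncol(mat), length(mods),
                dimnames = list(colnames(mat), paste0("M", mods)))
  for (i in seq_along(mods)) {
    sub <- scale_per_transcript(mat[labels == mods[i], , drop = FALSE])
    if (nrow(sub) < 2) stop_invalid("module ", mods[i], " has < 2 members")
    sv <- svd(sub, nu = 0, nv = 1)
    if (sv$d[1] <= 1e-12) stop_degenerate("module ", mods[i], " is singular")
    e <- sv$v[, 1]
    profile <- colMeans(sub)
    if (sum(e * profile) < 0) e <- -e
    out[, i] <- e / sd(e)
  }
  out
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - pearson_r` is smallest, while it is below `merge_threshold`,
#' recomputing eigengenes after every merge. Final labels are renumbered
#' consecutively by decreasing module size.
#'
#' @param expr Expression used to recompute eigengenes.
#' @param labels Module labels.
#' @param merge_threshold Dissimilarity below which modules merge (default
#'   0.25).
#' @return Integer label vector after merging.
#' @export
merge_close_modules <- function(expr, labels, merge_threshold = 0.25) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eg <- module_eigengenes(expr, labels)
    diss <- 1 - cor(eg)
    diag(diss) <- Inf
    ij <- arrayInd(which.min(diss), dim(diss))
    if (diss[ij] >= merge_threshold) break
    a <- mods[min(ij)]; b <- mods[max(ij)]
    labels[labels == b] <- a
  }
  relabel_by_size(labels)
}

relabel_by_size <- function(labels) {
  mods <- unique(labels[labels > 0])
  if (length(mods) == 0) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), 0L)
  mods <- mods[order(-sizes, mods)]
  out <- labels
  for (i in seq_along(mods)) out[labels == mods[i]] <- i
  out
}

#' Correlate module eigengenes with age
#'
#' Pearson correlation of each eigengene with sample age, with a two-tailed
#' p-value from the t transform on `n - 2` degrees of freedom. A module is
#' flagged significant when `|r| >= min_cor` and `p <= alpha` (defaults 0.30
#' and 0.05).
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param ages Sample ages (>= 4 finite values).
#' @param min_cor,alpha Significance thresholds on `|r|` and p.
#' @return Data frame: `module`, `pearson_r`, `p_value`, `significant`.
#' @export
correlate_modules_with_age <- function(eigengenes, ages, min_cor = 0.30,
                                       alpha = 0.05) {
  if (length(ages) < 4 || any(!is.finite(ages)))
    stop_invalid("ages must be >= 4 finite values")
  stopifnot(nrow(eigengenes) == length(ages))
  res <- lapply(seq_len(ncol(eigengenes)), function(i) {
    e <- eigengenes[, i]
    if (sd(e) == 0 || sd(ages) == 0)
      return(data.frame(module = colnames(eigengenes)[i], pearson_r = NA_real_,
                        p_value = NA_real_, significant = FALSE))
    ct <- cor.test(e, ages, method = "pearson")
    data.frame(module = colnames(eigengenes)[i],
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               significant = abs(ct$estimate) >= min_cor & ct$p.value <= alpha)
  })
  do.call(rbind, res)
}

#' Detect, merge, and age-screen co-expression modules
#'
#' End-to-end network stage: soft adjacency, topological overlap, module
#' detection, eigengene merging, and eigengene-age correlation.
#'
#' @param expr A `normalized_expression` object or matrix.
#' @param ages Sample ages.
#' @param power,min_module_size,deep_split,merge_threshold,min_cor,alpha
#'   Stage parameters; see the individual operations.
#' @return Object of class `module_set`: `labels`, `eigengenes`, `age_stats`
#'   (with per-module transcript counts), and `params`.
#' @export
find_modules <- function(expr, ages, power = 12, min_module_size = 30,
                         deep_split = 2, merge_threshold = 0.25,
                         min_cor = 0.30, alpha = 0.05) {
  mat <- if (inherits(expr, "normalized_expression")) expr$matrix else expr
  adj <- soft_adjacency(mat, power = power)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom, min_module_size, deep_split)
  if (any(labels > 0))
    labels <- merge_close_modules(mat, labels, merge_threshold)
  if (!any(labels > 0)) {
    return(structure(list(labels = labels, eigengenes = NULL,
                          age_stats = NULL,
                          params = list(power = power,
                                        min_module_size = min_module_size,
                                        deep_split = deep_split,
                                        merge_threshold = merge_threshold)),
                     class = "module_set"))
  }
  eg <- module_eigengenes(mat, labels)
  stats <- correlate_modules_with_age(eg, ages, min_cor, alpha)
  stats$n_transcripts <- vapply(sort(unique(labels[labels > 0])),
                                function(m) sum(labels == m), 0L)
  structure(list(labels = labels, eigengenes = eg, age_stats = stats,
                 params = list(power = power,
                               min_module_size = min_module_size,
                               deep_split = deep_split,
                               merge_threshold = merge_threshold,
                               min_cor = min_cor, alpha = alpha)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0]))
  cat("Module set:", n_mod, "modules over", length(x$labels), "transcripts (",
      sum(x$labels == 0), "unassigned )\n")
  if (!is.null(x$age_stats)) print(x$age_stats, row.names = FALSE)
  invisible(x)
}
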