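#' Read pathway gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (name, description, genes...).
#' @return Named list of character vectors of member gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_invalid("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "agecourse", pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Two-tailed Fisher's exact test for gene-set overlap
#'
#' Tests whether a pathway is over- or under-represented in a gene set
#' relative to a universe, from the 2x2 table (in set / not in set) x
#' (in pathway / not in pathway). The two-tailed p sums hypergeometric
#' probabilities of all tables at least as extreme (probability no larger
#' than the observed table's).
#'
#' @param set_genes Genes in the query set (subset of `universe_genes`).
#' @param pathway_genes Pathway members (subset of `universe_genes`).
#' @param universe_genes Background universe of gene IDs.
#' @return List with `table` (2x2 counts) and `p`.
#' @export
fisher_enrichment <- function(set_genes, pathway_genes, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) stop_invalid("empty universe")
  set_genes <- unique(intersect(set_genes, universe_genes))
  pathway_genes <- unique(intersect(pathway_genes, universe_genes))
  a <- length(intersect(set_genes, pathway_genes))
  b <- length(set_genes) - a
  c_ <- length(pathway_genes) - a
  d <- length(universe_genes) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(set = c("in_set", "out_set"),
                                pathway = c("in_pathway", "out_pathway")))
  list(table = tab, p = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Activation z-score of a pathway
#'
#' Directional consistency statistic `z = sum(x_i) / sqrt(N)` over member
#' directions `x_i = +1` (up with age) or `-1` (down with age), where `N` is
#' the number of members observed. `|z| = sqrt(N)` exactly when all members
#' agree; `z = 0` under balanced up/down. The denominator exponent is
#' configurable (`denominator = "sqrt_n"` is the standard convention;
#' `"n"` divides by N instead).
#'
#' @param directions Non-empty vector of +1/-1 member directions.
#' @param denominator `"sqrt_n"` (default) or `"n"`.
#' @return The z-score.
#' @export
activation_zscore <- function(directions, denominator = c("sqrt_n", "n")) {
  denominator <- match.arg(denominator)
  if (length(directions) == 0) stop_invalid("directions must be non-empty")
  if (!all(directions %in% c(-1, 1)))
    stop_invalid("directions must be +1 or -1")
  n <- length(directions)
  sum(directions) / if (denominator == "sqrt_n") sqrt(n) else n
}

#' Exact two-tailed binomial skew test
#'
#' Tests whether `k` successes in `n` trials deviate from the null success
#' probability `p0`, summing `P(X = j)` over all outcomes with point
#' probability no larger than the observed one (the standard exact two-tailed
#' construction). Used to test category skew, e.g. whether downregulated
#' pathways are disproportionately metabolic.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability in (0, 1); default 0.5.
#' @return Two-tailed p-value.
#' @export
binomial_skew_test <- function(k, n, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop_invalid("p0 must be in (0, 1)")
  if (n < 1 || k < 0 || k > n) stop_invalid("need 0 <= k <= n, n >= 1")
  binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Assign per-gene age directions
#'
#' Direction is the sign of the gene's module-age correlation (encoded
#' downstream as a fold-change of +/-2); for genes whose chosen trajectory is
#' quadratic the direction is overridden by the post-vertex slope sign, i.e.
#' the sign of the quadratic coefficient B2.
#'
#' @param labels Named module labels per transcript (0 = unassigned).
#' @param module_stats `age_stats` data frame from [find_modules()] (needs
#'   `module`, `pearson_r`, `p_value`).
#' @param fits Optional per-transcript trajectory fits from
#'   [fit_trajectories()] (needs `transcript_id`, `chosen_model`, `b2_quad`).
#' @return Data frame `transcript_id`, `direction` (+1/-1), `fold_change`
#'   (+/-2), `p` (the module p-value, inherited); genes with neither a module
#'   sign nor a quadratic fit are dropped with a warning.
#' @export
assign_directions <- function(labels, module_stats, fits = NULL) {
  ids <- names(labels)
  mod_of <- paste0("M", labels)
  r <- module_stats$pearson_r[match(mod_of, module_stats$module)]
  p <- module_stats$p_value[match(mod_of, module_stats$module)]
  dir <- sign(r)
  if (!is.null(fits)) {
    m <- match(ids, fits$transcript_id)
    quad <- !is.na(m) & fits$chosen_model[m] == "quadratic"
    dir[quad] <- sign(fits$b2_quad[m[quad]])
  }
  bad <- is.na(dir) | dir == 0
  if (any(bad))
    warning(sum(bad), " transcript(s) had no direction source; excluded")
  data.frame(transcript_id = ids[!bad], direction = as.integer(dir[!bad]),
             fold_change = 2 * as.integer(dir[!bad]),
             p = p[!bad], stringsAsFactors = FALSE)
}

#' Directional pathway enrichment
#'
#' For every pathway: overlap with the query set, two-tailed Fisher exact
#' p-value against the universe, Benjamini-Hochberg adjustment across
#' pathways, and the activation z-score over the directions of the overlapping
#' genes.
#'
#' @param directions Data frame from [assign_directions()] (the query set:
#'   every row is an age-associated gene with a +/-1 direction).
#' @param pathways Named list of pathway member IDs (e.g. from [read_gmt()]).
#' @param universe_genes Universe of gene IDs; defaults to all transcripts
#'   that passed the count filter (callers pass them explicitly).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return Data frame of class `enrichment_result`: `pathway`, `n_overlap`,
#'   `n_pathway`, `fisher_p`, `bh_adjusted_p`, `z`, `significant`.
#' @export
pathway_enrichment <- function(directions, pathways, universe_genes,
                               alpha = 0.05) {
  if (length(pathways) == 0) stop_invalid("no pathways supplied")
  set_genes <- directions$transcript_id
  rows <- lapply(names(pathways), function(nm) {
    pg <- pathways[[nm]]
    fe <- fisher_enrichment(set_genes, pg, universe_genes)
    ov <- intersect(set_genes, pg)
    z <- if (length(ov) == 0) NA_real_ else
      activation_zscore(directions$direction[match(ov, set_genes)])
    data.frame(pathway = nm, n_overlap = length(ov),
               n_pathway = length(intersect(pg, universe_genes)),
               fisher_p = fe$p, z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_adjusted_p <- bh_adjust(out$fisher_p)
  out$significant <- out$bh_adjusted_p <= alpha
  out <- out[, c("pathway", "n_overlap", "n_pathway", "fisher_p",
                 "bh_adjusted_p", "z", "significant")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}
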