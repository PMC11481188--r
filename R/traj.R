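#' Fit linear and quadratic age trajectories and choose between them
#'
#' Ordinary least squares of `y = B0 + B1*x` and `y = B0 + B1*x + B2*x^2`,
#' compared with the extra sum-of-squares F test
#' `F = (SSE_lin - SSE_quad) / (SSE_quad / df_quad)` on `(1, df_quad)`
#' degrees of freedom. The quadratic model is chosen when `f_p <= alpha`.
#' The age effect is then tested against the null impact of age (`B1 = 0`
#' under the linear model, `B2 = 0` under the quadratic) by the coefficient
#' t test. For quadratic fits the vertex (tipping-point) age `-B1 / (2*B2)`
#' is extracted and flagged when it lies inside the observed age range
#' (plus `vertex_margin` years).
#'
#' When both models fit essentially perfectly (improvement below numerical
#' tolerance) the simpler linear model is kept.
#'
#' @param ages Ages in years; >= 4 distinct values.
#' @param values Response vector (one transcript's expression, or a pathway
#'   average).
#' @param alpha F-test significance level for preferring the quadratic model.
#' @param vertex_margin Years beyond the observed age range within which a
#'   vertex still counts as in-range.
#' @return Object of class `trajectory_fit`: linear and quadratic
#'   coefficients with SSE and df, `f_stat`, `f_p`, `chosen_model`,
#'   `age_effect_p`, `vertex_age`, `vertex_in_range`.
#' @export
fit_trajectory <- function(ages, values, alpha = 0.05, vertex_margin = 1.0) {
  if (length(ages) != length(values)) stop_invalid("ages and values differ in length")
  if (length(unique(ages)) < 4)
    stop_invalid("need >= 4 distinct ages")
  if (any(!is.finite(ages)) || any(!is.finite(values)))
    stop_invalid("ages and values must be finite")
  x <- as.numeric(ages); y <- as.numeric(values)
  n <- length(x)
  fl <- lm(y ~ x)
  fq <- lm(y ~ x + I(x^2))
  sse_l <- sum(resid(fl)^2); sse_q <- sum(resid(fq)^2)
  df_q <- n - 3
  tss <- sum((y - mean(y))^2)
  tol <- 1e-10 * max(tss, 1e-12)
  if (sse_l - sse_q <= tol) {            # no measurable quadratic improvement
    f_stat <- 0; f_p <- 1
  } else if (sse_q <= tol) {             # exact quadratic
    f_stat <- Inf; f_p <- 0
  } else {
    f_stat <- (sse_l - sse_q) / (sse_q / df_q)
    f_p <- pf(f_stat, 1, df_q, lower.tail = FALSE)
  }
  chosen <- if (f_p <= alpha) "quadratic" else "linear"
  cl <- unname(coef(fl)); cq <- unname(coef(fq))
  age_effect_p <- if (chosen == "linear") coef_p(fl, 2L) else coef_p(fq, 3L)
  vtx <- NA_real_; in_range <- FALSE
  if (chosen == "quadratic" && is.finite(cq[3]) && cq[3] != 0) {
    vtx <- vertex(cq[2], cq[3])
    in_range <- vtx >= min(x) - vertex_margin & vtx <= max(x) + vertex_margin
  }
  structure(list(b0_lin = cl[1], b1_lin = cl[2], sse_lin = sse_l, df_lin = n - 2,
                 b0_quad = cq[1], b1_quad = cq[2], b2_quad = cq[3],
                 sse_quad = sse_q, df_quad = df_q,
                 f_stat = f_stat, f_p = f_p, chosen_model = chosen,
                 age_effect_p = age_effect_p,
                 vertex_age = vtx, vertex_in_range = in_range),
            class = "trajectory_fit")
}

coef_p <- function(fit, idx) {
  # summary.lm warns on numerically perfect fits; the p-value is still valid
  s <- suppressWarnings(summary(fit))$coefficients
  if (nrow(s) < idx || !is.finite(s[idx, 4])) 1 else s[idx, 4]
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Trajectory fit:", x$chosen_model,
      sprintf("(F = %.3g, p = %.3g; age-effect p = %.3g)\n",
              x$f_stat, x$f_p, x$age_effect_p))
  if (x$chosen_model == "quadratic")
    cat(sprintf("  vertex age %.2f yr (%s range)\n", x$vertex_age,
                if (x$vertex_in_range) "in" else "outside"))
  invisible(x)
}

#' Vertex age of a quadratic trajectory
#'
#' The extremum of `B0 + B1*x + B2*x^2`, i.e. `-B1 / (2*B2)`: the age at
#' which the trajectory changes direction.
#'
#' @param b1 Linear coefficient.
#' @param b2 Quadratic coefficient (non-zero).
#' @return Vertex age in years.
#' @export
vertex <- function(b1, b2) {
  if (!is.finite(b2) || b2 == 0) stop_invalid("vertex undefined for B2 = 0")
  -b1 / (2 * b2)
}

#' Fit trajectories for every transcript in a matrix
#'
#' @param mat Transcripts x samples matrix.
#' @param ages Sample ages.
#' @param ... Passed to [fit_trajectory()].
#' @return Data frame with one row per transcript: coefficients, F statistic
#'   and p, chosen model, age-effect p, vertex age and in-range flag.
#' @export
fit_trajectories <- function(mat, ages, ...) {
  assert_matrix(mat, "expression")
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    f <- fit_trajectory(ages, mat[i, ], ...)
    data.frame(transcript_id = rownames(mat)[i] %||% as.character(i),
               b1_lin = f$b1_lin, b1_quad = f$b1_quad, b2_quad = f$b2_quad,
               sse_lin = f$sse_lin, sse_quad = f$sse_quad,
               f_stat = f$f_stat, f_p = f$f_p, chosen_model = f$chosen_model,
               age_effect_p = f$age_effect_p, vertex_age = f$vertex_age,
               vertex_in_range = f$vertex_in_range, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway tipping point: mean and SD of member vertices
#'
#' Aggregates the vertex ages of a pathway's member transcripts, counting
#' only members whose chosen model is quadratic and whose vertex lies inside
#' the observed age range: a pathway's tipping point is reported as mean
#' +/- sample standard deviation over those members.
#'
#' @param fits Data frame from [fit_trajectories()].
#' @param members Transcript IDs of the pathway.
#' @return List: `mean_vertex`, `sd_vertex` (0 with `sd_defined = FALSE` when
#'   only one member is eligible), `n_members`, `vertices`. `NULL` fields and
#'   a warning when no member is eligible.
#' @export
pathway_tipping_point <- function(fits, members) {
  sel <- fits$transcript_id %in% members &
    fits$chosen_model == "quadratic" & fits$vertex_in_range
  v <- fits$vertex_age[sel]
  if (length(v) == 0) {
    warning("no eligible quadratic members; empty tipping point")
    return(list(mean_vertex = NA_real_, sd_vertex = NA_real_,
                sd_defined = FALSE, n_members = 0L, vertices = numeric(0)))
  }
  list(mean_vertex = mean(v),
       sd_vertex = if (length(v) > 1) sd(v) else 0,
       sd_defined = length(v) > 1, n_members = length(v), vertices = v)
}

#' Average pathway profile and its trajectory fit
#'
#' Per-sample mean of the members' standardized expression, fitted with
#' [fit_trajectory()] - the pathway-level analogue of the per-transcript
#' regression.
#'
#' @param expr_scaled Standardized expression matrix (rows scaled, see
#'   [scale_per_transcript()]).
#' @param members Pathway transcript IDs (>= 1 present in the matrix).
#' @param ages Sample ages.
#' @param ... Passed to [fit_trajectory()].
#' @return List with `profile` (per-sample mean) and `fit`.
#' @export
pathway_average_profile <- function(expr_scaled, members, ages, ...) {
  present <- intersect(members, rownames(expr_scaled))
  if (length(present) == 0) stop_invalid("no pathway members in the matrix")
  profile <- colMeans(expr_scaled[present, , drop = FALSE])
  list(profile = profile, fit = fit_trajectory(ages, profile, ...))
}

#' Hierarchical clustering of expression profiles
#'
#' Average-linkage agglomeration on Euclidean distances between row
#' profiles; the agglomeration is deterministic for a given input order.
#'
#' @param expr_scaled Matrix with >= 2 rows.
#' @return An [stats::hclust] object (leaf `order`, merge `height`s).
#' @export
cluster_profiles <- function(expr_scaled) {
  assert_matrix(expr_scaled, "expression")
  if (nrow(expr_scaled) < 2) stop_invalid("need >= 2 profiles")
  hclust(dist(expr_scaled, method = "euclidean"), method = "average")
}

#' Principal component analysis of expression profiles
#'
#' Rows (transcript profiles) are the observations; columns are centred.
#'
#' @param expr_scaled Matrix with >= 2 rows and >= 2 columns.
#' @return List with `scores` (rows x components), `rotation`, and
#'   `explained` (variance fractions, summing to <= 1).
#' @export
pca_profiles <- function(expr_scaled) {
  assert_matrix(expr_scaled, "expression")
  if (nrow(expr_scaled) < 2 || ncol(expr_scaled) < 2)
    stop_invalid("need >= 2 profiles and >= 2 samples")
  p <- prcomp(expr_scaled, center = TRUE, scale. = FALSE)
  list(scores = p$x, rotation = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2))
}
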