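#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test pf pt lm coef fisher.test p.adjust binom.test
#'   rnbinom rpois rnorm runif rlnorm sd var prcomp hclust dist cutree
#'   as.dist quantile resid fitted aggregate uniroot setNames
#' @importFrom utils write.table read.table head
NULL

# Derive a sub-seed for a named random stream from the master seed, so that
# every generator consumes its own stream and adding a stage never perturbs
# the draws of another. Kept below 2^31 - 1.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 10007 + h * 2654435) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("agecourse_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("agecourse_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) == 0L || ncol(x) == 0L)
    stop_invalid(what, " must be a non-empty numeric matrix")
  invisible(x)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))
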