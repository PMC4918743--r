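# RNG handling: every stochastic routine takes an integer seed, runs under a
# locally-set RNG state, and restores the caller's state afterwards, so
# results are reproducible bit-for-bit and independent of call order.

.datatable.aware <- TRUE

#' Evaluate an expression under a local RNG seed
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds from one master seed, all below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Cosine similarity of two vectors.
cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Format a p-value for reports
#'
#' Values at or above 0.001 are shown to 4 decimals; smaller values in
#' scientific notation with 3 significant digits.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p >= 0.001, sprintf("%.4f", p),
         sprintf("%.2e", signif(p, 3)))
}
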