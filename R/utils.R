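#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# encode an ordered gene pair (i, j) as a single integer index in 1..M^2
pair_index <- function(i, j, n_genes) (i - 1L) * n_genes + j

index_pair <- function(idx, n_genes) {
  i <- (idx - 1L) %/% n_genes + 1L
  j <- (idx - 1L) %% n_genes + 1L
  cbind(i, j)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
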