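# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# run expr with a locally-set RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# row-standardize a matrix: mean 0, sd 1 per row; constant rows -> 0, flagged
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  constant <- sdv < 1e-12 | !is.finite(sdv)
  sdv[constant] <- 1
  std <- (m - mu) / sdv
  std[constant, ] <- 0
  list(std = std, constant = constant)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used throughout validation to compare recovered kinetic/wave modules with
#' planted ground truth; 1 means identical partitions up to relabeling,
#' values near 0 mean chance-level agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
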