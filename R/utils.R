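#' @keywords internal
"_PACKAGE"

#' @importFrom methods is as
#' @importFrom stats rnorm rpois rbinom runif sd var qnorm dist setNames median
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a parent seed and a stream label
#'
#' All stochastic components (splits, initialisation, dropout, augmentation,
#' posterior sampling, subsampling in metrics) draw their seeds through this
#' helper so that a single top-level seed determines the whole run while
#' independent streams stay decorrelated. The result is kept below 2^31 - 1.
#'
#' @param seed integer parent seed
#' @param ... labels (coerced to character) identifying the stream
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, as.character(unlist(list(...)))), collapse = "/")
  # simple polynomial rolling hash over the label bytes, kept in 31-bit range
  bytes <- utf8ToInt(lab)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}

#' Standardize columns of a matrix to zero mean and unit variance
#'
#' Zero-variance columns fall back to scale 1 so they standardise to all
#' zeros instead of dividing by zero.
#'
#' @param x numeric matrix (cells x features)
#' @param params optional list with `center` and `scale` to reuse
#' @return list with `x` (standardized dense matrix) and `params`
#'   (`center`, `scale`)
#' @export
standardize_features <- function(x, params = NULL) {
  x <- as_dense(x)
  if (is.null(params)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale <= 0] <- 1
    params <- list(center = center, scale = scale)
  }
  x <- sweep(x, 2, params$center, "-")
  x <- sweep(x, 2, params$scale, "/")
  list(x = x, params = params)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

one_hot <- function(values, levels) {
  values <- as.character(values)
  unseen <- setdiff(unique(values), levels)
  stop_if(length(unseen) > 0,
          "unseen covariate category: ", paste(unseen, collapse = ", "))
  m <- matrix(0, nrow = length(values), ncol = length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(values), match(values, levels))] <- 1
  m
}

# pairwise squared Euclidean distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
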