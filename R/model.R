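#' Construct modality-specific translator parameters
#'
#' A translator is a linear map from a modality's native feature space (f
#' features) into the shared gene-centric space (g genes). Two forms exist:
#' `masked_dense`, `h = x (W * mask) + b`, where the binary mask encodes a
#' biological prior on which features may feed which genes; and `low_rank`,
#' `h = x A B + b`, the unconstrained factorised form used after the mask is
#' lifted. A dataset whose features already are the shared genes can use the
#' identity translator (`NULL`).
#'
#' @param form `"masked_dense"` or `"low_rank"`
#' @param W f x g weight matrix (masked_dense)
#' @param mask f x g binary matrix or NULL for all-ones (masked_dense)
#' @param A,B f x d and d x g factors (low_rank)
#' @param b length-g bias
#' @param modality modality tag
#' @return list of class `TranslatorParams`
#' @export
translator_params <- function(form = c("masked_dense", "low_rank"),
                              W = NULL, mask = NULL, A = NULL, B = NULL,
                              b = NULL, modality = "other") {
  form <- match.arg(form)
  if (form == "masked_dense") {
    stop_if(is.null(W), "masked_dense form requires W")
    W <- as_dense(W)
    if (!is.null(mask)) {
      mask <- as_dense(mask)
      stop_if(!all(mask %in% c(0, 1)), "mask entries must be 0/1")
      stop_if(!all(dim(mask) == dim(W)), "mask shape must match W")
      W <- W * mask
    }
    b <- b %||% numeric(ncol(W))
    stop_if(length(b) != ncol(W), "bias length must equal gene count")
    out <- list(form = form, W = W, mask = mask, b = b, modality = modality)
  } else {
    stop_if(is.null(A) || is.null(B), "low_rank form requires A and B")
    A <- as_dense(A); B <- as_dense(B)
    stop_if(ncol(A) != nrow(B), "A and B inner dimensions must match")
    b <- b %||% numeric(ncol(B))
    stop_if(length(b) != ncol(B), "bias length must equal gene count")
    out <- list(form = form, A = A, B = B, b = b, modality = modality)
  }
  structure(out, class = "TranslatorParams")
}

#' Apply a translator to a cell-by-feature matrix
#'
#' @param x cells x f matrix
#' @param params a [translator_params()] or `NULL` for the identity map
#' @return cells x g matrix in the shared gene space
#' @export
translate <- function(x, params) {
  x <- as_dense(x)
  if (is.null(params)) return(x)
  stopifnot(inherits(params, "TranslatorParams"))
  if (params$form == "masked_dense") {
    stop_if(ncol(x) != nrow(params$W),
            "input has ", ncol(x), " features; translator expects ",
            nrow(params$W))
    W <- if (is.null(params$mask)) params$W else params$W * params$mask
    sweep(x %*% W, 2, params$b, "+")
  } else {
    stop_if(ncol(x) != nrow(params$A),
            "input has ", ncol(x), " features; translator expects ",
            nrow(params$A))
    sweep((x %*% params$A) %*% params$B, 2, params$b, "+")
  }
}

# gradient of translate w.r.t. translator parameters given upstream dh
translate_backward <- function(x, params, dh) {
  if (is.null(params)) return(NULL)
  if (params$form == "masked_dense") {
    dW <- crossprod(x, dh)
    if (!is.null(params$mask)) dW <- dW * params$mask
    list(W = dW, b = colSums(dh))
  } else {
    t1 <- x %*% params$A
    list(A = crossprod(x, dh %*% t(params$B)),
         B = crossprod(t1, dh),
         b = colSums(dh))
  }
}

#' Convert a masked-dense translator to the low-rank factorised form
#'
#' The effective masked weight matrix `W * mask` is factorised by truncated
#' SVD into `A = U_d diag(s_d)^(1/2)` and `B = diag(s_d)^(1/2) V_d^T`
#' (symmetric square-root split, fixing the factor scale); the bias carries
#' over unchanged. At `d >= rank(W * mask)` the product `A B` reproduces the
#' masked weights, making the phase-1 to phase-2 handoff continuous.
#'
#' @param params a masked_dense [translator_params()]
#' @param d compressed dimension (default 128; clamped to `min(f, g)` with a
#'   warning)
#' @return a low_rank [translator_params()]
#' @export
decompose_translator <- function(params, d = 128) {
  stopifnot(inherits(params, "TranslatorParams"))
  stop_if(params$form != "masked_dense",
          "decompose_translator expects the masked_dense form")
  W <- if (is.null(params$mask)) params$W else params$W * params$mask
  dmax <- min(dim(W))
  if (d > dmax) {
    warning("d = ", d, " exceeds min(f, g) = ", dmax, "; clamping",
            call. = FALSE)
    d <- dmax
  }
  sv <- svd(W, nu = d, nv = d)
  s <- sqrt(sv$d[seq_len(d)])
  A <- sv$u %*% diag(s, d, d)
  B <- diag(s, d, d) %*% t(sv$v)
  translator_params("low_rank", A = A, B = B, b = params$b,
                    modality = params$modality)
}

#' Initialize a translator by ordinary least squares on paired cells
#'
#' For jointly-profiled data, fits a linear regression predicting each
#' shared-space target feature of the RNA side from the other modality's
#' features (minimising the sum of squared differences, with intercept).
#' Rank-deficient designs get the minimum-norm solution (SVD pseudoinverse),
#' so the fit is exact whenever an exact linear map exists. Used to
#' initialize the vertical translator in place of phase-1 training.
#'
#' @param x_other paired cells x f matrix (predictor modality)
#' @param target paired cells x g matrix (shared-space target, row-aligned)
#' @param modality modality tag recorded on the returned translator
#' @return a masked_dense [translator_params()] without a mask (W = f x g
#'   coefficients, b = intercepts)
#' @export
init_translator_by_regression <- function(x_other, target,
                                          modality = "other") {
  x_other <- as_dense(x_other); target <- as_dense(target)
  stop_if(nrow(x_other) != nrow(target),
          "paired inputs must have the same number of cells (",
          nrow(x_other), " vs ", nrow(target), ")")
  stop_if(nrow(x_other) < 2, "need at least 2 paired cells")
  cx <- colMeans(x_other); cy <- colMeans(target)
  xc <- sweep(x_other, 2, cx, "-")
  yc <- sweep(target, 2, cy, "-")
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  # minimum-norm least squares: W = V diag(1/s) U^T yc
  W <- sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], yc))
  b <- as.numeric(cy - crossprod(W, cx))
  translator_params("masked_dense", W = W, b = b, modality = modality)
}

relu <- function(x) pmax(x, 0)

layer_norm_forward <- function(a, gamma, beta, eps = 1e-5) {
  m <- rowMeans(a)
  v <- rowMeans((a - m)^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- (a - m) * inv
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dout, cache, gamma) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * cache$xhat)
  da <- (dxhat - rm1 - cache$xhat * rm2) * cache$inv
  list(da = da, dgamma = dgamma, dbeta = dbeta)
}

#' Initialize shared encoder parameters
#'
#' A fully-connected network with 3 hidden layers (layer normalization and
#' ReLU between them) mapping the g-dimensional translated space to the 2k
#' outputs of a diagonal Gaussian posterior: a mean head and a log-scale
#' head (`sigma = exp(log_scale)`, log-scale clamped to `[-10, 5]`).
#' Feature dropout (default rate 0.25) is applied to the encoder input in
#' training mode only.
#'
#' @param input_dim g, the shared gene-space dimension
#' @param k latent dimensionality (default 32)
#' @param hidden sizes of the 3 hidden layers (default `c(512, 256, 128)`)
#' @param dropout_rate input feature dropout rate (default 0.25)
#' @param seed initialisation seed
#' @return list of class `EncoderParams`
#' @export
encoder_params <- function(input_dim, k = 32, hidden = c(512, 256, 128),
                           dropout_rate = 0.25, seed = 1) {
  dims <- c(input_dim, hidden)
  with_seed(seed, {
    layers <- lapply(seq_along(hidden), function(i) {
      fan_in <- dims[i]
      list(W = matrix(rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / fan_in)),
                      dims[i], dims[i + 1]),
           b = numeric(dims[i + 1]),
           gamma = rep(1, dims[i + 1]),
           beta = numeric(dims[i + 1]))
    })
    hlast <- hidden[length(hidden)]
    structure(list(layers = layers,
                   Wmu = matrix(rnorm(hlast * k, 0, sqrt(1 / hlast)),
                                hlast, k),
                   bmu = numeric(k),
                   Wls = matrix(rnorm(hlast * k, 0, sqrt(1 / hlast)),
                                hlast, k),
                   bls = rep(-1, k),
                   k = k, input_dim = input_dim, hidden = hidden,
                   dropout_rate = dropout_rate),
              class = "EncoderParams")
  })
}

# Full encoder forward pass. Returns mu, sigma and (optionally) the caches
# needed for backprop. Dropout mask is drawn from drop_seed when training.
encoder_forward <- function(h, enc, training = FALSE, drop_seed = NULL,
                            cache = FALSE) {
  h <- as_dense(h)
  stop_if(any(!is.finite(h)), "encoder input must be finite")
  stop_if(ncol(h) != enc$input_dim,
          "encoder expects ", enc$input_dim, " inputs, got ", ncol(h))
  caches <- list()
  if (training && enc$dropout_rate > 0) {
    keep <- 1 - enc$dropout_rate
    dm <- with_seed(drop_seed %||% 1L,
                    matrix(rbinom(length(h), 1, keep), nrow(h), ncol(h))) /
      keep
    x <- h * dm
    caches$dropmask <- dm
  } else {
    x <- h
  }
  caches$input <- x
  for (i in seq_along(enc$layers)) {
    ly <- enc$layers[[i]]
    a <- sweep(x %*% ly$W, 2, ly$b, "+")
    ln <- layer_norm_forward(a, ly$gamma, ly$beta)
    out <- relu(ln$out)
    caches[[paste0("layer", i)]] <- list(x_in = x, ln = ln, ln_out = ln$out)
    x <- out
  }
  caches$h_top <- x
  mu <- sweep(x %*% enc$Wmu, 2, enc$bmu, "+")
  ls_raw <- sweep(x %*% enc$Wls, 2, enc$bls, "+")
  ls <- pmin(pmax(ls_raw, -10), 5)
  res <- list(mu = mu, sigma = exp(ls), log_sigma = ls)
  if (cache) {
    caches$ls_raw <- ls_raw
    res$cache <- caches
  }
  res
}

# Backward pass through the encoder. dmu, dls are gradients w.r.t. mu and
# (clamped) log sigma. Returns parameter gradients (same structure as enc)
# and the gradient w.r.t. the encoder input h.
encoder_backward <- function(enc, cache, dmu, dls) {
  dls_raw <- dls * (cache$ls_raw > -10 & cache$ls_raw < 5)
  g <- list(Wmu = crossprod(cache$h_top, dmu), bmu = colSums(dmu),
            Wls = crossprod(cache$h_top, dls_raw), bls = colSums(dls_raw))
  dx <- dmu %*% t(enc$Wmu) + dls_raw %*% t(enc$Wls)
  g$layers <- vector("list", length(enc$layers))
  for (i in rev(seq_along(enc$layers))) {
    ly <- enc$layers[[i]]
    cc <- cache[[paste0("layer", i)]]
    dout <- dx * (cc$ln_out > 0)
    lb <- layer_norm_backward(dout, cc$ln, ly$gamma)
    g$layers[[i]] <- list(W = crossprod(cc$x_in, lb$da),
                          b = colSums(lb$da),
                          gamma = lb$dgamma, beta = lb$dbeta)
    dx <- lb$da %*% t(ly$W)
  }
  dh <- if (!is.null(cache$dropmask)) dx * cache$dropmask else dx
  list(grads = g, dh = dh)
}

#' Encode translated features into a latent Gaussian posterior
#'
#' @param h cells x g matrix in the shared gene space
#' @param params an [encoder_params()]
#' @param training if `TRUE`, apply input feature dropout (seeded)
#' @param drop_seed seed for the dropout mask when training
#' @return list of class `LatentPosterior` with `mu`, `sigma` (both
#'   cells x k; sigma strictly positive)
#' @export
encode <- function(h, params, training = FALSE, drop_seed = 1L) {
  fw <- encoder_forward(h, params, training = training,
                        drop_seed = drop_seed)
  structure(list(mu = fw$mu, sigma = fw$sigma), class = "LatentPosterior")
}

#' Sample latent coordinates via the reparameterization trick
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, 1)` drawn from `seed`.
#'
#' @param post a `LatentPosterior` (list with `mu`, `sigma`)
#' @param seed integer seed
#' @return cells x k matrix
#' @export
sample_latent <- function(post, seed = 1L) {
  eps <- with_seed(seed, matrix(rnorm(length(post$mu)), nrow(post$mu),
                                ncol(post$mu)))
  post$mu + post$sigma * eps
}

#' Initialize shared projector parameters
#'
#' A single linear layer (no normalization, no activation) mapping the
#' latent coordinates concatenated with one-hot covariates into a slightly
#' higher-dimensional space `p > k`. Conditioning on covariates lets the
#' projector absorb batch / species / modality variation so the latent space
#' does not have to encode it.
#'
#' @param k latent dimensionality
#' @param cov_levels named list: covariate column -> character vector of
#'   categories (the frozen vocabulary)
#' @param p output dimensionality (default `k + 16`); must exceed `k`
#' @param seed initialisation seed
#' @return list of class `ProjectorParams`
#' @export
projector_params <- function(k, cov_levels = list(), p = k + 16, seed = 1) {
  stop_if(p <= k, "projector output dimension p must exceed k")
  n_cov <- sum(vapply(cov_levels, length, 1L))
  d_in <- k + n_cov
  with_seed(seed, {
    structure(list(P = matrix(rnorm(d_in * p, 0, sqrt(1 / d_in)), d_in, p),
                   b = numeric(p), cov_levels = cov_levels, k = k, p = p),
              class = "ProjectorParams")
  })
}

covariate_onehot <- function(covariates, cov_levels) {
  if (length(cov_levels) == 0) {
    return(matrix(0, nrow(covariates), 0))
  }
  do.call(cbind, lapply(names(cov_levels), function(nm) {
    stop_if(!nm %in% colnames(covariates),
            "covariate column missing: ", nm)
    one_hot(covariates[[nm]], cov_levels[[nm]])
  }))
}

#' Project latent coordinates conditioned on covariates
#'
#' @param z cells x k latent matrix
#' @param covariates data.frame with the covariate columns named in the
#'   projector's vocabulary; unseen categories raise an error naming them
#' @param params a [projector_params()]
#' @return cells x p matrix
#' @export
project <- function(z, covariates, params) {
  stopifnot(inherits(params, "ProjectorParams"))
  z <- as_dense(z)
  stop_if(ncol(z) != params$k, "z must have k = ", params$k, " columns")
  C <- covariate_onehot(covariates, params$cov_levels)
  inp <- cbind(z, C)
  sweep(inp %*% params$P, 2, params$b, "+")
}

project_backward <- function(z, C, params, dy) {
  inp <- cbind(z, C)
  list(grads = list(P = crossprod(inp, dy), b = colSums(dy)),
       dz = (dy %*% t(params$P))[, seq_len(params$k), drop = FALSE])
}
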