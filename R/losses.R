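#' Loss configuration
#'
#' @param beta information-bottleneck weight on the KL term (default 0.05)
#' @param tau contrastive temperature (default 0.1)
#' @param reduction `"mean"` divides the contrastive sum by the number of
#'   cell-view terms (2N) for scale-invariant training; `"sum"` is the raw
#'   double sum
#' @return list of class `LossConfig`
#' @export
loss_config <- function(beta = 0.05, tau = 0.1,
                        reduction = c("mean", "sum")) {
  stop_if(beta < 0, "beta must be non-negative")
  stop_if(tau <= 0, "tau must be positive")
  structure(list(beta = beta, tau = tau,
                 reduction = match.arg(reduction)),
            class = "LossConfig")
}

#' KL divergence from a diagonal Gaussian posterior to the standard normal
#'
#' Mean over cells of `sum_k 0.5 * (mu^2 + sigma^2 - 1 - 2 log sigma)`.
#'
#' @param mu cells x k posterior means
#' @param sigma cells x k posterior standard deviations (strictly positive)
#' @return scalar KL (non-negative; zero iff the posterior is the prior)
#' @export
kl_to_standard_normal <- function(mu, sigma) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  stop_if(any(sigma <= 0), "sigma must be strictly positive")
  mean(rowSums(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))))
}

# gradient of kl_to_standard_normal w.r.t. mu and log sigma
kl_grad <- function(mu, sigma) {
  n <- nrow(mu)
  list(dmu = mu / n, dlog_sigma = (sigma^2 - 1) / n)
}

row_normalize <- function(y, eps = 1e-12) {
  nrm <- sqrt(rowSums(y^2))
  nrm[nrm < eps] <- eps
  list(yhat = y / nrm, norm = nrm)
}

# Core decoupled contrastive loss over two row-aligned views.
#
# Stacks the two views into 2N rows; for row i the positive is its partner
# row (same cell, other view) and the negatives are both views of every
# other cell (2(N-1) terms). Per row:
#   L_i = -cos(y_i, y_partner(i)) / tau + log U_i,
#   U_i = sum_{j: cell(j) != cell(i)} exp(cos(y_i, y_j) / tau).
# The positive pair is excluded from U (the decoupled form).
# Returns loss and, if grad = TRUE, gradients w.r.t. both views.
dc_loss_core <- function(Y1, Y2, tau, reduction = "mean", grad = FALSE) {
  stop_if(nrow(Y1) != nrow(Y2) || ncol(Y1) != ncol(Y2),
          "views must be row-aligned matrices of equal shape")
  n <- nrow(Y1)
  stop_if(n < 2, "decoupled contrastive loss needs at least 2 cells")
  Y <- rbind(Y1, Y2)
  rn <- row_normalize(Y)
  S <- tcrossprod(rn$yhat)            # 2N x 2N cosine similarities
  cell <- rep(seq_len(n), 2)
  partner <- c(seq_len(n) + n, seq_len(n))
  same_cell <- outer(cell, cell, "==")
  E <- exp(S / tau)
  E_neg <- E
  E_neg[same_cell] <- 0               # drop self and positive partner
  U <- rowSums(E_neg)
  pos <- S[cbind(seq_len(2 * n), partner)]
  loss <- sum(-pos / tau + log(U))
  denom <- if (reduction == "mean") 2 * n else 1
  out <- list(loss = loss / denom)
  if (grad) {
    # dL/dS over the full (asymmetric-role) similarity matrix
    G <- E_neg / (tau * U)            # row i's negatives
    G[cbind(seq_len(2 * n), partner)] <-
      G[cbind(seq_len(2 * n), partner)] - 1 / tau
    Gs <- G + t(G)                    # S_ij appears for both rows i and j
    # d cos(y_i, y_j)/d y_i = (yhat_j - S_ij yhat_i) / ||y_i||
    dY <- (Gs %*% rn$yhat - rowSums(Gs * S) * rn$yhat) / rn$norm
    dY <- dY / denom
    out$dY1 <- dY[seq_len(n), , drop = FALSE]
    out$dY2 <- dY[seq_len(n) + n, , drop = FALSE]
  }
  out
}

#' Decoupled contrastive loss between two augmented views
#'
#' The horizontal-integration objective, applied to projector outputs: for
#' each cell the positive pair is its two augmented views, and the
#' normalizer sums cosine-similarity terms over both views of all other
#' cells in the minibatch, excluding the positive pair (the decoupled form).
#'
#' @param Y1,Y2 cells x p projected embeddings of view 1 and view 2,
#'   row-aligned by cell
#' @param tau temperature
#' @param reduction `"mean"` (per cell-view average, default) or `"sum"`
#'   (the raw double sum over views and cells)
#' @return scalar loss
#' @export
dc_loss_two_views <- function(Y1, Y2, tau = 0.1,
                              reduction = c("mean", "sum")) {
  dc_loss_core(as.matrix(Y1), as.matrix(Y2), tau,
               match.arg(reduction))$loss
}

#' Decoupled contrastive loss between two jointly-profiled modalities
#'
#' The vertical-integration objective: identical structure to
#' [dc_loss_two_views()], but the two "views" of a cell are its latent
#' embeddings from two modalities, and the loss is computed on the latent
#' space z rather than projector outputs.
#'
#' @param Z_A,Z_B cells x k latent embeddings, row-aligned by joint-cell
#'   identity
#' @param tau temperature
#' @param reduction `"mean"` or `"sum"`
#' @return scalar loss
#' @export
dc_loss_paired_modalities <- function(Z_A, Z_B, tau = 0.1,
                                      reduction = c("mean", "sum")) {
  dc_loss_core(as.matrix(Z_A), as.matrix(Z_B), tau,
               match.arg(reduction))$loss
}

#' Total variational information bottleneck objective
#'
#' @param contrastive scalar contrastive loss
#' @param kl scalar KL term
#' @param config a [loss_config()]
#' @return `contrastive + beta * kl`
#' @export
total_vib_loss <- function(contrastive, kl, config = loss_config()) {
  stop_if(!is.finite(contrastive) || !is.finite(kl),
          "loss terms must be finite")
  contrastive + config$beta * kl
}
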