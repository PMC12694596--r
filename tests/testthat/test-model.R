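test_that("translators apply their linear forms exactly", {
  set.seed(31)
  x <- matrix(rnorm(5 * 4), 5, 4)
  # identity (shared space)
  expect_identical(translate(x, NULL), x)
  # masked dense: the mask must zero excluded weights at construction
  W <- matrix(rnorm(4 * 3), 4, 3)
  mask <- matrix(c(1, 0), 4, 3)
  tr <- translator_params("masked_dense", W = W, mask = mask,
                          modality = "atac")
  expect_equal(tr$W, W * mask, ignore_attr = TRUE)
  expect_equal(translate(x, tr), x %*% (W * mask), ignore_attr = TRUE)
  # low rank
  A <- matrix(rnorm(4 * 2), 4, 2); B <- matrix(rnorm(2 * 3), 2, 3)
  lr <- translator_params("low_rank", A = A, B = B, b = c(1, 2, 3))
  expect_equal(translate(x, lr),
               sweep(x %*% A %*% B, 2, c(1, 2, 3), "+"),
               ignore_attr = TRUE)
  expect_error(translate(matrix(0, 2, 7), tr), "expects")
  expect_error(translator_params("masked_dense", W = W,
                                 mask = matrix(2, 4, 3)), "0/1")
})

test_that("SVD decomposition is exact at full rank (two-phase handoff)", {
  set.seed(32)
  W <- matrix(rnorm(12 * 8), 12, 8)
  mask <- matrix(rbinom(96, 1, 0.5), 12, 8)
  tr <- translator_params("masked_dense", W = W, mask = mask,
                          b = rnorm(8))
  lr <- decompose_translator(tr, d = 8)
  x <- matrix(rnorm(6 * 12), 6, 12)
  expect_equal(translate(x, lr), translate(x, tr), tolerance = 1e-10)
  expect_equal(lr$b, tr$b)
})

test_that("truncated decomposition equals the best rank-d approximation", {
  set.seed(33)
  W <- matrix(rnorm(10 * 7), 10, 7)
  tr <- translator_params("masked_dense", W = W)
  d <- 3
  lr <- expect_silent(decompose_translator(tr, d))
  got <- lr$A %*% lr$B
  sv <- svd(W)
  want <- sv$u[, 1:d] %*% diag(sv$d[1:d]) %*% t(sv$v[, 1:d])
  expect_equal(got, want, tolerance = 1e-10)
  # Eckart-Young: no rank-d matrix is closer in Frobenius norm
  expect_equal(norm(W - got, "F"),
               sqrt(sum(sv$d[(d + 1):7]^2)), tolerance = 1e-10)
  expect_warning(decompose_translator(tr, 99), "clamping")
})

test_that("regression initialization solves the normal equations", {
  set.seed(34)
  # overdetermined, unique solution: compare against lm()
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- matrix(rnorm(50 * 3), 50, 3)
  reg <- init_translator_by_regression(x, y)
  for (j in 1:3) {
    fit <- lm(y[, j] ~ x)
    expect_equal(unname(reg$W[, j]), unname(coef(fit)[-1]),
                 tolerance = 1e-8)
    expect_equal(unname(reg$b[j]), unname(coef(fit)[1]), tolerance = 1e-8)
  }
  # consistent system is recovered exactly
  W0 <- matrix(rnorm(6 * 3), 6, 3)
  y2 <- x %*% W0 + 5
  reg2 <- init_translator_by_regression(x, y2)
  expect_equal(reg2$W, W0, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(reg2$b, rep(5, 3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(init_translator_by_regression(x[1:3, ], y), "same number")
  expect_error(init_translator_by_regression(x[1, , drop = FALSE],
                                             y[1, , drop = FALSE]),
               "at least 2")
})

test_that("encoder is deterministic in eval mode, stochastic in training", {
  set.seed(35)
  enc <- encoder_params(20, k = 5, hidden = c(16, 12, 8),
                        dropout_rate = 0.25, seed = 2)
  h <- matrix(rnorm(10 * 20), 10, 20)
  p1 <- encode(h, enc)
  p2 <- encode(h, enc)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$sigma, p2$sigma)
  expect_true(all(p1$sigma > 0))
  expect_true(all(p1$sigma >= exp(-10) & p1$sigma <= exp(5)))
  t1 <- encode(h, enc, training = TRUE, drop_seed = 1)
  t2 <- encode(h, enc, training = TRUE, drop_seed = 1)
  t3 <- encode(h, enc, training = TRUE, drop_seed = 2)
  expect_identical(t1$mu, t2$mu)
  expect_false(identical(t1$mu, t3$mu))
  expect_error(encode(matrix(0, 2, 7), enc), "expects 20 inputs")
  expect_error(encode(matrix(NA_real_, 2, 20), enc), "finite")
})

test_that("reparameterized sampling has the posterior's moments", {
  enc <- encoder_params(6, k = 3, hidden = c(8, 8, 8), seed = 4)
  post <- encode(matrix(rnorm(4 * 6), 4, 6), enc)
  zs <- vapply(1:4000, function(s) sample_latent(post, seed = s)[1, 1], 0)
  expect_equal(mean(zs), post$mu[1, 1], tolerance = 0.05)
  expect_equal(sd(zs), post$sigma[1, 1], tolerance = 0.05)
  expect_identical(sample_latent(post, 7), sample_latent(post, 7))
})

test_that("full-model analytic gradients match finite differences", {
  set.seed(36)
  n <- 4; f <- 6; g <- 5; k <- 3; p <- 5
  x <- matrix(rnorm(n * f), n, f)
  tr <- translator_params("low_rank",
                          A = matrix(rnorm(f * 2), f, 2),
                          B = matrix(rnorm(2 * g), 2, g))
  enc <- encoder_params(g, k = k, hidden = c(7, 6, 5),
                        dropout_rate = 0, seed = 3)
  prj <- projector_params(k, list(batch = c("b1", "b2")), p = p, seed = 3)
  cov <- data.frame(batch = rep(c("b1", "b2"), 2))
  lossfun <- function(enc_, tr_, prj_) {
    fw <- multivib:::encoder_forward(translate(x, tr_), enc_,
                                     training = FALSE, cache = TRUE)
    z <- fw$mu + fw$sigma * 0.3           # fixed eps for determinism
    y <- project(z, cov, prj_)
    dc_loss_two_views(y, y + 0.1, tau = 0.4) +
      0.05 * kl_to_standard_normal(fw$mu, fw$sigma)
  }
  # analytic gradients via the package's backward passes
  fw <- multivib:::encoder_forward(translate(x, tr), enc,
                                   training = FALSE, cache = TRUE)
  z <- fw$mu + fw$sigma * 0.3
  y <- project(z, cov, prj)
  core <- multivib:::dc_loss_core(y, y + 0.1, 0.4, "mean", grad = TRUE)
  C <- multivib:::covariate_onehot(cov, prj$cov_levels)
  pb <- multivib:::project_backward(z, C, prj, core$dY1 + core$dY2)
  kg <- multivib:::kl_grad(fw$mu, fw$sigma)
  dmu <- pb$dz + kg$dmu * 0.05
  dls <- pb$dz * (0.3 * fw$sigma) + kg$dlog_sigma * 0.05
  eb <- multivib:::encoder_backward(enc, fw$cache, dmu, dls)
  tb <- multivib:::translate_backward(x, tr, eb$dh)
  h <- 1e-5
  fd <- function(get, set) {
    obj <- list(enc = enc, tr = tr, prj = prj)
    up <- function(delta) {
      o <- obj; o <- set(o, get(o) + delta)
      lossfun(o$enc, o$tr, o$prj)
    }
    (up(h) - up(-h)) / (2 * h)
  }
  # encoder first-layer weight
  g1 <- fd(function(o) o$enc$layers[[1]]$W[2, 3],
           function(o, v) { o$enc$layers[[1]]$W[2, 3] <- v; o })
  expect_equal(eb$grads$layers[[1]]$W[2, 3], g1, tolerance = 1e-5)
  # log-sigma head weight
  g2 <- fd(function(o) o$enc$Wls[4, 1],
           function(o, v) { o$enc$Wls[4, 1] <- v; o })
  expect_equal(eb$grads$Wls[4, 1], g2, tolerance = 1e-5)
  # translator factor A
  g3 <- fd(function(o) o$tr$A[5, 1],
           function(o, v) { o$tr$A[5, 1] <- v; o })
  expect_equal(tb$A[5, 1], g3, tolerance = 1e-5)
  # projector weight on a covariate input row
  g4 <- fd(function(o) o$prj$P[k + 1, 2],
           function(o, v) { o$prj$P[k + 1, 2] <- v; o })
  expect_equal(unname(pb$grads$P[k + 1, 2]), g4, tolerance = 1e-5)
})

test_that("projector validates dimensions and covariate vocabulary", {
  expect_error(projector_params(5, p = 5), "must exceed")
  prj <- projector_params(3, list(batch = c("b1", "b2")), p = 6, seed = 1)
  z <- matrix(rnorm(6), 2, 3)
  y <- project(z, data.frame(batch = c("b1", "b2")), prj)
  expect_equal(dim(y), c(2L, 6L))
  expect_error(project(z, data.frame(batch = c("b1", "b9")), prj),
               "unseen covariate category: b9")
  expect_error(project(z, data.frame(other = c("a", "b")), prj),
               "covariate column missing: batch")
  expect_error(project(matrix(0, 2, 5), data.frame(batch = c("b1", "b1")),
                       prj), "k = 3")
})

test_that("layer norm backward matches finite differences", {
  set.seed(37)
  a <- matrix(rnorm(12), 3, 4)
  gamma <- runif(4, 0.5, 2); beta <- rnorm(4)
  fw <- multivib:::layer_norm_forward(a, gamma, beta)
  dout <- matrix(rnorm(12), 3, 4)
  bk <- multivib:::layer_norm_backward(dout, fw, gamma)
  h <- 1e-6
  f <- function(am) sum(multivib:::layer_norm_forward(am, gamma, beta)$out *
                          dout)
  ap <- a; ap[2, 3] <- ap[2, 3] + h
  am <- a; am[2, 3] <- am[2, 3] - h
  expect_equal(bk$da[2, 3], (f(ap) - f(am)) / (2 * h), tolerance = 1e-6)
})
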