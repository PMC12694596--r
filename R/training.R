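#' Training configuration
#'
#' @param mode `"horizontal"`, `"vertical"`, or `"mosaic"`
#' @param phase1_epochs epochs with the masked-dense translator (default 100)
#' @param phase2_epochs epochs after low-rank conversion (default 200)
#' @param batch_size minibatch size (default 256)
#' @param learning_rate Adam learning rate (default 1e-3)
#' @param seed global seed controlling splits, initialisation, dropout,
#'   augmentation and posterior sampling
#' @param holdout_fraction fraction of cells (joint cells in vertical mode)
#'   excluded from every gradient step; 0 or 0.2 in typical use
#' @param k latent dimensionality (default 32)
#' @param p projector output dimension (default `k + 16`)
#' @param hidden encoder hidden layer sizes (default `c(512, 256, 128)`)
#' @param d compressed rank of the low-rank translator (default 128)
#' @param dropout_rate encoder input feature dropout (default 0.25)
#' @param loss a [loss_config()]
#' @param covariate_cols covariate columns fed to the projector; `NULL`
#'   means every column present in the datasets' covariate tables
#' @return list of class `TrainConfig`
#' @export
train_config <- function(mode = c("horizontal", "vertical", "mosaic"),
                         phase1_epochs = 100, phase2_epochs = 200,
                         batch_size = 256, learning_rate = 1e-3, seed = 1,
                         holdout_fraction = 0, k = 32, p = k + 16,
                         hidden = c(512, 256, 128), d = 128,
                         dropout_rate = 0.25, loss = loss_config(),
                         covariate_cols = NULL) {
  stop_if(phase1_epochs < 0 || phase2_epochs < 0, "epochs must be >= 0")
  stop_if(holdout_fraction < 0 || holdout_fraction >= 1,
          "holdout_fraction must be in [0, 1)")
  structure(list(mode = match.arg(mode), phase1_epochs = phase1_epochs,
                 phase2_epochs = phase2_epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed,
                 holdout_fraction = holdout_fraction, k = k, p = p,
                 hidden = hidden, d = d, dropout_rate = dropout_rate,
                 loss = loss, covariate_cols = covariate_cols),
            class = "TrainConfig")
}

# ---- optimiser ------------------------------------------------------------

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  idx <- if (!is.null(names(b))) names(b) else seq_along(b)
  for (nm in idx) out[[nm]] <- grads_add(a[[nm]], b[[nm]])
  out
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.numeric(g)) {
      if (is.null(s)) s <- list(m = g * 0, v = g * 0)
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
    } else {
      if (is.null(s)) s <- vector("list", length(g))
      if (!is.null(names(g))) names(s) <- names(g)
      idx <- if (!is.null(names(g))) names(g) else seq_along(g)
      for (nm in idx) {
        r <- rec(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      list(p = p, s = s)
    }
  }
  rec(params, grads, state)
}

# ---- model state ----------------------------------------------------------

#' Construct an empty model state
#'
#' Aggregates the translator registry (one entry per modality tag; `NULL`
#' marks the identity translator for datasets already in the shared gene
#' space), the shared encoder and projector, the frozen covariate
#' vocabulary, and the training history.
#'
#' @param shared_genes character vector defining the shared gene-centric
#'   space (encoder input order)
#' @param config a [train_config()]
#' @param cov_levels named list of covariate vocabularies
#' @return list of class `ModelState`
#' @export
model_state <- function(shared_genes, config, cov_levels = list()) {
  g <- length(shared_genes)
  enc <- encoder_params(g, k = config$k, hidden = config$hidden,
                        dropout_rate = config$dropout_rate,
                        seed = derive_seed(config$seed, "encoder"))
  proj <- projector_params(config$k, cov_levels, p = config$p,
                           seed = derive_seed(config$seed, "projector"))
  structure(list(translators = list(), encoder = enc, projector = proj,
                 shared_genes = shared_genes, config = config,
                 history = data.frame(), trained_cell_ids = character(),
                 holdout_ids = character(), opt = list(), step = 0L),
            class = "ModelState")
}

#' @export
print.ModelState <- function(x, ...) {
  cat(sprintf("ModelState: k = %d, shared genes = %d, translators: %s\n",
              x$encoder$k, length(x$shared_genes),
              if (length(x$translators) == 0) "none" else
                paste(names(x$translators), collapse = ", ")))
  invisible(x)
}

collect_cov_levels <- function(datasets, cols = NULL) {
  all_cols <- unique(unlist(lapply(datasets, function(d)
    colnames(d$covariates))))
  cols <- cols %||% all_cols
  out <- list()
  for (cc in cols) {
    vals <- unlist(lapply(datasets, function(d)
      if (cc %in% colnames(d$covariates))
        as.character(d$covariates[[cc]]) else character(0)))
    out[[cc]] <- sort(unique(vals))
  }
  out
}

# Extend the projector vocabulary with categories first seen in a later
# mosaic stage: new one-hot columns are appended within their covariate
# block with zero-initialised weight rows, so existing cells project
# identically.
extend_projector <- function(proj, new_levels) {
  old <- proj$cov_levels
  merged <- old
  for (cc in names(new_levels)) {
    merged[[cc]] <- union(merged[[cc]] %||% character(0), new_levels[[cc]])
  }
  if (identical(merged, old)) return(proj)
  offsets_old <- c(0, cumsum(vapply(old, length, 1L)))
  d_in_new <- proj$k + sum(vapply(merged, length, 1L))
  P_new <- matrix(0, d_in_new, proj$p)
  P_new[seq_len(proj$k), ] <- proj$P[seq_len(proj$k), , drop = FALSE]
  row_new <- proj$k
  for (i in seq_along(merged)) {
    cc <- names(merged)[i]
    for (lv in merged[[cc]]) {
      row_new <- row_new + 1
      j <- match(cc, names(old))
      if (!is.na(j) && lv %in% old[[cc]]) {
        old_row <- proj$k + offsets_old[j] + match(lv, old[[cc]])
        P_new[row_new, ] <- proj$P[old_row, ]
      }
    }
  }
  proj$P <- P_new
  proj$cov_levels <- merged
  proj
}

translator_key <- function(dataset) dataset$modality

dataset_is_shared_space <- function(dataset, shared_genes) {
  identical(as.character(dataset$feature_ids), as.character(shared_genes))
}

split_holdout <- function(ids, fraction, seed) {
  n_hold <- floor(fraction * length(ids))
  if (n_hold == 0) return(list(train = ids, holdout = character(0)))
  hold <- with_seed(seed, sample(ids, n_hold))
  list(train = setdiff(ids, hold), holdout = hold)
}

minibatches <- function(idx, batch_size, seed) {
  idx <- with_seed(seed, sample(idx))
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# one gradient step of horizontal training on a single-dataset minibatch
horizontal_step <- function(state, x, covs, tr_key, phase, step_seed) {
  cfg <- state$config
  tau <- cfg$loss$tau
  beta <- cfg$loss$beta
  tr <- state$translators[[tr_key]]
  views <- list()
  for (v in 1:2) {
    xv <- augment(x, derive_seed(step_seed, "aug", v))
    h <- translate(xv, tr)
    fw <- encoder_forward(h, state$encoder, training = TRUE,
                          drop_seed = derive_seed(step_seed, "drop", v),
                          cache = TRUE)
    eps <- with_seed(derive_seed(step_seed, "eps", v),
                     matrix(rnorm(length(fw$mu)), nrow(fw$mu), ncol(fw$mu)))
    z <- fw$mu + fw$sigma * eps
    C <- covariate_onehot(covs, state$projector$cov_levels)
    y <- sweep(cbind(z, C) %*% state$projector$P, 2, state$projector$b, "+")
    views[[v]] <- list(x = xv, fw = fw, eps = eps, z = z, C = C, y = y)
  }
  dc <- dc_loss_core(views[[1]]$y, views[[2]]$y, tau,
                     reduction = cfg$loss$reduction, grad = TRUE)
  kls <- vapply(views, function(vv)
    kl_to_standard_normal(vv$fw$mu, vv$fw$sigma), 0)
  kl <- mean(kls)
  loss <- dc$loss + beta * kl
  enc_g <- NULL; proj_g <- NULL; tr_g <- NULL
  for (v in 1:2) {
    vv <- views[[v]]
    dy <- if (v == 1) dc$dY1 else dc$dY2
    pb <- project_backward(vv$z, vv$C, state$projector, dy)
    proj_g <- grads_add(proj_g, pb$grads)
    dz <- pb$dz
    kg <- kl_grad(vv$fw$mu, vv$fw$sigma)
    dmu <- dz + beta * 0.5 * kg$dmu
    dls <- dz * vv$fw$sigma * vv$eps + beta * 0.5 * kg$dlog_sigma
    eb <- encoder_backward(state$encoder, vv$fw$cache, dmu, dls)
    enc_g <- grads_add(enc_g, eb$grads)
    if (!is.null(tr)) {
      tr_g <- grads_add(tr_g, translate_backward(vv$x, tr, eb$dh))
    }
  }
  list(loss = loss, contrastive = dc$loss, kl = kl,
       grads = list(encoder = enc_g, projector = proj_g, translator = tr_g),
       tr_key = tr_key, phase = phase)
}

apply_step <- function(state, grads, tr_key = NULL) {
  cfg <- state$config
  state$step <- state$step + 1L
  r <- adam_update(state$encoder, grads$encoder,
                   state$opt$encoder, cfg$learning_rate, state$step)
  state$encoder <- r$p; state$opt$encoder <- r$s
  if (!is.null(grads$projector)) {
    r <- adam_update(state$projector, grads$projector,
                     state$opt$projector, cfg$learning_rate, state$step)
    state$projector <- r$p; state$opt$projector <- r$s
  }
  if (!is.null(grads$translator) && !is.null(tr_key)) {
    key <- paste0("tr.", tr_key)
    r <- adam_update(state$translators[[tr_key]], grads$translator,
                     state$opt[[key]], cfg$learning_rate, state$step)
    state$translators[[tr_key]] <- r$p; state$opt[[key]] <- r$s
    tr <- state$translators[[tr_key]]
    if (tr$form == "masked_dense" && !is.null(tr$mask)) {
      # projection step keeps masked weights exactly zero
      state$translators[[tr_key]]$W <- tr$W * tr$mask
    }
  }
  state
}

#' Two-phase horizontal integration
#'
#' Datasets sharing a gene-centric feature space (directly, or through a
#' biologically masked translator) are aligned by contrasting two augmented
#' views of each cell on the covariate-conditioned projector outputs, with a
#' KL bottleneck on the latent posterior. Phase 1 trains masked-dense
#' translators; phase 2 converts each trainable translator to the low-rank
#' form (lifting the mask) and keeps training. Minibatches are drawn from a
#' single dataset at a time, datasets interleaved round-robin.
#'
#' @param datasets named list of preprocessed (standardized) OmicsDatasets
#' @param masks named list (by modality tag) of binary feature x gene mask
#'   matrices for every dataset not already in the shared space
#' @param config a [train_config()]
#' @param state optional existing [model_state()] to continue from (used by
#'   mosaic training)
#' @param stage label recorded in the history
#' @return a trained `ModelState`
#' @export
train_horizontal <- function(datasets, masks = list(), config = train_config("horizontal"),
                             state = NULL, stage = "horizontal") {
  stop_if(length(datasets) == 0, "no datasets given")
  for (d in datasets) stop_if(length(d$cell_ids) == 0, "empty dataset")
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, translator_key, "")
  # determine the shared gene space
  shared <- NULL
  for (i in seq_along(datasets)) {
    key <- translator_key(datasets[[i]])
    if (!is.null(masks[[key]])) {
      shared <- colnames(masks[[key]]) %||% shared
    } else if (is.null(shared)) {
      shared <- datasets[[i]]$feature_ids
    }
  }
  if (is.null(state)) {
    state <- model_state(shared, config,
                         collect_cov_levels(datasets, config$covariate_cols))
  } else {
    state$projector <- extend_projector(
      state$projector, collect_cov_levels(datasets, config$covariate_cols))
    shared <- state$shared_genes
  }
  g <- length(shared)
  # register translators
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    key <- translator_key(ds)
    if (!is.null(state$translators[[key]]) ||
        (key %in% names(state$translators))) next
    if (dataset_is_shared_space(ds, shared)) {
      state$translators[key] <- list(NULL)  # identity
    } else {
      mk <- masks[[key]]
      stop_if(is.null(mk),
              "dataset '", key, "' is not in the shared gene space and has ",
              "no mask")
      mk <- as_dense(mk)
      stop_if(nrow(mk) != length(ds$feature_ids) || ncol(mk) != g,
              "mask for '", key, "' has wrong shape")
      W0 <- with_seed(derive_seed(config$seed, "tr_init", key),
                      matrix(rnorm(nrow(mk) * g, 0,
                                   sqrt(1 / max(1, nrow(mk)))),
                             nrow(mk), g))
      state$translators[[key]] <- translator_params(
        "masked_dense", W = W0, mask = mk, modality = ds$modality)
    }
  }
  # holdout split per dataset
  train_idx <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    sp <- split_holdout(ds$cell_ids, config$holdout_fraction,
                        derive_seed(config$seed, "holdout", names(datasets)[i]))
    train_idx[[i]] <- match(sp$train, ds$cell_ids)
    state$holdout_ids <- union(state$holdout_ids, sp$holdout)
  }
  run_phase <- function(state, phase, n_epochs) {
    for (ep in seq_len(n_epochs)) {
      ep_loss <- 0; ep_dc <- 0; ep_kl <- 0; nb <- 0
      batches_by_ds <- lapply(seq_along(datasets), function(i)
        minibatches(train_idx[[i]], config$batch_size,
                    derive_seed(config$seed, stage, phase, "ep", ep, i)))
      max_b <- max(vapply(batches_by_ds, length, 1L))
      for (b in seq_len(max_b)) {
        for (i in seq_along(datasets)) {
          if (b > length(batches_by_ds[[i]])) next
          idx <- batches_by_ds[[i]][[b]]
          if (length(idx) < 2) next
          ds <- datasets[[i]]
          st <- horizontal_step(
            state, as_dense(ds$matrix[idx, , drop = FALSE]),
            ds$covariates[idx, , drop = FALSE], translator_key(ds), phase,
            derive_seed(config$seed, stage, phase, ep, b, i))
          state <- apply_step(state, st$grads, st$tr_key)
          state$trained_cell_ids <- union(state$trained_cell_ids,
                                          ds$cell_ids[idx])
          ep_loss <- ep_loss + st$loss
          ep_dc <- ep_dc + st$contrastive
          ep_kl <- ep_kl + st$kl
          nb <- nb + 1
        }
      }
      if (nb > 0) {
        state$history <- rbind(state$history, data.frame(
          stage = stage, phase = phase, epoch = ep,
          loss = ep_loss / nb, contrastive = ep_dc / nb, kl = ep_kl / nb))
      }
    }
    state
  }
  state <- run_phase(state, 1L, config$phase1_epochs)
  if (config$phase2_epochs > 0) {
    for (key in names(state$translators)) {
      tr <- state$translators[[key]]
      if (!is.null(tr) && tr$form == "masked_dense") {
        state$translators[[key]] <-
          decompose_translator(tr, min(config$d, min(dim(tr$W))))
        state$opt[[paste0("tr.", key)]] <- NULL
      }
    }
    state <- run_phase(state, 2L, config$phase2_epochs)
  }
  state
}

# one gradient step of vertical training on a paired minibatch
vertical_step <- function(state, xa, xb, key_a, key_b, step_seed) {
  cfg <- state$config
  beta <- cfg$loss$beta
  sides <- list(list(x = xa, key = key_a), list(x = xb, key = key_b))
  fws <- list()
  for (v in 1:2) {
    tr <- state$translators[[sides[[v]]$key]]
    h <- translate(sides[[v]]$x, tr)
    fw <- encoder_forward(h, state$encoder, training = TRUE,
                          drop_seed = derive_seed(step_seed, "drop", v),
                          cache = TRUE)
    eps <- with_seed(derive_seed(step_seed, "eps", v),
                     matrix(rnorm(length(fw$mu)), nrow(fw$mu), ncol(fw$mu)))
    fws[[v]] <- list(fw = fw, eps = eps, z = fw$mu + fw$sigma * eps,
                     tr = tr, x = sides[[v]]$x, key = sides[[v]]$key)
  }
  dc <- dc_loss_core(fws[[1]]$z, fws[[2]]$z, cfg$loss$tau,
                     reduction = cfg$loss$reduction, grad = TRUE)
  kl <- mean(vapply(fws, function(vv)
    kl_to_standard_normal(vv$fw$mu, vv$fw$sigma), 0))
  loss <- dc$loss + beta * kl
  enc_g <- NULL; tr_gs <- list()
  for (v in 1:2) {
    vv <- fws[[v]]
    dz <- if (v == 1) dc$dY1 else dc$dY2
    kg <- kl_grad(vv$fw$mu, vv$fw$sigma)
    dmu <- dz + beta * 0.5 * kg$dmu
    dls <- dz * vv$fw$sigma * vv$eps + beta * 0.5 * kg$dlog_sigma
    eb <- encoder_backward(state$encoder, vv$fw$cache, dmu, dls)
    enc_g <- grads_add(enc_g, eb$grads)
    if (!is.null(vv$tr)) {
      tr_gs[[vv$key]] <- grads_add(tr_gs[[vv$key]],
                                   translate_backward(vv$x, vv$tr, eb$dh))
    }
  }
  list(loss = loss, contrastive = dc$loss, kl = kl, enc_g = enc_g,
       tr_gs = tr_gs)
}

kl_only_step <- function(state, x, key, step_seed) {
  beta <- state$config$loss$beta
  tr <- state$translators[[key]]
  h <- translate(x, tr)
  fw <- encoder_forward(h, state$encoder, training = TRUE,
                        drop_seed = derive_seed(step_seed, "drop"),
                        cache = TRUE)
  kl <- kl_to_standard_normal(fw$mu, fw$sigma)
  kg <- kl_grad(fw$mu, fw$sigma)
  eb <- encoder_backward(state$encoder, fw$cache, beta * kg$dmu,
                         beta * kg$dlog_sigma)
  tr_g <- if (!is.null(tr)) translate_backward(x, tr, eb$dh) else NULL
  list(kl = kl, enc_g = eb$grads, tr_g = tr_g)
}

#' Vertical integration with regression-initialised translators
#'
#' For two jointly-profiled modalities, the non-shared-space translator is
#' initialised by least squares from the paired cells (predicting the
#' shared-space representation), converted directly to the low-rank form
#' (skipping phase 1), and trained with the paired-modality decoupled
#' contrastive loss on the latent space plus the KL bottleneck (averaged
#' over both modality views). Cells without a pairing pass through the
#' encoder in their own minibatches and contribute only the KL term.
#'
#' @param paired list of two preprocessed OmicsDatasets with `pairing` maps
#'   defining at least 2 joint cells
#' @param config a [train_config()]
#' @param state optional existing state (mosaic continuation)
#' @param stage history label
#' @param translator_init `"regression"` (the default: least squares on the
#'   training-visible paired cells, the phase-1 substitute) or `"random"`
#'   (an untrained low-rank translator, giving the no-training baseline
#'   model when combined with zero epochs)
#' @return a trained `ModelState`
#' @export
train_vertical <- function(paired, config = train_config("vertical"),
                           state = NULL, stage = "vertical",
                           translator_init = c("regression", "random")) {
  translator_init <- match.arg(translator_init)
  stop_if(length(paired) != 2, "vertical training expects two datasets")
  ds_a <- paired[[1]]; ds_b <- paired[[2]]
  stop_if(is.null(ds_a$pairing) || is.null(ds_b$pairing),
          "both datasets need pairing maps")
  joint <- intersect(ds_a$pairing, ds_b$pairing)
  stop_if(length(joint) < 2, "need at least 2 paired joint cells")
  key_a <- translator_key(ds_a); key_b <- translator_key(ds_b)
  if (is.null(state)) {
    shared <- ds_a$feature_ids
    state <- model_state(shared, config,
                         collect_cov_levels(paired, config$covariate_cols))
  } else {
    state$projector <- extend_projector(
      state$projector, collect_cov_levels(paired, config$covariate_cols))
    shared <- state$shared_genes
  }
  stop_if(!dataset_is_shared_space(ds_a, shared),
          "the first dataset must be in the shared gene space")
  if (!key_a %in% names(state$translators)) {
    state$translators[key_a] <- list(NULL)
  }
  # holdout on joint cells, before any initialisation uses the pairing
  sp <- split_holdout(joint, config$holdout_fraction,
                      derive_seed(config$seed, "holdout", stage))
  state$holdout_ids <- union(state$holdout_ids, sp$holdout)
  idx_a <- match(sp$train, ds_a$pairing)
  idx_b <- match(sp$train, ds_b$pairing)
  rows_a <- match(names(ds_a$pairing)[idx_a], ds_a$cell_ids)
  rows_b <- match(names(ds_b$pairing)[idx_b], ds_b$cell_ids)
  if (!key_b %in% names(state$translators)) {
    if (translator_init == "regression") {
      xa_tr <- translate(as_dense(ds_a$matrix[rows_a, , drop = FALSE]),
                         state$translators[[key_a]])
      reg <- init_translator_by_regression(
        as_dense(ds_b$matrix[rows_b, , drop = FALSE]), xa_tr,
        modality = ds_b$modality)
      d <- min(config$d, min(dim(reg$W)))
      state$translators[[key_b]] <- decompose_translator(reg, d)
    } else {
      f <- length(ds_b$feature_ids)
      g <- length(shared)
      d <- min(config$d, f, g)
      state$translators[[key_b]] <- with_seed(
        derive_seed(config$seed, "tr_rand", key_b),
        translator_params("low_rank",
                          A = matrix(rnorm(f * d, 0, sqrt(1 / f)), f, d),
                          B = matrix(rnorm(d * g, 0, sqrt(1 / d)), d, g),
                          modality = ds_b$modality))
    }
  }
  # unpaired (or held-out-pairing) cells contribute KL only
  unpaired <- list(
    list(ds = ds_a, key = key_a,
         rows = setdiff(seq_along(ds_a$cell_ids), rows_a)),
    list(ds = ds_b, key = key_b,
         rows = setdiff(seq_along(ds_b$cell_ids), rows_b)))
  hold_rows_a <- match(names(ds_a$pairing)[match(sp$holdout, ds_a$pairing)],
                       ds_a$cell_ids)
  hold_rows_b <- match(names(ds_b$pairing)[match(sp$holdout, ds_b$pairing)],
                       ds_b$cell_ids)
  unpaired[[1]]$rows <- setdiff(unpaired[[1]]$rows, hold_rows_a)
  unpaired[[2]]$rows <- setdiff(unpaired[[2]]$rows, hold_rows_b)
  n_epochs <- config$phase2_epochs
  for (ep in seq_len(n_epochs)) {
    ep_loss <- 0; ep_dc <- 0; ep_kl <- 0; nb <- 0
    ord <- with_seed(derive_seed(config$seed, stage, "ep", ep),
                     sample(seq_along(sp$train)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in seq_along(batches)) {
      sel <- batches[[b]]
      if (length(sel) < 2) next
      st <- vertical_step(
        state, as_dense(ds_a$matrix[rows_a[sel], , drop = FALSE]),
        as_dense(ds_b$matrix[rows_b[sel], , drop = FALSE]),
        key_a, key_b, derive_seed(config$seed, stage, ep, b))
      grads <- list(encoder = st$enc_g)
      state <- apply_step(state, grads)
      for (key in names(st$tr_gs)) {
        state <- apply_step(state, list(translator = st$tr_gs[[key]]), key)
        state$step <- state$step - 1L
      }
      state$trained_cell_ids <- union(
        state$trained_cell_ids,
        c(ds_a$cell_ids[rows_a[sel]], ds_b$cell_ids[rows_b[sel]]))
      ep_loss <- ep_loss + st$loss; ep_dc <- ep_dc + st$contrastive
      ep_kl <- ep_kl + st$kl; nb <- nb + 1
    }
    for (up in unpaired) {
      if (length(up$rows) < 2) next
      ub <- minibatches(up$rows, config$batch_size,
                        derive_seed(config$seed, stage, "unpaired", ep,
                                    up$key))
      for (b in seq_along(ub)) {
        if (length(ub[[b]]) < 2) next
        st <- kl_only_step(state,
                           as_dense(up$ds$matrix[ub[[b]], , drop = FALSE]),
                           up$key,
                           derive_seed(config$seed, stage, "up", ep, b,
                                       up$key))
        state <- apply_step(state, list(encoder = st$enc_g,
                                        translator = st$tr_g), up$key)
        state$trained_cell_ids <- union(state$trained_cell_ids,
                                        up$ds$cell_ids[ub[[b]]])
      }
    }
    if (nb > 0) {
      state$history <- rbind(state$history, data.frame(
        stage = stage, phase = 2L, epoch = ep, loss = ep_loss / nb,
        contrastive = ep_dc / nb, kl = ep_kl / nb))
    }
  }
  state
}

#' Continual dataset-by-dataset mosaic integration
#'
#' Runs an ordered schedule of horizontal and vertical stages. The shared
#' encoder and projector always inherit weights from the previous stage;
#' translators for previously seen modalities are warm-started from the
#' registry, while new modalities get a translator created per their stage's
#' mode (masked phase-1 training for horizontal, regression initialisation
#' for vertical).
#'
#' @param schedule list of stages, each a list with `datasets` (named list),
#'   `mode` (`"horizontal"` or `"vertical"`), optional `masks`, and optional
#'   `config` overriding epoch counts for that stage
#' @param config the base [train_config()]
#' @return the final `ModelState` with the union translator registry
#' @export
train_mosaic <- function(schedule, config = train_config("mosaic")) {
  stop_if(length(schedule) == 0, "empty schedule")
  state <- NULL
  snapshots <- list()
  for (si in seq_along(schedule)) {
    stg <- schedule[[si]]
    cfg <- stg$config %||% config
    cfg$seed <- derive_seed(config$seed, "stage", si)
    label <- paste0("stage", si, ":", stg$mode)
    snapshots[[paste0(label, ":start")]] <-
      if (is.null(state)) NULL else state$encoder
    if (stg$mode == "horizontal") {
      state <- train_horizontal(stg$datasets, stg$masks %||% list(), cfg,
                                state = state, stage = label)
    } else if (stg$mode == "vertical") {
      state <- train_vertical(stg$datasets, cfg, state = state,
                              stage = label)
    } else {
      stop("unknown stage mode: ", stg$mode, call. = FALSE)
    }
    snapshots[[paste0(label, ":end")]] <- state$encoder
  }
  state$encoder_snapshots <- snapshots
  state
}

#' Embed datasets with a trained model
#'
#' Runs every dataset through its registered translator and the shared
#' encoder in evaluation mode (no augmentation, no dropout) and returns the
#' posterior means (or, with `use_mean = FALSE`, one seeded reparameterised
#' sample per cell).
#'
#' @param datasets named list of preprocessed OmicsDatasets
#' @param state a trained `ModelState`
#' @param use_mean return posterior means (default) or sampled coordinates
#' @param seed sampling seed when `use_mean = FALSE`
#' @return an [embedding_table()] covering all cells of all datasets
#' @export
embed_datasets <- function(datasets, state, use_mean = TRUE, seed = 1L) {
  stopifnot(inherits(state, "ModelState"))
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, translator_key, "")
  tabs <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    key <- translator_key(ds)
    stop_if(!key %in% names(state$translators),
            "no registered translator for modality '", key, "'")
    h <- translate(as_dense(ds$matrix), state$translators[[key]])
    post <- encode(h, state$encoder, training = FALSE)
    z <- if (use_mean) post$mu else
      sample_latent(post, derive_seed(seed, "embed", key))
    embedding_table(z, ds$cell_ids, ds$covariates,
                    if (is.null(ds$cell_type_labels)) NULL else
                      ds$cell_type_labels,
                    rep(names(datasets)[i], length(ds$cell_ids)))
  })
  do.call(rbind_embeddings, tabs)
}
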