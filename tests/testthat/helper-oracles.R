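# Independent naive-loop oracles used to validate the vectorized
# implementations. These are deliberately written with explicit loops and
# scalar formulas, sharing no code with the package internals.

naive_kl <- function(mu, sigma) {
  tot <- 0
  for (i in seq_len(nrow(mu))) {
    for (k in seq_len(ncol(mu))) {
      tot <- tot + 0.5 * (mu[i, k]^2 + sigma[i, k]^2 - 1 -
                            2 * log(sigma[i, k]))
    }
  }
  tot / nrow(mu)
}

naive_cos <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

# decoupled contrastive loss, explicit anchor loop over the 2N stacked rows
naive_dc <- function(Y1, Y2, tau, reduction = "mean") {
  n <- nrow(Y1)
  Y <- rbind(Y1, Y2)
  cell <- rep(seq_len(n), 2)
  partner <- c(seq_len(n) + n, seq_len(n))
  total <- 0
  for (i in seq_len(2 * n)) {
    pos <- -naive_cos(Y[i, ], Y[partner[i], ]) / tau
    U <- 0
    for (j in seq_len(2 * n)) {
      if (cell[j] != cell[i]) {
        U <- U + exp(naive_cos(Y[i, ], Y[j, ]) / tau)
      }
    }
    total <- total + pos + log(U)
  }
  if (reduction == "mean") total / (2 * n) else total
}

# silhouette widths by definition (explicit average-distance loops)
naive_asw <- function(z, labels) {
  n <- nrow(z)
  d <- as.matrix(dist(z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# LAES by definition, explicit per-cell neighbor search within the type
naive_laes <- function(z, types, mods, cell_type, k) {
  sel <- which(types == cell_type)
  N <- length(sel)
  d <- as.matrix(dist(z[sel, , drop = FALSE]))
  vals <- numeric(N)
  for (ii in seq_len(N)) {
    ord <- setdiff(order(d[ii, ]), ii)[seq_len(k)]
    own <- mods[sel] == mods[sel[ii]]
    na_k <- sum(own[ord])
    n_a <- sum(own)
    vals[ii] <- (na_k / n_a - (k - na_k) / (N - n_a)) * (N / k)
  }
  mean(vals)
}

# neighborhood group entropy over a fixed pooled set (no resampling)
naive_mixing <- function(z, groups, k) {
  d <- as.matrix(dist(z))
  lev <- unique(groups)
  ent <- numeric(nrow(z))
  for (i in seq_len(nrow(z))) {
    nb <- setdiff(order(d[i, ]), i)[seq_len(k)]
    e <- 0
    for (g in lev) {
      p <- mean(groups[nb] == g)
      if (p > 0) e <- e - p * log(p)
    }
    ent[i] <- e
  }
  mean(ent)
}

naive_transfer <- function(ref_z, ref_lab, qry_z, k) {
  d <- as.matrix(stats::dist(rbind(qry_z, ref_z)))
  nq <- nrow(qry_z)
  pred <- character(nq)
  for (i in seq_len(nq)) {
    di <- d[i, nq + seq_len(nrow(ref_z))]
    nb <- order(di)[seq_len(k)]
    votes <- table(ref_lab[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) { pred[i] <- top; next }
    best <- top[1]; bestw <- -Inf
    for (cl in top) {
      w <- sum(1 / pmax(di[nb[ref_lab[nb] == cl]], 1e-12))
      if (w > bestw) { bestw <- w; best <- cl }
    }
    pred[i] <- best
  }
  pred
}

# brute-force peak-gene window overlap in 0-based half-open coordinates
naive_mask <- function(peaks, genes, window) {
  m <- matrix(0, nrow(peaks), nrow(genes))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      gs <- genes$start[j] - window
      ge <- genes$end[j] + window
      if (peaks$start[i] < ge && peaks$end[i] > gs) m[i, j] <- 1
    }
  }
  m
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5e4,
                           max_len = 800, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small labeled embedding for metric tests: G Gaussian blobs x two groups
toy_embedding <- function(n_per = 20, types = c("A", "B", "C"),
                          groups = c("m1", "m2"), sep = 5, sd = 0.5,
                          seed = 1) {
  set.seed(seed)
  rows <- list(); tys <- c(); grs <- c()
  for (ti in seq_along(types)) {
    for (g in groups) {
      ctr <- c(ti * sep, -ti * sep)
      rows[[length(rows) + 1]] <-
        cbind(rnorm(n_per, ctr[1], sd), rnorm(n_per, ctr[2], sd))
      tys <- c(tys, rep(types[ti], n_per))
      grs <- c(grs, rep(g, n_per))
    }
  }
  z <- do.call(rbind, rows)
  emb <- embedding_table(z, cell_ids = sprintf("c%04d", seq_len(nrow(z))),
                         covariates = data.frame(modality = grs,
                                                 batch = grs),
                         cell_type_labels = tys,
                         source_dataset = grs)
  emb
}

small_counts_dataset <- function(n = 30, f = 12, modality = "rna",
                                 seed = 3) {
  set.seed(seed)
  m <- matrix(rpois(n * f, lambda = 4), n, f)
  omics_dataset(m,
                feature_ids = paste0("g", seq_len(f)),
                cell_ids = sprintf("%s_c%03d", modality, seq_len(n)),
                modality = modality,
                covariates = data.frame(
                  batch = rep(c("b1", "b2"), length.out = n)),
                cell_type_labels = rep(c("t1", "t2", "t3"),
                                       length.out = n))
}
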