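encode_node <- function(x) {
  if (is.matrix(x) && is.numeric(x)) {
    list(`.tensor` = TRUE, dim = dim(x),
         dimnames = dimnames(x), data = as.numeric(x))
  } else if (is.data.frame(x)) {
    list(`.df` = TRUE, data = as.list(x), rownames = rownames(x))
  } else if (is.list(x)) {
    out <- lapply(x, encode_node)
    cl <- setdiff(class(x), "list")
    if (length(cl) > 0) out$`.class` <- cl
    out$`.names` <- names(x) %||% character(0)
    out$`.null` <- which(vapply(x, is.null, TRUE))
    out
  } else {
    x
  }
}

decode_node <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x$`.tensor`)) {
    m <- matrix(as.numeric(unlist(x$data)), x$dim[[1]], x$dim[[2]])
    if (!is.null(x$dimnames)) {
      dimnames(m) <- lapply(x$dimnames, function(d)
        if (length(d) == 0) NULL else as.character(unlist(d)))
    }
    return(m)
  }
  if (isTRUE(x$`.df`)) {
    df <- as.data.frame(lapply(x$data, unlist), stringsAsFactors = FALSE)
    return(df)
  }
  cl <- x$`.class`
  nms <- x$`.names`
  nulls <- x$`.null`
  x$`.class` <- NULL; x$`.names` <- NULL; x$`.null` <- NULL
  out <- lapply(x, decode_node)
  if (!is.null(nms) && length(nms) == length(out)) names(out) <- unlist(nms)
  for (i in unlist(nulls)) out[i] <- list(NULL)
  if (!is.null(cl)) class(out) <- c(unlist(cl), "list")
  out
}

#' Save a trained model state as a JSON checkpoint
#'
#' Writes every parameter tensor (translator registry, encoder, projector)
#' plus the run configuration and training history into a single JSON file
#' at full precision. Optimiser moments are not persisted; resumed training
#' restarts the optimiser.
#'
#' @param state a `ModelState`
#' @param path output file
#' @export
save_model_state <- function(state, path) {
  stopifnot(inherits(state, "ModelState"))
  slim <- state
  slim$opt <- list()
  jsonlite::write_json(encode_node(unclass(slim)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model state saved by [save_model_state()]
#' @param path checkpoint file
#' @return a `ModelState`
#' @export
load_model_state <- function(path) {
  stop_if(!file.exists(path), "checkpoint not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  st <- decode_node(raw)
  # scalar/vector fields lose their shape in JSON; restore the simple ones
  fix_vec <- function(x) if (is.list(x)) unlist(x) else x
  st$shared_genes <- fix_vec(st$shared_genes)
  st$trained_cell_ids <- as.character(fix_vec(st$trained_cell_ids))
  st$holdout_ids <- as.character(fix_vec(st$holdout_ids))
  st$step <- as.integer(st$step)
  for (f in c("bmu", "bls", "k", "input_dim", "hidden", "dropout_rate")) {
    st$encoder[[f]] <- fix_vec(st$encoder[[f]])
  }
  for (i in seq_along(st$encoder$layers)) {
    for (f in c("b", "gamma", "beta")) {
      st$encoder$layers[[i]][[f]] <- fix_vec(st$encoder$layers[[i]][[f]])
    }
  }
  st$projector$b <- fix_vec(st$projector$b)
  st$projector$k <- fix_vec(st$projector$k)
  st$projector$p <- fix_vec(st$projector$p)
  st$projector$cov_levels <- lapply(st$projector$cov_levels, fix_vec)
  for (i in seq_along(st$translators)) {
    tr <- st$translators[[i]]
    if (is.null(tr)) next
    tr$b <- fix_vec(tr$b)
    tr$form <- fix_vec(tr$form)
    tr$modality <- fix_vec(tr$modality)
    st$translators[[i]] <- tr
  }
  loss_node <- st$config$loss
  cfg <- lapply(st$config[setdiff(names(st$config), "loss")], fix_vec)
  class(cfg) <- "TrainConfig"
  cfg$loss <- loss_config(as.numeric(loss_node$beta),
                          as.numeric(loss_node$tau),
                          as.character(loss_node$reduction))
  st$config <- cfg
  st$opt <- list()
  if (!is.data.frame(st$history)) st$history <- data.frame()
  class(st) <- "ModelState"
  for (i in seq_along(st$translators)) {
    if (!is.null(st$translators[[i]])) {
      class(st$translators[[i]]) <- "TranslatorParams"
    }
  }
  class(st$encoder) <- "EncoderParams"
  class(st$projector) <- "ProjectorParams"
  st
}
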