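#' Training configuration for the CPI model
#'
#' Defaults follow the training protocol used for the reported models:
#' learning rate 1e-4, weight decay 1e-4, dropout 0.2, Adam, and early
#' stopping with a patience of 10 epochs on the validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay, applied uniformly to all parameters.
#' @param dropout Dropout fraction for the two fully-connected layers of the
#'   protein encoder.
#' @param patience Early stopping halts after this many successive epochs
#'   without validation improvement.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param seed Seed driving initialization, shuffling and dropout.
#' @param nosplit Train the HGCN-nosplit ablation (whole molecule as one
#'   substructure).
#' @param kernel Customizable kernel size of the protein encoder.
#' @param verbose Print per-epoch losses.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         dropout = 0.2, patience = 10L, batch_size = 64L,
                         max_epochs = 100L, seed = 1L, nosplit = FALSE,
                         kernel = 6L, verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, patience >= 1L,
            batch_size >= 1L, max_epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay, dropout = dropout,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), nosplit = isTRUE(nosplit),
                 kernel = as.integer(kernel), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Four-layer fully-connected head ending in two logits.
.head_dims <- c(256L, 128L, 64L, 2L)

head_init <- function(in_dim, dims = .head_dims) {
  layers <- list()
  d_prev <- in_dim
  for (i in seq_along(dims)) {
    layers[[i]] <- list(W = init_matrix(d_prev, dims[i], fan_in = d_prev),
                        b = init_vector(dims[i]))
    d_prev <- dims[i]
  }
  layers
}

head_forward <- function(layers, X) {
  caches <- list()
  n <- length(layers)
  for (i in seq_len(n)) {
    lin <- linear_forward(X, layers[[i]]$W, layers[[i]]$b)
    caches[[i]] <- list(lin = lin)
    X <- lin$out
    if (i < n) {
      act <- relu_forward(X)
      caches[[i]]$act <- act
      X <- act$out
    }
  }
  list(out = X, caches = caches)
}

head_backward <- function(dout, fwd, layers) {
  n <- length(layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (i < n) dout <- relu_backward(dout, fwd$caches[[i]]$act)
    lb <- linear_backward(dout, fwd$caches[[i]]$lin, layers[[i]]$W)
    grads[[i]] <- list(W = lb$dW, b = lb$db)
    dout <- lb$dX
  }
  list(dX = dout, grads = grads)
}

.decompose_cached <- function(smiles) {
  cache <- new.env(parent = emptyenv())
  for (s in unique(smiles)) assign(s, decompose(s), envir = cache)
  cache
}

.tokenize_cached <- function(sequences, vocab, max_len) {
  cache <- new.env(parent = emptyenv())
  for (s in unique(sequences)) {
    assign(s, tokenize(s, vocab, max_len), envir = cache)
  }
  cache
}

.ids_matrix <- function(sequences, tok_cache, max_len) {
  out <- matrix(0L, length(sequences), max_len)
  for (i in seq_along(sequences)) {
    out[i, ] <- get(sequences[i], envir = tok_cache)$ids
  }
  out
}

# Forward the full model for one batch of records. Returns logits and the
# caches needed for backprop.
.model_forward <- function(params, buffers, records, ctx, training) {
  graphs <- lapply(records$smiles, get, envir = ctx$mol_cache)
  cb <- hgcn_batch(graphs, ctx$atom_vocab, nosplit = ctx$hgcn_config$nosplit)
  comp <- hgcn_forward(params$compound, buffers$compound, cb,
                       ctx$hgcn_config, training)
  ids <- .ids_matrix(records$sequence, ctx$tok_cache,
                     ctx$protein_config$max_len)
  prot <- protein_forward(params$protein, ids, ctx$protein_config, training)
  feat <- cbind(comp$out, prot$out)
  hf <- head_forward(params$head, feat)
  list(logits = hf$out, comp = comp, prot = prot, head = hf,
       buffers = list(compound = comp$buffers),
       comp_dim = ncol(comp$out))
}

.model_backward <- function(dlogits, fwd, params, ctx) {
  hb <- head_backward(dlogits, fwd$head, params$head)
  dcomp <- hb$dX[, seq_len(fwd$comp_dim), drop = FALSE]
  dprot <- hb$dX[, fwd$comp_dim + seq_len(ncol(hb$dX) - fwd$comp_dim),
                 drop = FALSE]
  list(compound = hgcn_backward(dcomp, fwd$comp, ctx$hgcn_config),
       protein = protein_backward(dprot, fwd$prot, params$protein,
                                  ctx$protein_config),
       head = hb$grads)
}

.mean_loss <- function(params, buffers, records, ctx, chunk = 256L) {
  n <- nrow(records)
  total <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- .model_forward(params, buffers, records[idx, , drop = FALSE],
                          ctx, training = FALSE)
    sx <- softmax_xent(fwd$logits, records$label[idx])
    total <- total + sx$loss * length(idx)
  }
  total / n
}

#' Train the CPI prediction model
#'
#' Minimizes the softmax cross-entropy with Adam. Training stops when the
#' validation loss has not improved for `patience` successive epochs or when
#' `max_epochs` is reached; the weights of the best-validation epoch are
#' returned. The atom vocabulary and the token length (`longest training
#' sequence + 2`) are derived from the training records.
#'
#' @param train,val Data frames with columns `smiles`, `sequence`, `label`
#'   (0/1).
#' @param config A [train_config()].
#' @return An object of class `cpi_model`: parameters, normalization
#'   buffers, configurations, vocabularies, the per-epoch `history`
#'   (train/validation loss), `best_epoch` and `stopped_epoch`.
#' @export
train_model <- function(train, val, config = train_config()) {
  for (d in list(train, val)) {
    stopifnot(is.data.frame(d),
              all(c("smiles", "sequence", "label") %in% names(d)))
    if (!all(d$label %in% c(0L, 1L))) stop("labels must be 0/1")
  }
  if (nrow(train) == 0L || nrow(val) == 0L) {
    stop("train and validation sets must be non-empty")
  }
  if (length(unique(train$label)) < 2L) {
    warning("training set contains a single class")
  }
  set.seed(config$seed)

  atom_vocab <- atom_vocabulary(train$smiles)
  token_vocab <- build_vocabulary()
  max_len <- max(nchar(train$sequence)) + 2L
  hcfg <- hgcn_config(nosplit = config$nosplit)
  pcfg <- protein_cnn_config(max_len, kernel = config$kernel,
                             dropout = config$dropout)
  ctx <- list(atom_vocab = atom_vocab, token_vocab = token_vocab,
              hgcn_config = hcfg, protein_config = pcfg,
              mol_cache = .decompose_cached(c(train$smiles, val$smiles)),
              tok_cache = .tokenize_cached(c(train$sequence, val$sequence),
                                           token_vocab, max_len))

  params <- list(compound = hgcn_init(hcfg, length(atom_vocab)),
                 protein = protein_init(pcfg),
                 head = head_init(hcfg$output_dim + pcfg$output_dim))
  buffers <- list(compound = hgcn_buffers(hcfg))
  opt <- adam_init(params)

  n <- nrow(train)
  best <- list(loss = Inf, epoch = 0L, params = params, buffers = buffers)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- train[idx, , drop = FALSE]
      fwd <- .model_forward(params, buffers, batch, ctx, training = TRUE)
      buffers <- fwd$buffers
      sx <- softmax_xent(fwd$logits, batch$label)
      if (!is.finite(sx$loss)) {
        stop(sprintf("training aborted: non-finite loss at epoch %d", epoch))
      }
      ep_loss <- ep_loss + sx$loss * length(idx)
      grads <- .model_backward(sx$dlogits, fwd, params, ctx)
      upd <- adam_step(params, grads, opt, lr = config$learning_rate,
                       weight_decay = config$weight_decay)
      params <- upd$params
      opt <- upd$state
    }
    val_loss <- .mean_loss(params, buffers, val, ctx)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / n, val_loss))
    }
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, params = params,
                   buffers = buffers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- epoch
        break
      }
    }
  }
  structure(list(params = best$params, buffers = best$buffers,
                 config = list(hgcn = hcfg, protein = pcfg, train = config),
                 atom_vocab = atom_vocab, token_vocab = token_vocab,
                 max_len = max_len, history = history,
                 best_epoch = best$epoch, stopped_epoch = stopped,
                 format_version = 1L),
            class = "cpi_model")
}

#' @export
print.cpi_model <- function(x, ...) {
  cat(sprintf(paste0("<cpi_model> HGCN%s + 1D-CNN (kernel %d, max_len %d)\n",
                     "  best epoch %d (val loss %.4f), stopped at %d\n"),
              if (x$config$hgcn$nosplit) "-nosplit" else "",
              x$config$protein$kernel, x$max_len, x$best_epoch,
              min(x$history$val_loss), x$stopped_epoch))
  invisible(x)
}

# Internal single-pair / batch forward used by predict functions.
.prepare_pair <- function(model, compound, protein) {
  h <- if (inherits(compound, "hierarchical_graph")) compound
       else decompose(compound)
  tok <- if (inherits(protein, "token_sequence")) protein
         else tokenize(protein, model$token_vocab, model$max_len)
  list(h = h, tok = tok)
}

#' Predict the interaction probability for one compound-protein pair
#'
#' Concatenates the compound and protein embeddings, applies the four-layer
#' head and a softmax over the two logits.
#'
#' @param model A trained [train_model()] model.
#' @param compound SMILES string or `hierarchical_graph`.
#' @param protein Amino-acid sequence or `token_sequence`.
#' @return A list of class `prediction_result`: `probability` (of class 1),
#'   `probs` (both classes, summing to one), `logits`, and `label`
#'   (0/1 at threshold 0.5).
#' @export
predict_proba <- function(model, compound, protein) {
  stopifnot(inherits(model, "cpi_model"))
  pair <- .prepare_pair(model, compound, protein)
  cemb <- encode_compound(pair$h, model$params$compound, model$config$hgcn,
                          model$atom_vocab, model$buffers$compound)
  pemb <- encode_protein(pair$tok, model$params$protein,
                         model$config$protein)
  hf <- head_forward(model$params$head, matrix(c(cemb, pemb), nrow = 1))
  p <- drop(softmax(hf$out))
  structure(list(probability = p[2], probs = p, logits = drop(hf$out),
                 label = as.integer(p[2] >= 0.5)),
            class = "prediction_result")
}

#' Predict interaction probabilities for a table of pairs
#'
#' @param model A trained [train_model()] model.
#' @param records Data frame with columns `smiles` and `sequence`.
#' @param chunk Number of pairs evaluated per forward pass.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_table <- function(model, records, chunk = 256L) {
  stopifnot(inherits(model, "cpi_model"))
  ctx <- list(atom_vocab = model$atom_vocab,
              hgcn_config = model$config$hgcn,
              protein_config = model$config$protein,
              mol_cache = .decompose_cached(records$smiles),
              tok_cache = .tokenize_cached(records$sequence,
                                           model$token_vocab, model$max_len))
  n <- nrow(records)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- .model_forward(model$params, model$buffers,
                          records[idx, , drop = FALSE], ctx,
                          training = FALSE)
    out[idx] <- softmax(fwd$logits)[, 2]
  }
  out
}

#' Classification metrics: AUC, F1 and MSE
#'
#' AUC is the rank-based (Mann-Whitney) concordance of the class-1
#' probability against the labels; F1 uses threshold 0.5; MSE is the mean
#' squared difference between the class-1 probability and the 0/1 label.
#'
#' @param probs Numeric vector of class-1 probabilities.
#' @param labels Integer 0/1 labels of the same length.
#' @return List with `auc` (NA with a message when only one class is
#'   present), `f1` and `mse`.
#' @export
evaluate <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- if (n1 == 0L || n0 == 0L) {
    NA_real_
  } else {
    r <- rank(probs)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(probs >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc, f1 = f1, mse = mean((probs - labels)^2))
}

# --- Checkpoints ---------------------------------------------------------

#' Save a trained model to a JSON checkpoint
#'
#' The checkpoint bundles the weights, normalization buffers, both
#' vocabularies, the token length and all configurations, under a
#' `format_version` field.
#'
#' @param model A `cpi_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cpi_model"))
  obj <- list(format_version = model$format_version,
              atom_vocab = model$atom_vocab,
              token_vocab = unclass(model$token_vocab),
              max_len = model$max_len,
              config = lapply(model$config, unclass),
              params = model$params,
              buffers = model$buffers,
              history = model$history,
              best_epoch = model$best_epoch,
              stopped_epoch = model$stopped_epoch)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

.restore_tree <- function(x) {
  if (is.list(x)) lapply(x, .restore_tree) else x
}

#' Load a model from a JSON checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return A `cpi_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format version")
  }
  fix_mat <- function(p) {
    # length-1 dims collapse to vectors in JSON; restore matrix shape for W
    rapply(p, function(x) x, how = "replace")
  }
  tv <- obj$token_vocab
  token_vocab <- structure(list(symbols = tv$symbols,
                                pad_id = as.integer(tv$pad_id),
                                begin_id = as.integer(tv$begin_id),
                                end_id = as.integer(tv$end_id)),
                           class = "token_vocabulary")
  hc <- obj$config$hgcn
  hcfg <- hgcn_config(hc$atom_steps, hc$subgraph_steps, hc$initial_dim,
                      hc$output_dim, hc$nosplit)
  pc <- obj$config$protein
  pcfg <- protein_cnn_config(pc$max_len, pc$embed_dim, pc$kernel,
                             pc$channels, pc$fc_dim, pc$output_dim,
                             pc$dropout)
  tc <- obj$config$train
  tcfg <- train_config(tc$learning_rate, tc$weight_decay, tc$dropout,
                       tc$patience, tc$batch_size, tc$max_epochs, tc$seed,
                       tc$nosplit, tc$kernel)
  params <- .ensure_shapes(fix_mat(obj$params))
  history <- do.call(rbind, lapply(obj$history, as.data.frame))
  if (is.null(history)) {
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
  }
  structure(list(params = params,
                 buffers = .restore_tree(obj$buffers),
                 config = list(hgcn = hcfg, protein = pcfg, train = tcfg),
                 atom_vocab = obj$atom_vocab, token_vocab = token_vocab,
                 max_len = as.integer(obj$max_len), history = history,
                 best_epoch = obj$best_epoch,
                 stopped_epoch = obj$stopped_epoch,
                 format_version = 1L),
            class = "cpi_model")
}

# jsonlite returns 1-row matrices as vectors; coerce weight leaves named W
# (and embed) back to matrices when needed
.ensure_shapes <- function(tree, parent = "") {
  if (is.list(tree)) {
    out <- lapply(seq_along(tree), function(i) {
      nm <- if (!is.null(names(tree))) names(tree)[i] else ""
      .ensure_shapes(tree[[i]], nm)
    })
    names(out) <- names(tree)
    return(out)
  }
  if (parent %in% c("W", "embed") && is.null(dim(tree))) {
    matrix(tree, nrow = 1)
  } else {
    tree
  }
}
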