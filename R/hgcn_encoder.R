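#' Configuration of the hierarchical compound encoder
#'
#' @param atom_steps Number of message-passing steps at the atom level
#'   (default 2, as used for the reported models).
#' @param subgraph_steps Number of message-passing steps at the substructure
#'   level (default 1).
#' @param initial_dim Width of the initial atom embedding (default 64).
#' @param output_dim Width of the final compound embedding (default 128).
#' @param nosplit If `TRUE`, bypass the substructure decomposition and treat
#'   the whole molecule as one substructure (the HGCN-nosplit ablation).
#' @return A list of class `hgcn_config`.
#' @export
hgcn_config <- function(atom_steps = 2L, subgraph_steps = 1L,
                        initial_dim = 64L, output_dim = 128L,
                        nosplit = FALSE) {
  stopifnot(atom_steps >= 0L, subgraph_steps >= 0L,
            initial_dim >= 1L, output_dim >= 1L)
  structure(list(atom_steps = as.integer(atom_steps),
                 subgraph_steps = as.integer(subgraph_steps),
                 initial_dim = as.integer(initial_dim),
                 output_dim = as.integer(output_dim),
                 nosplit = isTRUE(nosplit)),
            class = "hgcn_config")
}

# Trainable parameters. Atom-level layers keep the initial width and are each
# followed by batch normalization (gamma/beta trainable; running statistics
# live in separate buffers, see hgcn_buffers); the (last) subgraph-level
# layer widens to output_dim and has no normalization.
hgcn_init <- function(config, vocab_size) {
  d0 <- config$initial_dim
  atom_layers <- lapply(seq_len(config$atom_steps), function(t) {
    list(W = init_matrix(2L * d0, d0, fan_in = 2L * d0),
         b = init_vector(d0),
         gamma = rep(1, d0), beta = rep(0, d0))
  })
  sub_layers <- lapply(seq_len(config$subgraph_steps), function(t) {
    d_out <- if (t == config$subgraph_steps) config$output_dim else d0
    list(W = init_matrix(2L * d0, d_out, fan_in = 2L * d0),
         b = init_vector(d_out))
  })
  list(embed = init_matrix(vocab_size, d0, fan_in = vocab_size),
       atom_layers = atom_layers,
       sub_layers = sub_layers)
}

# Running batch-normalization statistics (not updated by the optimizer).
hgcn_buffers <- function(config) {
  d0 <- config$initial_dim
  list(atom_layers = lapply(seq_len(config$atom_steps), function(t) {
    list(mean = rep(0, d0), var = rep(1, d0))
  }))
}

#' One graph message-passing step
#'
#' Each node receives the sum of its neighbors' state vectors as its message;
#' the new state is `ReLU(W [h, m] + b)` where `[h, m]` concatenates the old
#' state with the message. Nodes without neighbors receive a zero message.
#' If the layer carries `gamma`/`beta`, batch normalization over the node
#' rows follows the activation.
#'
#' @param states Numeric matrix of node states (one row per node).
#' @param edges Two-column integer matrix of directed edges `(src, dst)`;
#'   for an undirected graph include both directions. `NULL` or zero rows
#'   means no neighbors anywhere (all messages zero).
#' @param layer List with `W` (`2*d_in x d_out`), `b`, and optionally
#'   `gamma`/`beta` for normalization.
#' @param training Logical; normalization uses batch statistics when `TRUE`
#'   and `buffers` statistics when `FALSE`.
#' @param buffers Optional list with `mean` and `var` running statistics
#'   (required when `training = FALSE` and the layer is normalized).
#' @return Matrix of updated node states.
#' @export
conv_step <- function(states, edges, layer, training = TRUE, buffers = NULL) {
  if (ncol(layer$W) != length(layer$b)) {
    stop("layer bias width does not match W output width")
  }
  if (2L * ncol(states) != nrow(layer$W)) {
    stop(sprintf("state width %d incompatible with W expecting input %d",
                 ncol(states), nrow(layer$W) / 2))
  }
  .conv_step_forward(states, edges, layer, training, buffers)$out
}

.aggregate_messages <- function(H, edges) {
  M <- matrix(0, nrow(H), ncol(H))
  if (!is.null(edges) && nrow(edges) > 0L) {
    add <- rowsum(H[edges[, 1], , drop = FALSE], group = edges[, 2])
    rows <- as.integer(rownames(add))
    M[rows, ] <- add
  }
  M
}

# Batch normalization with external buffers.
.bn_forward <- function(X, gamma, beta, buf, training,
                        momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu, "-")
    v <- colMeans(xc * xc)
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    v_run <- if (n > 1) v * n / (n - 1) else v
    buf$var <- (1 - momentum) * buf$var + momentum * v_run
  } else {
    if (is.null(buf)) stop("evaluation-mode normalization needs buffers")
    mu <- buf$mean
    v <- buf$var
    xc <- sweep(X, 2, mu, "-")
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, buf = buf,
       cache = list(xhat = xhat, istd = istd, training = training))
}

.bn_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  n <- nrow(dout)
  d <- ncol(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  if (cache$training) {
    t2 <- matrix(colMeans(dxhat), n, d, byrow = TRUE)
    t3 <- xhat * matrix(colMeans(dxhat * xhat), n, d, byrow = TRUE)
    dX <- sweep(dxhat - t2 - t3, 2, cache$istd, "*")
  } else {
    dX <- sweep(dxhat, 2, cache$istd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.conv_step_forward <- function(H, edges, layer, training, buf = NULL) {
  M <- .aggregate_messages(H, edges)
  lin <- linear_forward(cbind(H, M), layer$W, layer$b)
  act <- relu_forward(lin$out)
  out <- act$out
  bn_cache <- NULL
  if (!is.null(layer$gamma)) {
    bnf <- .bn_forward(out, layer$gamma, layer$beta, buf, training)
    out <- bnf$out
    buf <- bnf$buf
    bn_cache <- bnf$cache
  }
  list(out = out, lin = lin, act = act, bn_cache = bn_cache, buf = buf,
       layer = layer, d_in = ncol(H))
}

.conv_step_backward <- function(dout, cache, edges) {
  layer <- cache$layer
  grads <- list(W = NULL, b = NULL)
  if (!is.null(layer$gamma)) {
    bnb <- .bn_backward(dout, cache$bn_cache, layer$gamma)
    dout <- bnb$dX
    grads$gamma <- bnb$dgamma
    grads$beta <- bnb$dbeta
  }
  dZ <- relu_backward(dout, cache$act)
  lb <- linear_backward(dZ, cache$lin, layer$W)
  grads$W <- lb$dW
  grads$b <- lb$db
  d_in <- cache$d_in
  dH <- lb$dX[, seq_len(d_in), drop = FALSE]
  dM <- lb$dX[, d_in + seq_len(d_in), drop = FALSE]
  if (!is.null(edges) && nrow(edges) > 0L) {
    add <- rowsum(dM[edges[, 2], , drop = FALSE], group = edges[, 1])
    rows <- as.integer(rownames(add))
    dH[rows, ] <- dH[rows, , drop = FALSE] + add
  }
  # reorder so the gradient tree matches the parameter tree
  grads <- grads[names(layer)[names(layer) %in% names(grads)]]
  list(dH = dH, grads = grads)
}

#' Coordinate-wise maximum readout
#'
#' @param vectors Numeric matrix whose rows are equal-width embedding vectors
#'   (at least one row), or a single vector.
#' @return A single vector: the coordinate-wise maximum.
#' @export
max_pool_readout <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0L) stop("max_pool_readout of an empty set")
  apply(vectors, 2, max)
}

# Grouped coordinate-wise max with argmax bookkeeping for backprop.
.grouped_max_forward <- function(X, groups) {
  d <- ncol(X)
  n_g <- length(groups)
  out <- matrix(0, n_g, d)
  arg <- matrix(0L, n_g, d)
  for (g in seq_len(n_g)) {
    rows <- groups[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- X[rows, ]
      arg[g, ] <- rows
    } else {
      Xs <- X[rows, , drop = FALSE]
      w <- max.col(t(Xs), ties.method = "first")
      out[g, ] <- Xs[cbind(w, seq_len(d))]
      arg[g, ] <- rows[w]
    }
  }
  list(out = out, arg = arg)
}

.grouped_max_backward <- function(dout, arg, n_in_rows) {
  d <- ncol(dout)
  dX <- matrix(0, n_in_rows, d)
  lin <- (rep(seq_len(d), each = nrow(dout)) - 1L) * n_in_rows +
    as.vector(arg)
  dX[lin] <- as.vector(dout) # groups are disjoint: no collisions
  dX
}

# Assemble a batch of hierarchical graphs into flat index structures: one row
# per atom copy, directed intra-substructure bond lists, and directed
# virtual-edge lists at the substructure level.
hgcn_batch <- function(graphs, vocab, nosplit = FALSE) {
  if (nosplit) {
    graphs <- lapply(graphs, function(h) as_single_substructure(h$source))
  }
  labels <- integer(0)
  copy_off <- 0L
  sub_off <- 0L
  atom_edges <- list()
  sub_edges <- list()
  sub_atom_rows <- list()
  mol_sub_rows <- list()
  sub_count <- 0L
  unk <- length(vocab)
  for (mi in seq_along(graphs)) {
    h <- graphs[[mi]]
    mol_subs <- integer(0)
    for (s in h$substructures) {
      ids <- match(s$atoms$element, vocab)
      ids[is.na(ids)] <- unk
      labels <- c(labels, ids)
      n_a <- length(ids)
      sub_count <- sub_count + 1L
      sub_atom_rows[[sub_count]] <- copy_off + seq_len(n_a)
      mol_subs <- c(mol_subs, sub_count)
      if (nrow(s$bonds) > 0L) {
        e <- cbind(copy_off + s$bonds$i, copy_off + s$bonds$j)
        atom_edges[[length(atom_edges) + 1L]] <- rbind(e, e[, 2:1])
      }
      copy_off <- copy_off + n_a
    }
    mol_sub_rows[[mi]] <- mol_subs
    if (nrow(h$virtual_edges) > 0L) {
      ve <- cbind(sub_off + h$virtual_edges[, 1],
                  sub_off + h$virtual_edges[, 2])
      sub_edges[[length(sub_edges) + 1L]] <- rbind(ve, ve[, 2:1])
    }
    sub_off <- sub_off + length(h$substructures)
  }
  list(labels = labels,
       atom_edges = if (length(atom_edges)) do.call(rbind, atom_edges)
                    else matrix(integer(0), ncol = 2),
       sub_edges = if (length(sub_edges)) do.call(rbind, sub_edges)
                   else matrix(integer(0), ncol = 2),
       sub_atom_rows = sub_atom_rows,
       mol_sub_rows = mol_sub_rows,
       n_copies = copy_off, n_subs = sub_count, n_mols = length(graphs))
}

# Forward pass over a batch; returns embeddings (n_mols x output width), the
# cache for backprop, and refreshed batch-norm buffers.
hgcn_forward <- function(params, buffers, batch, config, training = FALSE) {
  H <- params$embed[batch$labels, , drop = FALSE]
  atom_caches <- vector("list", config$atom_steps)
  for (t in seq_len(config$atom_steps)) {
    f <- .conv_step_forward(H, batch$atom_edges, params$atom_layers[[t]],
                            training, buffers$atom_layers[[t]])
    H <- f$out
    buffers$atom_layers[[t]] <- f$buf
    atom_caches[[t]] <- f
  }
  sub0 <- .grouped_max_forward(H, batch$sub_atom_rows)
  S <- sub0$out
  sub_caches <- vector("list", config$subgraph_steps)
  for (t in seq_len(config$subgraph_steps)) {
    f <- .conv_step_forward(S, batch$sub_edges, params$sub_layers[[t]],
                            training)
    S <- f$out
    sub_caches[[t]] <- f
  }
  g <- .grouped_max_forward(S, batch$mol_sub_rows)
  list(out = g$out, buffers = buffers,
       cache = list(atom_caches = atom_caches, sub0 = sub0,
                    sub_caches = sub_caches, graph = g, batch = batch,
                    n_sub_rows = nrow(S), n_atom_rows = nrow(H),
                    embed_dim = ncol(params$embed),
                    vocab_size = nrow(params$embed)))
}

hgcn_backward <- function(dout, fwd, config) {
  cache <- fwd$cache
  batch <- cache$batch
  dS <- .grouped_max_backward(dout, cache$graph$arg, cache$n_sub_rows)
  sub_grads <- vector("list", config$subgraph_steps)
  for (t in rev(seq_len(config$subgraph_steps))) {
    b <- .conv_step_backward(dS, cache$sub_caches[[t]], batch$sub_edges)
    dS <- b$dH
    sub_grads[[t]] <- b$grads
  }
  dH <- .grouped_max_backward(dS, cache$sub0$arg, cache$n_atom_rows)
  atom_grads <- vector("list", config$atom_steps)
  for (t in rev(seq_len(config$atom_steps))) {
    b <- .conv_step_backward(dH, cache$atom_caches[[t]], batch$atom_edges)
    dH <- b$dH
    atom_grads[[t]] <- b$grads
  }
  dE <- matrix(0, cache$vocab_size, cache$embed_dim)
  add <- rowsum(dH, group = batch$labels)
  rows <- as.integer(rownames(add))
  dE[rows, ] <- add
  list(embed = dE, atom_layers = atom_grads, sub_layers = sub_grads)
}

#' Encode one compound into its embedding vector
#'
#' Runs the full hierarchical pipeline in evaluation mode: initial atom
#' embedding, `atom_steps` intra-substructure message-passing layers (each
#' followed by batch normalization), max-pool readout to substructure states,
#' `subgraph_steps` message-passing layers over virtual edges, and a final
#' max-pool readout over substructures.
#'
#' @param h A `hierarchical_graph` (see [decompose()]).
#' @param params Encoder parameters (e.g. `model$params$compound` of a
#'   trained [train_model()] model).
#' @param config An [hgcn_config()].
#' @param vocab Element vocabulary from [atom_vocabulary()].
#' @param buffers Batch-normalization buffers matching `params` (e.g.
#'   `model$buffers$compound`).
#' @return Numeric vector of width `config$output_dim`.
#' @export
encode_compound <- function(h, params, config, vocab,
                            buffers = hgcn_buffers(config)) {
  batch <- hgcn_batch(list(h), vocab, nosplit = config$nosplit)
  drop(hgcn_forward(params, buffers, batch, config, training = FALSE)$out)
}
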