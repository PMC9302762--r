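# Independent reference implementations used as oracles.

ns <- asNamespace("hgcncpi")

# Build a molecular_graph directly (bypassing SMILES parsing) from an edge
# list and per-bond aromatic flags; elements drawn from `elements`.
make_molgraph <- function(n_atoms, edges, aromatic, elements) {
  bonds <- if (length(aromatic)) {
    data.frame(i = pmin(edges[, 1], edges[, 2]),
               j = pmax(edges[, 1], edges[, 2]),
               aromatic = aromatic)
  } else {
    data.frame(i = integer(0), j = integer(0), aromatic = logical(0))
  }
  structure(list(atoms = data.frame(index = seq_len(n_atoms),
                                    element = elements,
                                    stringsAsFactors = FALSE),
                 bonds = bonds, smiles = "synthetic",
                 aromaticity_model = "manual"),
            class = "molecular_graph")
}

decompose_molgraph <- function(g) {
  add_virtual_edges(find_substructures(g, partition_bonds(g)), g)
}

# All labeled connected graphs on n nodes (edge subsets of the complete
# graph whose union is connected).
enumerate_connected_graphs <- function(n) {
  if (n == 1L) return(list(matrix(integer(0), ncol = 2)))
  all_edges <- t(utils::combn(n, 2))
  m <- nrow(all_edges)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    if (length(sel) < n - 1L) next
    e <- all_edges[sel, , drop = FALSE]
    # connectivity by BFS
    adj <- lapply(seq_len(n), function(v) {
      c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
    })
    seen <- logical(n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    if (all(seen)) out[[length(out) + 1L]] <- e
  }
  out
}

# Naive per-node-loop compound encoder: literal evaluation of the two-level
# message passing (neighbor-sum messages, ReLU(W[h,m]+b) updates, max-pool
# readouts), with the atom-level normalization computed by explicit loops.
naive_encode_compound <- function(h, params, config, vocab,
                                  training = TRUE, eps = 1e-5) {
  subs <- h$substructures
  unk <- length(vocab)
  # per-substructure atom states
  states <- lapply(subs, function(s) {
    ids <- match(s$atoms$element, vocab)
    ids[is.na(ids)] <- unk
    t(sapply(ids, function(id) params$embed[id, ]))
  })
  neighbors <- lapply(subs, function(s) {
    lapply(seq_len(nrow(s$atoms)), function(v) {
      c(s$bonds$j[s$bonds$i == v], s$bonds$i[s$bonds$j == v])
    })
  })
  for (t in seq_len(config$atom_steps)) {
    lay <- params$atom_layers[[t]]
    new_states <- states
    for (si in seq_along(subs)) {
      H <- states[[si]]
      Hn <- matrix(0, nrow(H), ncol(lay$W))
      for (v in seq_len(nrow(H))) {
        m <- rep(0, ncol(H))
        for (u in neighbors[[si]][[v]]) m <- m + H[u, ]
        z <- as.vector(t(lay$W) %*% c(H[v, ], m)) + lay$b
        Hn[v, ] <- pmax(z, 0)
      }
      new_states[[si]] <- Hn
    }
    # normalization over every atom copy in the molecule (explicit loops)
    all_rows <- do.call(rbind, new_states)
    mu <- apply(all_rows, 2, mean)
    va <- apply(all_rows, 2, function(x) mean((x - mean(x))^2))
    states <- lapply(new_states, function(H) {
      for (v in seq_len(nrow(H))) {
        H[v, ] <- lay$gamma * (H[v, ] - mu) / sqrt(va + eps) + lay$beta
      }
      H
    })
  }
  S <- t(sapply(states, function(H) apply(H, 2, max)))
  if (length(states) == 1L) S <- matrix(S, nrow = 1)
  ve <- h$virtual_edges
  sub_neighbors <- lapply(seq_along(subs), function(i) {
    c(ve[ve[, 1] == i, 2], ve[ve[, 2] == i, 1])
  })
  for (t in seq_len(config$subgraph_steps)) {
    lay <- params$sub_layers[[t]]
    Sn <- matrix(0, nrow(S), ncol(lay$W))
    for (ci in seq_len(nrow(S))) {
      m <- rep(0, ncol(S))
      for (cj in sub_neighbors[[ci]]) m <- m + S[cj, ]
      z <- as.vector(t(lay$W) %*% c(S[ci, ], m)) + lay$b
      Sn[ci, ] <- pmax(z, 0)
    }
    S <- Sn
  }
  apply(S, 2, max)
}

# Brute-force AUC: fraction of concordant positive-negative pairs (ties 0.5).
bruteforce_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
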