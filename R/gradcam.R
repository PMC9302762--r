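#' Per-channel importance weights from feature-map gradients
#'
#' The weight of channel `k` is the length-average of the gradient of the
#' class score with respect to that channel of the last convolutional
#' feature map: `alpha_k = (1/L) * sum_i d y_c / d A[i, k]`.
#'
#' @param rec List with `A` (feature map, positions x channels) and `grad`
#'   (gradient of the class score, same shape).
#' @return Numeric vector of one weight per channel.
#' @export
channel_weights <- function(rec) {
  stopifnot(is.matrix(rec$grad))
  if (nrow(rec$grad) == 0L) stop("zero-length feature map")
  if (!is.null(rec$A) && !identical(dim(rec$A), dim(rec$grad))) {
    stop("gradient shape does not match activation shape")
  }
  colMeans(rec$grad)
}

#' Class-discriminative localization map
#'
#' Position-wise ReLU of the channel-weighted sum of feature maps:
#' `ReLU(sum_k alpha_k A^k)`. The ReLU keeps only features with a positive
#' influence on the class of interest.
#'
#' @param alpha Channel weights from [channel_weights()].
#' @param A Feature map matrix (positions x channels).
#' @return Nonnegative numeric vector over map positions.
#' @export
compute_cam <- function(alpha, A) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (length(alpha) != ncol(A)) {
    stop(sprintf("channel count mismatch: %d weights, %d channels",
                 length(alpha), ncol(A)))
  }
  pmax(drop(A %*% alpha), 0)
}

#' Explain a CPI prediction with per-residue Grad-CAM saliency
#'
#' Runs a forward pass caching the activations of the protein encoder's last
#' convolutional layer, backpropagates the pre-softmax logit of the target
#' class to those activations, combines channel weights and activations into
#' a localization map, linearly interpolates the map onto the token
#' positions, crops to the residue span (begin/end/pad masked out) and
#' min-max normalizes to `[0, 1]`. Residues at or above
#' `highlight_threshold` form the highlighted set. The base model is not
#' modified or retrained.
#'
#' @param model A trained [train_model()] model.
#' @param compound SMILES string or `hierarchical_graph`.
#' @param protein Amino-acid sequence or `token_sequence`.
#' @param class Target class (default 1 = interaction).
#' @param highlight_threshold Saliency cutoff for the highlighted residue
#'   set (default 0.2).
#' @return An object of class `saliency_map`: `raw` (nonnegative map at
#'   last-conv positions), `projected` (per-residue saliency in `[0, 1]`),
#'   `residues`, `highlighted` (residue positions with saliency >=
#'   threshold), `threshold`, `class`, `probability` and `flat` (TRUE when
#'   the raw map was all zeros and normalization was skipped).
#' @export
explain <- function(model, compound, protein, class = 1L,
                    highlight_threshold = 0.2) {
  stopifnot(inherits(model, "cpi_model"), class %in% c(0L, 1L))
  pair <- .prepare_pair(model, compound, protein)
  pcfg <- model$config$protein
  hcfg <- model$config$hgcn

  cb <- hgcn_batch(list(pair$h), model$atom_vocab, nosplit = hcfg$nosplit)
  comp <- hgcn_forward(model$params$compound, model$buffers$compound, cb,
                       hcfg, training = FALSE)
  prot <- protein_forward(model$params$protein,
                          matrix(pair$tok$ids, nrow = 1), pcfg,
                          training = FALSE)
  feat <- cbind(comp$out, prot$out)
  hf <- head_forward(model$params$head, feat)
  probs <- drop(softmax(hf$out))

  dlogits <- matrix(0, 1, 2)
  dlogits[1, class + 1L] <- 1
  hb <- head_backward(dlogits, hf, model$params$head)
  dprot <- hb$dX[, hcfg$output_dim + seq_len(pcfg$output_dim), drop = FALSE]
  dA <- protein_backward(dprot, prot, model$params$protein, pcfg,
                         to_conv3_only = TRUE)$dA

  A <- prot$cache$A # last-conv activations (map positions x channels)
  alpha <- channel_weights(list(A = A, grad = dA))
  raw <- compute_cam(alpha, A)

  # interpolate the map onto token positions, then crop to the residue span
  L_map <- length(raw)
  L_tok <- pcfg$max_len
  tok_val <- if (L_map == 1L) {
    rep(raw, L_tok)
  } else {
    stats::approx(x = seq(0, 1, length.out = L_map), y = raw,
                  xout = seq(0, 1, length.out = L_tok))$y
  }
  res_val <- tok_val[1L + seq_len(pair$tok$n_residues)]

  flat <- max(res_val) <= 0
  projected <- if (flat) {
    rep(0, length(res_val))
  } else if (max(res_val) == min(res_val)) {
    rep(1, length(res_val))
  } else {
    (res_val - min(res_val)) / (max(res_val) - min(res_val))
  }
  structure(list(raw = raw, projected = projected,
                 residues = pair$tok$residues,
                 highlighted = which(projected >= highlight_threshold &
                                       !flat),
                 threshold = highlight_threshold,
                 class = as.integer(class),
                 probability = probs[class + 1L],
                 flat = flat),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(paste0("<saliency_map> class %d (p = %.3f): %d residues,",
                     " %d highlighted (>= %.2f)%s\n"),
              x$class, x$probability, length(x$projected),
              length(x$highlighted), x$threshold,
              if (x$flat) " [flat map]" else ""))
  invisible(x)
}

#' @describeIn explain Heat-strip visualization of a saliency map: one bar
#'   per residue, highlighted residues in color, the threshold as a dashed
#'   line.
#' @param x A `saliency_map`.
#' @param ... Further arguments passed to [graphics::barplot()].
#' @export
plot.saliency_map <- function(x, ...) {
  cols <- ifelse(seq_along(x$projected) %in% x$highlighted,
                 "firebrick", "grey70")
  graphics::barplot(x$projected, names.arg = x$residues, border = NA,
                    col = cols, space = 0, las = 2, cex.names = 0.5,
                    ylab = "Grad-CAM saliency", ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Tabulate a saliency map per residue
#'
#' @param sal A `saliency_map` from [explain()].
#' @return Data frame with columns `position` (1-based), `residue`,
#'   `saliency` and `highlighted`.
#' @export
saliency_table <- function(sal) {
  stopifnot(inherits(sal, "saliency_map"))
  data.frame(position = seq_along(sal$projected),
             residue = sal$residues,
             saliency = sal$projected,
             highlighted = seq_along(sal$projected) %in% sal$highlighted)
}

#' Highlighted regions as 1-based inclusive intervals
#'
#' Merges consecutive highlighted residues into intervals over sequence
#' coordinates, suitable for BED-like export.
#'
#' @param sal A `saliency_map`.
#' @return Data frame with columns `start` and `end` (1-based, inclusive).
#' @export
saliency_intervals <- function(sal) {
  stopifnot(inherits(sal, "saliency_map"))
  pos <- sal$highlighted
  if (length(pos) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  breaks <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[head(breaks, -1L) + 1L],
             end = pos[breaks[-1L]])
}
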