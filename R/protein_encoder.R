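#' Build the 24-token residue vocabulary
#'
#' The vocabulary holds the 20 amino acids of the standard genetic code plus
#' Selenocysteine (U) and Pyrrolysine (O), and two special symbols marking
#' the begin and end of a sequence. The pad id (0) is reserved and distinct
#' from the 24 symbols.
#'
#' @return An object of class `token_vocabulary`: list with `symbols`
#'   (ordered character vector of length 24), `pad_id` (0) and the ids of the
#'   begin/end tokens.
#' @export
build_vocabulary <- function() {
  residues <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                "U", "O")
  symbols <- c(residues, "<begin>", "<end>")
  structure(list(symbols = symbols, pad_id = 0L,
                 begin_id = 23L, end_id = 24L),
            class = "token_vocabulary")
}

#' Tokenize an amino-acid sequence to a fixed-length id vector
#'
#' The output is `begin + residues + end`, truncated or 0-padded to exactly
#' `max_len` ids. Truncation keeps the first `max_len - 2` residues and still
#' appends the end token.
#'
#' @param sequence Amino-acid string over the 22 residue letters
#'   (case-insensitive).
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Total token length (longest training sequence + 2).
#' @return An object of class `token_sequence`: list with `ids` (integer
#'   vector of length `max_len`, 0 = pad), `n_residues` (residue tokens kept)
#'   and `residues` (the kept residue characters).
#' @export
tokenize <- function(sequence, vocab, max_len) {
  stopifnot(inherits(vocab, "token_vocabulary"), max_len >= 3L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  ids <- match(chars, vocab$symbols)
  bad <- which(is.na(ids) | ids > 22L)
  if (length(bad)) {
    stop(sprintf("invalid residue letter '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  keep <- min(length(ids), max_len - 2L)
  ids <- ids[seq_len(keep)]
  out <- c(vocab$begin_id, ids, vocab$end_id)
  out <- c(out, rep(0L, max_len - length(out)))
  structure(list(ids = out, n_residues = keep,
                 residues = chars[seq_len(keep)]),
            class = "token_sequence")
}

#' Configuration of the 1D-CNN protein encoder
#'
#' Three 1D convolutions interleaved with two max-pooling layers, then two
#' fully-connected layers. The first convolution kernel is fixed at 3 and the
#' last pooling kernel at 12; the remaining kernels share the customizable
#' size `kernel`. Pool stride equals the pool kernel; convolutions use stride
#' 1 and no padding.
#'
#' @param max_len Token length of inputs (longest training sequence + 2).
#' @param embed_dim Token embedding width (default 64).
#' @param kernel Customizable kernel size for the second/third convolutions
#'   and first pooling layer (default 6).
#' @param channels Channels of every convolution (default 64).
#' @param fc_dim Width of the intermediate fully-connected layer
#'   (default 512).
#' @param output_dim Width of the protein embedding (default 128).
#' @param dropout Dropout fraction applied to the two fully-connected layers
#'   during training (default 0.2).
#' @return A list of class `protein_cnn_config`, including the per-layer map
#'   lengths in `$lengths`.
#' @export
protein_cnn_config <- function(max_len, embed_dim = 64L, kernel = 6L,
                               channels = 64L, fc_dim = 512L,
                               output_dim = 128L, dropout = 0.2) {
  stopifnot(max_len >= 3L, kernel >= 1L, dropout >= 0, dropout < 1)
  conv_kernels <- c(3L, as.integer(kernel), as.integer(kernel))
  pool_kernels <- c(as.integer(kernel), 12L)
  L <- as.integer(max_len)
  lens <- integer(5)
  lens[1] <- L - conv_kernels[1] + 1L
  lens[2] <- lens[1] - conv_kernels[2] + 1L
  lens[3] <- lens[2] %/% pool_kernels[1]
  lens[4] <- lens[3] - conv_kernels[3] + 1L
  lens[5] <- if (lens[4] >= 1L) lens[4] %/% pool_kernels[2] else 0L
  if (any(lens < 1L)) {
    stop(sprintf(paste0("max_len %d is too short for the receptive field of",
                        " kernel %d (map lengths %s); increase max_len to",
                        " at least %d"),
                 L, kernel, paste(lens, collapse = "/"),
                 .min_max_len(kernel)))
  }
  structure(list(max_len = L, embed_dim = as.integer(embed_dim),
                 kernel = as.integer(kernel),
                 conv_kernels = conv_kernels, pool_kernels = pool_kernels,
                 channels = as.integer(channels), fc_dim = as.integer(fc_dim),
                 output_dim = as.integer(output_dim), dropout = dropout,
                 lengths = lens,
                 flat_dim = lens[5] * as.integer(channels)),
            class = "protein_cnn_config")
}

# smallest max_len whose final map length is >= 1
.min_max_len <- function(kernel) {
  k <- as.integer(kernel)
  l4 <- 12L                      # need one full window for the last pool
  l3 <- l4 + k - 1L
  l2 <- l3 * k
  l1 <- l2 + k - 1L
  l1 + 2L
}

protein_init <- function(config) {
  d <- config$embed_dim
  ch <- config$channels
  ck <- config$conv_kernels
  list(embed = init_matrix(24L, d, fan_in = 24L),
       conv1 = list(W = init_matrix(ck[1] * d, ch, fan_in = ck[1] * d),
                    b = init_vector(ch)),
       conv2 = list(W = init_matrix(ck[2] * ch, ch, fan_in = ck[2] * ch),
                    b = init_vector(ch)),
       conv3 = list(W = init_matrix(ck[3] * ch, ch, fan_in = ck[3] * ch),
                    b = init_vector(ch)),
       fc1 = list(W = init_matrix(config$flat_dim, config$fc_dim,
                                  fan_in = config$flat_dim),
                  b = init_vector(config$fc_dim)),
       fc2 = list(W = init_matrix(config$fc_dim, config$output_dim,
                                  fan_in = config$fc_dim),
                  b = init_vector(config$output_dim)))
}

# Precompute stacked-layout index maps for a batch size B.
protein_index_maps <- function(config, B) {
  L <- config$max_len
  lens <- config$lengths
  ck <- config$conv_kernels
  pk <- config$pool_kernels
  list(c1 = conv_index(B, L, ck[1]),
       c2 = conv_index(B, lens[1], ck[2]),
       p1 = conv_index(B, lens[2], pk[1], stride = pk[1]),
       c3 = conv_index(B, lens[3], ck[3]),
       p2 = conv_index(B, lens[4], pk[2], stride = pk[2]))
}

# Forward pass for a batch of token id matrices (B x max_len). Dropout is
# active only when training = TRUE.
protein_forward <- function(params, ids, config, training = FALSE,
                            im = NULL) {
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1)
  B <- nrow(ids)
  if (is.null(im)) im <- protein_index_maps(config, B)
  d <- config$embed_dim
  idv <- as.vector(t(ids)) # stacked rows: block b = sequence b
  X <- matrix(0, B * config$max_len, d)
  nz <- idv > 0L
  X[nz, ] <- params$embed[idv[nz], , drop = FALSE]

  c1 <- conv1d_forward(X, params$conv1$W, params$conv1$b, im$c1)
  r1 <- relu_forward(c1$out)
  c2 <- conv1d_forward(r1$out, params$conv2$W, params$conv2$b, im$c2)
  r2 <- relu_forward(c2$out)
  p1 <- maxpool_forward(r2$out, im$p1)
  c3 <- conv1d_forward(p1$out, params$conv3$W, params$conv3$b, im$c3)
  r3 <- relu_forward(c3$out)            # last-conv activations (Grad-CAM A)
  p2 <- maxpool_forward(r3$out, im$p2)

  L5 <- config$lengths[5]
  arr <- array(t(p2$out), dim = c(config$channels, L5, B))
  flat <- t(matrix(arr, config$channels * L5, B))

  f1 <- linear_forward(flat, params$fc1$W, params$fc1$b)
  rf1 <- relu_forward(f1$out)
  dr1 <- dropout_forward(rf1$out, config$dropout, training)
  f2 <- linear_forward(dr1$out, params$fc2$W, params$fc2$b)
  dr2 <- dropout_forward(f2$out, config$dropout, training)

  list(out = dr2$out,
       cache = list(B = B, im = im, idv = idv, nz = nz,
                    c1 = c1, r1 = r1, c2 = c2, r2 = r2, p1 = p1,
                    c3 = c3, r3 = r3, p2 = p2, flat_rows = B,
                    f1 = f1, rf1 = rf1, dr1 = dr1, f2 = f2, dr2 = dr2,
                    A = r3$out))
}

# Backward from d(out); to_conv3_only = TRUE stops at the last-conv
# activations and returns their gradient (the Grad-CAM path).
protein_backward <- function(dout, fwd, params, config,
                             to_conv3_only = FALSE) {
  cache <- fwd$cache
  im <- cache$im
  B <- cache$B
  d <- config$embed_dim
  ch <- config$channels
  L5 <- config$lengths[5]

  dout <- dropout_backward(dout, cache$dr2)
  l2b <- linear_backward(dout, cache$f2, params$fc2$W)
  dfc1 <- dropout_backward(l2b$dX, cache$dr1)
  dfc1 <- relu_backward(dfc1, cache$rf1)
  l1b <- linear_backward(dfc1, cache$f1, params$fc1$W)

  # unflatten: inverse of the forward reshape; element (c, p, b) goes to
  # stacked row (b-1)*L5 + p, column c
  arr <- array(t(l1b$dX), dim = c(ch, L5, B))
  dp2 <- matrix(aperm(arr, c(2, 3, 1)), B * L5, ch)

  dr3 <- maxpool_backward(dp2, cache$p2, nrow(cache$r3$out))
  dA <- dr3
  if (to_conv3_only) {
    return(list(dA = dA))
  }
  dc3 <- relu_backward(dr3, cache$r3)
  c3b <- conv1d_backward(dc3, cache$c3, params$conv3$W, im$c3,
                         nrow(cache$p1$out))
  dr2 <- maxpool_backward(c3b$dX, cache$p1, nrow(cache$r2$out))
  dc2 <- relu_backward(dr2, cache$r2)
  c2b <- conv1d_backward(dc2, cache$c2, params$conv2$W, im$c2,
                         nrow(cache$r1$out))
  dc1 <- relu_backward(c2b$dX, cache$r1)
  c1b <- conv1d_backward(dc1, cache$c1, params$conv1$W, im$c1,
                         B * config$max_len)

  dE <- matrix(0, 24L, d)
  nz <- cache$nz
  if (any(nz)) {
    add <- rowsum(c1b$dX[nz, , drop = FALSE], group = cache$idv[nz])
    rows <- as.integer(rownames(add))
    dE[rows, ] <- add
  }
  list(embed = dE,
       conv1 = list(W = c1b$dW, b = c1b$db),
       conv2 = list(W = c2b$dW, b = c2b$db),
       conv3 = list(W = c3b$dW, b = c3b$db),
       fc1 = list(W = l1b$dW, b = l1b$db),
       fc2 = list(W = l2b$dW, b = l2b$db))
}

#' Encode a tokenized protein sequence into its embedding vector
#'
#' Runs the 1D-CNN stack in evaluation mode: token embedding (pad maps to the
#' zero vector), convolution (kernel 3), convolution (kernel `k`), max pool
#' (kernel `k`), convolution (kernel `k`), max pool (kernel 12), flatten, and
#' two fully-connected layers.
#'
#' @param tokens A `token_sequence` from [tokenize()] (its length must equal
#'   `config$max_len`).
#' @param params Encoder parameters (e.g. `model$params$protein`).
#' @param config A [protein_cnn_config()].
#' @return Numeric vector of width `config$output_dim`.
#' @export
encode_protein <- function(tokens, params, config) {
  stopifnot(inherits(tokens, "token_sequence"))
  if (length(tokens$ids) != config$max_len) {
    stop(sprintf("token sequence length %d does not match config max_len %d",
                 length(tokens$ids), config$max_len))
  }
  drop(protein_forward(params, matrix(tokens$ids, nrow = 1), config,
                       training = FALSE)$out)
}
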