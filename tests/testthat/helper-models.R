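# Construct a small untrained model (random weights, seeded) without going
# through train_model; used by prediction/saliency contract tests.
make_tiny_model <- function(seed = 1L, kernel = 2L, max_len = 32L,
                            atom_vocab = c("C", "N", "O", "<unk>"),
                            nosplit = FALSE) {
  set.seed(seed)
  hcfg <- hgcn_config(initial_dim = 8L, output_dim = 12L, nosplit = nosplit)
  pcfg <- protein_cnn_config(max_len, embed_dim = 8L, kernel = kernel,
                             channels = 6L, fc_dim = 10L, output_dim = 12L,
                             dropout = 0)
  params <- list(compound = ns$hgcn_init(hcfg, length(atom_vocab)),
                 protein = ns$protein_init(pcfg),
                 head = ns$head_init(24L, dims = c(16L, 8L, 4L, 2L)))
  structure(list(params = params,
                 buffers = list(compound = ns$hgcn_buffers(hcfg)),
                 config = list(hgcn = hcfg, protein = pcfg,
                               train = train_config(kernel = kernel)),
                 atom_vocab = atom_vocab,
                 token_vocab = build_vocabulary(),
                 max_len = as.integer(max_len),
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 best_epoch = 0L, stopped_epoch = 0L,
                 format_version = 1L),
            class = "cpi_model")
}

# A fast-training configuration for desk-scale fits.
tiny_train_config <- function(seed = 1L, max_epochs = 10L,
                              batch_size = 8L, ...) {
  train_config(seed = seed, max_epochs = max_epochs,
               batch_size = batch_size, kernel = 2L, ...)
}

# A small planted-rule dataset with short proteins (compatible with
# kernel = 2 encoders).
tiny_dataset <- function(n_pairs = 60L, seed = 1L, label_noise = 0) {
  generate_synthetic_dataset(synthetic_spec(
    n_compounds = 15L, n_proteins = 10L, n_pairs = n_pairs,
    protein_length = 40L, label_noise = label_noise, seed = seed))
}
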