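test_that("interaction tables read with validation and row tracking", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("smiles\tsequence\tlabel",
               "CCO\tMKWVHE\t1",
               "c1ccccc1\tARNDKW\t0",
               "Cc1ccccc1\tMKHEHA\t1"), path)
  df <- read_interaction_table(path)
  expect_equal(nrow(df), 3)
  expect_equal(df$row, 1:3)

  writeLines(c("smiles\tsequence\tlabel", "CCO\tMKWVHE\t2"), path)
  expect_error(read_interaction_table(path), "row 1")

  writeLines(c("smiles\tsequence\tic50", "CCO\tMKWVHE\t50"), path)
  df <- read_interaction_table(path)
  expect_false("label" %in% names(df))
  expect_equal(df$ic50, 50)

  writeLines(c("smiles\tlabel", "CCO\t1"), path)
  expect_error(read_interaction_table(path), "sequence")

  writeLines(c("smiles\tsequence\tlabel",
               "CCO\tMKWVHE\t1",
               "xx((\tARNDKW\t0"), path)
  expect_error(read_interaction_table(path, strict = TRUE), "row 2")
  expect_message(df <- read_interaction_table(path, strict = FALSE),
                 "dropping 1")
  expect_equal(nrow(df), 1)
})

test_that("IC50 labeling applies the dataset-specific thresholds", {
  expect_equal(label_from_ic50(50, "bindingdb"), "positive")
  expect_equal(label_from_ic50(20000, "bindingdb"), "negative")
  expect_equal(label_from_ic50(5000, "bindingdb"), "excluded")
  # bindingdb bounds are strict
  expect_equal(label_from_ic50(100, "bindingdb"), "excluded")
  expect_equal(label_from_ic50(10000, "bindingdb"), "excluded")
  # chembl27 bounds are inclusive
  expect_equal(label_from_ic50(100, "chembl27"), "positive")
  expect_equal(label_from_ic50(1000, "chembl27"), "negative")
  expect_equal(label_from_ic50(500, "chembl27"), "excluded")
  expect_equal(label_from_ic50(c(1, 99.9, 101), "bindingdb"),
               c("positive", "positive", "excluded"))
  expect_error(label_from_ic50(-5, "bindingdb"), "positive")
})

test_that("splits are stratified, disjoint, exhaustive and seeded", {
  df <- data.frame(smiles = paste0("C", 1:100), sequence = paste0("S", 1:100),
                   label = rep(c(0L, 1L), 50))
  s1 <- split_dataset(df, "holdout", fractions = c(0.5, 0.25, 0.25),
                      seed = 3L)
  expect_equal(nrow(s1$train), 50)
  expect_equal(nrow(s1$validation), 25)
  expect_equal(nrow(s1$test), 25)
  for (part in s1) {
    expect_lte(abs(sum(part$label == 1) - sum(part$label == 0)), 1)
  }
  all_rows <- c(s1$train$smiles, s1$validation$smiles, s1$test$smiles)
  expect_setequal(all_rows, df$smiles)
  s2 <- split_dataset(df, "holdout", fractions = c(0.5, 0.25, 0.25),
                      seed = 3L)
  expect_identical(s1, s2)

  folds <- split_dataset(df, "kfold", k = 5L, seed = 4L)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) nrow(f$test), 0L)
  expect_equal(sizes, rep(20L, 5))
  test_rows <- unlist(lapply(folds, function(f) f$test$smiles))
  expect_setequal(test_rows, df$smiles) # disjoint + exhaustive
  expect_equal(length(test_rows), 100L)
  for (f in folds) {
    expect_equal(sum(f$test$label == 1), 10)
    expect_setequal(c(f$train$smiles, f$test$smiles), df$smiles)
  }
  expect_error(split_dataset(df[1:3, ], "kfold", k = 5L), "exceeds")
})

test_that("scenario tags follow train membership and partition the test set", {
  train <- data.frame(smiles = c("c1", "c1", "c2"),
                      sequence = c("p1", "p2", "p1"))
  test <- data.frame(smiles = c("c1", "c9", "c9", "c2"),
                     sequence = c("p9", "p1", "p9", "p2"))
  tags <- stratify_scenarios(train, test)
  expect_equal(as.character(tags),
               c("known_compound_new_protein",
                 "new_compound_known_protein",
                 "new_compound_new_protein",
                 "known_compound_known_protein"))
  expect_equal(sum(table(tags)), nrow(test))
  # property: tags always partition any test set
  set.seed(5)
  big_test <- data.frame(
    smiles = sample(paste0("c", 1:6), 40, replace = TRUE),
    sequence = sample(paste0("p", 1:6), 40, replace = TRUE))
  t2 <- stratify_scenarios(train, big_test)
  expect_false(any(is.na(t2)))
  expect_equal(sum(table(t2)), 40)
})

test_that("the generator is deterministic and respects the planted rule", {
  spec <- synthetic_spec(n_compounds = 15L, n_proteins = 10L, n_pairs = 80L,
                         protein_length = 40L, seed = 6L)
  d1 <- generate_synthetic_dataset(spec)
  d2 <- generate_synthetic_dataset(spec)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 80)
  # noise-free labels match the fragment AND motif conjunction exactly
  has_frag <- attr(d1, "has_fragment")
  has_motif <- attr(d1, "has_motif")
  expect_equal(d1$label, as.integer(has_frag & has_motif))
  expect_equal(has_motif, grepl(spec$motif, d1$sequence, fixed = TRUE))
  # pairs are unique
  expect_false(anyDuplicated(paste(d1$smiles, d1$sequence)) > 0)
})

test_that("label noise flips a binomial share of labels", {
  spec <- synthetic_spec(n_compounds = 40L, n_proteins = 30L,
                         n_pairs = 1000L, protein_length = 40L,
                         label_noise = 0.1, seed = 7L)
  d <- generate_synthetic_dataset(spec)
  clean <- as.integer(attr(d, "has_fragment") & attr(d, "has_motif"))
  n_flipped <- sum(d$label != clean)
  # within 3 sigma of Binomial(1000, 0.1)
  expect_lt(abs(n_flipped - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_equal(which(d$label != clean), which(attr(d, "flipped")))
})

test_that("generated compounds parse and decompose nontrivially", {
  d <- generate_synthetic_dataset(synthetic_spec(
    n_compounds = 20L, n_proteins = 2L, n_pairs = 40L,
    protein_length = 40L, seed = 8L))
  for (smi in unique(d$smiles)) {
    h <- decompose(smi) # errors if unparsable
    expect_gte(length(h$substructures), 2)
    kinds <- vapply(h$substructures, `[[`, TRUE, "aromatic")
    expect_true(any(kinds) && any(!kinds))
  }
})

test_that("FASTA sequences join into interaction tables by id", {
  fasta <- tempfile(fileext = ".fa")
  writeLines(c(">p1 some kinase", "MKWVHE", ">p2", "ARNDKW"), fasta)
  seqs <- read_protein_fasta(fasta)
  expect_equal(seqs, c(p1 = "MKWVHE", p2 = "ARNDKW"))
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("smiles\tsequence_id\tlabel",
               "CCO\tp2\t1",
               "Cc1ccccc1\tp1\t0"), tab)
  df <- read_interaction_table(tab, fasta = fasta)
  expect_equal(df$sequence, c("ARNDKW", "MKWVHE"))
  writeLines(c("smiles\tsequence_id\tlabel", "CCO\tp9\t1"), tab)
  expect_error(read_interaction_table(tab, fasta = fasta), "p9")
})

test_that("split manifests carry part and scenario columns", {
  df <- generate_synthetic_dataset(synthetic_spec(
    n_compounds = 12L, n_proteins = 8L, n_pairs = 60L,
    protein_length = 40L, seed = 12L))
  parts <- split_dataset(df, "holdout", seed = 12L)
  path <- tempfile(fileext = ".tsv")
  write_split_manifest(parts, path)
  man <- utils::read.delim(path)
  expect_equal(nrow(man), 60L)
  expect_setequal(unique(man$part), c("train", "validation", "test"))
  test_rows <- man[man$part == "test", ]
  expect_false(any(is.na(test_rows$scenario)))
  expect_true(all(is.na(man$scenario[man$part != "test"])))
})
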