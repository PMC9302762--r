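#' Read a compound-protein interaction table
#'
#' Reads a delimited text file with a header naming at least `smiles` and
#' `sequence`, plus `label` (0/1) and/or `ic50` (nM). The delimiter defaults
#' to tab for `.tsv`/`.txt` and comma for `.csv`.
#'
#' @param path File path.
#' @param sep Field delimiter; guessed from the extension when `NULL`.
#' @param validate_smiles Parse every unique SMILES and act on failures.
#' @param strict With `validate_smiles`: `TRUE` stops at the first
#'   unparsable SMILES; `FALSE` drops the offending rows with a message.
#' @param fasta Optional FASTA file; when the table has a `sequence_id`
#'   column instead of `sequence`, sequences are joined in by id.
#' @return Data frame of interaction records; the original row number of
#'   each record is kept in the `row` column.
#' @export
read_interaction_table <- function(path, sep = NULL, validate_smiles = TRUE,
                                   strict = TRUE, fasta = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!is.null(fasta) && !"sequence" %in% names(df)) {
    if (!"sequence_id" %in% names(df)) {
      stop("joining a FASTA file requires a `sequence_id` column")
    }
    seqs <- read_protein_fasta(fasta)
    hit <- match(df$sequence_id, names(seqs))
    if (anyNA(hit)) {
      stop(sprintf("sequence_id '%s' not found in %s",
                   df$sequence_id[which(is.na(hit))[1]], fasta))
    }
    df$sequence <- unname(seqs[hit])
  }
  need <- c("smiles", "sequence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols,
                                                collapse = ", ")))
  }
  if (!any(c("label", "ic50") %in% names(df))) {
    stop("table must contain a `label` or an `ic50` column")
  }
  df$row <- seq_len(nrow(df))
  if ("label" %in% names(df)) {
    bad <- which(!df$label %in% c(0L, 1L))
    if (length(bad)) {
      stop(sprintf("invalid label %s in row %d (labels must be 0/1)",
                   df$label[bad[1]], bad[1]))
    }
  }
  if ("ic50" %in% names(df) && any(df$ic50 <= 0, na.rm = TRUE)) {
    stop("ic50 values must be positive (nM)")
  }
  if (validate_smiles) {
    ok <- vapply(df$smiles, function(s) {
      !inherits(try(parse_smiles(s), silent = TRUE), "try-error")
    }, TRUE)
    if (!all(ok)) {
      bad_rows <- df$row[!ok]
      if (strict) {
        stop(sprintf("unparsable SMILES '%s' in row %d",
                     df$smiles[!ok][1], bad_rows[1]))
      }
      message(sprintf("dropping %d row(s) with unparsable SMILES: %s",
                      sum(!ok), paste(utils::head(bad_rows, 5),
                                      collapse = ", ")))
      df <- df[ok, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences (names taken from
#'   the first word of each header).
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- vapply(strsplit(names(aa), "[[:space:]]+"),
                       `[[`, "", 1L)
  out
}

#' Write a split manifest as TSV
#'
#' Records every split part in one table with a `part` column; test records
#' additionally carry their cold-start `scenario` tag relative to the
#' training part.
#'
#' @param parts Holdout split from [split_dataset()] (list with `train`,
#'   `validation`, `test`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(parts, path) {
  stopifnot(all(c("train", "validation", "test") %in% names(parts)))
  rows <- list()
  for (p in c("train", "validation", "test")) {
    d <- parts[[p]]
    if (nrow(d) == 0L) next
    d$part <- p
    d$scenario <- if (p == "test") {
      as.character(stratify_scenarios(parts$train, d))
    } else {
      NA_character_
    }
    rows[[p]] <- d
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binary activity label from an IC50 measurement
#'
#' Applies the dataset-specific thresholds: under the `bindingdb` rule a
#' sample is positive when IC50 < 100 nM and negative when IC50 > 10000 nM
#' (strict inequalities); under the `chembl27` rule positive when
#' IC50 <= 100 nM and negative when IC50 >= 1000 nM (inclusive). Values in
#' between are excluded.
#'
#' @param ic50 Numeric vector of IC50 concentrations in nM (> 0).
#' @param rule `"bindingdb"` or `"chembl27"`.
#' @return Character vector over `"positive"`, `"negative"`, `"excluded"`.
#' @export
label_from_ic50 <- function(ic50, rule = c("bindingdb", "chembl27")) {
  rule <- match.arg(rule)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be positive and finite (nM)")
  }
  out <- rep("excluded", length(ic50))
  if (rule == "bindingdb") {
    out[ic50 < 100] <- "positive"
    out[ic50 > 10000] <- "negative"
  } else {
    out[ic50 <= 100] <- "positive"
    out[ic50 >= 1000] <- "negative"
  }
  out
}

# Label-stratified assignment of items to groups with given fractions.
# Fractional remainders are carried across classes so the per-group totals
# track the target fractions as closely as possible.
.stratified_assign <- function(labels, fractions) {
  n <- length(labels)
  assign <- integer(n)
  carry <- rep(0, length(fractions))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    target <- fractions * length(idx) + carry
    sizes <- pmax(floor(target), 0)
    rem <- length(idx) - sum(sizes)
    if (rem > 0) {
      extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    carry <- target - sizes
    assign[idx] <- rep(seq_along(fractions), times = sizes)
  }
  assign
}

#' Split interaction records for training and evaluation
#'
#' `holdout` produces label-stratified train/validation/test subsets at the
#' given fractions; `kfold` produces `k` label-stratified folds
#' (disjoint and exhaustive), each fold serving once as the test set.
#'
#' @param records Data frame with a `label` column.
#' @param mode `"holdout"` or `"kfold"`.
#' @param fractions Holdout fractions for train/validation/test
#'   (default 0.8/0.1/0.1).
#' @param k Number of folds (default 5).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return For `holdout`: list with `train`, `validation`, `test` data
#'   frames. For `kfold`: list of `k` lists, each with `train` and `test`
#'   (fold assignments also returned as attribute `fold`).
#' @export
split_dataset <- function(records, mode = c("holdout", "kfold"),
                          fractions = c(0.8, 0.1, 0.1), k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), "label" %in% names(records))
  set.seed(seed)
  if (mode == "holdout") {
    stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
    g <- .stratified_assign(records$label, fractions)
    list(train = records[g == 1L, , drop = FALSE],
         validation = records[g == 2L, , drop = FALSE],
         test = records[g == 3L, , drop = FALSE])
  } else {
    k <- as.integer(k)
    if (k > nrow(records)) {
      stop(sprintf("k = %d exceeds the number of records (%d)", k,
                   nrow(records)))
    }
    g <- .stratified_assign(records$label, rep(1 / k, k))
    folds <- lapply(seq_len(k), function(fold) {
      list(train = records[g != fold, , drop = FALSE],
           test = records[g == fold, , drop = FALSE])
    })
    attr(folds, "fold") <- g
    folds
  }
}

#' Tag test pairs with their cold-start scenario
#'
#' A compound or protein is "known" when its exact SMILES or sequence occurs
#' in the training records; the known-known tag covers unseen pairs of seen
#' elements.
#'
#' @param train,test Data frames with columns `smiles` and `sequence`.
#' @return Factor of length `nrow(test)` over the four scenario levels
#'   `new_compound_known_protein`, `known_compound_new_protein`,
#'   `new_compound_new_protein`, `known_compound_known_protein`.
#' @export
stratify_scenarios <- function(train, test) {
  known_c <- test$smiles %in% train$smiles
  known_p <- test$sequence %in% train$sequence
  tag <- ifelse(known_c & known_p, "known_compound_known_protein",
         ifelse(known_c, "known_compound_new_protein",
         ifelse(known_p, "new_compound_known_protein",
                "new_compound_new_protein")))
  factor(tag, levels = c("new_compound_known_protein",
                         "known_compound_new_protein",
                         "new_compound_new_protein",
                         "known_compound_known_protein"))
}

#' Specification of a synthetic planted-rule CPI dataset
#'
#' The generator emulates a binary CPI screen at desk scale: compounds are
#' assembled from aromatic ring and aliphatic linker fragments (so the
#' reduced-graph decomposition is nontrivial), proteins are uniform random
#' sequences over the 20 standard residues, and the interaction rule is a
#' detectable conjunction: a pair is positive iff the compound contains the
#' designated positive ring fragment (pyrimidine) AND the protein contains
#' the planted motif. Labels are flipped with probability `label_noise`.
#'
#' @param n_compounds,n_proteins,n_pairs Library and dataset sizes.
#' @param protein_length Residue length of the generated proteins.
#' @param motif Planted residue motif (default a 6-mer to match the default
#'   convolution kernel).
#' @param label_noise Label flip probability in `[0, 0.5)`.
#' @param frag_prob Fraction of compounds carrying the positive fragment.
#'   The default 0.7 (with `motif_prob` 0.7) yields approximately balanced
#'   labels, emulating the balanced benchmark CPI datasets.
#' @param motif_prob Fraction of proteins carrying the motif.
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 60L, n_proteins = 40L,
                           n_pairs = 500L, protein_length = 120L,
                           motif = "WHKWHE", label_noise = 0,
                           frag_prob = 0.7, motif_prob = 0.7, seed = 1L) {
  stopifnot(n_compounds >= 1L, n_proteins >= 1L, n_pairs >= 1L,
            label_noise >= 0, label_noise < 0.5,
            n_pairs <= n_compounds * n_proteins,
            nchar(motif) >= 1L, protein_length > nchar(motif))
  structure(list(n_compounds = as.integer(n_compounds),
                 n_proteins = as.integer(n_proteins),
                 n_pairs = as.integer(n_pairs),
                 protein_length = as.integer(protein_length),
                 motif = motif, label_noise = label_noise,
                 frag_prob = frag_prob, motif_prob = motif_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Ring fragments as templates: `term` closes the chain, `bridge` continues
# it through the ring (the %s branch carries the rest of the molecule, %d is
# the ring-closure digit). The positive fragment is the pyrimidine ring.
.ring_library <- list(
  benzene = list(term = "c%dccccc%d", bridge = "c%dccc(%s)cc%d"),
  pyridine = list(term = "c%dccncc%d", bridge = "c%dccnc(%s)c%d"),
  furan = list(term = "c%dccoc%d", bridge = "c%dcc(%s)oc%d"),
  pyrimidine = list(term = "c%dcncnc%d", bridge = "c%dcnc(%s)nc%d"))

.linker_library <- c("C", "CC", "CCC", "CNC", "CCO", "CC(=O)C")

# Assemble one SMILES from ring names and linkers, innermost ring first.
.assemble_smiles <- function(rings, linkers) {
  n <- length(rings)
  cur <- sprintf(.ring_library[[rings[n]]]$term, n, n)
  if (n > 1L) {
    for (i in rev(seq_len(n - 1L))) {
      branch <- paste0(linkers[i + 1L], cur)
      cur <- sprintf(.ring_library[[rings[i]]]$bridge, i, branch, i)
    }
  }
  paste0(linkers[1L], cur)
}

#' Generate a synthetic planted-rule CPI dataset
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `smiles`, `sequence`, `label`. The
#'   ground-truth indicators are attached as attributes `has_fragment` and
#'   `has_motif` (per record) and `flipped` (which labels were noise-flipped).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  residues <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  neg_rings <- setdiff(names(.ring_library), "pyrimidine")

  n_pos_c <- max(1L, round(spec$frag_prob * spec$n_compounds))
  has_frag <- seq_len(spec$n_compounds) <= n_pos_c
  compounds <- vapply(seq_len(spec$n_compounds), function(i) {
    n_rings <- sample(2:3, 1L)
    rings <- sample(neg_rings, n_rings, replace = TRUE)
    if (has_frag[i]) rings[sample.int(n_rings, 1L)] <- "pyrimidine"
    linkers <- sample(.linker_library, n_rings, replace = TRUE)
    .assemble_smiles(rings, linkers)
  }, "")

  n_pos_p <- max(1L, round(spec$motif_prob * spec$n_proteins))
  has_motif <- seq_len(spec$n_proteins) <= n_pos_p
  motif_len <- nchar(spec$motif)
  proteins <- vapply(seq_len(spec$n_proteins), function(i) {
    s <- paste(sample(residues, spec$protein_length, replace = TRUE),
               collapse = "")
    if (has_motif[i]) {
      at <- sample.int(spec$protein_length - motif_len + 1L, 1L)
      substr(s, at, at + motif_len - 1L) <- spec$motif
    }
    s
  }, "")
  # motifs can arise by chance in "negative" proteins; record the truth
  has_motif <- grepl(spec$motif, proteins, fixed = TRUE)

  if (!any(has_frag) || !any(has_motif)) {
    stop("infeasible specification: no positive pair is possible")
  }
  pair_idx <- sample.int(spec$n_compounds * spec$n_proteins, spec$n_pairs)
  ci <- (pair_idx - 1L) %% spec$n_compounds + 1L
  pi_ <- (pair_idx - 1L) %/% spec$n_compounds + 1L
  label <- as.integer(has_frag[ci] & has_motif[pi_])
  flipped <- stats::runif(spec$n_pairs) < spec$label_noise
  label[flipped] <- 1L - label[flipped]

  out <- data.frame(smiles = compounds[ci], sequence = proteins[pi_],
                    label = label, stringsAsFactors = FALSE)
  attr(out, "has_fragment") <- has_frag[ci]
  attr(out, "has_motif") <- has_motif[pi_]
  attr(out, "flipped") <- flipped
  out
}
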