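#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string to a heavy-atom molecular graph using OpenBabel
#' (via \pkg{ChemmineOB}). Implicit hydrogens are excluded. Aromatic bonds are
#' flagged according to OpenBabel's aromaticity perception, read from the MOL2
#' bond block (`ar` bond type).
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `molecular_graph`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with columns `index` (1-based) and `element`.}
#'     \item{bonds}{data.frame with columns `i`, `j` (atom indices, `i < j`)
#'       and `aromatic` (logical). Each bond is stored once.}
#'     \item{smiles}{the input string.}
#'     \item{aromaticity_model}{the perception model used (`"openbabel"`).}
#'   }
#' @examples
#' g <- parse_smiles("Cc1ccccc1")
#' nrow(g$atoms)            # 7 heavy atoms
#' sum(g$bonds$aromatic)    # 6 aromatic ring bonds
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string")
  }
  mol2 <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", smiles))
  if (!nzchar(trimws(mol2))) {
    stop(sprintf("unparsable SMILES string: '%s'", smiles))
  }
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  atom_at <- which(lines == "@<TRIPOS>ATOM")
  bond_at <- which(lines == "@<TRIPOS>BOND")
  if (length(atom_at) != 1L) {
    stop(sprintf("unparsable SMILES string: '%s'", smiles))
  }
  section_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt)) min(nxt) - 1L else length(lines)
  }
  atom_lines <- lines[seq(atom_at + 1L, section_end(atom_at))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  atom_fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
  # MOL2 atom type ("C.ar", "N.3", "Cl") carries the element before the dot
  element <- vapply(atom_fields, function(f) sub("\\..*$", "", f[6]), "")
  atoms <- data.frame(index = seq_along(element), element = element,
                      stringsAsFactors = FALSE)
  if (length(bond_at) == 1L && section_end(bond_at) > bond_at) {
    bond_lines <- lines[seq(bond_at + 1L, section_end(bond_at))]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  } else {
    bond_lines <- character(0)
  }
  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    i <- vapply(bf, function(f) as.integer(f[2]), 0L)
    j <- vapply(bf, function(f) as.integer(f[3]), 0L)
    aromatic <- vapply(bf, function(f) f[4] == "ar", TRUE)
    lo <- pmin(i, j); hi <- pmax(i, j)
    bonds <- data.frame(i = lo, j = hi, aromatic = aromatic)
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), aromatic = logical(0))
  }
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles,
                 aromaticity_model = "openbabel"),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s\n  %d atoms, %d bonds (%d aromatic)\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds), sum(x$bonds$aromatic)))
  invisible(x)
}

#' Partition bonds into aromatic and non-aromatic sets
#'
#' @param g A `molecular_graph`.
#' @return A list with data.frames `aromatic` and `non_aromatic`; the two sets
#'   are disjoint and together contain every bond of `g`.
#' @export
partition_bonds <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  list(aromatic = g$bonds[g$bonds$aromatic, , drop = FALSE],
       non_aromatic = g$bonds[!g$bonds$aromatic, , drop = FALSE])
}

# Connected components of one bond partition; each component becomes a
# substructure with fresh local atom indices. `aromatic` tags the side.
.components_of_side <- function(g, side_bonds, aromatic, id_start) {
  subs <- list()
  if (nrow(side_bonds) > 0L) {
    ig <- igraph::graph_from_edgelist(
      cbind(as.character(side_bonds$i), as.character(side_bonds$j)),
      directed = FALSE)
    comp <- igraph::components(ig)
    names_v <- igraph::V(ig)$name
    for (cid in seq_len(comp$no)) {
      orig <- sort(as.integer(names_v[comp$membership == cid]))
      local <- seq_along(orig)
      keep <- side_bonds$i %in% orig & side_bonds$j %in% orig
      b <- side_bonds[keep, , drop = FALSE]
      subs[[length(subs) + 1L]] <- structure(list(
        id = id_start + length(subs),
        aromatic = aromatic,
        atoms = data.frame(local = local,
                           element = g$atoms$element[orig],
                           orig = orig,
                           stringsAsFactors = FALSE),
        bonds = data.frame(i = match(b$i, orig), j = match(b$j, orig),
                           aromatic = b$aromatic)),
        class = "substructure")
    }
  }
  subs
}

#' Detect substructures by connected components within each bond partition
#'
#' Connected components are computed independently within the aromatic-bond
#' subgraph and the non-aromatic-bond subgraph. An atom incident to bonds of
#' both kinds is copied into one substructure per kind; an atom with no bonds
#' at all forms its own single-atom non-aromatic substructure.
#'
#' @param g A `molecular_graph`.
#' @param partition Output of [partition_bonds()] on `g`.
#' @return A list of `substructure` objects. Each carries `id`, `aromatic`,
#'   `atoms` (columns `local`, `element`, `orig` mapping back to `g`) and
#'   `bonds` over local indices.
#' @export
find_substructures <- function(g, partition = partition_bonds(g)) {
  stopifnot(inherits(g, "molecular_graph"))
  subs <- .components_of_side(g, partition$aromatic, TRUE, 1L)
  subs <- c(subs, .components_of_side(g, partition$non_aromatic, FALSE,
                                      length(subs) + 1L))
  bonded <- unique(c(g$bonds$i, g$bonds$j))
  lone <- setdiff(g$atoms$index, bonded)
  for (a in lone) {
    subs[[length(subs) + 1L]] <- structure(list(
      id = length(subs) + 1L,
      aromatic = FALSE,
      atoms = data.frame(local = 1L, element = g$atoms$element[a], orig = a,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = integer(0), j = integer(0),
                         aromatic = logical(0))),
      class = "substructure")
  }
  subs
}

#' Link substructures that share an original atom with virtual edges
#'
#' One unweighted virtual edge is added per pair of substructures sharing at
#' least one atom of the source molecule, regardless of how many atoms are
#' shared. No self-edges.
#'
#' @param subs List of `substructure` objects from [find_substructures()].
#' @param source The `molecular_graph` the substructures were derived from.
#' @return An object of class `hierarchical_graph` with fields
#'   `substructures`, `virtual_edges` (two-column integer matrix of
#'   substructure id pairs, `i < j`) and `source`.
#' @export
add_virtual_edges <- function(subs, source) {
  stopifnot(inherits(source, "molecular_graph"))
  n <- length(subs)
  edges <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (n >= 2L) {
    origs <- lapply(subs, function(s) s$atoms$orig)
    for (a in seq_len(n - 1L)) {
      for (b in seq(a + 1L, n)) {
        if (length(intersect(origs[[a]], origs[[b]])) > 0L) {
          edges <- rbind(edges, c(subs[[a]]$id, subs[[b]]$id))
        }
      }
    }
  }
  structure(list(substructures = subs, virtual_edges = edges, source = source),
            class = "hierarchical_graph")
}

#' Decompose a SMILES string into its hierarchical (reduced) graph
#'
#' Composition of [parse_smiles()], [partition_bonds()],
#' [find_substructures()] and [add_virtual_edges()]: the molecule is split
#' into aromatic and non-aromatic bond sets, connected components of each set
#' become substructure nodes, and virtual edges link substructures sharing an
#' atom. A molecule whose bonds are all of one kind reduces to a single node.
#'
#' @param smiles A SMILES string.
#' @return A `hierarchical_graph`.
#' @examples
#' h <- decompose("c1ccccc1-c1ccccc1")   # biphenyl
#' length(h$substructures)               # 3: two rings + the linker
#' nrow(h$virtual_edges)                 # 2
#' @export
decompose <- function(smiles) {
  g <- parse_smiles(smiles)
  add_virtual_edges(find_substructures(g, partition_bonds(g)), g)
}

#' @export
print.hierarchical_graph <- function(x, ...) {
  n_arom <- sum(vapply(x$substructures, `[[`, TRUE, "aromatic"))
  cat(sprintf(paste0("<hierarchical_graph> %s\n  %d substructures",
                     " (%d aromatic), %d virtual edges\n"),
              x$source$smiles, length(x$substructures), n_arom,
              nrow(x$virtual_edges)))
  invisible(x)
}

#' Treat a whole molecule as a single substructure (no splitting)
#'
#' Builds the degenerate hierarchical graph used by the `nosplit` ablation:
#' one substructure holding every atom and every bond, and no virtual edges.
#'
#' @param g A `molecular_graph`.
#' @return A `hierarchical_graph` with a single substructure node.
#' @export
as_single_substructure <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  sub <- structure(list(
    id = 1L,
    aromatic = all(g$bonds$aromatic) && nrow(g$bonds) > 0L,
    atoms = data.frame(local = g$atoms$index, element = g$atoms$element,
                       orig = g$atoms$index, stringsAsFactors = FALSE),
    bonds = g$bonds[, c("i", "j", "aromatic")]),
    class = "substructure")
  structure(list(substructures = list(sub),
                 virtual_edges = matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("i", "j"))),
                 source = g),
            class = "hierarchical_graph")
}

#' Build an element vocabulary from training compounds
#'
#' @param smiles_list Character vector of SMILES strings (typically the
#'   training compounds).
#' @return Character vector of sorted element symbols followed by the reserved
#'   `"<unk>"` slot for elements unseen at training time.
#' @export
atom_vocabulary <- function(smiles_list) {
  elements <- unique(unlist(lapply(unique(smiles_list), function(s) {
    parse_smiles(s)$atoms$element
  })))
  c(sort(elements), "<unk>")
}

#' One-hot featurize the atom copies of a hierarchical graph
#'
#' Produces one feature row per atom copy; an atom duplicated into several
#' substructures receives identical rows in each. Elements outside the
#' vocabulary map to the reserved unknown slot.
#'
#' @param h A `hierarchical_graph`.
#' @param vocab Element vocabulary from [atom_vocabulary()] (last entry is the
#'   unknown slot).
#' @return A list with one matrix per substructure (`n_atoms x length(vocab)`
#'   one-hot rows) and attribute `label_ids` (list of per-substructure integer
#'   label vectors).
#' @export
featurize_atoms <- function(h, vocab) {
  stopifnot(inherits(h, "hierarchical_graph"))
  unk <- length(vocab)
  ids <- lapply(h$substructures, function(s) {
    m <- match(s$atoms$element, vocab)
    m[is.na(m)] <- unk
    m
  })
  mats <- lapply(ids, function(v) {
    m <- matrix(0, nrow = length(v), ncol = length(vocab))
    m[cbind(seq_along(v), v)] <- 1
    m
  })
  attr(mats, "label_ids") <- ids
  mats
}

#' Serialize a hierarchical graph to JSON
#'
#' @param h A `hierarchical_graph`.
#' @return A JSON string with fields `smiles`, `aromaticity_model`, `atoms`,
#'   `bonds`, `substructures` (id, aromatic, atom_indices into the source
#'   molecule, bonds over local indices) and `virtual_edges`.
#' @export
hierarchical_graph_json <- function(h) {
  stopifnot(inherits(h, "hierarchical_graph"))
  obj <- list(
    smiles = h$source$smiles,
    aromaticity_model = h$source$aromaticity_model,
    atoms = h$source$atoms,
    bonds = h$source$bonds,
    substructures = lapply(h$substructures, function(s) {
      list(id = s$id, aromatic = s$aromatic,
           atom_indices = s$atoms$orig, bonds = s$bonds)
    }),
    virtual_edges = if (nrow(h$virtual_edges)) {
      unname(apply(h$virtual_edges, 1, function(r) as.list(r)))
    } else {
      list()
    })
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}
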