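#' Element code table for neighbor labels
#'
#' The 31 element symbols assigned numeric classes 1--31 in alphabetical
#' order (Ag=1 ... Zn=31; C=7, H=11, N=17, O=19), plus the catch-all
#' class 32 used after consolidation for every element other than C, N
#' and O. Code 0 marks an empty slot.
#'
#' @return Named integer vector mapping symbol to code.
#' @export
element_table <- function() {
  syms <- c("Ag", "Al", "As", "B", "Bi", "Br", "C", "Cl", "F", "Ge",
            "H", "Hg", "I", "K", "Li", "Mg", "N", "Na", "O", "P",
            "Pb", "Pd", "S", "Sb", "Se", "Si", "Sn", "Te", "Ti", "Tl",
            "Zn")
  stats::setNames(seq_along(syms), syms)
}

.element_code <- function(symbol) {
  tab <- element_table()
  code <- unname(tab[symbol])
  if (any(is.na(code))) {
    warning("element(s) outside the 31-symbol table mapped to class 32: ",
            paste(unique(symbol[is.na(code)]), collapse = ", "),
            call. = FALSE)
    code[is.na(code)] <- 32L
  }
  as.integer(code)
}

.new_label <- function(atoms = integer(4), bonds = integer(4)) {
  structure(as.integer(c(atoms, bonds)), class = "neighbor_label")
}

#' @export
print.neighbor_label <- function(x, ...) {
  cat("<neighbor_label> ", format_label(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.neighbor_label <- function(x, ...) format_label(x)

#' Print a neighbor label in 8-integer notation
#'
#' @param label a `neighbor_label` (or plain length-8 integer vector:
#'   four atom codes followed by four aligned bond orders).
#' @return Character scalar like `"7, 17, 0, 0, 1, 2, 0, 0"`.
#' @export
format_label <- function(label) paste(as.integer(label), collapse = ", ")

#' Parse the 8-integer label notation
#'
#' @param x character scalar of 8 comma-separated integers.
#' @return A `neighbor_label`.
#' @export
parse_label <- function(x) {
  v <- as.integer(strsplit(trimws(x), "\\s*,\\s*")[[1]])
  if (length(v) != 8L || any(is.na(v))) stop("expected 8 integers: ", x)
  .new_label(v[1:4], v[5:8])
}

label_atoms <- function(label) as.integer(label)[1:4]
label_bonds <- function(label) as.integer(label)[5:8]

#' Raw neighbor label of a carbon atom
#'
#' Records each explicit neighbor of the atom as an (element code, bond
#' order) slot pair; slots for fewer than four neighbors stay 0. Implicit
#' hydrogens (completed from standard valence) occupy no slot, matching
#' how connection tables usually omit them; explicit hydrogens appear
#' with code 11 until [zero_hydrogens()] removes them.
#'
#' @param graph a kekulized [mol_graph()] (all bond orders 1--3).
#' @param atom index of a carbon atom.
#' @return A pre-canonical `neighbor_label`.
#' @export
raw_label <- function(graph, atom) {
  if (graph$atoms$element[atom] != "C")
    stop("atom ", atom, " of '", graph$molecule_id, "' is not carbon")
  nb <- graph_neighbors(graph, atom)
  if (nrow(nb) > 4L)
    stop("carbon ", atom, " of '", graph$molecule_id,
         "' has degree > 4; record rejected")
  atoms <- integer(4); bonds <- integer(4)
  if (nrow(nb)) {
    atoms[seq_len(nrow(nb))] <- .element_code(nb$element)
    bonds[seq_len(nrow(nb))] <- nb$order
  }
  .new_label(atoms, bonds)
}

#' Zero out hydrogen slots
#'
#' Resets every slot holding hydrogen (code 11) to (0, 0), so the four
#' bond-order labels may sum to less than 4; the shortfall is the number
#' of attached hydrogens.
#'
#' @param label a `neighbor_label`.
#' @return The label with hydrogen slots cleared.
#' @export
zero_hydrogens <- function(label) {
  a <- label_atoms(label); b <- label_bonds(label)
  h <- a == 11L
  a[h] <- 0L; b[h] <- 0L
  .new_label(a, b)
}

#' Canonicalize a neighbor label
#'
#' Sorts the occupied slot pairs by ascending bond order, breaking ties
#' by ascending atom code; empty slots trail all occupied slots.
#' Idempotent, and invariant under any permutation of the input slots.
#'
#' @param label an H-zeroed `neighbor_label`.
#' @return The canonical label.
#' @examples
#' canonicalize_label(parse_label("7, 7, 19, 17, 1, 1, 1, 1"))
#' @export
canonicalize_label <- function(label) {
  a <- label_atoms(label); b <- label_bonds(label)
  occ <- a != 0L
  ord <- order(b[occ], a[occ])
  .new_label(c(a[occ][ord], rep(0L, sum(!occ))),
             c(b[occ][ord], rep(0L, sum(!occ))))
}

#' Consolidate rare elements into class 32
#'
#' Replaces every nonzero atom code other than carbon (7), nitrogen (17)
#' and oxygen (19) with the shared class 32, then re-canonicalizes. This
#' shortening collapses chemically rare neighbor types into one class.
#'
#' @param label a canonical `neighbor_label`.
#' @return The consolidated canonical label.
#' @export
consolidate_label <- function(label) {
  a <- label_atoms(label)
  keep <- a %in% c(0L, 7L, 17L, 19L)
  a[!keep] <- 32L
  canonicalize_label(.new_label(a, label_bonds(label)))
}

#' Full neighbor-label pipeline for one carbon
#'
#' `raw_label()` then [zero_hydrogens()], [canonicalize_label()] and
#' (optionally) [consolidate_label()]. The result is a pure function of
#' the atom's one-bond environment.
#'
#' @inheritParams raw_label
#' @param consolidate collapse rare elements into class 32 (default TRUE).
#' @return A canonical `neighbor_label`.
#' @export
neighbor_label <- function(graph, atom, consolidate = TRUE) {
  lab <- canonicalize_label(zero_hydrogens(raw_label(graph, atom)))
  if (consolidate) lab <- consolidate_label(lab)
  lab
}

#' Neighbor labels for every carbon in a graph
#'
#' @inheritParams neighbor_label
#' @return Named list of `neighbor_label`s, one per carbon atom, named by
#'   atom index.
#' @export
carbon_labels <- function(graph, consolidate = TRUE) {
  idx <- graph$atoms$index[graph$atoms$element == "C"]
  stats::setNames(lapply(idx, neighbor_label, graph = graph,
                         consolidate = consolidate),
                  as.character(idx))
}

#' Substructure label of a hydrogen atom
#'
#' A hydrogen inherits the neighbor label of the single carbon it is
#' bonded to, so 1H signals are classified by the attached carbon's
#' environment. Hydrogens bonded to anything other than exactly one
#' carbon (hydroxyl, amine, unbonded) are rejected.
#'
#' @param graph a kekulized [mol_graph()].
#' @param h_atom index of a hydrogen atom.
#' @inheritParams neighbor_label
#' @return A canonical `neighbor_label`.
#' @export
hydrogen_substructure <- function(graph, h_atom, consolidate = TRUE) {
  if (graph$atoms$element[h_atom] != "H")
    stop("atom ", h_atom, " is not hydrogen")
  nb <- graph_neighbors(graph, h_atom)
  if (nrow(nb) != 1L || nb$element != "C")
    stop("hydrogen ", h_atom, " of '", graph$molecule_id,
         "' is not bonded to exactly one carbon; record rejected")
  neighbor_label(graph, nb$index, consolidate = consolidate)
}

#' Build a substructure class vocabulary
#'
#' Consolidates the distinct labels of a corpus into classes 0..m-1,
#' assigned in lexicographic order of the 8-integer codes so the mapping
#' is deterministic for a given corpus.
#'
#' @param labels list of `neighbor_label`s (typically from the training
#'   split only).
#' @return An object of class `substructure_vocabulary`: data frame with
#'   columns `label` (8-integer notation) and `class` (0-based index),
#'   plus attribute `m`.
#' @export
build_vocabulary <- function(labels) {
  if (!length(labels)) stop("empty label corpus")
  keys <- vapply(labels, format_label, character(1))
  mat <- do.call(rbind, lapply(unique(keys), function(k)
    as.integer(parse_label(k))))
  ord <- do.call(order, as.data.frame(mat))
  uniq <- unique(keys)[ord]
  structure(data.frame(label = uniq, class = seq_along(uniq) - 1L,
                       stringsAsFactors = FALSE),
            m = length(uniq), class = c("substructure_vocabulary",
                                        "data.frame"))
}

#' Map labels to vocabulary classes
#'
#' Labels absent from the vocabulary (unseen at training time) map to the
#' reserved unknown class `m`, which evaluation excludes from accuracy
#' numerators.
#'
#' @param labels list of `neighbor_label`s.
#' @param vocabulary a [build_vocabulary()] result.
#' @return Integer vector of 0-based class indices (`m` = unknown).
#' @export
labels_to_classes <- function(labels, vocabulary) {
  keys <- vapply(labels, format_label, character(1))
  cls <- vocabulary$class[match(keys, vocabulary$label)]
  cls[is.na(cls)] <- attr(vocabulary, "m")
  as.integer(cls)
}

#' Write/read a vocabulary as a plain-text table
#'
#' @param vocabulary a `substructure_vocabulary`.
#' @param file path.
#' @return `file` invisibly, or the re-read vocabulary.
#' @export
write_vocabulary <- function(vocabulary, file) {
  utils::write.table(vocabulary, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, m = nrow(df),
            class = c("substructure_vocabulary", "data.frame"))
}
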