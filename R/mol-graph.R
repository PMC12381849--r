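#' Molecular graph
#'
#' A light container for the connection table of one molecule: atoms
#' (1-based contiguous indices plus element symbols) and bonds (atom pair
#' plus integer order). Bond order 4 denotes an aromatic bond as in molfile
#' V2000; [kekulize_graph()] rewrites such bonds to alternating single and
#' double bonds so that every order lies in 1--3, which the neighbor
#' encoder requires.
#'
#' @param molecule_id character scalar identifying the molecule.
#' @param elements character vector of element symbols, one per atom; atom
#'   `k` has index `k`.
#' @param bonds data frame (or matrix) with columns `i`, `j`, `order`.
#' @return An object of class `mol_graph`: a list with `molecule_id`,
#'   `atoms` (data frame `index`, `element`) and `bonds` (data frame `i`,
#'   `j`, `order`).
#' @examples
#' g <- mol_graph("ethanol", c("C", "C", "O"),
#'                data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
#' implicit_h_count(g)
#' @export
mol_graph <- function(molecule_id, elements, bonds = NULL) {
  stopifnot(is.character(molecule_id), length(molecule_id) == 1L)
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecular graph needs at least one atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
  }
  if (nrow(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references an atom index outside 1..", n,
           " in molecule '", molecule_id, "'")
    if (any(bonds$i == bonds$j))
      stop("self-bond in molecule '", molecule_id, "'")
    if (any(!bonds$order %in% c(1L, 2L, 3L, 4L)))
      stop("unsupported bond order in molecule '", molecule_id,
           "' (expected 1-4)")
  }
  structure(list(molecule_id = molecule_id,
                 atoms = data.frame(index = seq_len(n), element = elements,
                                    stringsAsFactors = FALSE),
                 bonds = bonds),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$molecule_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  comp <- table(x$atoms$element)
  cat("  composition:",
      paste0(names(comp), comp, collapse = " "), "\n")
  invisible(x)
}

# standard valences used to complete implicit hydrogens; elements absent
# from this table get no implicit H
.std_valence <- c(C = 4L, N = 3L, O = 2L, H = 1L, S = 2L, P = 3L,
                  F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L)

#' Explicit neighbors of one atom
#'
#' @param graph a [mol_graph()].
#' @param atom atom index.
#' @return data frame with one row per explicit neighbor: `index`,
#'   `element`, `order`.
#' @export
graph_neighbors <- function(graph, atom) {
  b <- graph$bonds
  hit_i <- b$i == atom
  hit_j <- b$j == atom
  idx <- c(b$j[hit_i], b$i[hit_j])
  data.frame(index = idx,
             element = graph$atoms$element[idx],
             order = c(b$order[hit_i], b$order[hit_j]),
             stringsAsFactors = FALSE)
}

#' Implicit hydrogen counts
#'
#' Completes the hydrogen count of each heavy atom from its standard
#' valence minus the sum of explicit bond orders. Aromatic bonds (order 4)
#' must be kekulized first. Explicit hydrogens are counted as ordinary
#' single-bond neighbors, so an atom with fully explicit H gets 0.
#'
#' @param graph a [mol_graph()] with all bond orders in 1--3.
#' @param atoms atom indices; defaults to every atom.
#' @return Integer vector of implicit H counts (never negative).
#' @export
implicit_h_count <- function(graph, atoms = graph$atoms$index) {
  if (nrow(graph$bonds) && any(graph$bonds$order == 4L))
    stop("kekulize the graph before computing implicit hydrogens")
  vapply(atoms, function(a) {
    el <- graph$atoms$element[a]
    val <- .std_valence[el]
    if (is.na(val)) return(0L)
    used <- sum(graph_neighbors(graph, a)$order)
    max(0L, as.integer(val) - as.integer(used))
  }, integer(1))
}

#' Total attached hydrogens (explicit + implicit)
#'
#' @inheritParams implicit_h_count
#' @return Integer vector.
#' @export
attached_h_count <- function(graph, atoms = graph$atoms$index) {
  vapply(atoms, function(a) {
    nb <- graph_neighbors(graph, a)
    sum(nb$element == "H") + implicit_h_count(graph, a)
  }, integer(1))
}

#' Kekulize aromatic bonds
#'
#' Rewrites molfile aromatic bonds (order 4) as alternating single/double
#' bonds by backtracking assignment: each aromatic carbon receives exactly
#' one double bond among its aromatic bonds (zero if it already carries an
#' exocyclic double or triple bond), trivalent aromatic nitrogen
#' (pyrrole-type) receives zero, divalent aromatic nitrogen
#' (pyridine-type) one, and aromatic O/S/Se receive zero. Graphs without
#' order-4 bonds are returned unchanged.
#'
#' @param graph a [mol_graph()].
#' @return A `mol_graph` whose bond orders all lie in 1--3.
#' @export
kekulize_graph <- function(graph) {
  b <- graph$bonds
  arom <- which(b$order == 4L)
  if (!length(arom)) return(graph)

  atoms_in <- sort(unique(c(b$i[arom], b$j[arom])))
  # target number of double bonds each aromatic atom must receive
  target <- vapply(atoms_in, function(a) {
    el <- graph$atoms$element[a]
    nb_orders <- graph_neighbors(graph, a)$order
    deg <- length(nb_orders)
    if (any(nb_orders %in% c(2L, 3L))) return(0L)  # exocyclic multiple bond
    if (el == "C") return(1L)
    if (el == "N") return(if (deg >= 3L) 0L else 1L)
    if (el %in% c("O", "S", "Se", "P")) return(0L)
    0L
  }, integer(1))
  names(target) <- atoms_in

  assign <- rep(NA_integer_, length(arom))  # 1 or 2 for each aromatic bond
  n_left <- vapply(atoms_in, function(a)
    sum(b$i[arom] == a | b$j[arom] == a), integer(1))
  names(n_left) <- atoms_in
  need <- target

  solve <- function(k) {
    if (k > length(arom)) return(all(need == 0L))
    e <- arom[k]
    ai <- as.character(b$i[e]); aj <- as.character(b$j[e])
    for (ord in c(2L, 1L)) {
      d <- if (ord == 2L) 1L else 0L
      if (need[ai] - d < 0L || need[aj] - d < 0L) next
      need[ai] <<- need[ai] - d; need[aj] <<- need[aj] - d
      n_left[ai] <<- n_left[ai] - 1L; n_left[aj] <<- n_left[aj] - 1L
      ok <- need[ai] <= n_left[ai] && need[aj] <= n_left[aj]
      if (ok) {
        assign[k] <<- ord
        if (solve(k + 1L)) return(TRUE)
        assign[k] <<- NA_integer_
      }
      need[ai] <<- need[ai] + d; need[aj] <<- need[aj] + d
      n_left[ai] <<- n_left[ai] + 1L; n_left[aj] <<- n_left[aj] + 1L
    }
    FALSE
  }
  if (!solve(1L))
    stop("could not kekulize molecule '", graph$molecule_id, "'")
  b$order[arom] <- assign
  graph$bonds <- b
  graph
}
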