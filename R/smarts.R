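#' Ordered SMARTS functional-group list
#'
#' Holds an ordered sequence of SMARTS patterns; order is significant
#' because atom classification takes the first matching entry. The
#' packaged defaults ship the published post-optimization orders for
#' 13C and 1H data; [load_smarts_list()] reads the same plain-text
#' format (one SMARTS per line, optional name after a tab).
#'
#' @param smarts character vector of SMARTS strings.
#' @param names optional group names (`NA` for unnamed entries).
#' @param nucleus `"13C"` or `"1H"`.
#' @param validate check every pattern parses (needs the RDKit backend).
#' @return An object of class `smarts_list`: data frame with columns
#'   `smarts`, `name`, plus attribute `nucleus`.
#' @export
smarts_list <- function(smarts, names = NULL, nucleus = "13C",
                        validate = FALSE) {
  stopifnot(nucleus %in% c("13C", "1H"))
  if (is.null(names)) names <- rep(NA_character_, length(smarts))
  obj <- structure(data.frame(smarts = as.character(smarts),
                              name = as.character(names),
                              stringsAsFactors = FALSE),
                   nucleus = nucleus,
                   class = c("smarts_list", "data.frame"))
  if (validate) {
    ok <- unlist(.smarts_backend(sdf_file = NULL, smarts = obj$smarts,
                                 validate_only = TRUE)$valid)
    if (!all(ok))
      stop("invalid SMARTS pattern(s): ",
           paste(obj$smarts[!ok], collapse = ", "))
  }
  obj
}

#' @rdname smarts_list
#' @param file path to a SMARTS table (one pattern per line, optional
#'   tab-separated name).
#' @export
load_smarts_list <- function(file, nucleus = "13C", validate = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smarts_list(vapply(parts, `[`, character(1), 1),
              vapply(parts, function(p)
                if (length(p) > 1L) p[2] else NA_character_, character(1)),
              nucleus = nucleus, validate = validate)
}

#' @rdname smarts_list
#' @export
default_smarts <- function(nucleus = c("13C", "1H"), validate = FALSE) {
  nucleus <- match.arg(nucleus)
  f <- system.file("extdata",
                   if (nucleus == "13C") "smarts_13c.tsv"
                   else "smarts_1h.tsv",
                   package = "nmrsubstr")
  load_smarts_list(f, nucleus = nucleus, validate = validate)
}

# ---- RDKit subprocess backend ----------------------------------------

.python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter on PATH; SMARTS matching needs the RDKit ",
       "backend")
}

.smarts_backend <- function(sdf_file, smarts, validate_only = FALSE) {
  script <- system.file("python", "smarts_match.py",
                        package = "nmrsubstr")
  jin <- tempfile(fileext = ".json")
  jout <- tempfile(fileext = ".json")
  on.exit(unlink(c(jin, jout)), add = TRUE)
  jsonlite::write_json(list(smarts = smarts,
                            validate_only = validate_only),
                       jin, auto_unbox = TRUE)
  if (is.null(sdf_file)) sdf_file <- tempfile(fileext = ".sdf")
  if (!file.exists(sdf_file)) writeLines(character(), sdf_file)
  status <- system2(.python_bin(), c(script, sdf_file, jin, jout),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(jout))
    stop("SMARTS backend failed (exit status ", status, ")")
  jsonlite::read_json(jout, simplifyVector = FALSE)
}

#' Atom-level SMARTS matches for a set of molecules
#'
#' Runs every pattern of a [smarts_list()] against every molecule and
#' returns, per molecule, the set of 1-based atom indices each pattern
#' covers. Aromaticity is perceived by the matching toolkit on its own
#' copy of the molecule, so kekulized and aromatic connection tables
#' give the same matches.
#'
#' @param graphs list of [mol_graph()] objects (or an `nmr_record_set`,
#'   whose graphs are used).
#' @param patterns a `smarts_list`.
#' @return List (one element per molecule) of lists (one per pattern) of
#'   integer atom-index vectors; `NULL` for molecules the backend could
#'   not sanitize.
#' @export
match_smarts_atoms <- function(graphs, patterns) {
  if (inherits(graphs, "nmr_record_set"))
    graphs <- lapply(graphs, `[[`, "graph")
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  dummy <- lapply(graphs, function(g)
    list(graph = g,
         spectrum = spectrum_record(g$molecule_id, "13C",
                                    data.frame(atom_index = 1L,
                                               shift = 0))))
  write_nmr_sdf(dummy, tf)
  res <- .smarts_backend(tf, patterns$smarts)
  lapply(res$matches, function(mm) {
    if (is.null(mm)) return(NULL)
    lapply(mm, function(v) as.integer(unlist(v)))
  })
}

#' First-match functional-group assignment
#'
#' Classifies atoms by the first entry of the ordered SMARTS list whose
#' match covers the atom; an atom matching no pattern falls into the
#' catch-all "unclassified" class (one past the last list position). In
#' 1H mode each queried hydrogen is classified through the carbon it is
#' bonded to, whose assigned group becomes the hydrogen's substructure.
#'
#' @param graph a [mol_graph()].
#' @param atoms atom indices to classify; defaults to all carbons (13C
#'   lists) or all hydrogens bonded to one carbon (1H lists).
#' @param patterns a `smarts_list`.
#' @param matches precomputed [match_smarts_atoms()] entry for this
#'   molecule (avoids re-running the backend in loops).
#' @return Integer vector of 1-based class indices in
#'   `1..(nrow(patterns) + 1)`, named by atom index; the fallback class
#'   is `nrow(patterns) + 1`.
#' @export
assign_group <- function(graph, patterns, atoms = NULL, matches = NULL) {
  nucleus <- attr(patterns, "nucleus")
  if (is.null(atoms)) {
    atoms <- if (identical(nucleus, "1H")) {
      hs <- graph$atoms$index[graph$atoms$element == "H"]
      hs[vapply(hs, function(h) {
        nb <- graph_neighbors(graph, h)
        nrow(nb) == 1L && nb$element == "C"
      }, logical(1))]
    } else graph$atoms$index[graph$atoms$element == "C"]
  }
  if (is.null(matches))
    matches <- match_smarts_atoms(list(graph), patterns)[[1]]
  if (is.null(matches))
    stop("molecule '", graph$molecule_id,
         "' could not be sanitized for SMARTS matching")
  fallback <- nrow(patterns) + 1L
  out <- vapply(atoms, function(a) {
    query <- a
    if (identical(nucleus, "1H")) {
      nb <- graph_neighbors(graph, a)
      if (nrow(nb) != 1L || nb$element != "C")
        stop("hydrogen ", a, " of '", graph$molecule_id,
             "' is not bonded to exactly one carbon")
      query <- nb$index
    }
    for (k in seq_along(matches))
      if (query %in% matches[[k]]) return(k)
    fallback
  }, integer(1))
  stats::setNames(out, atoms)
}

#' Baseline ordering of a SMARTS list
#'
#' The pre-optimization ordering rule: aromatic patterns precede
#' aliphatic ones; within each block patterns are sorted by descending
#' string length, ties alphabetically.
#'
#' @param patterns a `smarts_list`; an `aromatic` logical column is used
#'   when present, otherwise aromaticity is inferred from the pattern
#'   text (lowercase aromatic primitives, `a`, or `:` bonds).
#' @return The reordered `smarts_list`.
#' @export
baseline_order <- function(patterns) {
  arom <- if (!is.null(patterns$aromatic)) patterns$aromatic
  else grepl("\\[(?:[^]]*;)?[cnops]|(?<![A-Z])[cnops][0-9(]|:|\\[a",
             patterns$smarts, perl = TRUE)
  ord <- order(!arom, -nchar(patterns$smarts), patterns$smarts)
  structure(patterns[ord, , drop = FALSE], nucleus =
              attr(patterns, "nucleus"),
            class = class(patterns))
}

#' Randomized order optimization
#'
#' Scores the baseline order plus `n_perm` uniformly random permutations
#' of the list with a user-supplied validation-accuracy function and
#' returns the best-scoring order; ties keep the first encountered
#' candidate (so a constant score function returns the baseline). A
#' score-function failure skips that permutation with a warning.
#'
#' @param patterns a `smarts_list`.
#' @param score_fn function taking a `smarts_list` and returning a
#'   scalar score (e.g. validation accuracy of a model trained with that
#'   ordering).
#' @param n_perm number of random reorganizations (default 100).
#' @param seed RNG seed for the permutations.
#' @param all_permutations score every permutation exhaustively instead
#'   of sampling (small lists only).
#' @return The best-scoring `smarts_list`, with attributes `score` and
#'   `n_evaluated`.
#' @export
optimize_order <- function(patterns, score_fn, n_perm = 100L, seed = 1L,
                           all_permutations = FALSE) {
  stopifnot(is.function(score_fn), n_perm >= 1L)
  base <- baseline_order(patterns)
  n <- nrow(patterns)
  perms <- if (all_permutations) {
    .all_perms(n)
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) sample.int(n))
  }
  candidates <- c(list(seq_len(n)), perms)  # baseline first
  reorder1 <- function(ord, from) structure(
    from[ord, , drop = FALSE], nucleus = attr(patterns, "nucleus"),
    class = class(patterns))
  best <- NULL; best_score <- -Inf; n_eval <- 0L
  for (k in seq_along(candidates)) {
    cand <- if (k == 1L) base else reorder1(candidates[[k]], patterns)
    sc <- tryCatch(score_fn(cand), error = function(e) {
      warning("score_fn failed on candidate ", k, ": ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
    if (is.na(sc)) next
    n_eval <- n_eval + 1L
    if (sc > best_score) {
      best <- cand
      best_score <- sc
    }
  }
  if (is.null(best)) stop("score_fn failed on every candidate order")
  structure(best, score = best_score, n_evaluated = n_eval)
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}
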