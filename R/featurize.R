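#' Normalize an experimental condition to its maximum
#'
#' Min/max-style normalization `value / maximum` used for field strength
#' (MHz) and temperature (K); a missing value maps to 0, the sentinel for
#' unavailable conditions.
#'
#' @param value condition value, or `NA`.
#' @param maximum positive normalization maximum (e.g. the maximum over
#'   the training split).
#' @param record_id optional identifier used in error messages.
#' @return Value in `[0, 1]`.
#' @examples
#' normalize_condition(50, 700)   # 0.07143
#' normalize_condition(298, 323)  # 0.9226
#' @export
normalize_condition <- function(value, maximum, record_id = NULL) {
  stopifnot(is.numeric(maximum), maximum > 0)
  if (length(value) != 1L) return(vapply(value, normalize_condition,
                                         numeric(1), maximum = maximum))
  if (is.na(value)) return(0)
  if (value < 0) stop("negative condition value", if (!is.null(record_id))
    paste0(" in record '", record_id, "'"))
  if (value > maximum)
    stop("condition value ", value, " exceeds maximum ", maximum,
         if (!is.null(record_id)) paste0(" in record '", record_id, "'"))
  value / maximum
}

#' Encode a multiplicity symbol as an integer
#'
#' s/d/t/q mark 0/1/2/3 attached hydrogens and map to 1/2/3/4; an absent
#' symbol maps to the sentinel 0.
#'
#' @param symbol character vector over `{"s","d","t","q"}` or `NA`.
#' @return Integer vector in 0--4.
#' @export
encode_multiplicity <- function(symbol) {
  map <- c(s = 1L, d = 2L, t = 3L, q = 4L)
  out <- integer(length(symbol))
  present <- !is.na(symbol)
  if (any(present & !symbol %in% names(map)))
    stop("unknown multiplicity symbol: ",
         paste(unique(symbol[present & !symbol %in% names(map)]),
               collapse = ", "))
  out[present] <- map[symbol[present]]
  out
}

#' Ordered per-molecule shift sequence
#'
#' The variable-length model input: all shifts of a molecule ordered from
#' lowest to highest, with the multiplicity codes co-permuted so entry k
#' of both lists describes the same signal. Equal shifts are ordered by
#' (multiplicity code, atom index) so the output is deterministic for any
#' input ordering.
#'
#' @param record a [spectrum_record()] with at least one signal.
#' @return List with `shifts` (ascending numeric), `multiplicities`
#'   (integer codes), `atom_index` and `length`.
#' @export
build_molecule_sequence <- function(record) {
  sig <- record$signals
  if (!nrow(sig)) stop("record '", record$molecule_id, "' has no signals")
  mult <- encode_multiplicity(sig$multiplicity)
  ord <- order(sig$shift, mult, sig$atom_index)
  list(shifts = sig$shift[ord], multiplicities = mult[ord],
       atom_index = sig$atom_index[ord], length = nrow(sig))
}

#' Solvent vocabulary and encoding
#'
#' Solvent names are given integer codes by descending frequency in the
#' training data (ties alphabetical), starting at 1; missing or unknown
#' solvents code to 0. `encode_solvent()` optionally also returns the
#' equivalent one-hot vector (all-zero for code 0), which carries exactly
#' the same information.
#'
#' @param names character vector of training-split solvent names
#'   (`NA` entries ignored).
#' @return For `solvent_vocabulary()`: named integer vector code per name.
#' @export
solvent_vocabulary <- function(names) {
  names <- names[!is.na(names)]
  if (!length(names)) return(stats::setNames(integer(), character()))
  freq <- table(names)
  ord <- order(-as.integer(freq), names(freq))
  stats::setNames(seq_along(ord), names(freq)[ord])
}

#' @rdname solvent_vocabulary
#' @param name solvent name(s) to encode (`NA` allowed).
#' @param vocabulary result of `solvent_vocabulary()`.
#' @param onehot also return the one-hot matrix.
#' @return For `encode_solvent()`: integer code vector, or (with
#'   `onehot = TRUE`) a list with `code` and a `length(vocabulary)`-column
#'   binary matrix `onehot`.
#' @export
encode_solvent <- function(name, vocabulary, onehot = FALSE) {
  code <- unname(vocabulary[name])
  code[is.na(code)] <- 0L
  code <- as.integer(code)
  if (!onehot) return(code)
  oh <- matrix(0L, nrow = length(code), ncol = length(vocabulary),
               dimnames = list(NULL, names(vocabulary)))
  hit <- code > 0L
  oh[cbind(which(hit), code[hit])] <- 1L
  list(code = code, onehot = oh)
}

#' Zero-pad a molecule sequence
#'
#' @param seq result of [build_molecule_sequence()].
#' @param max_len fixed length to pad to.
#' @return List with numeric `shifts` and integer `multiplicities`, both
#'   of length `max_len` with trailing zeros, plus the original `length`.
#' @export
pad_sequence <- function(seq, max_len) {
  if (seq$length > max_len)
    stop("sequence of length ", seq$length, " exceeds max_len ", max_len)
  pad <- function(v, fill) c(v, rep(fill, max_len - length(v)))
  list(shifts = pad(seq$shifts, 0),
       multiplicities = pad(seq$multiplicities, 0L),
       length = seq$length)
}

#' Feature configuration learned from a training split
#'
#' Fixes everything featurization needs so that held-out data is encoded
#' exactly as the training data was: normalization maxima for field
#' strength and temperature (falling back to 700 MHz and 323 K when the
#' training split has none), the solvent vocabulary, the padded sequence
#' length (longest training molecule) and the solvent encoding mode.
#'
#' @param records training-split `nmr_record_set`.
#' @param solvent_onehot use one-hot instead of integer solvent codes.
#' @param field_max,temp_max,max_len optional overrides.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(records, solvent_onehot = FALSE,
                           field_max = NULL, temp_max = NULL,
                           max_len = NULL) {
  fs <- vapply(records, function(p) p$spectrum$field_strength, numeric(1))
  tp <- vapply(records, function(p) p$spectrum$temperature, numeric(1))
  sv <- vapply(records, function(p) p$spectrum$solvent, character(1))
  lens <- vapply(records, function(p) nrow(p$spectrum$signals), integer(1))
  structure(list(
    field_max = if (!is.null(field_max)) field_max
                else if (all(is.na(fs))) 700 else max(fs, na.rm = TRUE),
    temp_max = if (!is.null(temp_max)) temp_max
               else if (all(is.na(tp))) 323 else max(tp, na.rm = TRUE),
    solvents = solvent_vocabulary(sv),
    solvent_onehot = solvent_onehot,
    max_len = if (!is.null(max_len)) max_len else max(lens)),
    class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config> field_max", x$field_max, "MHz, temp_max",
      x$temp_max, "K, max_len", x$max_len, "\n")
  cat("  solvents:", if (length(x$solvents))
    paste0(names(x$solvents), "=", x$solvents, collapse = ", ")
    else "(none)", if (x$solvent_onehot) "[one-hot]" else "[integer]", "\n")
  invisible(x)
}

#' Build model inputs from records
#'
#' Produces one training row per signal: a fixed input (the signal's own
#' shift, multiplicity code and encoded conditions) and the shared
#' variable input (the molecule's ordered shift/multiplicity sequence,
#' zero-padded to `config$max_len` with a validity mask). 1H records get
#' a zeroed multiplicity channel since the database supplies
#' multiplicities for 13C only.
#'
#' @param records an `nmr_record_set`.
#' @param config a [feature_config()] (fit it on the training split).
#' @param ablate_conditions zero out field/temperature/solvent inputs
#'   (the "unspecified conditions" comparison).
#' @return An object of class `feature_bundle`: list with matrix `fixed`
#'   (n x p), arrays `seq_shifts` and `seq_mult` (n x max_len), matrix
#'   `mask`, integer `lengths`, `molecule` (record index per row),
#'   `atom_index`, and the `config`.
#' @export
featurize_records <- function(records, config,
                              ablate_conditions = FALSE) {
  rows_fixed <- list(); seq_s <- list(); seq_m <- list()
  lens <- integer(); mol <- integer(); atom <- integer()
  for (k in seq_along(records)) {
    r <- records[[k]]$spectrum
    ms <- build_molecule_sequence(r)
    padded <- pad_sequence(ms, config$max_len)
    fn <- normalize_condition(r$field_strength, config$field_max,
                              r$molecule_id)
    tn <- normalize_condition(r$temperature, config$temp_max,
                              r$molecule_id)
    sol <- encode_solvent(r$solvent, config$solvents,
                          onehot = config$solvent_onehot)
    if (ablate_conditions) {
      fn <- 0; tn <- 0
      sol <- if (config$solvent_onehot)
        list(code = 0L, onehot = matrix(0L, 1, length(config$solvents)))
      else 0L
    }
    mult <- encode_multiplicity(r$signals$multiplicity)
    if (r$nucleus == "1H") {
      mult[] <- 0L
      padded$multiplicities[] <- 0L
    }
    for (s in seq_len(nrow(r$signals))) {
      cond <- if (config$solvent_onehot)
        c(fn, tn, as.numeric(sol$onehot[1, ]))
      else c(fn, tn, as.numeric(sol[1]))
      rows_fixed[[length(rows_fixed) + 1L]] <-
        c(r$signals$shift[s], mult[s], cond)
      seq_s[[length(seq_s) + 1L]] <- padded$shifts
      seq_m[[length(seq_m) + 1L]] <- padded$multiplicities
      lens <- c(lens, ms$length)
      mol <- c(mol, k)
      atom <- c(atom, r$signals$atom_index[s])
    }
  }
  fixed <- do.call(rbind, rows_fixed)
  sol_names <- if (config$solvent_onehot)
    paste0("solvent_", names(config$solvents)) else "solvent_code"
  colnames(fixed) <- c("shift", "multiplicity", "field_norm", "temp_norm",
                       sol_names)
  mask <- do.call(rbind, lapply(lens, function(L)
    c(rep(1, L), rep(0, config$max_len - L))))
  structure(list(fixed = fixed,
                 seq_shifts = do.call(rbind, seq_s),
                 seq_mult = do.call(rbind, seq_m),
                 mask = mask, lengths = lens, molecule = mol,
                 atom_index = atom, config = config),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("<feature_bundle> ", nrow(x$fixed), " signals from ",
      length(unique(x$molecule)), " records; fixed dim ", ncol(x$fixed),
      ", sequence length ", x$config$max_len, "\n", sep = "")
  invisible(x)
}
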