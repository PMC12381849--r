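#' Spectrum record
#'
#' One NMR experiment for one molecule: per-atom signals plus optional
#' experimental-condition metadata. Signals carry the 1-based atom index
#' they are assigned to, the chemical shift in ppm, and (for 13C) an
#' optional multiplicity symbol s/d/t/q encoding the number of attached
#' hydrogens (0/1/2/3).
#'
#' @param molecule_id character scalar; must match the paired graph.
#' @param nucleus `"13C"` or `"1H"`.
#' @param signals data frame with columns `atom_index` (integer), `shift`
#'   (ppm), `multiplicity` (character, `NA` when absent).
#' @param field_strength spectrometer field in MHz, or `NA` when unknown.
#' @param temperature sample temperature in K, or `NA`.
#' @param solvent solvent name, or `NA`.
#' @param provenance `"experimental"` or `"computational"`.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(molecule_id, nucleus, signals,
                            field_strength = NA_real_,
                            temperature = NA_real_,
                            solvent = NA_character_,
                            provenance = "experimental") {
  stopifnot(nucleus %in% c("13C", "1H"),
            provenance %in% c("experimental", "computational"))
  signals <- as.data.frame(signals)
  if (!all(c("atom_index", "shift") %in% names(signals)))
    stop("signals need atom_index and shift columns")
  if (is.null(signals$multiplicity))
    signals$multiplicity <- rep(NA_character_, nrow(signals))
  signals$atom_index <- as.integer(signals$atom_index)
  signals$shift <- as.numeric(signals$shift)
  signals$multiplicity <- as.character(signals$multiplicity)
  if (any(!is.finite(signals$shift)))
    stop("non-finite chemical shift in record '", molecule_id, "'")
  bad <- !is.na(signals$multiplicity) &
    !signals$multiplicity %in% c("s", "d", "t", "q")
  if (any(bad))
    stop("unknown multiplicity symbol '",
         signals$multiplicity[bad][1], "' in record '", molecule_id, "'")
  structure(list(molecule_id = molecule_id, nucleus = nucleus,
                 signals = signals[, c("atom_index", "shift", "multiplicity")],
                 field_strength = as.numeric(field_strength),
                 temperature = as.numeric(temperature),
                 solvent = as.character(solvent),
                 provenance = provenance),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat("<spectrum_record> ", x$molecule_id, " [", x$nucleus, ", ",
      x$provenance, "]: ", nrow(x$signals), " signals\n", sep = "")
  cat("  field ", ifelse(is.na(x$field_strength), "?",
                         paste0(x$field_strength, " MHz")),
      ", temp ", ifelse(is.na(x$temperature), "?",
                        paste0(x$temperature, " K")),
      ", solvent ", ifelse(is.na(x$solvent), "?", x$solvent), "\n", sep = "")
  invisible(x)
}

.sdf_datablock_lines <- function(value) {
  # ChemmineR joins multi-line property values with " __ "
  strsplit(value, " __ ", fixed = TRUE)[[1]]
}

.parse_spectrum_lines <- function(lines) {
  parts <- strsplit(trimws(lines), "\\s+")
  atom_index <- integer(length(parts))
  shift <- numeric(length(parts))
  mult <- rep(NA_character_, length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 2L) stop("malformed spectrum line: ", lines[k])
    atom_index[k] <- as.integer(p[1])
    shift[k] <- as.numeric(p[2])
    if (length(p) >= 3L) mult[k] <- p[3]
  }
  data.frame(atom_index = atom_index, shift = shift, multiplicity = mult,
             stringsAsFactors = FALSE)
}

.record_from_sdf <- function(sdf, id, graph = NULL) {
  if (is.null(graph)) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (NROW(bb)) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    graph <- mol_graph(id, elements, bonds)
  }
  db <- ChemmineR::datablock(sdf)
  get1 <- function(tag) if (tag %in% names(db)) db[[tag]] else NA_character_
  spec_raw <- get1("SPECTRUM")
  if (is.na(spec_raw)) stop("record '", id, "' has no SPECTRUM field")
  signals <- .parse_spectrum_lines(.sdf_datablock_lines(spec_raw))
  nucleus <- get1("NUCLEUS")
  if (is.na(nucleus)) stop("record '", id, "' has no NUCLEUS field")
  num_or_na <- function(v) if (is.na(v)) NA_real_ else as.numeric(v)
  rec <- spectrum_record(
    molecule_id = id, nucleus = nucleus, signals = signals,
    field_strength = num_or_na(get1("FIELD_STRENGTH")),
    temperature = num_or_na(get1("TEMPERATURE")),
    solvent = get1("SOLVENT"),
    provenance = if ("Program" %in% names(db)) "computational"
                 else "experimental")
  n <- nrow(graph$atoms)
  if (any(rec$signals$atom_index < 1L | rec$signals$atom_index > n))
    stop("record '", id, "': signal atom index out of range")
  el <- graph$atoms$element[rec$signals$atom_index]
  want <- if (nucleus == "13C") "C" else "H"
  if (any(el != want))
    stop("record '", id, "': ", nucleus, " signal assigned to non-",
         want, " atom")
  list(graph = graph, spectrum = rec)
}

#' Parse nmrshiftdb2-style SDF records
#'
#' Reads an SDF (V2000) stream whose data blocks carry per-atom spectrum
#' entries and condition metadata under the tags `NUCLEUS`, `SPECTRUM`
#' (one `atom_index shift [multiplicity]` line per signal),
#' `FIELD_STRENGTH` (MHz), `TEMPERATURE` (K) and `SOLVENT`. A record with
#' a `Program` tag is flagged as computational, mirroring how nmrshiftdb2
#' marks calculated spectra. Malformed records are skipped with a warning,
#' never aborting the whole stream.
#'
#' @param file path to an SDF file, or `NULL` when `text` is given.
#' @param text character vector of SDF lines (alternative to `file`).
#' @return An object of class `nmr_record_set`: a list of
#'   `list(graph = mol_graph, spectrum = spectrum_record)` pairs with an
#'   attribute `n_skipped` counting dropped records.
#' @seealso [write_nmr_sdf()] for the inverse operation.
#' @export
parse_nmr_sdf <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either file or text must be given")
    if (!file.exists(file)) stop("cannot read '", file, "'")
    text <- readLines(file, warn = FALSE)
  }
  # split into molecule blocks on the $$$$ delimiter; the delimiter-level
  # structure is ours, the chemistry parsing is ChemmineR's
  ends <- grep("^\\$\\$\\$\\$", text)
  if (!length(ends) && length(trimws(text)) && any(nzchar(trimws(text))))
    ends <- length(text)
  starts <- c(1L, head(ends, -1L) + 1L)
  pairs <- list()
  n_skipped <- 0L
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  for (k in seq_along(ends)) {
    block <- text[starts[k]:ends[k]]
    if (!any(nzchar(trimws(block)))) next
    if (!any(grepl("^\\$\\$\\$\\$", block))) block <- c(block, "$$$$")
    res <- tryCatch({
      writeLines(block, tf)
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
      sdf <- sdfset[[1]]
      id <- ChemmineR::sdfid(sdfset)[1]
      if (is.na(id) || !nzchar(id)) id <- paste0("record_", k)
      graph <- NULL
      if (!ChemmineR::validSDF(sdfset[1])) {
        # ChemmineR cannot parse a legal bond-free connection table;
        # recover the atoms from the block directly in that one case
        ci <- grep("V2000", block)[1]
        if (is.na(ci)) ci <- 4L
        counts <- block[ci]
        natoms <- suppressWarnings(
          as.integer(substr(counts, 1L, 3L)))
        nbonds <- suppressWarnings(
          as.integer(substr(counts, 4L, 6L)))
        if (is.na(natoms) || is.na(nbonds) || nbonds != 0L ||
            natoms < 1L)
          stop("invalid CTAB block")
        elements <- vapply(block[ci + seq_len(natoms)], function(l)
          strsplit(trimws(l), "\\s+")[[1]][4], character(1),
          USE.NAMES = FALSE)
        graph <- mol_graph(id, elements, NULL)
      }
      .record_from_sdf(sdf, id, graph)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_skipped <- n_skipped + 1L
      warning("skipping record ", k, ": ", conditionMessage(res),
              call. = FALSE)
    } else {
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  structure(pairs, class = "nmr_record_set", n_skipped = n_skipped)
}

#' @export
print.nmr_record_set <- function(x, ...) {
  prov <- vapply(x, function(p) p$spectrum$provenance, character(1))
  cat("<nmr_record_set> ", length(x), " records (",
      sum(prov == "experimental"), " experimental, ",
      sum(prov == "computational"), " computational)\n", sep = "")
  sk <- attr(x, "n_skipped")
  if (!is.null(sk) && sk > 0) cat("  ", sk, " malformed records skipped\n")
  invisible(x)
}

#' @export
`[.nmr_record_set` <- function(x, i) {
  structure(unclass(x)[i], class = "nmr_record_set",
            n_skipped = attr(x, "n_skipped"))
}

.sdf_from_pair <- function(pair) {
  g <- pair$graph
  r <- pair$spectrum
  n <- nrow(g$atoms)
  ab <- matrix(0, nrow = n, ncol = 5,
               dimnames = list(paste(g$atoms$element, g$atoms$index,
                                     sep = "_"),
                               c("C1", "C2", "C3", "C5", "C6")))
  bb <- if (nrow(g$bonds)) {
    matrix(c(g$bonds$i, g$bonds$j, g$bonds$order,
             rep(0, nrow(g$bonds))),
           ncol = 4, dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
  } else matrix(numeric(), ncol = 4,
                dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
  hdr <- c(Molecule_Name = g$molecule_id, Source = "  nmrsubstr",
           Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 n, nrow(g$bonds)))
  fmt_num <- function(x) sprintf("%.12g", x)
  sig_lines <- sprintf("%d %s%s", r$signals$atom_index,
                       fmt_num(r$signals$shift),
                       ifelse(is.na(r$signals$multiplicity), "",
                              paste0(" ", r$signals$multiplicity)))
  db <- c(NUCLEUS = r$nucleus,
          SPECTRUM = paste(sig_lines, collapse = " __ "))
  if (!is.na(r$field_strength))
    db["FIELD_STRENGTH"] <- fmt_num(r$field_strength)
  if (!is.na(r$temperature)) db["TEMPERATURE"] <- fmt_num(r$temperature)
  if (!is.na(r$solvent)) db["SOLVENT"] <- r$solvent
  if (r$provenance == "computational") db["Program"] <- "calculated"
  methods::new("SDF", header = hdr, atomblock = ab, bondblock = bb,
               datablock = db)
}

#' Write nmrshiftdb2-style SDF records
#'
#' Serializes record pairs in the dialect read by [parse_nmr_sdf()];
#' `parse_nmr_sdf(write_nmr_sdf(x))` reproduces `x` structurally. Missing
#' condition fields are omitted from the data block and read back as
#' missing.
#'
#' @param records an `nmr_record_set` (or plain list of pairs).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_nmr_sdf <- function(records, file) {
  sdfs <- lapply(records, .sdf_from_pair)
  ids <- vapply(records, function(p) p$graph$molecule_id, character(1))
  set <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, file)
  invisible(file)
}

#' Keep experimental spectra only
#'
#' Drops every record whose spectrum is flagged computational (a
#' `Program` tag in the source file); order is preserved and the
#' operation is idempotent.
#'
#' @param records an `nmr_record_set`.
#' @return The filtered `nmr_record_set`.
#' @export
filter_experimental <- function(records) {
  keep <- vapply(records, function(p)
    p$spectrum$provenance == "experimental", logical(1))
  structure(unclass(records)[keep], class = "nmr_record_set",
            n_skipped = attr(records, "n_skipped"))
}

#' Metadata-missingness summary
#'
#' Counts how many spectra lack each experimental condition (field
#' strength, solvent, temperature). Single-condition fields are marginal
#' counts; pair fields count the exact combination (those two missing,
#' the third present); `missing_all` is the exact triple. Derived
#' quantities decompose the marginals into exactly-one counts and sum
#' them with the exact pairs and the triple to give the number of spectra
#' missing at least one condition.
#'
#' @param x an `nmr_record_set`, or a data frame with logical columns
#'   `missing_field`, `missing_solvent`, `missing_temperature` (one row
#'   per spectrum).
#' @return An object of class `missingness_summary`: a list of counts
#'   (`total_records`, `missing_field`, `missing_solvent`,
#'   `missing_temperature`, `missing_fs_and_solvent`,
#'   `missing_fs_and_temp`, `missing_solv_and_temp`, `missing_all`) plus
#'   derived `only_field`, `only_solvent`, `only_temperature`,
#'   `missing_any`.
#' @examples
#' df <- data.frame(missing_field = c(TRUE, FALSE),
#'                  missing_solvent = c(TRUE, FALSE),
#'                  missing_temperature = c(TRUE, FALSE))
#' missingness_summary(df)
#' @export
missingness_summary <- function(x) {
  if (inherits(x, "nmr_record_set") || (is.list(x) && !is.data.frame(x))) {
    x <- data.frame(
      missing_field = vapply(x, function(p)
        is.na(p$spectrum$field_strength), logical(1)),
      missing_solvent = vapply(x, function(p)
        is.na(p$spectrum$solvent), logical(1)),
      missing_temperature = vapply(x, function(p)
        is.na(p$spectrum$temperature), logical(1)))
  }
  f <- x$missing_field; s <- x$missing_solvent; t <- x$missing_temperature
  out <- list(
    total_records = nrow(x),
    missing_field = sum(f),
    missing_solvent = sum(s),
    missing_temperature = sum(t),
    missing_fs_and_solvent = sum(f & s & !t),
    missing_fs_and_temp = sum(f & t & !s),
    missing_solv_and_temp = sum(s & t & !f),
    missing_all = sum(f & s & t))
  out$only_field <- sum(f & !s & !t)
  out$only_solvent <- sum(s & !f & !t)
  out$only_temperature <- sum(t & !f & !s)
  out$missing_any <- sum(f | s | t)
  structure(out, class = "missingness_summary")
}

#' Derived quantities from printed missingness counts
#'
#' Reconstructs the exactly-one-condition counts and the
#' missing-at-least-one total from a table of marginal single-condition
#' counts, exact pair counts and the exact triple count, without access
#' to the underlying records.
#'
#' @param total_records,missing_field,missing_solvent,missing_temperature
#'   totals and marginal counts.
#' @param missing_fs_and_solvent,missing_fs_and_temp,missing_solv_and_temp
#'   exact-combination pair counts.
#' @param missing_all exact triple count.
#' @return A `missingness_summary` with the derived fields filled in.
#' @export
missingness_from_counts <- function(total_records, missing_field,
                                    missing_solvent, missing_temperature,
                                    missing_fs_and_solvent,
                                    missing_fs_and_temp,
                                    missing_solv_and_temp, missing_all) {
  out <- list(total_records = total_records,
              missing_field = missing_field,
              missing_solvent = missing_solvent,
              missing_temperature = missing_temperature,
              missing_fs_and_solvent = missing_fs_and_solvent,
              missing_fs_and_temp = missing_fs_and_temp,
              missing_solv_and_temp = missing_solv_and_temp,
              missing_all = missing_all)
  out$only_field <- missing_field - missing_fs_and_solvent -
    missing_fs_and_temp - missing_all
  out$only_solvent <- missing_solvent - missing_fs_and_solvent -
    missing_solv_and_temp - missing_all
  out$only_temperature <- missing_temperature - missing_fs_and_temp -
    missing_solv_and_temp - missing_all
  if (out$only_field < 0 || out$only_solvent < 0 || out$only_temperature < 0)
    stop("inconsistent counts: a marginal is smaller than its exact ",
         "sub-combinations")
  out$missing_any <- out$only_field + out$only_solvent +
    out$only_temperature + missing_fs_and_solvent + missing_fs_and_temp +
    missing_solv_and_temp + missing_all
  structure(out, class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  pc <- function(n) sprintf("%d (%.0f%%)", n, 100 * n / x$total_records)
  cat("Metadata missingness over", x$total_records, "spectra\n")
  cat("  field strength missing (marginal):", x$missing_field, "\n")
  cat("  solvent missing (marginal):       ", x$missing_solvent, "\n")
  cat("  temperature missing (marginal):   ", x$missing_temperature, "\n")
  cat("  exactly field+solvent:", x$missing_fs_and_solvent,
      " field+temp:", x$missing_fs_and_temp,
      " solvent+temp:", x$missing_solv_and_temp, "\n")
  cat("  all three missing:", pc(x$missing_all), "\n")
  cat("  at least one missing:", pc(x$missing_any), "\n")
  invisible(x)
}
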