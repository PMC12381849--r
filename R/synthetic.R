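#' Synthetic dataset configuration
#'
#' Parameters of the seeded spectrum generator used for desk-scale
#' benchmarks. Molecules are drawn from a curated structure library
#' (four named demonstration compounds) plus random acyclic
#' valence-respecting graphs; each carbon's 13C shift is a deterministic
#' function of its consolidated neighbor label plus condition offsets
#' and Gaussian noise, so the spectrum-to-substructure mapping the
#' models must learn exists by construction.
#'
#' Defaults define the benchmark conditions: 200 molecules of 4--9
#' heavy atoms from a carbon-rich palette, class base shifts spaced
#' 10 ppm apart (separable: spacing > 6 noise SD at the default 0.5 ppm
#' noise), solvent offsets of -10/0/+10 ppm that alias one class onto
#' its neighbors when the solvent is unknown, small linear field and
#' temperature terms, and no missing metadata.
#'
#' @param n_molecules molecule count (default 200).
#' @param atoms_per_molecule heavy-atom count range for random graphs.
#' @param element_palette symbols drawn (with repetition as weights) for
#'   random graphs; must be a subset of [element_table()] symbols.
#' @param bond_order_probs sampling weights for single/double/triple
#'   bonds in random graphs (where valence allows).
#' @param base_shift_table optional named vector mapping label notation
#'   (see [format_label()]) to base shift in ppm; `NULL` derives one
#'   with `base_shift_spacing` between lexicographically ordered labels.
#' @param base_shift_start,base_shift_spacing derivation parameters
#'   (ppm).
#' @param solvent_offsets named ppm offsets per solvent.
#' @param field_coefficient ppm added per unit of field / 700 MHz.
#' @param temperature_coefficient ppm added per unit of temp / 323 K.
#' @param noise_sd Gaussian shift noise in ppm (default 0.5).
#' @param missing_condition_rate per-condition independent drop
#'   probability (default 0).
#' @param include_curated include the four curated molecules.
#' @param separable enforce spacing > 6 * noise_sd.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 200L,
                             atoms_per_molecule = c(4L, 9L),
                             element_palette = c(rep("C", 8), "N", "O"),
                             bond_order_probs = c(0.88, 0.12, 0),
                             base_shift_table = NULL,
                             base_shift_start = 10,
                             base_shift_spacing = 10,
                             solvent_offsets = c(CDCl3 = 0, DMSO = 10,
                                                 C6D6 = -10),
                             field_coefficient = 1.5,
                             temperature_coefficient = 1.0,
                             noise_sd = 0.5,
                             missing_condition_rate = 0,
                             include_curated = TRUE,
                             separable = TRUE,
                             seed = 1L) {
  if (!all(unique(element_palette) %in% names(element_table())))
    stop("element_palette must be a subset of the element table symbols")
  stopifnot(length(atoms_per_molecule) == 2L,
            atoms_per_molecule[1] >= 2L,
            atoms_per_molecule[1] <= atoms_per_molecule[2],
            missing_condition_rate >= 0, missing_condition_rate <= 1)
  if (separable && base_shift_spacing <= 6 * noise_sd)
    stop("separable mode needs base_shift_spacing > 6 * noise_sd")
  stopifnot(length(bond_order_probs) == 3L, all(bond_order_probs >= 0),
            sum(bond_order_probs) > 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_per_molecule = as.integer(atoms_per_molecule),
                 element_palette = element_palette,
                 bond_order_probs = bond_order_probs,
                 base_shift_table = base_shift_table,
                 base_shift_start = base_shift_start,
                 base_shift_spacing = base_shift_spacing,
                 solvent_offsets = solvent_offsets,
                 field_coefficient = field_coefficient,
                 temperature_coefficient = temperature_coefficient,
                 noise_sd = noise_sd,
                 missing_condition_rate = missing_condition_rate,
                 include_curated = include_curated,
                 separable = separable, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Curated demonstration molecules
#'
#' Loads the four named structures shipped with the package
#' (beta-sitosterol, caffeine, aspirin, cyclopropylbenzene) as
#' kekulized [mol_graph()] objects. Their connection tables are real;
#' any shifts the generator attaches to them are synthetic.
#'
#' @return Named list of `mol_graph`s.
#' @export
curated_molecules <- function() {
  f <- system.file("extdata", "curated_molecules.sdf",
                   package = "nmrsubstr")
  set <- suppressWarnings(ChemmineR::read.SDFset(f))
  ids <- ChemmineR::sdfid(set)
  out <- lapply(seq_along(set), function(k) {
    ab <- ChemmineR::atomblock(set[[k]])
    bb <- ChemmineR::bondblock(set[[k]])
    mol_graph(ids[k], sub("_.*$", "", rownames(ab)),
              data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                         order = as.integer(bb[, 3])))
  })
  stats::setNames(out, ids)
}

# random acyclic graph respecting standard valences; atom 1 forced to C
# so every molecule has a carbon spectrum
.random_molecule <- function(id, n_heavy, palette,
                             order_probs = c(0.88, 0.12, 0)) {
  elements <- c("C", sample(palette, n_heavy - 1L, replace = TRUE))
  free <- unname(.std_valence[elements])
  free[is.na(free)] <- 1L
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  for (k in 2L:n_heavy) {
    open <- which(free[seq_len(k - 1L)] > 0L)
    if (!length(open)) {  # all valence used; restart with fresh draw
      return(NULL)
    }
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    max_ord <- min(free[parent], free[k], 3L)
    pr <- order_probs[seq_len(max_ord)]
    ord <- if (max_ord == 1L || sum(pr) == 0) 1L
    else sample(seq_len(max_ord), 1L, prob = pr)
    bonds <- rbind(bonds, data.frame(i = parent, j = k, order = ord))
    free[parent] <- free[parent] - ord
    free[k] <- free[k] - ord
  }
  mol_graph(id, elements, bonds)
}

.condition_shift <- function(config, solvent, field, temp) {
  unname(config$solvent_offsets[solvent]) +
    config$field_coefficient * field / 700 +
    config$temperature_coefficient * temp / 323
}

#' Generate a synthetic spectrum dataset
#'
#' Assembles molecules, derives each carbon's ground-truth consolidated
#' neighbor label, and emits one 13C [spectrum_record()] per molecule:
#' shift = base shift of the label + solvent offset + field and
#' temperature terms + Gaussian noise; multiplicity comes from the true
#' attached-hydrogen count (0/1/2/3 H gives s/d/t/q). Conditions are
#' then dropped independently at the configured rate. Fully reproducible
#' from the seed.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_dataset`: `records` (an
#'   `nmr_record_set`), `truth` (data frame `molecule_id`, `record`,
#'   `atom_index`, `label`, plus list column `label_obj`), `base_shifts`
#'   (named ppm vector per label), `conditions` (the undropped per-record
#'   solvent/field/temperature, for oracle use), and `config`.
#' @export
generate_synthetic <- function(config) {
  set.seed(config$seed)
  graphs <- list()
  if (config$include_curated) {
    cur <- curated_molecules()
    graphs <- cur[seq_len(min(length(cur), config$n_molecules))]
  }
  k <- length(graphs)
  attempt <- 0L
  while (length(graphs) < config$n_molecules) {
    attempt <- attempt + 1L
    n_heavy <- sample(config$atoms_per_molecule[1]:
                        config$atoms_per_molecule[2], 1L)
    g <- .random_molecule(sprintf("syn%04d", length(graphs) + 1L),
                          n_heavy, config$element_palette,
                          config$bond_order_probs)
    if (is.null(g)) {
      if (attempt > 50L * config$n_molecules)
        stop("unsatisfiable valence configuration")
      next
    }
    graphs[[length(graphs) + 1L]] <- g
  }

  labels_per_mol <- lapply(graphs, carbon_labels)
  all_keys <- unlist(lapply(labels_per_mol, function(ll)
    vapply(ll, format_label, character(1))))
  base <- config$base_shift_table
  if (is.null(base)) {
    vocab <- build_vocabulary(unlist(labels_per_mol, recursive = FALSE))
    labs <- vocab$label
    # grid-slot assignment: classes sharing an attached-H count (hence
    # a multiplicity symbol) occupy contiguous slots, frequent classes
    # at the block center and rare ones at the block edges. When the
    # solvent offsets equal the slot spacing this keeps a shift list
    # ambiguous about the solvent for most molecules: confusable
    # neighbors share the multiplicity, and the slots whose offsets
    # betray the solvent (block boundaries, grid ends) belong to rare
    # classes
    freq <- table(all_keys)[labs]
    hcnt <- vapply(labs, function(l)
      4L - sum(as.integer(parse_label(l))[5:8]), integer(1))
    slots <- integer(length(labs)); names(slots) <- labs
    nxt <- 1L
    for (h in sort(unique(hcnt), decreasing = TRUE)) {
      blk <- labs[hcnt == h]
      blk <- blk[order(-as.integer(freq[blk]), blk)]
      k <- length(blk)
      center_out <- order(abs(seq_len(k) - (k + 1) / 2))
      slots[blk] <- (nxt:(nxt + k - 1L))[center_out]
      nxt <- nxt + k
    }
    base <- stats::setNames(config$base_shift_start +
                              config$base_shift_spacing * (slots - 1L),
                            labs)
  }

  solvents <- names(config$solvent_offsets)
  fields <- c(300, 400, 500, 600, 700)
  temps <- c(273, 283, 298, 310, 323)
  pairs <- vector("list", length(graphs))
  truth <- list()
  cond <- data.frame(record = seq_along(graphs),
                     solvent = sample(solvents, length(graphs),
                                      replace = TRUE),
                     field = sample(fields, length(graphs),
                                    replace = TRUE),
                     temperature = sample(temps, length(graphs),
                                          replace = TRUE))
  for (g_ix in seq_along(graphs)) {
    g <- graphs[[g_ix]]
    labs <- labels_per_mol[[g_ix]]
    c_idx <- as.integer(names(labs))
    keys <- vapply(labs, format_label, character(1))
    if (any(!keys %in% names(base)))
      stop("base_shift_table lacks label(s): ",
           paste(setdiff(keys, names(base)), collapse = "; "))
    offs <- .condition_shift(config, cond$solvent[g_ix],
                             cond$field[g_ix], cond$temperature[g_ix])
    shift <- base[keys] + offs +
      stats::rnorm(length(keys), 0, config$noise_sd)
    nh <- attached_h_count(g, c_idx)
    mult <- c("s", "d", "t", "q")[pmin(nh, 3L) + 1L]
    mult[nh > 3L] <- NA_character_  # >3 H has no s/d/t/q symbol
    drop3 <- stats::runif(3) < config$missing_condition_rate
    rec <- spectrum_record(
      g$molecule_id, "13C",
      data.frame(atom_index = c_idx, shift = unname(shift),
                 multiplicity = mult),
      field_strength = if (drop3[1]) NA_real_ else cond$field[g_ix],
      temperature = if (drop3[2]) NA_real_ else cond$temperature[g_ix],
      solvent = if (drop3[3]) NA_character_ else cond$solvent[g_ix])
    pairs[[g_ix]] <- list(graph = g, spectrum = rec)
    truth[[g_ix]] <- data.frame(molecule_id = g$molecule_id,
                                record = g_ix, atom_index = c_idx,
                                label = unname(keys),
                                stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$label_obj <- lapply(truth$label, parse_label)
  structure(list(records = structure(pairs, class = "nmr_record_set",
                                     n_skipped = 0L),
                 truth = truth, base_shifts = base, conditions = cond,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$records), " molecules, ",
      nrow(x$truth), " carbon signals, ",
      length(unique(x$truth$label)), " distinct labels\n", sep = "")
  invisible(x)
}

#' Nearest-base-shift oracle classifier
#'
#' The analytic ceiling for the synthetic benchmark: each signal is
#' assigned the label whose base shift is nearest, after subtracting the
#' known condition terms when `use_conditions = TRUE` (and that record's
#' conditions are not hidden). With conditions hidden, solvent offsets
#' alias classes onto each other and accuracy drops by construction.
#'
#' @param dataset a [generate_synthetic()] result.
#' @param use_conditions subtract solvent/field/temperature terms before
#'   the nearest-neighbor lookup.
#' @return List with `accuracy`, and `predictions` (data frame with
#'   truth and predicted label per signal).
#' @export
oracle_classifier <- function(dataset, use_conditions = TRUE) {
  base <- dataset$base_shifts
  cfg <- dataset$config
  preds <- character(nrow(dataset$truth))
  ptr <- 1L
  for (g_ix in seq_along(dataset$records)) {
    r <- dataset$records[[g_ix]]$spectrum
    shifts <- r$signals$shift
    corr <- if (use_conditions) {
      sol <- r$solvent; fld <- r$field_strength; tmp <- r$temperature
      off <- (if (is.na(sol)) 0 else unname(cfg$solvent_offsets[sol])) +
        (if (is.na(fld)) 0 else cfg$field_coefficient * fld / 700) +
        (if (is.na(tmp)) 0 else cfg$temperature_coefficient * tmp / 323)
      shifts - off
    } else shifts
    for (s in seq_along(corr)) {
      preds[ptr] <- names(base)[which.min(abs(base - corr[s]))]
      ptr <- ptr + 1L
    }
  }
  df <- dataset$truth[, c("molecule_id", "atom_index", "label")]
  df$predicted <- preds
  list(accuracy = mean(df$predicted == df$label), predictions = df)
}
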