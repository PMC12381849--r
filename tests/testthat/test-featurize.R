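test_that("condition normalization reproduces the worked values", {
  expect_equal(normalize_condition(50, 700), 0.07143, tolerance = 5e-5)
  expect_equal(normalize_condition(298, 323), 0.9226, tolerance = 5e-5)
  expect_equal(normalize_condition(700, 700), 1.0)
  expect_equal(normalize_condition(NA, 700), 0)
  expect_error(normalize_condition(800, 700, "rec1"), "rec1")
  # monotone and bounded on a grid
  vals <- normalize_condition(seq(0, 323, by = 17), 323)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("multiplicity symbols map to 0-4 with 0 for absent", {
  expect_equal(encode_multiplicity(c("s", "d", "t", "q")), 1:4)
  expect_equal(encode_multiplicity(NA_character_), 0L)
  expect_error(encode_multiplicity("x"), "unknown multiplicity")
})

test_that("molecule sequences sort shifts ascending with co-permuted multiplicities", {
  shifts <- c(17.6, 18.3, 22.6, 26.5, 31.7, 33.5, 33.5, 41.8, 42.0,
              42.2, 78.34, 140.99, 158.3, 193.4, 203.0)
  mult <- c("q", "t", "q", "t", "t", "s", "s", "t", "s", "d", "s", "s",
            "d", "d", "d")
  rec <- spectrum_record("tbl1", "13C",
                         data.frame(atom_index = 1:15, shift = shifts,
                                    multiplicity = mult))
  ms <- build_molecule_sequence(rec)
  expect_equal(ms$multiplicities,
               c(4, 3, 4, 3, 3, 1, 1, 3, 1, 2, 1, 1, 2, 2, 2))
  expect_equal(ms$shifts, sort(shifts))
  expect_equal(ms$length, 15L)
  # permutation invariance: every input order of a 4-signal record gives
  # the same output (exhaustive oracle)
  sig <- data.frame(atom_index = 1:4, shift = c(30, 10, 30, 20),
                    multiplicity = c("d", "q", "s", "t"))
  ref <- build_molecule_sequence(spectrum_record("p", "13C", sig))
  for (p in nmrsubstr:::.all_perms(4L)) {
    out <- build_molecule_sequence(
      spectrum_record("p", "13C", sig[p, ]))
    expect_identical(out, ref)
  }
  single <- spectrum_record("s", "13C",
                            data.frame(atom_index = 1, shift = 5,
                                       multiplicity = "s"))
  expect_equal(build_molecule_sequence(single)$length, 1L)
  expect_error(build_molecule_sequence(
    spectrum_record("e", "13C", data.frame(atom_index = integer(),
                                           shift = numeric()))),
    "no signals")
})

test_that("solvent codes rank by frequency and one-hot is equivalent", {
  vocab <- solvent_vocabulary(c("DMSO", "CDCl3", "CDCl3", "D2O",
                                "CDCl3", "DMSO", NA))
  expect_equal(vocab, c(CDCl3 = 1L, DMSO = 2L, D2O = 3L))
  expect_equal(encode_solvent("CDCl3", vocab), 1L)
  expect_equal(encode_solvent(NA_character_, vocab), 0L)
  expect_equal(encode_solvent("unknown", vocab), 0L)
  # frequency ties resolve alphabetically
  v2 <- solvent_vocabulary(c("b", "a"))
  expect_equal(names(v2), c("a", "b"))
  # bijection between integer and one-hot encodings over a 5-name vocab
  v5 <- solvent_vocabulary(rep(letters[1:5], times = 5:1))
  names_all <- c(names(v5), NA)
  enc <- encode_solvent(names_all, v5, onehot = TRUE)
  expect_equal(dim(enc$onehot), c(6L, 5L))
  expect_equal(rowSums(enc$onehot), c(rep(1, 5), 0))
  decoded <- apply(enc$onehot, 1, function(r)
    if (any(r == 1)) which(r == 1) else 0L)
  expect_equal(unname(decoded), enc$code)
})

test_that("padding preserves the prefix and round-trips", {
  seq3 <- list(shifts = c(1.5, 2.5, 9), multiplicities = c(4L, 1L, 2L),
               length = 3L)
  p <- pad_sequence(seq3, 8L)
  expect_equal(p$shifts, c(1.5, 2.5, 9, rep(0, 5)))
  expect_equal(p$multiplicities, c(4L, 1L, 2L, rep(0L, 5)))
  expect_identical(pad_sequence(seq3, 3L)$shifts, seq3$shifts)
  expect_equal(p$shifts[seq_len(p$length)], seq3$shifts)  # truncation
  expect_error(pad_sequence(seq3, 2L), "exceeds")
})

test_that("feature bundles assemble fixed and variable inputs", {
  ds <- generate_synthetic(synthetic_config(n_molecules = 12, seed = 21))
  cfg <- feature_config(ds$records)
  expect_equal(cfg$max_len,
               max(vapply(ds$records, function(p)
                 nrow(p$spectrum$signals), integer(1))))
  fb <- featurize_records(ds$records, cfg)
  expect_equal(nrow(fb$fixed), nrow(ds$truth))
  expect_true(all(fb$fixed[, "field_norm"] >= 0 &
                    fb$fixed[, "field_norm"] <= 1))
  # padded prefix equals the molecule sequence, trailing zeros after
  for (r in c(1L, 5L)) {
    L <- fb$lengths[r]
    expect_true(all(fb$seq_shifts[r, seq_len(L)] ==
                      sort(fb$seq_shifts[r, seq_len(L)])))
    if (L < cfg$max_len)
      expect_true(all(fb$seq_shifts[r, (L + 1):cfg$max_len] == 0))
  }
  # ablation zeroes exactly the three condition columns
  fb0 <- featurize_records(ds$records, cfg, ablate_conditions = TRUE)
  expect_true(all(fb0$fixed[, c("field_norm", "temp_norm",
                                "solvent_code")] == 0))
  expect_identical(fb0$fixed[, "shift"], fb$fixed[, "shift"])
  # missing conditions become zeros
  ds2 <- generate_synthetic(synthetic_config(n_molecules = 6, seed = 2,
                                             missing_condition_rate = 1))
  fb2 <- featurize_records(ds2$records, feature_config(ds2$records))
  expect_true(all(fb2$fixed[, c("field_norm", "temp_norm",
                                "solvent_code")] == 0))
})

test_that("config falls back to documented maxima without metadata", {
  ds <- generate_synthetic(synthetic_config(n_molecules = 6, seed = 2,
                                            missing_condition_rate = 1))
  cfg <- feature_config(ds$records)
  expect_equal(cfg$field_max, 700)
  expect_equal(cfg$temp_max, 323)
  expect_length(cfg$solvents, 0L)
})

test_that("1H records carry a zeroed multiplicity channel", {
  g <- mol_graph("h2", c("C", "H", "H"),
                 data.frame(i = c(1, 1), j = c(2, 3), order = c(1, 1)))
  rec <- spectrum_record("h2", "1H",
                         data.frame(atom_index = c(2, 3),
                                    shift = c(1.2, 1.4),
                                    multiplicity = c("d", "d")))
  fb <- featurize_records(
    structure(list(list(graph = g, spectrum = rec)),
              class = "nmr_record_set"),
    feature_config(structure(list(list(graph = g, spectrum = rec)),
                             class = "nmr_record_set")))
  expect_true(all(fb$fixed[, "multiplicity"] == 0))
  expect_true(all(fb$seq_mult == 0))
})
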