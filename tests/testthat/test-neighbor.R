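test_that("element table matches the published numbering", {
  tab <- element_table()
  expect_length(tab, 31L)
  expect_equal(unname(tab[c("Ag", "C", "H", "N", "O", "Zn")]),
               c(1L, 7L, 11L, 17L, 19L, 31L))
  # alphabetical order defines the codes
  expect_identical(names(tab), sort(names(tab)))
})

test_that("raw labels record explicit neighbors and reject high degree", {
  g <- cn_env_graph()
  raw <- raw_label(g, 1)
  expect_equal(as.integer(raw), c(7, 17, 0, 0, 1, 2, 0, 0))
  expect_error(raw_label(g, 3), "not carbon")
  # CO2-like central carbon
  co2 <- mol_graph("co2", c("C", "O", "O"),
                   data.frame(i = c(1, 1), j = c(2, 3), order = c(2, 2)))
  expect_equal(as.integer(neighbor_label(co2, 1)),
               c(19, 19, 0, 0, 2, 2, 0, 0))
  deg5 <- mol_graph("deg5", c("C", rep("O", 5)),
                    data.frame(i = rep(1, 5), j = 2:6, order = rep(1, 5)))
  expect_error(raw_label(deg5, 1), "degree")
})

test_that("hydrogen slots zero out and reduce the bond-slot sum", {
  m <- methane_graph()
  raw <- raw_label(m, 1)
  expect_equal(as.integer(raw)[1:4], rep(11L, 4))
  z <- zero_hydrogens(raw)
  expect_equal(as.integer(z), rep(0L, 8))
  # the worked environment keeps a bond-slot sum of 3 (one slot lost to
  # an implicit hydrogen)
  lab <- neighbor_label(cn_env_graph(), 1, consolidate = FALSE)
  expect_equal(as.integer(lab), c(7, 17, 0, 0, 1, 2, 0, 0))
  expect_equal(sum(as.integer(lab)[5:8]), 3L)
  # no-H labels are fixed points
  no_h <- parse_label("7, 19, 0, 0, 1, 2, 0, 0")
  expect_equal(as.integer(zero_hydrogens(no_h)), as.integer(no_h))
})

test_that("canonicalization sorts by bond then atom with zeros trailing", {
  expect_equal(
    format_label(canonicalize_label(parse_label("7, 7, 19, 17, 1, 1, 1, 1"))),
    "7, 7, 17, 19, 1, 1, 1, 1")
  # the two printed spellings of the same environment coincide
  expect_equal(
    format_label(canonicalize_label(parse_label("17, 7, 0, 0, 2, 1, 0, 0"))),
    "7, 17, 0, 0, 1, 2, 0, 0")
})

test_that("canonicalize is idempotent and permutation-invariant", {
  # exhaustive oracle: every slot ordering of several labels must give
  # the same canonical form
  perms <- nmrsubstr:::.all_perms(4L)
  labels <- list(c(7L, 17L, 0L, 0L, 1L, 2L, 0L, 0L),
                 c(7L, 7L, 17L, 19L, 1L, 1L, 1L, 1L),
                 c(19L, 19L, 0L, 0L, 2L, 2L, 0L, 0L),
                 c(6L, 9L, 23L, 7L, 1L, 1L, 2L, 3L))
  for (lab in labels) {
    ref <- canonicalize_label(parse_label(paste(lab, collapse = ", ")))
    expect_identical(canonicalize_label(ref), ref)  # idempotent
    for (p in perms) {
      shuffled <- c(lab[1:4][p], lab[5:8][p])
      out <- canonicalize_label(
        parse_label(paste(shuffled, collapse = ", ")))
      expect_identical(as.integer(out), as.integer(ref))
    }
  }
})

test_that("consolidation maps rare elements to 32 and preserves C/N/O", {
  expect_equal(
    as.integer(consolidate_label(parse_label("7, 23, 0, 0, 1, 1, 0, 0"))),
    c(7, 32, 0, 0, 1, 1, 0, 0))
  expect_equal(
    as.integer(consolidate_label(parse_label("6, 9, 0, 0, 1, 1, 0, 0"))),
    c(32, 32, 0, 0, 1, 1, 0, 0))
  keep <- parse_label("7, 17, 19, 0, 1, 1, 2, 0")
  expect_identical(as.integer(consolidate_label(keep)), as.integer(keep))
})

test_that("the full pipeline is a pure function of the environment", {
  # isomorphic environments in different molecules yield identical labels
  g1 <- mol_graph("a", c("C", "C", "N", "O"),
                  data.frame(i = c(1, 1, 2), j = c(2, 3, 4),
                             order = c(1, 2, 1)))
  g2 <- mol_graph("b", c("O", "N", "C", "C"),
                  data.frame(i = c(4, 4, 3), j = c(3, 2, 1),
                             order = c(1, 2, 1)))
  expect_identical(as.integer(neighbor_label(g1, 1)),
                   as.integer(neighbor_label(g2, 4)))
  # bond-slot sum never exceeds 4; equals 4 only with no attached H
  ds <- generate_synthetic(synthetic_config(n_molecules = 25, seed = 13))
  for (p in ds$records) {
    for (a in p$graph$atoms$index[p$graph$atoms$element == "C"]) {
      lab <- neighbor_label(p$graph, a)
      bsum <- sum(as.integer(lab)[5:8])
      expect_lte(bsum, 4L)
      if (bsum == 4L) expect_equal(attached_h_count(p$graph, a), 0L)
    }
  }
})

test_that("vocabulary is deterministic and consolidation shrinks it", {
  ds <- generate_synthetic(synthetic_config(n_molecules = 20, seed = 17))
  raw_labs <- unlist(lapply(ds$records, function(p)
    carbon_labels(p$graph, consolidate = FALSE)), recursive = FALSE)
  con_labs <- unlist(lapply(ds$records, function(p)
    carbon_labels(p$graph)), recursive = FALSE)
  v_raw <- build_vocabulary(raw_labs)
  v_con <- build_vocabulary(con_labs)
  # set-size oracle
  expect_equal(attr(v_con, "m"),
               length(unique(vapply(con_labs, format_label,
                                    character(1)))))
  expect_lte(attr(v_con, "m"), attr(v_raw, "m"))
  expect_identical(v_con, build_vocabulary(rev(con_labs)))
  # corpus order does not matter
  expect_equal(attr(build_vocabulary(con_labs[c(1, 1, 1)]), "m"), 1L)
  expect_error(build_vocabulary(list()), "empty")
  # unseen labels map to the reserved unknown class m
  v1 <- build_vocabulary(con_labs[1])
  cls <- labels_to_classes(con_labs, v1)
  expect_true(all(cls %in% c(0L, attr(v1, "m"))))
  # plain-text persistence round-trips
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v_con, tf)
  expect_equal(read_vocabulary(tf)$label, v_con$label)
})

test_that("hydrogens inherit the attached carbon's label", {
  m <- methane_graph()
  expect_equal(as.integer(hydrogen_substructure(m, 2)), rep(0L, 8))
  # benzene with one explicit H
  b <- mol_graph("benzene_h", c(rep("C", 6), "H"),
                 data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
                            order = c(4, 4, 4, 4, 4, 4, 1)))
  bk <- kekulize_graph(b)
  expect_identical(as.integer(hydrogen_substructure(bk, 7)),
                   as.integer(neighbor_label(bk, 1)))
  # hydroxyl hydrogen is rejected (bonded to oxygen)
  eth <- mol_graph("ethanol_h", c("C", "C", "O", "H"),
                   data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                              order = c(1, 1, 1)))
  expect_error(hydrogen_substructure(eth, 4), "rejected")
  expect_error(hydrogen_substructure(eth, 1), "not hydrogen")
})
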