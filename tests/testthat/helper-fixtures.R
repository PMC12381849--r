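# shared fixture builders; everything is generated in code

# the three-heavy-atom environment used throughout the neighbor-encoder
# examples: a carbon bonded to one carbon (single) and one nitrogen
# (double), remaining valence filled by implicit hydrogen
cn_env_graph <- function() {
  mol_graph("cn_env", c("C", "C", "N"),
            data.frame(i = c(1, 1), j = c(2, 3), order = c(1, 2)))
}

benzene_graph <- function() {
  mol_graph("benzene", rep("C", 6),
            data.frame(i = 1:6, j = c(2:6, 1), order = rep(4L, 6)))
}

methane_graph <- function() {
  mol_graph("methane", c("C", "H", "H", "H", "H"),
            data.frame(i = rep(1, 4), j = 2:5, order = rep(1L, 4)))
}

ethanol_graph <- function() {
  mol_graph("ethanol", c("C", "C", "O"),
            data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
}

# hand-written two-record SDF stream: ethanol (experimental) and a
# computational record carrying a Program tag
ethanol_sdf_lines <- function() {
  c("ethanol", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.0000    0.0000    0.0000 C   0  0",
    "    2.0000    0.0000    0.0000 O   0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "M  END",
    "> <NUCLEUS>", "13C", "",
    "> <SPECTRUM>", "1 18.3 q", "2 57.8 t", "",
    "> <FIELD_STRENGTH>", "400", "",
    "> <SOLVENT>", "CDCl3", "",
    "$$$$",
    "calc1", "  test", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "M  END",
    "> <NUCLEUS>", "13C", "",
    "> <SPECTRUM>", "1 100.0", "",
    "> <Program>", "gaussian", "",
    "$$$$")
}

# minimal feature bundle with hand-chosen values, for model unit tests
tiny_bundle <- function(nb = 6L, Tn = 4L, seed = 42L, tied = FALSE) {
  set.seed(seed)
  lens <- sample(seq_len(Tn), nb, replace = TRUE)
  lens[which.max(lens)] <- Tn
  mk <- do.call(rbind, lapply(lens, function(L)
    c(rep(1, L), rep(0, Tn - L))))
  sm <- if (tied) matrix(sample(0:4, nb * Tn, TRUE), nb, Tn)
        else matrix(stats::runif(nb * Tn, 0, 4), nb, Tn)
  structure(list(
    fixed = matrix(stats::rnorm(nb * 3), nb, 3,
                   dimnames = list(NULL,
                                   c("shift", "multiplicity", "x"))),
    seq_shifts = matrix(stats::rnorm(nb * Tn), nb, Tn) * mk,
    seq_mult = sm * mk,
    mask = mk, lengths = lens,
    molecule = seq_len(nb), atom_index = seq_len(nb),
    config = list(max_len = Tn)),
    class = "feature_bundle")
}

# a small learnable dataset: class fully determined by the fixed shift
separable_bundle <- function(n_per_class = 30L, m = 4L, seed = 7L) {
  set.seed(seed)
  n <- n_per_class * m
  cls <- rep(seq_len(m) - 1L, each = n_per_class)
  shift <- 20 * cls + stats::rnorm(n, 0, 0.1)
  Tn <- 3L
  structure(list(
    fixed = cbind(shift = shift, multiplicity = 0, x = 0),
    seq_shifts = matrix(rep(shift, Tn), n, Tn),
    seq_mult = matrix(0, n, Tn),
    mask = matrix(1, n, Tn), lengths = rep(Tn, n),
    molecule = seq_len(n), atom_index = seq_len(n),
    config = list(max_len = Tn)),
    class = "feature_bundle", classes = cls, m = m)
}

rel_grad_errors <- function(arch, seed = 42L, n_coords = 3L,
                            tied = FALSE) {
  fb <- tiny_bundle(seed = seed, tied = tied)
  nb <- nrow(fb$fixed)
  cls <- sample(0:2, nb, replace = TRUE)
  onehot <- diag(3)[cls + 1L, ]
  spec <- model_spec(arch, m = 3, recurrent_units = 4,
                     seq_dense = c(5, 6), fixed_dense = 4,
                     head_dense = 5, conv_filters = c(3, 4),
                     cnn_dense = 6, seed = seed)
  model <- build_model(spec, 3L, fb$config$max_len)
  model$scaler <- nmrsubstr:::.fit_scaler(fb, seq_len(nb))
  batch <- nmrsubstr:::.prepare_batch(fb, seq_len(nb), model$scaler,
                                      truncate = arch != "cnn")
  loss_of <- function(flat) {
    p <- nmrsubstr:::.unflatten_params(flat, model$params)
    fw <- nmrsubstr:::.forward(p, spec, batch)
    nmrsubstr:::.softmax_ce(fw$logits, onehot)$loss
  }
  flat <- nmrsubstr:::.flatten_params(model$params)
  fw <- nmrsubstr:::.forward(model$params, spec, batch)
  ls <- nmrsubstr:::.softmax_ce(fw$logits, onehot)
  gr <- nmrsubstr:::.flatten_params(
    nmrsubstr:::.backward(model$params, spec, batch, fw, ls$dlogits))
  errs <- c()
  for (nm in names(flat)) {
    v <- flat[[nm]]
    for (i in sample(length(v), min(n_coords, length(v)))) {
      eps <- 1e-5
      fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + eps
      fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - eps
      num <- (loss_of(fp) - loss_of(fm)) / (2 * eps)
      ana <- gr[[nm]][i]
      errs <- c(errs, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  errs
}
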