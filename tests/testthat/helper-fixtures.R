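# Shared, lazily-built fixtures. The trained dictionary pair is expensive
# (~30 s) and reused across detector, pipeline and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# the canonical dictionary pair: 1000 windows/class, complete 256x256, T0=3
shared_dicts <- function() {
  fixture("dicts", {
    cfg <- synth_config(seed = 42)
    ts <- make_training_sets(cfg, 1000L)
    list(D1 = ksvd(ts$fm, n_atoms = 256L, T0 = 3L, n_iter = 30L, seed = 42L),
         D2 = ksvd(ts$nonfm, n_atoms = 256L, T0 = 3L, n_iter = 30L, seed = 42L))
  })
}

# held-out two-class corpus from an independent seed
shared_holdout <- function(n_per_class = 200L) {
  fixture(paste0("holdout", n_per_class),
          make_training_sets(synth_config(seed = 777), n_per_class))
}

# a random dictionary with orthonormal atoms (m >= n)
random_orthonormal_dict <- function(m, n, seed = 1) {
  with_seed(seed, qr.Q(qr(matrix(rnorm(m * n), m, n)))[, seq_len(n), drop = FALSE])
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# classify every column of a window matrix with the OMP detector
classify_columns <- function(Y, D1, D2, T0 = 3L) {
  vapply(seq_len(ncol(Y)),
         function(l) omp_classify(Y[, l], D1, D2, T0 = T0)$label,
         character(1))
}

write_recording_file <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste(names(df), collapse = sep),
               apply(df, 1L, paste, collapse = sep)), path)
  path
}
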