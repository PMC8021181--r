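# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default 64x64 high-contrast phantom, seed 1
fixture_phantom <- function() {
  memo("phantom64", make_phantom(seed = 1L))
}

# GMM-initialized annealed GMRF segmentation of the fixture phantom
fixture_segmentation <- function() {
  memo("seg64", suppressWarnings(segment_mri(fixture_phantom()$mri, seed = 1L)))
}

# masked-pixel agreement between a label field and the phantom truth
phantom_accuracy <- function(ph, field) {
  tn <- label_names(ph$labels)[ph$mri$mask]
  pn <- label_names(field)[ph$mri$mask]
  mean(tn == pn)
}

# assemble the joint precision matrix of a single-label lattice from the
# per-label parameters (the independent oracle for the site conditionals)
assemble_Q <- function(nr, nc, model, label) {
  nb <- model$neighborhood
  N <- nr * nc
  Q <- matrix(0, N, N)
  b00 <- model$beta00[label]
  for (p in seq_len(N)) {
    r0 <- (p - 1) %% nr + 1
    c0 <- (p - 1) %/% nr + 1
    Q[p, p] <- 1 / b00
    for (k in seq_len(nb$n)) {
      r1 <- r0 + nb$offsets[k, 1]
      c1 <- c0 + nb$offsets[k, 2]
      if (r1 >= 1 && r1 <= nr && c1 >= 1 && c1 <= nc) {
        q1 <- (c1 - 1) * nr + r1
        s <- nb$slot[k]
        Q[p, q1] <- Q[p, q1] - model$beta[label, s] / b00
      }
    }
  }
  Q
}
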