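# Shared in-code fixtures: tiny conformers and score sets built by hand so
# most tests run without the embedding helper.

# idealized methane: four H at tetrahedral vertices, C at the origin
methane_conformer <- function() {
  s <- 1.09 / sqrt(3)
  conformer3d(
    id = "methane",
    atoms = data.frame(
      element = c("C", "H", "H", "H", "H"),
      x = c(0, s, s, -s, -s),
      y = c(0, s, -s, s, -s),
      z = c(0, s, -s, -s, s)),
    bonds = data.frame(from = 1L, to = 2:5, order = 1L))
}

# three-atom bent "molecule" with mixed elements, handy for color checks
tiny_conformer <- function(id = "tiny") {
  conformer3d(
    id = id,
    atoms = data.frame(
      element = c("O", "C", "N"),
      x = c(-1.2, 0, 1.2),
      y = c(0.3, 0, 0.3),
      z = c(0, 0, 0)),
    bonds = data.frame(from = c(1L, 2L), to = c(2L, 3L), order = 1L))
}

single_atom_conformer <- function(element = "C") {
  conformer3d(id = "atom",
              atoms = data.frame(element = element, x = 0, y = 0, z = 0),
              bonds = data.frame(from = integer(0), to = integer(0),
                                 order = integer(0)))
}

random_scores_labels <- function(n, seed, p_active = 0.4, n_levels = Inf) {
  set.seed(seed)
  scores <- stats::runif(n)
  if (is.finite(n_levels)) {
    scores <- round(scores * n_levels) / n_levels  # force ties
  }
  labels <- ifelse(stats::runif(n) < p_active, "active", "inactive")
  if (length(unique(labels)) < 2) {
    labels[1:2] <- c("active", "inactive")
  }
  list(scores = scores, labels = labels)
}

write_tmp_library <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
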