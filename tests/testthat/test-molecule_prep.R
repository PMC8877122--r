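test_that("parse_library reads well-formed CSV and TSV preserving order", {
  p <- write_tmp_library(c("id,smiles,activity_score",
                           "m1,CCO,12.5", "m2,CCC,", "m3,c1ccccc1,80"))
  lib <- parse_library(p)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$id, c("m1", "m2", "m3"))
  expect_equal(lib$activity_score, c(12.5, NA, 80))

  pt <- write_tmp_library(c("id\tsmiles\tactivity_score",
                            "t1\tCC\t5"), ext = ".tsv")
  expect_equal(parse_library(pt)$smiles, "CC")
})

test_that("parse_library handles the empty and malformed cases", {
  empty <- write_tmp_library("id,smiles,activity_score")
  expect_equal(nrow(parse_library(empty)), 0)

  nosmiles <- write_tmp_library(c("id,activity_score", "m1,5"))
  expect_error(parse_library(nosmiles), "smiles")

  badrow <- write_tmp_library(c("id,smiles,activity_score", "m1,,5"))
  expect_error(parse_library(badrow), "row")
})

test_that("curate deduplicates by canonical structure", {
  lib <- data.frame(id = c("a", "b", "c"),
                    smiles = c("CCO", "OCC", "CCC"),
                    activity_score = c(1, 2, 3), label = NA)
  out <- suppressMessages(curate(lib, curation_rules()))
  expect_equal(out$id, c("a", "c"))  # first occurrence kept
})

test_that("curate removes carbon-free records and strips salts", {
  lib <- data.frame(id = c("salt", "acetate", "organic"),
                    smiles = c("[Na+].[Cl-]", "CC(=O)O.[Na+]", "CCCC"),
                    activity_score = 1:3, label = NA)
  out <- suppressMessages(curate(lib, curation_rules()))
  expect_equal(out$id, c("acetate", "organic"))
  # the retained acetate fragment is acetic acid (4 heavy atoms), not sodium
  expect_equal(canonical_smiles(out$smiles[1]), canonical_smiles("CC(=O)O"))
})

test_that("curate is idempotent and only changes multiplicities", {
  lib <- data.frame(
    id = sprintf("r%02d", 1:6),
    smiles = c("CCO", "OCC", "CC(C)C", "C(C)(C)C", "c1ccccc1", "CCN"),
    activity_score = 1:6, label = NA)
  once <- suppressMessages(curate(lib))
  twice <- suppressMessages(curate(once))
  expect_equal(once$id, twice$id)
  expect_equal(once$smiles, twice$smiles)
  # dedup keeps exactly the set of distinct canonical structures
  expect_setequal(canonical_smiles(once$smiles),
                  unique(canonical_smiles(lib$smiles)))
})

test_that("embed_3d produces a deterministic tetrahedral methane", {
  rec <- list(id = "methane", smiles = "C")
  cf <- embed_3d(rec, seed = 42)
  expect_s3_class(cf, "conformer3d")
  expect_equal(nrow(cf$atoms), 5)
  expect_setequal(cf$atoms$element, c("C", "H"))

  # all H-C-H angles within 2 degrees of the ideal 109.47
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")])
  c_idx <- which(cf$atoms$element == "C")
  h <- xyz[-c_idx, , drop = FALSE]
  ctr <- xyz[c_idx, ]
  vecs <- sweep(h, 2, ctr)
  for (i in 1:3) for (j in (i + 1):4) {
    ang <- acos(sum(vecs[i, ] * vecs[j, ]) /
                  sqrt(sum(vecs[i, ]^2) * sum(vecs[j, ]^2))) * 180 / pi
    expect_lt(abs(ang - 109.47), 2)
  }

  cf2 <- embed_3d(rec, seed = 42)
  expect_identical(cf$atoms, cf2$atoms)  # bitwise determinism
})

test_that("embed_3d fails cleanly on invalid SMILES, carrying the id", {
  expect_error(embed_3d(list(id = "bad1", smiles = "C(")), "bad1")
})

test_that("MMFF94 minimization never increases the energy", {
  recs <- data.frame(id = c("nb", "but"),
                     smiles = c("O=[N+]([O-])c1ccccc1", "CCCC"))
  confs <- embed_library(recs, seed = 3)
  expect_length(confs, 2)
  for (cf in confs) {
    expect_false(is.na(cf$energy))
    expect_lte(cf$energy, cf$energy_pre)
  }
})

test_that("SDF write/read round-trips atoms and bonds", {
  recs <- data.frame(id = "etoh", smiles = "CCO")
  cf <- embed_library(recs, seed = 5)[[1]]
  path <- tempfile(fileext = ".sdf")
  write_sdf(list(cf), path)
  back <- read_sdf(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$id, "etoh")
  expect_equal(back[[1]]$atoms$element, cf$atoms$element)
  expect_equal(back[[1]]$bonds, cf$bonds)
  xyz0 <- as.matrix(cf$atoms[, c("x", "y", "z")])
  xyz1 <- as.matrix(back[[1]]$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(xyz0 - xyz1)), 1e-4 + 1e-12)
})

test_that("SDF io handles the empty and malformed cases", {
  path <- tempfile(fileext = ".sdf")
  write_sdf(list(), path)
  expect_length(read_sdf(path), 0)

  # truncated bond block: counts line promises 2 bonds, file has 1
  bad <- c("mol", "", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "M  END", "$$$$")
  badpath <- tempfile(fileext = ".sdf")
  writeLines(bad, badpath)
  expect_error(read_sdf(badpath), "molecule 1")
})
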