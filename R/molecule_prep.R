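#' Read a molecule library table
#'
#' Parses a CSV or TSV file with one row per chemical into a molecule library
#' data frame. The file must have a header with `id`, `smiles` and
#' `activity_score` columns; `activity_score` is a PubChem-style 0-100 score
#' and may be missing. Row order is preserved and missing scores are kept as
#' `NA`. A `label` column (`"active"`/`"inactive"`) is added as `NA`; use
#' [label_library()] to set it from the activity-score threshold.
#'
#' @param path Path to a CSV or TSV file. The separator is sniffed from the
#'   header line (tab wins over comma when both occur).
#' @return A `data.frame` with columns `id`, `smiles`, `activity_score`,
#'   `label`.
#' @seealso [curate()], [label_library()]
#' @export
parse_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  required <- c("id", "smiles", "activity_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("library file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(df$id) | df$id == "" | is.na(df$smiles) | df$smiles == "")
  if (length(bad) > 0) {
    stop("unreadable record(s) at row(s): ", paste(bad, collapse = ", "),
         " (empty id or smiles)")
  }
  score <- suppressWarnings(as.numeric(df$activity_score))
  bad_score <- which(!is.na(df$activity_score) & df$activity_score != "" &
                       is.na(score))
  if (length(bad_score) > 0) {
    stop("non-numeric activity_score at row(s): ",
         paste(bad_score, collapse = ", "))
  }
  out <- data.frame(id = as.character(df$id),
                    smiles = as.character(df$smiles),
                    activity_score = score,
                    stringsAsFactors = FALSE)
  out$label <- if ("label" %in% names(df)) as.character(df$label) else
    rep(NA_character_, nrow(out))
  out
}

#' Write a molecule library table
#'
#' @param records Molecule library data frame.
#' @param path Output path; `.tsv`/`.tab` extension writes tab-separated,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Curation rules for a molecule library
#'
#' @param drop_duplicates Keep at most one record per canonical structure
#'   (first occurrence wins). Stereochemistry is retained, so distinct
#'   stereoisomers remain distinct records.
#' @param drop_inorganic Remove records whose structure contains no carbon
#'   atom.
#' @param strip_salts For multi-fragment SMILES (salts, mixtures), retain only
#'   the largest organic fragment before deduplication.
#' @return A list of class `curation_rules`.
#' @export
curation_rules <- function(drop_duplicates = TRUE, drop_inorganic = TRUE,
                           strip_salts = TRUE) {
  stopifnot(is.logical(drop_duplicates), is.logical(drop_inorganic),
            is.logical(strip_salts))
  structure(list(drop_duplicates = drop_duplicates,
                 drop_inorganic = drop_inorganic,
                 strip_salts = strip_salts),
            class = "curation_rules")
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with Open Babel. Unparseable input yields
#' `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where invalid).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) "")
    out <- trimws(strsplit(out, "\n")[[1]][1])
    out <- sub("\t.*$", "", out)
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Heavy-atom and carbon counts per SMILES, via a coordinate-free molblock.
# Returns a data.frame(n_atoms, n_carbon); NA rows for invalid SMILES.
smiles_atom_counts <- function(smiles) {
  res <- t(vapply(smiles, function(s) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = s)),
      error = function(e) "")
    lines <- strsplit(sdf, "\n")[[1]]
    if (length(lines) < 4) return(c(NA_real_, NA_real_))
    n_at <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    if (is.na(n_at)) return(c(NA_real_, NA_real_))
    elems <- vapply(lines[seq_len(n_at) + 4L], function(l)
      trimws(substr(l, 32, 34)), character(1))
    c(n_at, sum(elems == "C"))
  }, numeric(2), USE.NAMES = FALSE))
  data.frame(n_atoms = res[, 1], n_carbon = res[, 2])
}

# Largest organic fragment of a (possibly multi-fragment) SMILES.
# Organic = contains carbon; if no fragment is organic the largest fragment
# is returned. Ties break toward the earliest fragment.
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(smiles)
  counts <- smiles_atom_counts(frags)
  if (all(is.na(counts$n_atoms))) return(smiles)
  organic <- !is.na(counts$n_carbon) & counts$n_carbon > 0
  pool <- if (any(organic)) which(organic) else which(!is.na(counts$n_atoms))
  frags[pool[which.max(counts$n_atoms[pool])]]
}

#' Curate a molecule library
#'
#' Applies salt stripping, the organic filter and structure-level
#' deduplication to a molecule library, in that order. Records whose SMILES
#' cannot be parsed are dropped (with a message, never an error), matching a
#' screening-curation workflow where individual bad records must not abort the
#' run.
#'
#' Curation is idempotent: running it twice gives the same library.
#'
#' @param records Molecule library data frame (see [parse_library()]).
#' @param rules A [curation_rules()] object.
#' @return The curated library. Attribute `n_dropped` carries a named count of
#'   drops per reason.
#' @export
curate <- function(records, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  n0 <- nrow(records)
  if (rules$strip_salts) {
    multi <- grepl(".", records$smiles, fixed = TRUE)
    records$smiles[multi] <- vapply(records$smiles[multi],
                                    largest_organic_fragment, character(1))
  }
  can <- canonical_smiles(records$smiles)
  invalid <- is.na(can)
  if (any(invalid)) {
    message(sum(invalid), " record(s) dropped: unparseable SMILES")
    records <- records[!invalid, , drop = FALSE]
    can <- can[!invalid]
  }
  n_inorganic <- 0L
  if (rules$drop_inorganic && nrow(records) > 0) {
    counts <- smiles_atom_counts(can)
    inorganic <- is.na(counts$n_carbon) | counts$n_carbon == 0
    n_inorganic <- sum(inorganic)
    if (n_inorganic > 0) {
      message(n_inorganic, " record(s) dropped: no carbon atoms")
      records <- records[!inorganic, , drop = FALSE]
      can <- can[!inorganic]
    }
  }
  n_dup <- 0L
  if (rules$drop_duplicates && nrow(records) > 0) {
    keep <- !duplicated(can)
    n_dup <- sum(!keep)
    if (n_dup > 0) {
      message(n_dup, " record(s) dropped: duplicate canonical structure")
      records <- records[keep, , drop = FALSE]
    }
  }
  rownames(records) <- NULL
  structure(records,
            n_dropped = c(invalid_smiles = sum(invalid),
                          inorganic = n_inorganic,
                          duplicate = n_dup))
}

# ---------------------------------------------------------------------------
# 3D conformers

#' Construct a 3D conformer object
#'
#' @param id Molecule identifier.
#' @param atoms `data.frame` with columns `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom) and optionally `chg` (V2000 charge code).
#' @param bonds `data.frame` with columns `from`, `to` (1-based atom indices)
#'   and `order` (integer bond order).
#' @param energy MMFF94 energy (kcal/mol) of the conformer, or `NA`.
#' @param energy_pre Pre-minimization MMFF94 energy, or `NA`.
#' @return An object of class `conformer3d`.
#' @export
conformer3d <- function(id, atoms, bonds, energy = NA_real_,
                        energy_pre = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)),
            nrow(atoms) >= 1)
  if (is.null(atoms$chg)) atoms$chg <- 0L
  if (nrow(bonds) > 0) {
    stopifnot(all(c("from", "to", "order") %in% names(bonds)),
              all(bonds$from >= 1), all(bonds$to >= 1),
              all(bonds$from <= nrow(atoms)), all(bonds$to <= nrow(atoms)))
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 energy = energy, energy_pre = energy_pre),
            class = "conformer3d")
}

#' @export
print.conformer3d <- function(x, ...) {
  cat("<conformer3d> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$energy)) cat(sprintf(", MMFF94 energy %.3f kcal/mol", x$energy))
  cat("\n")
  invisible(x)
}

find_python <- function() {
  py <- getOption("snapqsar.python", "")
  if (nzchar(py)) return(py)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found on the PATH; ",
       "set options(snapqsar.python = ...)")
}

#' Generate MMFF94-minimized 3D conformers
#'
#' Embeds one low-energy conformer per molecule: distance-geometry embedding
#' (ETKDG) with an explicit random seed followed by MMFF94 force-field
#' minimization, run through RDKit. The same seed always reproduces the same
#' coordinates bit for bit. Hydrogens are made explicit. Embedding is retried
#' up to 5 times per molecule with incremented seeds before the molecule is
#' reported as failed.
#'
#' @param records Molecule library data frame with `id` and `smiles` columns.
#' @param seed Integer random seed for the embedding.
#' @return A list of [conformer3d()] objects, one per successfully embedded
#'   molecule, each carrying its pre- and post-minimization MMFF94 energies.
#'   Attribute `failures` is a `data.frame(id, reason)` of per-molecule
#'   failures.
#' @export
embed_library <- function(records, seed = 1L) {
  stopifnot(nrow(records) >= 1, !anyNA(records$smiles))
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(records$id, records$smiles, sep = "\t"), infile)
  script <- system.file("python", "embed3d.py", package = "snapqsar")
  out <- suppressWarnings(
    system2(find_python(), c(shQuote(script), shQuote(infile),
                             as.integer(seed), shQuote(outfile)),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("3D embedding helper failed (exit ", status, ")")
  }
  fail_lines <- grep("^FAIL\t", out, value = TRUE)
  failures <- if (length(fail_lines) > 0) {
    parts <- strsplit(fail_lines, "\t")
    data.frame(id = vapply(parts, `[`, "", 2),
               reason = vapply(parts, `[`, "", 3))
  } else {
    data.frame(id = character(0), reason = character(0))
  }
  confs <- if (file.exists(outfile) && file.size(outfile) > 0) {
    read_sdf(outfile)
  } else {
    list()
  }
  structure(confs, failures = failures)
}

#' Embed a single molecule
#'
#' Single-molecule wrapper around [embed_library()]. Fails with an error
#' carrying the molecule id if the SMILES is invalid or embedding fails.
#'
#' @param record One-row molecule library data frame, or a list with `id` and
#'   `smiles`.
#' @param seed Integer random seed.
#' @return A [conformer3d()] object.
#' @export
embed_3d <- function(record, seed = 1L) {
  df <- data.frame(id = as.character(record$id),
                   smiles = as.character(record$smiles))
  confs <- embed_library(df, seed = seed)
  if (length(confs) == 0) {
    failures <- attr(confs, "failures")
    reason <- if (nrow(failures) > 0) failures$reason[1] else "unknown"
    stop("embedding failed for molecule '", df$id, "': ", reason)
  }
  confs[[1]]
}

# ---------------------------------------------------------------------------
# SDF I/O (V2000)

fmt_coord <- function(x) formatC(round(x, 4), format = "f", digits = 4,
                                 width = 10)

#' Write conformers to an SD file (V2000)
#'
#' @param conformers List of [conformer3d()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  blocks <- vapply(conformers, function(cf) {
    stopifnot(inherits(cf, "conformer3d"))
    at <- cf$atoms
    bd <- cf$bonds
    lines <- c(
      cf$id, "  snapqsar", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(at), nrow(bd)),
      sprintf("%s%s%s %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
              fmt_coord(at$x), fmt_coord(at$y), fmt_coord(at$z),
              at$element, as.integer(at$chg)))
    if (nrow(bd) > 0) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                as.integer(bd$from), as.integer(bd$to),
                                as.integer(bd$order)))
    }
    prop <- character(0)
    if (!is.na(cf$energy)) {
      prop <- c(prop, ">  <energy>", format(cf$energy, digits = 17), "")
    }
    if (!is.na(cf$energy_pre)) {
      prop <- c(prop, ">  <energy_pre>", format(cf$energy_pre, digits = 17),
                "")
    }
    paste(c(lines, "M  END", prop, "$$$$"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read conformers from an SD file (V2000)
#'
#' @param path Path to a V2000 SD file.
#' @return List of [conformer3d()] objects. Malformed molecule blocks raise an
#'   error naming the molecule index.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  if (all(!nzchar(trimws(txt)))) return(list())
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(path))),
    error = function(e) stop("cannot parse SDF '", path, "': ",
                             conditionMessage(e)))
  lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    header <- ChemmineR::header(sdf)
    counts_line <- header[["Counts_Line"]]
    n_at <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
    n_bd <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
    if (is.na(n_at) || nrow(ab) != n_at ||
        (is.matrix(bb) && !is.na(n_bd) && nrow(bb) != n_bd)) {
      stop("malformed SDF block for molecule ", i, " in '", path, "'")
    }
    atoms <- data.frame(
      element = sub("_.*$", "", rownames(ab)),
      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
      chg = if (ncol(ab) >= 5) as.integer(ab[, 5]) else 0L)
    if (anyDuplicated(atoms[, c("x", "y", "z")]) > 0) {
      stop("molecule ", i, " in '", path,
           "' has two atoms at identical coordinates")
    }
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      if (anyNA(bb[, 1:3]) ||
          any(bb[, 1] < 1 | bb[, 1] > n_at | bb[, 2] < 1 | bb[, 2] > n_at)) {
        stop("malformed bond block for molecule ", i, " in '", path, "'")
      }
      data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else {
      data.frame(from = integer(0), to = integer(0), order = integer(0))
    }
    dt <- ChemmineR::datablock(sdf)
    # property names may carry a "  (n)" record suffix; strip it
    names(dt) <- trimws(sub("\\(\\d+\\)\\s*$", "", names(dt)))
    energy <- if ("energy" %in% names(dt)) as.numeric(dt[["energy"]]) else
      NA_real_
    energy_pre <- if ("energy_pre" %in% names(dt))
      as.numeric(dt[["energy_pre"]]) else NA_real_
    conformer3d(id = header[["Molecule_Name"]], atoms = atoms, bonds = bonds,
                energy = energy, energy_pre = energy_pre)
  })
}
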