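#' Read protein chains from a structure file
#'
#' Parses a PDB or mmCIF file and extracts one [protein_chain()] per polymer
#' chain. Only `ATOM` Calpha records are used; residues are ordered by
#' residue number (insertion codes lexicographically after their base
#' number), and residues lacking a Calpha atom are dropped and counted in a
#' warning. Chains left with fewer than 3 usable Calpha atoms are skipped
#' with a warning — such traces carry no tertiary-structure signal.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"` (dispatch on extension: `.cif`/`.mmcif` vs
#'   `.pdb`/`.ent`), `"pdb"`, or `"mmcif"`.
#' @param id Base identifier for the returned chains; defaults to the file
#'   name without extension. Multi-chain files get `<id>_<chain>` ids.
#' @return A list of [protein_chain()] objects (possibly empty).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("structure file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     cif = , mmcif = "mmcif",
                     pdb = , ent = "pdb",
                     rlang::abort(sprintf(
                       "cannot infer format from extension '.%s'; pass `format`", ext)))
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  atoms <- switch(format,
                  pdb = read_pdb_atoms(path),
                  mmcif = read_mmcif_atoms(path))
  atoms_to_chains(atoms, id)
}

# internal: ATOM table from a PDB file via bio3d
read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) {
      rlang::abort(sprintf("failed to parse PDB file %s: %s", path,
                           conditionMessage(e)))
    })
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  tibble::tibble(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    x = a$x, y = a$y, z = a$z
  )
}

# internal: ATOM table from an mmCIF file; name-aware `_atom_site` loop
# parser (column order in the loop header is honoured, not assumed).
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  atoms <- NULL
  for (ls in loop_starts) {
    j <- ls + 1L
    cols <- character()
    while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
      cols <- c(cols, trimws(lines[j]))
      j <- j + 1L
    }
    if (!any(startsWith(cols, "_atom_site."))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || ln == "#" || startsWith(ln, "loop_") ||
          startsWith(ln, "_") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                        quiet = TRUE)
      j <- j + 1L
    }
    if (!length(rows)) {
      rlang::abort(sprintf("mmCIF `_atom_site` loop in %s has no data rows", path))
    }
    nfield <- lengths(rows)
    if (any(nfield != length(cols))) {
      bad <- which(nfield != length(cols))[1L]
      rlang::abort(sprintf(
        "mmCIF parse error in %s: atom_site row %d has %d fields, expected %d",
        path, bad, nfield[bad], length(cols)))
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_atom_site\\.", "", cols)
    atoms <- m
    break
  }
  if (is.null(atoms)) {
    rlang::abort(sprintf("no `_atom_site` loop found in %s", path))
  }
  need <- c("group_PDB", "label_comp_id", "label_atom_id",
            "Cartn_x", "Cartn_y", "Cartn_z")
  missing_cols <- setdiff(need, colnames(atoms))
  if (length(missing_cols)) {
    rlang::abort(sprintf("mmCIF file %s lacks atom_site fields: %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  col_or <- function(nm, default) {
    if (nm %in% colnames(atoms)) atoms[, nm] else rep(default, nrow(atoms))
  }
  chain <- col_or("auth_asym_id", NA)
  if (all(is.na(chain))) chain <- col_or("label_asym_id", "A")
  resno <- col_or("auth_seq_id", NA)
  if (all(is.na(resno))) resno <- col_or("label_seq_id", "1")
  ins <- col_or("pdbx_PDB_ins_code", "")
  ins[ins %in% c("?", ".")] <- ""
  keep <- atoms[, "group_PDB"] == "ATOM"
  tibble::tibble(
    chain = as.character(chain[keep]),
    resno = suppressWarnings(as.integer(resno[keep])),
    insert = ins[keep],
    resid = atoms[keep, "label_comp_id"],
    elety = atoms[keep, "label_atom_id"],
    x = as.numeric(atoms[keep, "Cartn_x"]),
    y = as.numeric(atoms[keep, "Cartn_y"]),
    z = as.numeric(atoms[keep, "Cartn_z"])
  )
}

# internal: per-chain Calpha extraction shared by both readers
atoms_to_chains <- function(atoms, id) {
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    rlang::abort("structure file contains non-finite coordinates")
  }
  chains <- list()
  chain_ids <- unique(atoms$chain)
  multi <- length(chain_ids) > 1L
  for (cid in chain_ids) {
    a <- atoms[atoms$chain == cid, , drop = FALSE]
    # one row per residue, in residue-number order (insert codes after base)
    res_key <- paste(a$resno, a$insert, sep = "|")
    res <- a[!duplicated(res_key), c("resno", "insert"), drop = FALSE]
    res <- res[order(res$resno, res$insert), , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    ca_key <- paste(ca$resno, ca$insert, sep = "|")
    ca <- ca[!duplicated(ca_key), , drop = FALSE]
    ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
    n_missing <- nrow(res) - nrow(ca)
    if (n_missing > 0L) {
      rlang::warn(sprintf(
        "chain %s: %d residue(s) without a Calpha atom dropped", cid, n_missing))
    }
    if (nrow(ca) < 3L) {
      rlang::warn(sprintf(
        "chain %s skipped: only %d usable Calpha atom(s) (minimum 3)",
        cid, nrow(ca)))
      next
    }
    seq1 <- paste(three_to_one(ca$resid), collapse = "")
    cid_out <- if (multi) paste0(id, "_", cid) else id
    chains[[length(chains) + 1L]] <-
      protein_chain(cid_out, seq1, cbind(ca$x, ca$y, ca$z))
  }
  chains
}

# internal: three-letter -> one-letter residue codes; unknowns become X
three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(toupper(resid)))
  out[is.na(out) | !nzchar(out)] <- "X"
  out
}

one_to_three <- function(seq1) {
  out <- suppressWarnings(bio3d::aa123(strsplit(seq1, "")[[1]]))
  out[is.na(out) | !nzchar(out)] <- "UNK"
  out
}

#' Write a chain as a PDB file
#'
#' Emits fixed-width `ATOM` records (Calpha only), one `TER`, and `END`.
#' PDB's chain-id field is a single character, so longer identifiers are
#' truncated to their first character in the file (the full id survives only
#' in memory); a message notes the truncation. Coordinates are written at the
#' format's fixed 3-decimal precision, so a parse-after-write round trip is
#' exact to 1e-3 Angstrom.
#'
#' @param chain A [protein_chain()].
#' @param path Output file path.
#' @param format Only `"pdb"` is supported.
#' @return Invisibly, `path`.
#' @export
write_chain <- function(chain, path, format = "pdb") {
  stopifnot(inherits(chain, "protein_chain"))
  format <- match.arg(format, "pdb")
  cid <- chain$id
  if (nchar(cid) > 1L) {
    rlang::inform(sprintf(
      "chain id '%s' truncated to '%s' in the PDB chain-id field",
      cid, substr(cid, 1L, 1L)))
  }
  cid1 <- substr(cid, 1L, 1L)
  res3 <- one_to_three(chain$sequence)
  n <- chain_length(chain)
  xyz <- chain$ca_coords
  rec <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), res3, cid1, seq_len(n), xyz[, 1L], xyz[, 2L], xyz[, 3L])
  ter <- sprintf("TER   %5d      %3s %1s%4d", n + 1L, res3[n], cid1, n)
  ok <- tryCatch({
    writeLines(c(rec, ter, "END"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rlang::abort(sprintf("cannot write PDB file to %s", path))
  invisible(path)
}
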