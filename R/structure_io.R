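# Minimal PDB / mmCIF (PDBx _atom_site) readers and writers. No pre-installed
# R package in this stack parses macromolecular coordinate files, so the small
# subset needed here (ATOM/HETATM inventories, altloc collapse, author
# numbering) is implemented directly.

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Load a structure file into a ternary-complex object
#'
#' Parses a PDB or mmCIF file into a uniform atom table. Alternate locations
#' are collapsed to the highest-occupancy conformer (ties broken by altloc id,
#' lexicographically first wins) and waters are excluded. Chain roles are left
#' unassigned; see [assign_roles()].
#'
#' @param path path to a structure file
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, falling back to
#'   content sniffing)
#' @param source provenance tag, `"experimental"` or `"predicted"`
#' @param complex_id identifier; defaults to the file base name
#' @return a `ternary_complex` object: list with `complex_id`, `atoms`
#'   (data.frame: chain, resno, ins, resname, atom, altloc, element, x, y, z,
#'   occ, het), `source`, `roles`, `copies`
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = c("experimental", "predicted"),
                           complex_id = NULL) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      head1 <- readLines(path, n = 5L, warn = FALSE)
      if (any(grepl("^data_|_atom_site\\.", head1))) "mmcif" else "pdb"
    }
  }
  atoms <- switch(format, pdb = .parse_pdb(path), mmcif = .parse_mmcif(path))
  atoms <- atoms[!(atoms$resname %in% .WATER_RESNAMES), , drop = FALSE]
  atoms <- .collapse_altloc(atoms)
  if (nrow(atoms[!atoms$het, , drop = FALSE]) == 0) {
    stop("empty structure: no protein (ATOM) records in ", path)
  }
  structure(list(
    complex_id = complex_id %||% sub("\\.[^.]*$", "", basename(path)),
    atoms = atoms,
    source = source,
    roles = NULL,
    copies = NULL,
    ub_windows = list()
  ), class = "ternary_complex")
}

.parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  if (length(lines) == 0) stop("format error: no ATOM/HETATM records in ", path)
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (any(is.na(x) | is.na(y) | is.na(z) | is.na(resno))) {
    stop("format error: malformed ATOM record in ", path)
  }
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(lines, 77, 78)))
  atom <- trimws(substr(lines, 13, 16))
  elem[elem == ""] <- toupper(substr(gsub("[0-9]", "", atom), 1, 1))
  data.frame(
    chain = trimws(substr(lines, 22, 22)),
    resno = resno,
    ins = trimws(substr(lines, 27, 27)),
    resname = trimws(substr(lines, 18, 20)),
    atom = atom,
    altloc = trimws(substr(lines, 17, 17)),
    element = elem,
    x = x, y = y, z = z,
    occ = occ,
    het = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Tokenize one mmCIF data line, honouring single/double quotes.
.cif_tokens <- function(line) {
  out <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", out)
}

.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- grep("^\\s*loop_\\s*$", lines)
  atoms <- NULL
  for (start in i) {
    j <- start + 1L
    fields <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1L
    }
    if (!length(fields) || !all(startsWith(fields, "_atom_site."))) next
    rows <- character()
    while (j <= length(lines)) {
      ln <- lines[j]
      if (grepl("^\\s*(loop_|_|#|data_)", ln) || !nzchar(trimws(ln))) break
      rows <- c(rows, ln); j <- j + 1L
    }
    toks <- lapply(rows, .cif_tokens)
    nf <- length(fields)
    if (any(vapply(toks, length, 1L) != nf)) {
      stop("format error: ragged _atom_site loop in ", path)
    }
    m <- do.call(rbind, toks)
    colnames(m) <- sub("^_atom_site\\.", "", fields)
    atoms <- m
    break
  }
  if (is.null(atoms)) stop("format error: no _atom_site loop in ", path)
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% colnames(atoms)) return(atoms[, nm])
    if (!is.null(alt) && alt %in% colnames(atoms)) return(atoms[, alt])
    rep(default, nrow(atoms))
  }
  clean <- function(v) ifelse(v %in% c(".", "?"), "", v)
  resno <- suppressWarnings(as.integer(clean(get("auth_seq_id", "label_seq_id"))))
  if (any(is.na(resno))) stop("format error: unparseable residue numbers in ", path)
  occ <- suppressWarnings(as.numeric(clean(get("occupancy", default = "1"))))
  occ[is.na(occ)] <- 1
  data.frame(
    chain = clean(get("auth_asym_id", "label_asym_id")),
    resno = resno,
    ins = clean(get("pdbx_PDB_ins_code")),
    resname = clean(get("auth_comp_id", "label_comp_id")),
    atom = clean(get("label_atom_id", "auth_atom_id")),
    altloc = clean(get("label_alt_id")),
    element = toupper(clean(get("type_symbol"))),
    x = as.numeric(clean(get("Cartn_x"))),
    y = as.numeric(clean(get("Cartn_y"))),
    z = as.numeric(clean(get("Cartn_z"))),
    occ = occ,
    het = get("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Keep, per (chain, resno, ins, atom), the highest-occupancy altloc;
# ties broken by lexicographic altloc id.
.collapse_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Write a complex as a PDB file
#' @param complex a `ternary_complex`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(complex, path) {
  at <- complex$atoms
  rec <- ifelse(at$het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(at$atom) < 4, sprintf(" %-3s", at$atom), at$atom)
  lines <- sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(at)), name, "", at$resname, at$chain, at$resno,
    ifelse(at$ins == "", " ", at$ins), at$x, at$y, at$z, at$occ, 0, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a complex as an mmCIF file
#' @inheritParams write_pdb
#' @export
write_mmcif <- function(complex, path) {
  at <- complex$atoms
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", complex$complex_id)),
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "label_atom_id", "label_alt_id", "auth_comp_id",
      "auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "type_symbol"
    ))
  )
  rows <- sprintf(
    "%s %d %s %s %s %s %d %s %.3f %.3f %.3f %.3f %s",
    ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)), at$atom,
    ifelse(at$altloc == "", ".", at$altloc), at$resname, at$chain, at$resno,
    ifelse(at$ins == "", "?", at$ins), at$x, at$y, at$z, at$occ, at$element
  )
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Read a reference registry TSV
#'
#' The registry supplies the curated annotations the pipeline needs: the
#' 76-residue ubiquitin sequence, E2 sequences with catalytic cysteine and
#' crossover-helix span, and E3 sequences. Columns: `gene`, `uniprot`, `type`
#' (UB/E2/E3), `sequence`, `catalytic_cys`, `helix_start`, `helix_end`
#' (NA where not applicable).
#'
#' @param path TSV file
#' @return list with `ubiquitin_seq` (string), `e2` and `e3` (data.frames)
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "type", "sequence")
  if (!all(need %in% names(df))) {
    stop("registry must have columns: ", paste(need, collapse = ", "))
  }
  for (nm in c("catalytic_cys", "helix_start", "helix_end")) {
    if (!nm %in% names(df)) df[[nm]] <- NA_integer_
  }
  ub <- df$sequence[df$type == "UB"]
  if (length(ub) != 1 || nchar(ub) != 76) {
    stop("registry must contain exactly one UB entry with a 76-residue sequence")
  }
  e2 <- df[df$type == "E2", , drop = FALSE]
  bad <- !is.na(e2$catalytic_cys) &
    substr(e2$sequence, e2$catalytic_cys, e2$catalytic_cys) != "C"
  if (any(bad)) {
    stop("catalytic_cys does not point to C for: ",
         paste(e2$gene[bad], collapse = ", "))
  }
  list(ubiquitin_seq = ub, e2 = e2, e3 = df[df$type == "E3", , drop = FALSE])
}
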