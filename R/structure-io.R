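#' @importFrom stats sd setNames
#' @importFrom utils head tail
NULL

# Two-letter element symbols we try before falling back to one letter when a
# coordinate file leaves the element column blank.
.two_letter_elements <- c(
  "FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI", "CO", "SE",
  "CD", "HG", "MO", "AL", "SI", "LI", "BE"
)

#' Construct a structure model from an atom table
#'
#' A `StructureModel` is the unit every measurement in this package
#' consumes: a flat, ordered atom table (one row per atom) carrying chain,
#' author residue numbering, insertion code, residue and atom names,
#' coordinates in Angstrom, occupancy, altloc and isotropic B, plus flags
#' for HETATM records, hydrogens and waters.
#'
#' Atoms are ordered by chain (order of first appearance), then by
#' `(resseq, icode)`, then by original file order within a residue. After
#' altloc resolution (see [resolve_altlocs()]) a model holds at most one
#' atom per `(chain, resseq, icode, atom)`.
#'
#' @param atoms data.frame with columns `chain`, `resseq`, `icode`,
#'   `resname`, `atom`, `altloc`, `x`, `y`, `z`, `occ`, `b`, `element`,
#'   `het`, `hydrogen`, `water`.
#' @param id accession or label string.
#' @param source_format `"pdb"`, `"mmcif"` or `"generated"`.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, id = "model", source_format = "generated") {
  required <- c("chain", "resseq", "icode", "resname", "atom", "altloc",
                "x", "y", "z", "occ", "b", "element", "het", "hydrogen",
                "water")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("a StructureModel needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  if (any(!nzchar(atoms$atom))) stop("empty atom name")
  atoms$resname <- toupper(atoms$resname)
  chain_order <- unique(atoms$chain)
  ord <- order(match(atoms$chain, chain_order), atoms$resseq, atoms$icode)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(id = id, source_format = source_format, atoms = atoms),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel '%s' (%s): %d chains, %d residues, %d atoms\n",
              x$id, x$source_format, length(unique(a$chain)),
              nrow(unique(a[, c("chain", "resseq", "icode")])), nrow(a)))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model StructureModel
#' @return character vector in model order
#' @export
model_chains <- function(model) unique(model$atoms$chain)

.infer_element <- function(name) {
  vapply(name, function(nm) {
    letters_only <- gsub("[^A-Za-z]", "", toupper(nm))
    if (nchar(letters_only) == 0L) return("X")
    two <- substr(letters_only, 1L, 2L)
    if (two %in% .two_letter_elements && nchar(letters_only) >= 2L &&
        !(substr(letters_only, 1L, 1L) %in% c("C", "N", "O", "H", "S", "P") &&
          nchar(gsub("[^A-Za-z]", "", nm)) > 1L)) {
      # ambiguous cases like "CA" (calcium vs C-alpha) are resolved by the
      # caller via the HETATM flag; protein "CA"/"CB" etc. fall through here
      return(two)
    }
    substr(letters_only, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Resolve alternate locations deterministically
#'
#' Keeps, for every `(chain, resseq, icode, atom)` group, the conformer
#' with the highest occupancy; ties are broken by the lexicographically
#' smallest altloc identifier. The resolution report (one row per dropped
#' atom) is attached as attribute `"altloc_report"`.
#'
#' @param model StructureModel possibly carrying altloc duplicates
#' @return StructureModel with at most one atom per site
#' @export
resolve_altlocs <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resseq, a$icode, a$atom, sep = "\r")
  if (!anyDuplicated(key)) {
    attr(model, "altloc_report") <- data.frame()
    return(model)
  }
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    ord <- order(-a$occ[idx], a$altloc[idx])
    keep[idx[-ord[1L]]] <- FALSE
  }
  dropped <- a[!keep, c("chain", "resseq", "icode", "atom", "altloc", "occ")]
  model$atoms <- a[keep, , drop = FALSE]
  rownames(model$atoms) <- NULL
  attr(model, "altloc_report") <- dropped
  model
}

.parse_pdb_lines <- function(lines, id, path = "<text>") {
  rec <- substr(lines, 1, 6)
  atom_mask <- rec %in% c("ATOM  ", "HETATM")
  if (!any(atom_mask)) {
    stop("no ATOM/HETATM records in PDB input: ", path)
  }
  al <- lines[atom_mask]
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad) > 0L) {
      stop(sprintf("malformed %s field in %s at atom record %d: '%s'",
                   what, path, bad[1L], s[bad[1L]]))
    }
    v
  }
  name <- trimws(substr(al, 13, 16))
  if (any(!nzchar(name))) {
    stop("empty atom-name field in ", path, " at atom record ",
         which(!nzchar(name))[1L])
  }
  element <- trimws(substr(al, 77, 78))
  resname <- trimws(substr(al, 18, 20))
  no_el <- !nzchar(element)
  if (any(no_el)) element[no_el] <- .infer_element(name[no_el])
  occ <- num(substr(al, 55, 60), "occupancy", al)
  occ[is.na(occ)] <- 1
  b <- num(substr(al, 61, 66), "b-factor", al)
  b[is.na(b)] <- 0
  atoms <- data.frame(
    chain = substr(al, 22, 22),
    resseq = as.integer(num(substr(al, 23, 26), "residue number", al)),
    icode = trimws(substr(al, 27, 27)),
    resname = resname,
    atom = name,
    altloc = trimws(substr(al, 17, 17)),
    x = num(substr(al, 31, 38), "x coordinate", al),
    y = num(substr(al, 39, 46), "y coordinate", al),
    z = num(substr(al, 47, 54), "z coordinate", al),
    occ = pmin(pmax(occ, 0), 1),
    b = b,
    element = toupper(element),
    het = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$resseq))) {
    stop("malformed residue number in ", path)
  }
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atoms$water <- atoms$resname %in% .water_names
  structure_model(atoms, id = id, source_format = "pdb")
}

.split_pdb_models <- function(lines) {
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) == 0L) return(list(lines))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  lapply(seq_along(model_starts), function(i) {
    lines[(model_starts[i] + 1L):(model_ends[i] - 1L)]
  })
}

.parse_mmcif_tokens <- function(text) {
  # tokenizes a line of mmCIF data respecting single/double quotes
  scan(text = text, what = "character", quiet = TRUE, quote = "'\"")
}

.parse_mmcif <- function(lines, id, path = "<text>") {
  loop_rows <- grep("^\\s*loop_\\s*$", lines)
  site_rows <- grep("^_atom_site\\.", lines)
  if (length(site_rows) == 0L) stop("no _atom_site category in mmCIF input: ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[site_rows]))
  data_start <- max(site_rows) + 1L
  data_end <- data_start
  n <- length(lines)
  while (data_end <= n) {
    ln <- trimws(lines[data_end])
    if (ln == "" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "#") || startsWith(ln, "data_")) break
    data_end <- data_end + 1L
  }
  data_lines <- lines[data_start:(data_end - 1L)]
  toks <- lapply(data_lines, .parse_mmcif_tokens)
  nf <- length(fields)
  bad <- which(vapply(toks, length, integer(1)) != nf)
  if (length(bad) > 0L) {
    stop(sprintf("malformed atom_site row %d in %s: expected %d fields",
                 bad[1L], path, nf))
  }
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(primary, fallback = NULL, default = NA_character_) {
    if (primary %in% fields) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fields) return(m[, fallback])
    rep(default, nrow(m))
  }
  dot_blank <- function(v) { v[v %in% c(".", "?")] <- ""; v }
  model_num <- get("pdbx_PDB_model_num", default = "1")
  keep <- model_num == model_num[1L]  # model 1 only for single-model reads
  grp <- get("group_PDB", default = "ATOM")
  resname <- dot_blank(get("auth_comp_id", "label_comp_id"))
  element <- toupper(dot_blank(get("type_symbol")))
  name <- dot_blank(get("auth_atom_id", "label_atom_id"))
  no_el <- !nzchar(element)
  if (any(no_el)) element[no_el] <- .infer_element(name[no_el])
  atoms <- data.frame(
    chain = dot_blank(get("auth_asym_id", "label_asym_id")),
    resseq = as.integer(get("auth_seq_id", "label_seq_id")),
    icode = dot_blank(get("pdbx_PDB_ins_code", default = "")),
    resname = resname,
    atom = name,
    altloc = dot_blank(get("label_alt_id", default = "")),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = { o <- as.numeric(get("occupancy", default = "1")); o[is.na(o)] <- 1; pmin(pmax(o, 0), 1) },
    b = { bb <- as.numeric(get("B_iso_or_equiv", default = "0")); bb[is.na(bb)] <- 0; bb },
    element = element,
    het = grp == "HETATM",
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))) {
    stop("malformed coordinates in mmCIF input: ", path)
  }
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  atoms$water <- atoms$resname %in% .water_names
  structure_model(atoms, id = id, source_format = "mmcif")
}

#' Parse a macromolecular coordinate file
#'
#' Reads PDB (v3.3 fixed-column) or mmCIF (`atom_site` category) input into
#' a [structure_model()]. Alternate locations are resolved deterministically
#' (highest occupancy, ties to the lexicographically smallest altloc);
#' hydrogens and waters are retained but flagged so downstream measurements
#' can exclude them. For multi-model files, model 1 is returned unless
#' `ensemble = TRUE`, in which case a list of models (one per MODEL block)
#' is returned.
#'
#' @param source path to a file, or a character vector of lines.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (sniffed from the file
#'   extension, falling back to content).
#' @param id label for the resulting model; defaults to the file stem.
#' @param ensemble if TRUE and the input is a multi-model PDB file, return
#'   a list of StructureModels.
#' @return StructureModel, or list of StructureModels when `ensemble = TRUE`.
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif"),
                            id = NULL, ensemble = FALSE) {
  format <- match.arg(format)
  if (length(source) == 1L && !grepl("\n", source) &&
      (file.exists(source) || grepl("\\.(pdb|ent|cif|mmcif)$", source,
                                    ignore.case = TRUE))) {
    if (!file.exists(source)) stop("cannot read file: ", source)
    path <- source
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(source))
  } else {
    path <- "<text>"
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(id)) id <- "model"
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
                  any(grepl("^_atom_site\\.", head(lines, 2000L)))) {
      "mmcif"
    } else if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE) ||
               any(grepl("^(ATOM  |HETATM|HEADER|MODEL )", head(lines, 2000L)))) {
      "pdb"
    } else {
      stop("cannot determine format of ", path,
           "; pass format = 'pdb' or 'mmcif'")
    }
  }
  if (format == "mmcif") {
    model <- resolve_altlocs(.parse_mmcif(lines, id, path))
    return(model)
  }
  blocks <- .split_pdb_models(lines)
  if (ensemble && length(blocks) > 1L) {
    models <- lapply(seq_along(blocks), function(i) {
      resolve_altlocs(.parse_pdb_lines(blocks[[i]], sprintf("%s:%d", id, i),
                                       path))
    })
    return(models)
  }
  resolve_altlocs(.parse_pdb_lines(blocks[[1L]], id, path))
}

.pdb_atom_name_field <- function(name, element) {
  # names of up to 3 characters for 1-letter elements start in column 14
  vapply(seq_along(name), function(i) {
    nm <- name[i]
    if (nchar(nm) >= 4L || nchar(element[i]) >= 2L) {
      sprintf("%-4s", substr(nm, 1, 4))
    } else {
      sprintf(" %-3s", nm)
    }
  }, character(1))
}

#' Write a model (or ensemble) as a PDB file
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records. Coordinates are written
#' at the format's 0.001 A precision, which bounds the round-trip error of
#' [parse_structure()] on the written file.
#'
#' @param model StructureModel, or list of StructureModels (written as
#'   MODEL/ENDMDL blocks sharing a topology).
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  fmt_block <- function(m) {
    a <- m$atoms
    rec <- ifelse(a$het, "HETATM", "ATOM  ")
    sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, seq_len(nrow(a)) %% 100000L,
            .pdb_atom_name_field(a$atom, a$element),
            a$altloc, substr(a$resname, 1, 3), a$chain, a$resseq,
            ifelse(nzchar(a$icode), a$icode, " "),
            a$x, a$y, a$z, a$occ, a$b, substr(a$element, 1, 2))
  }
  if (inherits(model, "StructureModel")) {
    lines <- c(fmt_block(model), "END")
  } else {
    lines <- unlist(lapply(seq_along(model), function(i) {
      c(sprintf("MODEL %8d", i), fmt_block(model[[i]]), "ENDMDL")
    }))
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build an explicit atom selection
#'
#' An `AtomSelection` is an ordered table of `(chain, resseq, icode, atom)`
#' items; order is preserved through [select_atoms()] regardless of file
#' order. Duplicate items are forbidden.
#'
#' @param chain,resseq,atom vectors (recycled to a common length)
#' @param icode insertion codes, default blank
#' @return AtomSelection (data.frame subclass)
#' @export
atom_selection <- function(chain, resseq, atom, icode = "") {
  n <- max(length(chain), length(resseq), length(atom))
  sel <- data.frame(chain = rep_len(as.character(chain), n),
                    resseq = rep_len(as.integer(resseq), n),
                    icode = rep_len(as.character(icode), n),
                    atom = rep_len(as.character(atom), n),
                    stringsAsFactors = FALSE)
  key <- paste(sel$chain, sel$resseq, sel$icode, sel$atom, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate items in atom selection")
  class(sel) <- c("AtomSelection", "data.frame")
  sel
}

#' Combine atom selections preserving order
#' @param ... AtomSelection objects
#' @return AtomSelection
#' @export
c_selection <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  atom_selection(out$chain, out$resseq, out$atom, out$icode)
}

#' Expand segment specifications against a model
#'
#' A segment names a chain and an inclusive author-numbering residue range;
#' expansion enumerates, in residue order, the requested atom names of every
#' residue of the model falling in the range. This is how loop and core
#' segments from a site definition become concrete selections.
#'
#' @param model StructureModel
#' @param segments list of lists with elements `chain`, `start`, `end`
#' @param atoms atom names requested per residue (default backbone N, CA,
#'   C, O)
#' @param chain_override optionally measure the same segments on a
#'   different chain id (used for chain pairing)
#' @return AtomSelection of the atoms actually present in the model
#' @export
expand_segments <- function(model, segments, atoms = c("N", "CA", "C", "O"),
                            chain_override = NULL) {
  a <- model$atoms
  rows <- lapply(segments, function(seg) {
    ch <- if (is.null(chain_override)) seg$chain else chain_override
    res <- a[a$chain == ch & a$resseq >= seg$start & a$resseq <= seg$end &
               !a$water, , drop = FALSE]
    res <- unique(res[, c("chain", "resseq", "icode")])
    if (nrow(res) == 0L) return(NULL)
    data.frame(chain = rep(res$chain, each = length(atoms)),
               resseq = rep(res$resseq, each = length(atoms)),
               icode = rep(res$icode, each = length(atoms)),
               atom = rep(atoms, times = nrow(res)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("segment expansion selected no residues")
  }
  # keep only atoms that exist (e.g. Gly has no CB); order is preserved
  key_model <- paste(a$chain, a$resseq, a$icode, a$atom, sep = "\r")
  key_sel <- paste(out$chain, out$resseq, out$icode, out$atom, sep = "\r")
  out <- out[key_sel %in% key_model, , drop = FALSE]
  atom_selection(out$chain, out$resseq, out$atom, out$icode)
}

#' Resolve a selection to coordinates
#'
#' Returns the n x 3 coordinate matrix of the selected atoms, in selection
#' order. In strict mode (the default) any unresolved item is an error that
#' lists every missing `(residue, atom)` pair; in lenient mode missing items
#' are dropped and reported in the `"dropped"` attribute. Measurements in
#' this package use strict mode so atoms are never silently skipped.
#'
#' @param model StructureModel (altloc-resolved)
#' @param selection AtomSelection
#' @param strict error on missing atoms (default TRUE)
#' @return numeric matrix n x 3 with row names `chain/resseq/atom`
#' @export
select_atoms <- function(model, selection, strict = TRUE) {
  if (nrow(selection) == 0L) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  a <- model$atoms
  key_model <- paste(a$chain, a$resseq, a$icode, a$atom, sep = "\r")
  key_sel <- paste(selection$chain, selection$resseq, selection$icode,
                   selection$atom, sep = "\r")
  idx <- match(key_sel, key_model)
  if (anyNA(idx)) {
    miss <- selection[is.na(idx), , drop = FALSE]
    msg <- paste(sprintf("%s/%s%s/%s", miss$chain, miss$resseq,
                         ifelse(nzchar(miss$icode), miss$icode, ""),
                         miss$atom), collapse = ", ")
    if (strict) {
      stop("missing atoms in model '", model$id, "': ", msg)
    }
    idx <- idx[!is.na(idx)]
    sel_found <- selection[!is.na(match(key_sel, key_model)), , drop = FALSE]
    out <- cbind(x = a$x[idx], y = a$y[idx], z = a$z[idx])
    rownames(out) <- sprintf("%s/%d/%s", sel_found$chain, sel_found$resseq,
                             sel_found$atom)
    attr(out, "dropped") <- miss
    return(out)
  }
  out <- cbind(x = a$x[idx], y = a$y[idx], z = a$z[idx])
  rownames(out) <- sprintf("%s/%d/%s", selection$chain, selection$resseq,
                           selection$atom)
  out
}

#' Replace coordinates of selected atoms
#'
#' Inverse of [select_atoms()]: writes an n x 3 coordinate block back into
#' the model at the selected atoms (strict).
#'
#' @param model StructureModel
#' @param selection AtomSelection
#' @param coords n x 3 matrix in selection order
#' @return modified StructureModel
#' @export
set_atom_coords <- function(model, selection, coords) {
  a <- model$atoms
  key_model <- paste(a$chain, a$resseq, a$icode, a$atom, sep = "\r")
  key_sel <- paste(selection$chain, selection$resseq, selection$icode,
                   selection$atom, sep = "\r")
  idx <- match(key_sel, key_model)
  if (anyNA(idx)) stop("selection does not resolve in model '", model$id, "'")
  if (nrow(coords) != length(idx)) stop("coordinate block shape mismatch")
  a$x[idx] <- coords[, 1]; a$y[idx] <- coords[, 2]; a$z[idx] <- coords[, 3]
  model$atoms <- a
  model
}

#' All-atom coordinate matrix of a model
#' @param model StructureModel
#' @param heavy drop hydrogens (default TRUE)
#' @param waters keep waters (default FALSE)
#' @return n x 3 matrix
#' @export
model_coords <- function(model, heavy = TRUE, waters = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (heavy) keep <- keep & !a$hydrogen
  if (!waters) keep <- keep & !a$water
  as.matrix(a[keep, c("x", "y", "z")])
}
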