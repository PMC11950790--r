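#' Structure model container
#'
#' A light container for one structural model: a flat atom table plus
#' provenance. Most package functions take and return this class.
#'
#' @param atoms data.frame with columns `chain`, `resno` (author residue
#'   number, integer), `insert` (insertion code, `""` if none), `resid`
#'   (3-letter residue name), `elety` (atom name), `element` (element
#'   symbol), `x`, `y`, `z` (angstroms), `o` (occupancy).
#' @param model_id Identifier string.
#' @param source One of `"cryoem_reference"`, `"predicted"`, `"synthetic"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model",
                            source = c("synthetic", "cryoem_reference",
                                       "predicted")) {
  source <- match.arg(source)
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "o")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all atom coordinates must be finite")
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom records (chain/resno/insert/elety) in model")
  structure(list(model_id = model_id, source = source, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- chain_ids(x)
  cat(sprintf("<structure_model> %s (%s): %d chain(s), %d residues, %d atoms\n",
              x$model_id, x$source, length(ch),
              nrow(unique(x$atoms[, c("chain", "resno", "insert")])),
              nrow(x$atoms)))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of chain IDs.
#' @export
chain_ids <- function(model) sort(unique(model$atoms$chain))

# residue table (one row per residue) for one chain
chain_residues <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  unique(a[, c("chain", "resno", "insert", "resid")])
}

# atom subset; any filter left NULL is not applied
get_atoms <- function(model, chain = NULL, elety = NULL, resno = NULL,
                      heavy_only = FALSE) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  a
}

as_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Read a structure from PDB or mmCIF
#'
#' Parses the file with bio3d and normalizes it into a [structure_model()]:
#' author residue numbering is preserved, alternate locations are resolved to
#' the highest-occupancy conformer, and waters/hetero ligands (and, by
#' default, hydrogens) are excluded.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension; `.cif` /
#'   `.mmcif` read as mmCIF).
#' @param source Provenance tag stored on the model.
#' @param keep_hydrogens Keep hydrogen atoms (default drops them).
#' @return A `structure_model`. Residues lacking a CA atom are listed in
#'   `attr(model, "missing_ca")`, with a warning.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source = "predicted", keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, rm.alt = FALSE,
                                           verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s' as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE))
  at <- parsed$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no ATOM records in '%s'", path))
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  # element: prefer the element-symbol column, fall back to the atom name
  elem <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else
    rep(NA_character_, nrow(at))
  fallback <- toupper(sub("[0-9'\"]*$", "", sub("^[0-9]*", "", at$elety)))
  fallback <- substr(fallback, 1L, ifelse(fallback %in%
    c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), 2L, 1L))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  at$element <- elem
  if (!keep_hydrogens) at <- at[at$element != "H", , drop = FALSE]
  # altloc: keep the highest-occupancy conformer of each atom
  at$alt[is.na(at$alt)] <- ""
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      insert = at$insert, resid = at$resid, elety = at$elety,
                      element = at$element, x = at$x, y = at$y, z = at$z,
                      o = at$o, stringsAsFactors = FALSE)
  m <- structure_model(atoms,
                       model_id = tools::file_path_sans_ext(basename(path)),
                       source = source)
  res <- unique(m$atoms[, c("chain", "resno", "insert")])
  ca <- unique(m$atoms[m$atoms$elety == "CA", c("chain", "resno", "insert")])
  miss <- res[!paste(res$chain, res$resno, res$insert) %in%
                paste(ca$chain, ca$resno, ca$insert), , drop = FALSE]
  if (nrow(miss)) {
    warning(sprintf("%d residue(s) without CA atom in '%s'", nrow(miss),
                    basename(path)))
    attr(m, "missing_ca") <- miss
  }
  m
}

#' Write a structure model as PDB
#'
#' Fixed-width ATOM records; used for synthetic fixtures and superposed
#' (transformed) models. Coordinates are written to 3 decimals, the PDB
#' precision.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  name4 <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety),
                  sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, a$o, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Apply a rigid transform to a model
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix (applied to coordinate row vectors).
#' @param translation Length-3 translation (angstroms).
#' @return The transformed `structure_model`.
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"),
            is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  xyz <- as_xyz(model$atoms) %*% rotation
  xyz <- sweep(xyz, 2L, translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
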