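# Atomic model container and PDB/mmCIF input/output.
#
# An `atomic_model` is a light S3 wrapper around a data frame of atoms with
# columns chain, resno, resid, elety (atom name), elesy (element) and x, y, z
# coordinates in Angstrom. File parsing is delegated to bio3d; only the first
# model block of a multi-model file is kept.

new_atomic_model <- function(atoms, metadata = "") {
  stopifnot(is.data.frame(atoms))
  req <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name) triples in model")
  structure(list(atoms = atoms, metadata = metadata), class = "atomic_model")
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses the first model block of a PDB or mmCIF file into an
#' `atomic_model` object (a data frame of atoms with coordinates in
#' Angstrom).
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"pdb"` or `"mmcif"`; guessed from the file extension when
#'   omitted.
#' @return an object of class `atomic_model`.
#' @export
load_model <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0) stop("empty model: no atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    resid = a$resid,
    elety = a$elety,
    elesy = ifelse(is.na(a$elesy) | a$elesy == "",
                   substr(trimws(a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE)
  new_atomic_model(atoms, metadata = paste0(format, ":", basename(path)))
}

#' Write an atomic model to PDB
#'
#' @param model an `atomic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy)
  invisible(path)
}

#' Construct an atomic model from coordinates
#'
#' Builds an `atomic_model` from an n x 3 coordinate matrix, assigning one
#' pseudo-atom per row. Used by the synthetic generators and tests.
#'
#' @param xyz n x 3 matrix of coordinates (Angstrom).
#' @param chain chain identifier(s), recycled.
#' @param resno residue numbers; defaults to `1:n`.
#' @param elety atom name(s), recycled.
#' @param elesy element symbol(s), recycled.
#' @param metadata free-text provenance.
#' @return an `atomic_model`.
#' @export
model_from_xyz <- function(xyz, chain = "A", resno = NULL, elety = "CA",
                           elesy = "C", metadata = "synthetic") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(chain = rep_len(chain, n), resno = resno,
                      resid = rep_len("GLY", n),
                      elety = rep_len(elety, n), elesy = rep_len(elesy, n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new_atomic_model(atoms, metadata = metadata)
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("atomic_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  if (nzchar(x$metadata)) cat("  source:", x$metadata, "\n")
  invisible(x)
}

model_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

set_model_xyz <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Domain selection
#'
#' A selection is a list of blocks, each naming a chain, an inclusive
#' residue-number interval and an optional atom-name filter; residue
#' numbering is 1-based as deposited.
#'
#' @param chain chain id.
#' @param resno_range length-2 inclusive residue interval (or a single
#'   residue number).
#' @param elety optional character vector of atom names to keep.
#' @return an object of class `domain_selection` with a single block; blocks
#'   can be concatenated with [c()].
#' @export
domain_selection <- function(chain, resno_range, elety = NULL) {
  if (length(resno_range) == 1) resno_range <- c(resno_range, resno_range)
  stopifnot(length(resno_range) == 2, resno_range[1] <= resno_range[2])
  structure(list(list(chain = chain,
                      resno = as.integer(resno_range),
                      elety = elety)),
            class = "domain_selection")
}

#' @export
c.domain_selection <- function(...) {
  parts <- lapply(list(...), unclass)
  structure(do.call(c, parts), class = "domain_selection")
}

#' Apply a domain selection to a model
#'
#' @param model an `atomic_model`.
#' @param selection a `domain_selection`.
#' @return the selected rows of the atom table (>= 1 row, else an error).
#' @export
select_atoms <- function(model, selection) {
  stopifnot(inherits(model, "atomic_model"),
            inherits(selection, "domain_selection"))
  a <- model$atoms
  keep <- rep(FALSE, nrow(a))
  for (blk in unclass(selection)) {
    m <- a$chain == blk$chain &
      a$resno >= blk$resno[1] & a$resno <= blk$resno[2]
    if (!is.null(blk$elety)) m <- m & a$elety %in% blk$elety
    keep <- keep | m
  }
  out <- a[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("selection matches no atoms")
  out
}

#' Look up a single atom by address
#'
#' @param model an `atomic_model`.
#' @param chain chain id.
#' @param resno residue number.
#' @param elety atom name (default `"CA"`).
#' @return xyz coordinates (length-3 numeric).
#' @export
atom_coord <- function(model, chain, resno, elety = "CA") {
  a <- model$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i) == 0)
    stop("no such atom: chain ", chain, " resno ", resno, " name ", elety)
  as.numeric(a[i[1], c("x", "y", "z")])
}
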