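# Reading domain coordinates from PDB/mmCIF and FASTA plumbing.
# Only Ca atoms are retained; altlocs are resolved to the highest-occupancy
# conformer (ties: first listed); residues lacking a Ca are skipped with a
# warning. Positional indices (1..n after filtering) drive all downstream
# math; author residue numbers are kept for reporting.

#' Read one protein domain from a PDB or mmCIF file
#'
#' Parses ATOM records, keeps the Cα trace of the requested chain (and
#' optional author-numbering residue range) and returns a
#' [DomainStructure-class]. Coordinates are kept in Angstrom as read; no
#' re-centering is performed.
#'
#' @param path path to a PDB or mmCIF file.
#' @param chain chain identifier; may be omitted when the file has exactly
#'   one chain.
#' @param range optional inclusive `c(start, end)` interval of author
#'   residue numbers.
#' @param format `"auto"` (from extension; `.cif`/`.mmcif` is mmCIF,
#'   anything else PDB), `"pdb"` or `"cif"`.
#' @param id label for the domain; defaults to the file base name.
#' @return a [DomainStructure-class].
#' @examples
#' d <- makeTemplate(60, seed = 3)
#' f <- tempfile(fileext = ".pdb")
#' writeDomainPDB(d, f)
#' d2 <- readStructure(f, chain = "A")
#' stopifnot(domainLength(d2) == 60)
#' @export
readStructure <- function(path, chain = NULL, range = NULL,
                          format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("cannot parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) != 1L)
      stop("file has chains {", paste(chains, collapse = ", "),
           "}; specify one")
    chain <- chains
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found (available: ",
         paste(chains, collapse = ", "), ")")
  at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    at <- at[at$resno >= range[1] & at$resno <= range[2], , drop = FALSE]
    if (nrow(at) == 0L)
      stop("residue range [", range[1], ", ", range[2],
           "] does not overlap chain ", chain)
  }
  if (is.null(at$insert)) at$insert <- ""
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$resno, ins, sep = "_")
  res_order <- unique(key)                     # file order within the chain
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (is.null(ca$o)) ca$o <- 1
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  ca_key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert), sep = "_")
  keep <- integer(0)
  for (k in res_order) {
    idx <- which(ca_key == k)
    if (length(idx) == 0L) next
    if (length(idx) > 1L) idx <- idx[which.max(occ[idx])]  # altloc policy
    keep <- c(keep, idx)
  }
  n_missing <- length(res_order) - length(keep)
  if (n_missing > 0L)
    warning(n_missing, " residue(s) without a Ca atom skipped in ", path)
  if (length(keep) < 3L)
    stop("degenerate selection: fewer than 3 Ca atoms in ", path,
         " chain ", chain)
  ca <- ca[keep, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(ca$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  new("DomainStructure", id = id,
      coords = unname(cbind(ca$x, ca$y, ca$z)),
      aa = aa, resno = as.integer(ca$resno))
}

#' Write a Cα-only PDB file for a domain
#'
#' @param structure a [DomainStructure-class].
#' @param path output file.
#' @param chain chain identifier to write.
#' @return `path`, invisibly.
#' @export
writeDomainPDB <- function(structure, path, chain = "A") {
  n <- domainLength(structure)
  aa3 <- bio3d::aa123(structure@aa)
  aa3[is.na(aa3) | structure@aa == "X"] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure@coords)),
                   resno = structure@resno,
                   resid = aa3,
                   chain = rep(chain, n),
                   elety = rep("CA", n))
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings keeping sequences as a named character
#' vector; output is wrapped at 60 columns.
#'
#' @param x named character vector of sequences, or a list of
#'   [DomainStructure-class] objects (their sequences are extracted).
#' @param path FASTA file path.
#' @return `writeFasta` returns `path` invisibly; `readFasta` returns a
#'   named character vector.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeFasta(c(d1 = "AGW"), f)
#' readFasta(f)
#' @export
writeFasta <- function(x, path) {
  if (is.list(x))
    x <- setNames(vapply(x, domainSequence, character(1)),
                  vapply(x, domainId, character(1)))
  set <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname writeFasta
#' @export
readFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}
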