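#' Write a structure as a fixed-column PDB file
#'
#' Classic PDB ATOM records: serial in columns 7-11, atom name 13-16, residue
#' name 18-20, residue number 23-26, coordinates in Angstrom as `%8.3f` in
#' columns 31-54, element right-justified in 77-78. Serial and residue
#' numbers wrap modulo their field widths for very large systems, as MD
#' tooling conventionally does.
#'
#' @param structure atom tibble (see [nf_structure()]).
#' @param path output file.
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, title = "built by nanoforge") {
  s <- tibble::as_tibble(structure)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", title), con)
  box <- attr(structure, "box")
  if (!is.null(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90), con)
  }
  if (nrow(s) > 0) {
    nm <- ifelse(nchar(s$name) <= 3, paste0(" ", s$name), s$name)
    lines <- sprintf("ATOM  %5d %-4.4s %-3.3s %5d   %8.3f%8.3f%8.3f%6.2f%6.2f          %2.2s",
                     s$atom_id %% 100000L, nm, s$resname, s$resid %% 100000L,
                     s$x, s$y, s$z, 1, 0, toupper(s$element))
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file written by [write_pdb()] (or any fixed-column PDB)
#'
#' @param path PDB file.
#' @return atom tibble; CRYST1 box (if orthorhombic) in the `"box"` attribute.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) >= 1) {
    v <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33)))
    if (all(is.finite(v)) && all(v > 0)) box <- v
  }
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(at) == 0) return(nf_structure(tibble::tibble(
    atom_id = integer(), element = character(), name = character(),
    resid = integer(), resname = character(), molid = integer(),
    x = numeric(), y = numeric(), z = numeric()), box = box))
  df <- tibble::tibble(
    atom_id = as.integer(substr(at, 7, 11)),
    name = trimws(substr(at, 13, 16)),
    resname = trimws(substr(at, 18, 20)),
    resid = as.integer(substr(at, 23, 26)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    element = trimws(substr(at, 77, 78))
  )
  # element field may be absent in minimal files: fall back to the name
  noel <- df$element == ""
  df$element[noel] <- gsub("[^A-Za-z].*$", "", df$name[noel])
  df$element <- paste0(substr(df$element, 1, 1),
                       tolower(substr(df$element, 2, 2)))
  if (anyDuplicated(df$atom_id)) df$atom_id <- seq_len(nrow(df))
  nf_structure(df, box = box)
}

#' Write a structure in GRO format (nm, fixed columns)
#'
#' GRO stores coordinates in nanometres with `%8.3f` fields, so a round-trip
#' is accurate to 0.001 nm by construction.
#'
#' @inheritParams write_pdb
#' @export
write_gro <- function(structure, path, title = "built by nanoforge") {
  s <- tibble::as_tibble(structure)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(s)), con)
  if (nrow(s) > 0) {
    lines <- sprintf("%5d%-5.5s%5.5s%5d%8.3f%8.3f%8.3f",
                     s$resid %% 100000L, s$resname, s$name, s$atom_id %% 100000L,
                     s$x / 10, s$y / 10, s$z / 10)
    writeLines(lines, con)
  }
  box <- attr(structure, "box")
  if (is.null(box)) box <- c(0, 0, 0)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10), con)
  invisible(path)
}

#' Read a GRO file
#' @param path GRO file.
#' @return atom tibble, coordinates converted to Angstrom, box attribute set.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[2 + seq_len(n)]
  df <- tibble::tibble(
    resid = as.integer(substr(at, 1, 5)),
    resname = trimws(substr(at, 6, 10)),
    name = trimws(substr(at, 11, 15)),
    atom_id = as.integer(substr(at, 16, 20)),
    x = as.numeric(substr(at, 21, 28)) * 10,
    y = as.numeric(substr(at, 29, 36)) * 10,
    z = as.numeric(substr(at, 37, 44)) * 10
  )
  df$element <- gsub("[^A-Za-z].*$", "", df$name)
  df$element <- paste0(substr(df$element, 1, 1), tolower(substr(df$element, 2, 2)))
  if (n > 0 && anyDuplicated(df$atom_id)) df$atom_id <- seq_len(nrow(df))
  boxline <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  box <- if (length(boxline) >= 3 && all(boxline[1:3] > 0)) boxline[1:3] * 10 else NULL
  nf_structure(df, box = box)
}
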