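#' Write a backbone structure as a multi-model PDB file
#'
#' Emits fixed-format ATOM records, one MODEL/ENDMDL block per frame.
#' Coordinates are converted from nm to Angstrom on output.
#'
#' @param structure \code{BackboneStructure}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writePDB <- function(structure, file) {
  at <- structure@atoms
  con <- file(file, "w")
  on.exit(close(con))
  nf <- nFrames(structure)
  serial <- seq_len(nrow(at))
  for (f in seq_len(nf)) {
    xyz <- frameCoords(structure, f) * 10  # nm -> Angstrom
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, sprintf(" %-3s", at$name), at$resname, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    writeLines(if (nf > 1L) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a (multi-model) backbone PDB file
#'
#' Parses ATOM records for the backbone atoms N, CA, C, O; MODEL blocks become
#' frames. Coordinates are converted from Angstrom to nm.
#'
#' @param file path to a PDB file.
#' @return \code{BackboneStructure}.
#' @export
readPDB <- function(file) {
  lines <- readLines(file)
  isAtom <- startsWith(lines, "ATOM")
  isModel <- startsWith(lines, "MODEL")
  modelNo <- cumsum(isModel)
  if (!any(isModel)) modelNo <- rep(1L, length(lines)) else modelNo <- pmax(modelNo, 1L)
  al <- lines[isAtom]
  am <- modelNo[isAtom]
  name <- trimws(substr(al, 13, 16))
  keep <- name %in% c("N", "CA", "C", "O")
  al <- al[keep]; am <- am[keep]; name <- name[keep]
  resname <- trimws(substr(al, 18, 20))
  resid <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38)) / 10
  y <- as.numeric(substr(al, 39, 46)) / 10
  z <- as.numeric(substr(al, 47, 54)) / 10
  frames <- sort(unique(am))
  first <- am == frames[1]
  atoms <- data.frame(resid = resid[first], resname = resname[first],
                      name = name[first],
                      element = substr(name[first], 1, 1),
                      stringsAsFactors = FALSE)
  nat <- sum(first)
  arr <- array(NA_real_, dim = c(nat, 3L, length(frames)))
  for (k in seq_along(frames)) {
    sel <- am == frames[k]
    if (sum(sel) != nat) stop("PDB models differ in atom count")
    arr[, , k] <- cbind(x[sel], y[sel], z[sel])
  }
  new("BackboneStructure", coords = arr, atoms = atoms)
}
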