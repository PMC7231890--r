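# PDB reading/writing via bio3d, with a deterministic chain/segment scheme
# for assemblies of more than 62 peptides: the single-character chain ID
# cycles through A-Z, a-z, 0-9 and the 4-character segment ID "P0001",
# "P0002", ... identifies peptides uniquely. Reading prefers the segment ID
# and falls back to the chain ID.

CHAIN_ALPHABET <- c(LETTERS, letters, 0:9)

#' Write an atom table to a PDB file
#'
#' @param atoms A `zipper_atoms` tibble (strand, unit cell or block).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  if (!inherits(atoms, "zipper_atoms") || nrow(atoms) == 0) {
    abort("`atoms` must be a nonempty zipper_atoms table")
  }
  ok <- tryCatch(
    {
      con <- file(path, "w")
      close(con)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) abort(sprintf("destination '%s' is not writable", path))

  pep <- as.integer(factor(atoms$peptide, levels = unique(atoms$peptide)))
  chain <- CHAIN_ALPHABET[(pep - 1L) %% length(CHAIN_ALPHABET) + 1L]
  segid <- sprintf("%04d", pep)  # PDB segid field is 4 characters
  nres_max <- max(atoms$res_id)

  pdb_atoms <- data.frame(
    type = "ATOM",
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom,
    alt = "",
    resid = atoms$res_name,
    chain = chain,
    resno = atoms$res_id,
    insert = "",
    x = atoms$x, y = atoms$y, z = atoms$z,
    o = 1, b = 0,
    segid = segid,
    elesy = atoms$element,
    charge = "",
    stringsAsFactors = FALSE
  )
  pdb <- list(atom = pdb_atoms, xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))))
  class(pdb) <- "pdb"
  bio3d::write.pdb(
    pdb = NULL, file = path,
    eleno = pdb_atoms$eleno, elety = pdb_atoms$elety,
    resid = pdb_atoms$resid, chain = pdb_atoms$chain,
    resno = pdb_atoms$resno, xyz = pdb$xyz,
    o = pdb_atoms$o, b = pdb_atoms$b,
    segid = pdb_atoms$segid, elesy = pdb_atoms$elesy,
    print.segid = TRUE
  )
  invisible(path)
}

#' Read a PDB file into an atom table
#'
#' @param path PDB file path.
#' @return A `zipper_atoms` tibble; peptide identity is taken from the
#'   segment ID where present, else from the chain ID.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  pepkey <- if (!all(is.na(at$segid)) && !all(at$segid == "")) at$segid else at$chain
  df <- tibble(
    peptide = as.integer(factor(pepkey, levels = unique(pepkey))),
    res_id = as.integer(at$resno),
    res_name = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "", substr(at$elety, 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    charge = 0,
    i_a = NA_integer_, i_b = NA_integer_, i_c = NA_integer_,
    sense = NA_integer_
  )
  new_zipper_atoms(df)
}
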