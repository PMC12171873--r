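#' Select atoms of a trajectory
#'
#' Selections are either residue-number based strings of the form
#' `"chain:from-to"` or `"chain:resno"`, a plain numeric vector of residue
#' numbers (any chain), or a residue-name string `"resname=XXX"`.
#'
#' @param traj a [trajectory()].
#' @param selection selection specifier.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(traj, selection) {
  a <- traj$atoms
  if (is.numeric(selection))
    return(which(a$resno %in% selection))
  stopifnot(is.character(selection), length(selection) == 1L)
  if (grepl("^resname=", selection)) {
    rn <- sub("^resname=", "", selection)
    return(which(a$resname == rn))
  }
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("cannot parse selection '", selection,
         "' (expected 'chain:from-to', 'chain:resno' or 'resname=XXX')")
  chain <- parts[1]
  rng <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
  if (any(is.na(rng))) stop("non-numeric residue range in '", selection, "'")
  resnos <- if (length(rng) == 2L) seq(rng[1], rng[2]) else rng
  which(a$chain == chain & a$resno %in% resnos)
}

# Split an atom-index selection into per-residue groups, ordered by
# (chain, resno) first appearance.
split_by_residue <- function(traj, atom_idx) {
  a <- traj$atoms[atom_idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, sep = ":")
  split(atom_idx, factor(key, levels = unique(key)))
}
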