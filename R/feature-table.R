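#' Feature table
#'
#' Frames x features matrix with one descriptor per feature.  Rows align
#' with trajectory frames; descriptors record what each column measures.
#'
#' @param values numeric matrix, frames x features.
#' @param kind character vector (recycled): one of `chi1`,
#'   `helix_distance`, `ligand_distance`, `sasa`.
#' @param selection character vector (recycled): the selection each column
#'   was computed from.
#' @param units character vector (recycled), e.g. `"deg"` or `"angstrom"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, kind, selection, units) {
  values <- as.matrix(values)
  d <- data.frame(kind = rep_len(kind, ncol(values)),
                  selection = rep_len(selection, ncol(values)),
                  units = rep_len(units, ncol(values)),
                  stringsAsFactors = FALSE)
  colnames(values) <- paste(d$kind, d$selection, d$units, sep = "|")
  structure(list(values = values, descriptors = d), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "frames x", ncol(x$values),
      "features (", paste(unique(x$descriptors$kind), collapse = ", "), ")\n")
  invisible(x)
}

#' Column-bind feature tables computed on the same frames
#' @param ... `feature_table` objects with equal row counts.
#' @return a combined `feature_table`.
#' @export
bind_features <- function(...) {
  fts <- list(...)
  stopifnot(length(unique(vapply(fts, function(f) nrow(f$values), 1L))) == 1L)
  feature_table(do.call(cbind, lapply(fts, function(f) f$values)),
                kind = do.call(c, lapply(fts, function(f) f$descriptors$kind)),
                selection = do.call(c, lapply(fts, function(f) f$descriptors$selection)),
                units = do.call(c, lapply(fts, function(f) f$descriptors$units)))
}

#' Write a feature table as TSV
#'
#' The header line carries the `kind|selection|units` descriptor strings, so
#' the file round-trips through [read_feature_table()].
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  write.table(ft$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = ""))
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  feature_table(m,
                kind = vapply(parts, `[`, "", 1L),
                selection = vapply(parts, `[`, "", 2L),
                units = vapply(parts, `[`, "", 3L))
}

#' Map circular (dihedral) features to cos/sin pairs
#'
#' Dihedral angles wrap at +/-180 deg; projecting them to the unit circle
#' gives coordinates with ordinary Euclidean geometry, which the tICA and
#' clustering stages require.
#'
#' @param ft a [feature_table()].
#' @return a `feature_table` where every `chi1` column is replaced by a
#'   `cos`/`sin` pair; other columns pass through unchanged.
#' @export
expand_circular <- function(ft) {
  vals <- list(); kinds <- character(0); sels <- character(0); units <- character(0)
  for (j in seq_len(ncol(ft$values))) {
    d <- ft$descriptors[j, ]
    if (d$kind == "chi1") {
      rad <- ft$values[, j] * pi / 180
      vals <- c(vals, list(cos(rad), sin(rad)))
      kinds <- c(kinds, "chi1_cos", "chi1_sin")
      sels <- c(sels, d$selection, d$selection)
      units <- c(units, "1", "1")
    } else {
      vals <- c(vals, list(ft$values[, j]))
      kinds <- c(kinds, d$kind); sels <- c(sels, d$selection)
      units <- c(units, d$units)
    }
  }
  feature_table(do.call(cbind, vals), kinds, sels, units)
}
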