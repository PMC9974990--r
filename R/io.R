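# Readers and writers for the plain-text interchange formats: dense matrices
# as tab-separated text with '#' header comments, per-cell loci coordinate
# tables (the shape multiplexed FISH deposits take), and ensemble export as
# XYZ or multi-model PDB with loci as CA pseudo-atoms.

#' Read a dense matrix from tab-separated text
#'
#' Lines starting with `#` are treated as header comments. Fields may be
#' separated by any whitespace; `NA`/`nan` mark missing entries.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_dense_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, comment.char = "#",
                                   na.strings = c("NA", "nan", "NaN")))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a dense matrix as tab-separated text
#'
#' @param m numeric matrix.
#' @param path file path.
#' @param comments character vector of header lines (written prefixed `#`).
#' @export
write_dense_matrix <- function(m, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read per-cell loci coordinates
#'
#' Reads a delimited table with columns `cell_id`, `locus_index` (1-based),
#' `x`, `y`, `z` (nm) into an `M x N x 3` coordinate array. Loci absent from
#' a cell, or rows with any non-finite coordinate, are missing (`NA`) for
#' that cell. Row order is irrelevant: cells are ordered by sorted `cell_id`.
#'
#' @param x file path, or a data frame with the five columns above.
#' @param n_loci total number of loci `N`; defaults to the maximum index
#'   present.
#' @return `M x N x 3` array with attribute `source = "experimental"` and
#'   `cell_ids`.
#' @export
read_cell_coordinates <- function(x, n_loci = NULL) {
  df <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = "", comment.char = "#",
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  need <- c("cell_id", "locus_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(sprintf("coordinate table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$locus_index <- as.integer(df$locus_index)
  if (is.null(n_loci)) n_loci <- max(df$locus_index)
  if (any(df$locus_index < 1L | df$locus_index > n_loci)) {
    stop(sprintf("locus_index out of range 1..%d", n_loci), call. = FALSE)
  }
  key <- paste(df$cell_id, df$locus_index)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (cell, locus) rows, e.g. %s", key[duplicated(key)][1]),
         call. = FALSE)
  }
  cells <- sort(unique(df$cell_id))
  ens <- array(NA_real_, dim = c(length(cells), n_loci, 3L))
  ci <- match(df$cell_id, cells)
  for (p in 1:3) {
    ens[cbind(ci, df$locus_index, p)] <- df[[c("x", "y", "z")[p]]]
  }
  bad <- !is.finite(matrix(ens[, , 1], length(cells))) |
    !is.finite(matrix(ens[, , 2], length(cells))) |
    !is.finite(matrix(ens[, , 3], length(cells)))
  for (p in 1:3) {
    xp <- matrix(ens[, , p], length(cells))
    xp[bad] <- NA_real_
    ens[, , p] <- xp
  }
  attr(ens, "source") <- "experimental"
  attr(ens, "cell_ids") <- cells
  ens
}

#' Write per-cell loci coordinates
#'
#' Inverse of [read_cell_coordinates()]; missing loci are omitted.
#'
#' @param ens `M x N x 3` coordinate array.
#' @param path file path.
#' @export
write_cell_coordinates <- function(ens, path) {
  ens <- .check_ensemble(ens)
  m <- dim(ens)[1]; n <- dim(ens)[2]
  ids <- attr(ens, "cell_ids")
  if (is.null(ids)) ids <- seq_len(m)
  obs <- which(!is.na(matrix(ens[, , 1], m, n)), arr.ind = TRUE)
  df <- data.frame(cell_id = ids[obs[, 1]], locus_index = obs[, 2],
                   x = ens[cbind(obs, 1L)], y = ens[cbind(obs, 2L)],
                   z = ens[cbind(obs, 3L)])
  df <- df[order(df$cell_id, df$locus_index), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an ensemble as XYZ
#'
#' One XYZ frame per conformation; loci are atoms named `C`. Missing loci
#' are skipped within their frame.
#'
#' @param ens `M x N x 3` coordinate array.
#' @param path file path.
#' @export
write_ensemble_xyz <- function(ens, path) {
  ens <- .check_ensemble(ens)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(dim(ens)[1])) {
    xyz <- ens[m, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    keep <- !is.na(xyz[, 1])
    writeLines(as.character(sum(keep)), con)
    writeLines(sprintf("conformation %d", m), con)
    if (any(keep)) {
      writeLines(sprintf("C %.4f %.4f %.4f",
                         xyz[keep, 1], xyz[keep, 2], xyz[keep, 3]), con)
    }
  }
  invisible(path)
}

#' Export an ensemble as multi-model PDB
#'
#' One MODEL per conformation with loci as CA pseudo-atoms (residue number =
#' locus index). Coordinates are written in Angstrom columns as-is; rescale
#' beforehand if true nm output is needed by a downstream viewer.
#'
#' @param ens `M x N x 3` coordinate array.
#' @param path file path.
#' @export
write_ensemble_pdb <- function(ens, path) {
  ens <- .check_ensemble(ens)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(dim(ens)[1])) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens[m, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    serial <- 0L
    for (i in seq_len(nrow(xyz))) {
      if (is.na(xyz[i, 1])) next
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
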