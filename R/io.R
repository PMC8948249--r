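# Readers/writers for the standard formats the pipeline touches:
# MatrixMarket MTX + features/barcodes (10x dialect, optionally gzipped),
# GMT gene sets, ligand-receptor pair TSVs, and headered CSV/TSV tables.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_lines_maybe_gz <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a 10x-style sparse count matrix
#'
#' Reads a MatrixMarket coordinate matrix plus features and barcodes tables
#' (plain or gzipped). Features are rows (10x convention); the gene symbol is
#' taken from the second column of the features file when present (10x
#' id/symbol/type layout), else the first. Duplicate symbols are kept and
#' disambiguated deterministically with "-1", "-2", ... suffixes in file
#' order.
#'
#' @param path_matrix Path to the `.mtx(.gz)` file.
#' @param path_features,path_barcodes Paths to the features / barcodes TSVs.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path_matrix, path_features, path_barcodes) {
  con <- open_text(path_matrix)
  m <- tryCatch(Matrix::readMM(con), finally = close(con))
  feat <- utils::read.table(path_features, sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  bc <- utils::read.table(path_barcodes, sep = "\t",
                          header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(feat) != nrow(m))
    stop("format error: features file has ", nrow(feat),
         " rows but matrix declares ", nrow(m))
  if (nrow(bc) != ncol(m))
    stop("format error: barcodes file has ", nrow(bc),
         " rows but matrix declares ", ncol(m))
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  symbols <- disambiguate(as.character(symbols))
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(m@x) && any(m@x < 0))
    stop("format error: negative entries in ", path_matrix)
  if (length(m@x) && any(m@x != round(m@x)))
    stop("format error: non-integer entries in ", path_matrix)
  count_matrix(m, gene_symbols = symbols, barcodes = as.character(bc[[1]]))
}

disambiguate <- function(x) {
  dup <- x[duplicated(x)]
  if (!length(dup)) return(x)
  for (d in unique(dup)) {
    idx <- which(x == d)
    x[idx] <- paste0(d, "-", seq_along(idx))
  }
  x
}

#' Write a CountMatrix as MTX + features + barcodes
#'
#' @param counts A `CountMatrix`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default "": matrix.mtx, features.tsv,
#'   barcodes.tsv).
#' @return Invisibly, the three paths written.
#' @export
write_count_matrix <- function(counts, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, paste0(prefix, "matrix.mtx"))
  pf <- file.path(dir, paste0(prefix, "features.tsv"))
  pb <- file.path(dir, paste0(prefix, "barcodes.tsv"))
  m <- as(counts, "dgCMatrix")
  # integer MatrixMarket body: write by hand for byte-stable output
  tm <- as(m, "TsparseMatrix")
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(m), ncol(m), length(tm@x)),
             if (length(tm@x))
               paste(tm@i + 1L, tm@j + 1L, format(tm@x, scientific = FALSE,
                                                  trim = TRUE)))
  writeLines(lines, pm)
  writeLines(paste(rownames(m), rownames(m), "Gene Expression", sep = "\t"), pf)
  writeLines(colnames(m), pb)
  invisible(c(matrix = pm, features = pf, barcodes = pb))
}

#' Read gene sets from a GMT file
#'
#' Each line is `name <tab> description <tab> member1 <tab> member2 ...`.
#' Members are deduplicated (set semantics); line order is preserved.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one gene set per line), class
#'   `gene_sets`.
#' @export
read_gene_sets <- function(path) {
  lines <- read_lines_maybe_gz(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !any(nzchar(f[-(1:2)])))
      stop("format error: gene set '", f[1], "' has no members")
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  structure(sets, class = "gene_sets")
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, ".", sets[[n]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read a ligand-receptor pair database
#'
#' Accepts a TSV with `ligand_human` / `receptor_human` columns (extra
#' columns such as mouse symbols or provenance are kept), or the Ramilowski
#' "Pair.Name" style with a single `LIGAND_RECEPTOR` column.
#'
#' @param path Path to the TSV.
#' @return data.frame with at least `ligand_human`, `receptor_human`; pairs
#'   unique, symbols non-empty.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("ligand_human", "receptor_human") %in% names(df))) {
    pair_col <- grep("^pair", names(df), ignore.case = TRUE, value = TRUE)
    if (length(pair_col) != 1)
      stop("format error: need ligand_human/receptor_human columns ",
           "or a single Pair.Name-style column")
    parts <- strsplit(df[[pair_col]], "_", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("format error: pair names must be LIGAND_RECEPTOR")
    df$ligand_human <- vapply(parts, `[`, character(1), 1)
    df$receptor_human <- vapply(parts, `[`, character(1), 2)
  }
  if (any(!nzchar(df$ligand_human)) || any(!nzchar(df$receptor_human)))
    stop("format error: empty ligand or receptor symbol")
  df <- df[!duplicated(df[c("ligand_human", "receptor_human")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a ligand-receptor pair database
#' @param db data.frame with ligand_human / receptor_human columns.
#' @param path Output path.
#' @export
write_lr_database <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as headered UTF-8 CSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a headered CSV written by [write_table_csv()]
#' @param path Input path.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
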