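#' Read a genotype matrix from CSV/TSV
#'
#' Expects line IDs in the first column and marker IDs in the header row
#' (or the transpose, with `transpose = TRUE`). Missing dosage cells are
#' mean-imputed per marker column, with the imputation count reported;
#' duplicate line IDs and non-numeric cells are errors (the latter with
#' its row/column location).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension;
#'   `.tsv`/`.txt` are tab-separated).
#' @param transpose logical; the file stores markers x lines.
#' @return numeric matrix, lines x markers, with dimnames.
#' @export
readGenotypes <- function(path, transpose = FALSE) {
  df <- readDelim(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty genotype file: ", path)
  ids <- as.character(df[[1L]])
  M <- df[, -1L, drop = FALSE]
  for (j in seq_along(M)) {
    col <- M[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                     bad[1L], names(M)[j], path))
      M[[j]] <- as.numeric(col)
    }
  }
  X <- as.matrix(M)
  rownames(X) <- ids
  if (transpose) X <- t(X)
  if (anyDuplicated(rownames(X)))
    stop("duplicate line IDs in ", path)
  nMiss <- sum(is.na(X))
  if (nMiss > 0L) {
    warning(sprintf("mean-imputing %d missing genotype cell(s)", nMiss))
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[!miss, j])
    }
  }
  X
}

#' Write a genotype matrix as CSV
#'
#' Line IDs in the first column, marker IDs in the header, values at full
#' double precision.
#'
#' @param X numeric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(X, path) {
  X <- asMatrix(X)
  df <- data.frame(id = rownames(X),
                   apply(X, 2L, function(x) format(x, digits = 17L)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV/TSV
#'
#' Line IDs in the first column, one named numeric trait per remaining
#' column; missing values allowed. Traits that are entirely missing are
#' excluded with a warning.
#'
#' @param path CSV or TSV file.
#' @return data.frame with rownames = line IDs and one numeric column per
#'   trait.
#' @export
readPhenotypes <- function(path) {
  df <- readDelim(path)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty phenotype file: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate line IDs in ", path)
  traits <- df[, -1L, drop = FALSE]
  for (j in seq_along(traits)) traits[[j]] <- as.numeric(traits[[j]])
  allNA <- vapply(traits, function(x) all(is.na(x)), logical(1))
  if (any(allNA)) {
    warning("excluding entirely missing trait(s): ",
            paste(names(traits)[allNA], collapse = ", "))
    traits <- traits[, !allNA, drop = FALSE]
  }
  rownames(traits) <- ids
  traits
}

#' Align genotypes and phenotypes by line ID
#'
#' Intersects genotype rows and phenotype rows by exact string match,
#' order-independently, and returns complete cases for one trait.
#'
#' @param X genotype matrix with line-ID rownames.
#' @param pheno phenotype data.frame from [readPhenotypes()].
#' @param trait trait column name (default: first trait).
#' @return list with aligned `X`, `y` and the `ids` used.
#' @export
alignData <- function(X, pheno, trait = NULL) {
  if (is.null(trait)) trait <- colnames(pheno)[1L]
  if (!trait %in% colnames(pheno)) stop("unknown trait: ", trait)
  common <- intersect(rownames(X), rownames(pheno))
  if (length(common) == 0L)
    stop("no overlapping line IDs between genotypes and phenotypes")
  y <- pheno[common, trait]
  keep <- !is.na(y)
  list(X = X[common[keep], , drop = FALSE],
       y = as.numeric(y[keep]),
       ids = common[keep])
}

readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}
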