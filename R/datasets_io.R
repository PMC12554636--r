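#' Association, similarity and embedding containers
#'
#' Lightweight validated S3 containers for the three input kinds: the binary
#' drug-disease association matrix, square symmetric similarity matrices, and
#' dense per-entity embedding tables.
#'
#' @param matrix numeric matrix. For `association_table` entries must be 0/1
#'   with drugs as rows and diseases as columns; for `similarity_table` a
#'   square matrix with values in \[0, 1\], symmetrised as `(M + t(M))/2` when
#'   the maximum asymmetry is at most `1e-6`; for `embedding_matrix` any
#'   finite real matrix with one row per entity.
#' @param drug_ids,disease_ids,entity_ids character identifiers, unique,
#'   aligned with matrix rows/columns.
#' @param modality one of `"small_molecule"`, `"protein"`, `"disease_text"`,
#'   `"synthetic"`.
#' @return an object of class `association_table`, `similarity_table` or
#'   `embedding_matrix`.
#' @name containers
NULL

#' @rdname containers
#' @export
association_table <- function(matrix, drug_ids = rownames(matrix),
                              disease_ids = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(matrix)))
  if (is.null(disease_ids)) disease_ids <- paste0("disease", seq_len(ncol(matrix)))
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(drug_ids)) stopf("duplicate drug IDs (e.g. '%s')",
                                     drug_ids[duplicated(drug_ids)][1])
  if (anyDuplicated(disease_ids)) stopf("duplicate disease IDs (e.g. '%s')",
                                        disease_ids[duplicated(disease_ids)][1])
  if (length(drug_ids) != nrow(matrix) || length(disease_ids) != ncol(matrix))
    stopf("ID lists must match matrix dimensions")
  bad <- which(!(matrix %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(matrix))
    stopf("non-binary entry %s at row %d ('%s'), column %d ('%s')",
          format(matrix[bad[1]]), rc[1], drug_ids[rc[1]], rc[2], disease_ids[rc[2]])
  }
  if (sum(matrix) < 1) stopf("association table has no positive entries")
  storage.mode(matrix) <- "double"
  dimnames(matrix) <- list(drug_ids, disease_ids)
  structure(list(drug_ids = drug_ids, disease_ids = disease_ids,
                 matrix = matrix),
            class = "association_table")
}

#' @rdname containers
#' @export
similarity_table <- function(matrix, entity_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix))
    stopf("similarity matrix must be square, got %d x %d", nrow(matrix), ncol(matrix))
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(nrow(matrix)))
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stopf("duplicate entity IDs")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-6)
    stopf("similarity matrix asymmetric beyond tolerance (max |M - t(M)| = %g > 1e-6)", asym)
  matrix <- (matrix + t(matrix)) / 2
  if (any(!is.finite(matrix))) stopf("similarity matrix has non-finite values")
  if (min(matrix) < 0 || max(matrix) > 1)
    stopf("similarity values must lie in [0, 1]; range is [%g, %g]",
          min(matrix), max(matrix))
  dimnames(matrix) <- list(entity_ids, entity_ids)
  structure(list(entity_ids = entity_ids, matrix = matrix),
            class = "similarity_table")
}

#' @rdname containers
#' @export
embedding_matrix <- function(matrix, entity_ids = rownames(matrix),
                             modality = c("synthetic", "small_molecule",
                                          "protein", "disease_text")) {
  modality <- match.arg(modality)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(entity_ids)) entity_ids <- paste0("e", seq_len(nrow(matrix)))
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stopf("duplicate entity IDs")
  if (length(entity_ids) != nrow(matrix))
    stopf("entity_ids length (%d) != number of rows (%d)",
          length(entity_ids), nrow(matrix))
  if (any(!is.finite(matrix))) stopf("embedding matrix has non-finite values")
  dimnames(matrix) <- list(entity_ids, NULL)   # feature columns are anonymous
  structure(list(entity_ids = entity_ids, modality = modality,
                 matrix = matrix, dim = ncol(matrix)),
            class = "embedding_matrix")
}

#' @export
print.association_table <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf("<association_table> %d drugs x %d diseases, %d positives (density %.4f)\n",
              s$n_drugs, s$n_diseases, s$n_positives, s$density))
  invisible(x)
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d entities x %d dims (%s)\n",
              nrow(x$matrix), x$dim, x$modality))
  invisible(x)
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> %d entities, values in [%.3f, %.3f]\n",
              nrow(x$matrix), min(x$matrix), max(x$matrix)))
  invisible(x)
}

read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

detect_sep <- function(path, format) {
  if (format == "tsv") return("\t")
  if (format == "csv") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an association matrix from disk
#'
#' Reads a drug-disease 0/1 matrix from a TSV/CSV file with an ID header row
#' and ID first column (drugs as rows). Row and column order is preserved
#' exactly as in the file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param transpose set `TRUE` for disease-major sources; the matrix is
#'   transposed after reading so drugs end up as rows.
#' @return an [association_table()].
#' @export
load_association_table <- function(path, format = c("auto", "tsv", "csv"),
                                   transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  m <- read_delim_matrix(path, detect_sep(path, format))
  if (transpose) m <- t(m)
  association_table(m)
}

#' Read a similarity matrix from disk
#' @inheritParams load_association_table
#' @return a [similarity_table()].
#' @export
load_similarity_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  similarity_table(read_delim_matrix(path, detect_sep(path, format)))
}

#' Read an embedding table from disk
#' @inheritParams load_association_table
#' @param modality modality tag recorded on the result.
#' @return an [embedding_matrix()].
#' @export
load_embedding_matrix <- function(path, format = c("auto", "tsv", "csv"),
                                  modality = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  embedding_matrix(read_delim_matrix(path, detect_sep(path, format)),
                   modality = modality)
}

#' Write a matrix container to TSV/CSV
#'
#' Writes the matrix with its entity IDs so that the corresponding loader
#' reproduces IDs and values exactly (round-trip stable).
#'
#' @param x an [association_table()], [similarity_table()] or
#'   [embedding_matrix()].
#' @param path output path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_table <- function(x, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  sep <- detect_sep(path, format)
  m <- x$matrix
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise an association table
#'
#' @param assoc an [association_table()].
#' @return list with `n_drugs`, `n_diseases`, `n_positives` and `density`
#'   (positives over all pairs).
#' @examples
#' a <- association_table(matrix(c(1, 0, 0, 1), 2, 2))
#' dataset_summary(a)$n_positives
#' @export
dataset_summary <- function(assoc) {
  stopifnot(inherits(assoc, "association_table"))
  np <- sum(assoc$matrix)
  list(n_drugs = nrow(assoc$matrix), n_diseases = ncol(assoc$matrix),
       n_positives = as.integer(np),
       density = np / length(assoc$matrix))
}
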