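#' Construct an expression matrix container
#'
#' An `ExpressionMatrix` wraps a numeric genes x samples matrix together with
#' a record of the space its values live in: raw `"tpm"` or `"log2"`, where
#' log2 means the per-cell transform `log2(TPM + pseudocount)` has been
#' applied (default pseudocount 1.01).
#'
#' @param values numeric matrix, rows = genes, columns = samples, with
#'   non-empty unique dimnames.
#' @param space `"tpm"` or `"log2"`.
#' @param pseudocount pseudocount recorded for the log2 transform.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, space = c("tpm", "log2"),
                              pseudocount = 1.01) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values))
    stop("missing expression values are not allowed")
  if (space == "tpm" && any(values < 0))
    stop("tpm-space values must be >= 0")
  if (space == "log2" && any(values < log2(pseudocount) - 1e-12))
    stop("log2-space values must be >= log2(pseudocount)")
  structure(list(values = values, space = space, pseudocount = pseudocount),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids_of <- function(m) colnames(m$values)

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids, first column gene ids, tab-separated.
#'
#' @param path file path.
#' @param space space the stored values are in (`"tpm"` or `"log2"`).
#' @param pseudocount pseudocount for log2-space validation.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, space = c("tpm", "log2"), pseudocount = 1.01) {
  space <- match.arg(space)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene id column plus >=1 sample")
  gid <- df[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- as.matrix(df[-1])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell in %s at gene '%s', sample '%s'",
                 path, gid[bad[1]], colnames(df)[-1][bad[2]]))
  }
  dimnames(num) <- list(gid, colnames(df)[-1])
  expression_matrix(num, space = space, pseudocount = pseudocount)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; the first column is named `gene_id`.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform a TPM expression matrix
#'
#' Applies `x -> log2(x + pseudocount)` per cell, the normalization every
#' downstream score and test in the screen assumes. The default pseudocount
#' is 1.01, so a TPM of 0.99 maps exactly to 1.
#'
#' @param m an `ExpressionMatrix` in tpm space.
#' @return an `ExpressionMatrix` in log2 space, same shape and ids.
#' @export
normalize_expression <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$space != "tpm")
    stop("matrix is already in log2 space; refusing to double-transform")
  expression_matrix(log2(m$values + m$pseudocount), space = "log2",
                    pseudocount = m$pseudocount)
}

#' Invert the log2 normalization
#'
#' Maps log2-space values back to TPM via `2^y - pseudocount`, clipped at 0.
#'
#' @param m an `ExpressionMatrix` in log2 space.
#' @param clip clip small negative back-transformed values at 0 (default TRUE).
#' @return an `ExpressionMatrix` in tpm space.
#' @export
denormalize_expression <- function(m, clip = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$space != "log2") stop("matrix is not in log2 space")
  v <- 2^m$values - m$pseudocount
  if (clip) v[v < 0] <- 0
  expression_matrix(v, space = "tpm", pseudocount = m$pseudocount)
}
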