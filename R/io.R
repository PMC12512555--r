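#' Read a per-sample clinical table
#'
#' Mandatory columns: `sample_id`, `tissue` (values `tumor`/`normal`).
#' Recognized optional columns: `stage` (ordinal category), `surv_time`
#' (days, >= 0), `surv_event` (0/1). Any further columns are kept as
#' covariates for [clinical_association()].
#'
#' @param path TSV path.
#' @return a `data.frame` with one row per sample, class `SampleTable`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate a sample table
#'
#' @param df a data frame with at least `sample_id` and `tissue` columns.
#' @return the validated data frame, classed `SampleTable`.
#' @export
validate_sample_table <- function(df) {
  for (col in c("sample_id", "tissue"))
    if (!col %in% names(df)) stop("sample table missing mandatory column: ", col)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(df$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if ("surv_time" %in% names(df)) {
    if (!"surv_event" %in% names(df))
      stop("surv_event must accompany surv_time")
    has_t <- !is.na(df$surv_time)
    if (any(is.na(df$surv_event[has_t])))
      stop("surv_event missing where surv_time is present")
    if (any(df$surv_time[has_t] < 0)) stop("surv_time must be >= 0")
    if (!all(df$surv_event[has_t] %in% c(0, 1)))
      stop("surv_event must be 0 or 1")
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Write a sample table to TSV
#' @param df a `SampleTable`.
#' @param path output path.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene set (one gene id per line)
#'
#' @param path text file, one identifier per line; blank lines ignored.
#' @param name name to attach to the set.
#' @return list with `name` and `members`, class `GeneSet`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  members <- readLines(path)
  members <- members[nzchar(trimws(members))]
  gene_set(members, name = name)
}

#' Construct a gene set
#' @param members character vector of unique gene ids.
#' @param name set name.
#' @return a `GeneSet`.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- as.character(members)
  if (length(members) == 0) stop("gene set is empty")
  if (anyDuplicated(members)) stop("gene set has duplicate members")
  structure(list(name = name, members = members), class = "GeneSet")
}

#' Read signature weights (TSV: gene_id <TAB> weight)
#'
#' @param path TSV path with header `gene_id` and `weight`.
#' @return named numeric vector, class `SignatureWeights`.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("gene_id", "weight"))
    if (!col %in% names(df)) stop("weights file missing column: ", col)
  signature_weights(stats::setNames(as.numeric(df$weight), df$gene_id))
}

#' Construct signature weights
#' @param w named numeric vector, gene id -> weight.
#' @return a `SignatureWeights`.
#' @export
signature_weights <- function(w) {
  if (length(w) == 0) stop("signature weights empty")
  if (is.null(names(w)) || anyDuplicated(names(w)))
    stop("signature weights must be uniquely named by gene id")
  if (anyNA(w)) stop("signature weights contain NA")
  if (length(unique(w)) < 2)
    stop("signature needs at least two distinct weight values")
  structure(w, class = "SignatureWeights")
}

#' Write signature weights to TSV
#' @param w a `SignatureWeights`.
#' @param path output path.
#' @export
write_weights <- function(w, path) {
  utils::write.table(data.frame(gene_id = names(w), weight = as.numeric(w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Event-table TSV schema: fixed columns then per-sample paired count columns
# <sample>_inc / <sample>_skip and optional per-group tpm_<group> columns.
event_fixed_cols <- c("event_id", "gene_id", "event_class",
                      "inclusion_len", "skipping_len")

#' Read a splice-event junction-count table
#'
#' Fixed columns `event_id`, `gene_id`, `event_class` (SE/RI/MXE/A3SS/A5SS),
#' `inclusion_len`, `skipping_len`, followed by paired per-sample columns
#' `<sample>_inc` / `<sample>_skip` (non-negative integers) and optional
#' per-group gene-TPM columns `tpm_<group>`.
#'
#' @param path TSV path.
#' @return list with `events` (data.frame of fixed columns), `inc` and `skip`
#'   (integer matrices events x samples), `tpm` (matrix events x groups or
#'   NULL); class `SpliceEventTable`.
#' @export
read_event_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in event_fixed_cols)
    if (!col %in% names(df)) stop("event table missing column: ", col)
  extra <- setdiff(names(df), event_fixed_cols)
  inc_cols <- grep("_inc$", extra, value = TRUE)
  skip_cols <- grep("_skip$", extra, value = TRUE)
  tpm_cols <- grep("^tpm_", extra, value = TRUE)
  samples <- sub("_inc$", "", inc_cols)
  if (!setequal(samples, sub("_skip$", "", skip_cols)))
    stop("unpaired _inc/_skip sample columns in event table")
  take_counts <- function(cols) {
    m <- as.matrix(df[cols])
    suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
    if (anyNA(num) || any(num != floor(num)) || any(num < 0))
      stop("event table counts must be non-negative integers")
    storage.mode(num) <- "integer"
    num
  }
  inc <- take_counts(paste0(samples, "_inc"))
  skip <- take_counts(paste0(samples, "_skip"))
  dimnames(inc) <- dimnames(skip) <- list(df$event_id, samples)
  tpm <- NULL
  if (length(tpm_cols)) {
    tpm <- as.matrix(df[tpm_cols])
    mode(tpm) <- "numeric"
    dimnames(tpm) <- list(df$event_id, sub("^tpm_", "", tpm_cols))
  }
  splice_event_table(df[event_fixed_cols], inc, skip, tpm)
}

#' Construct a splice-event table
#'
#' @param events data.frame of the fixed event columns.
#' @param inc,skip integer matrices of inclusion / skipping junction counts,
#'   events x samples.
#' @param tpm optional numeric matrix of per-group gene TPM, events x groups.
#' @return a `SpliceEventTable`.
#' @export
splice_event_table <- function(events, inc, skip, tpm = NULL) {
  if (anyDuplicated(events$event_id)) stop("duplicate event_id")
  if (!all(events$event_class %in% c("SE", "RI", "MXE", "A3SS", "A5SS")))
    stop("unknown event_class")
  if (any(events$inclusion_len < 1) || any(events$skipping_len < 1))
    stop("effective lengths must be >= 1")
  if (!identical(dim(inc), dim(skip)))
    stop("inc/skip matrices must have identical shape")
  if (nrow(inc) != nrow(events)) stop("count rows must match event rows")
  if (any(inc < 0) || any(skip < 0)) stop("counts must be >= 0")
  structure(list(events = as.data.frame(events), inc = inc, skip = skip,
                 tpm = tpm), class = "SpliceEventTable")
}

#' Write a splice-event table to TSV
#' @param tab a `SpliceEventTable`.
#' @param path output path.
#' @export
write_event_table <- function(tab, path) {
  stopifnot(inherits(tab, "SpliceEventTable"))
  samples <- colnames(tab$inc)
  out <- tab$events
  for (s in samples) {
    out[[paste0(s, "_inc")]] <- tab$inc[, s]
    out[[paste0(s, "_skip")]] <- tab$skip[, s]
  }
  if (!is.null(tab$tpm))
    for (g in colnames(tab$tpm)) out[[paste0("tpm_", g)]] <- tab$tpm[, g]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.SpliceEventTable <- function(x, ...) {
  cat(sprintf("SpliceEventTable: %d events x %d samples\n",
              nrow(x$events), ncol(x$inc)))
  invisible(x)
}
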