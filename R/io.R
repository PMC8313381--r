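#' Read and write probe-by-sample matrices and sample sheets
#'
#' Feature matrices are tab-separated text with a header row of sample IDs
#' and the first column holding feature (probe or gene) IDs.  Sample sheets
#' are CSV with columns `sample_id`, `tissue` (ATM/CAM/NTM) and `sex`
#' (male/female).
#'
#' @param path file path.
#' @return `read_feature_matrix()`: numeric matrix with feature rownames and
#'   sample colnames.  `read_sample_sheet()`: validated data frame.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature matrix needs an ID column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated feature IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_feature_matrix
#' @param x numeric matrix with rownames (feature IDs) and colnames (samples).
#' @param id_name header for the feature-ID column.
#' @export
write_feature_matrix <- function(x, path, id_name = "feature_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_feature_matrix
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet
#'
#' Checks the `sample_id` / `tissue` / `sex` columns, rejects unknown tissue
#' or sex labels (naming the offending sample) and requires every tissue
#' type to be present.
#'
#' @param samples data frame with columns `sample_id`, `tissue`, `sex`.
#' @return the validated data frame (character columns), invisibly usable.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "tissue", "sex")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$tissue <- as.character(samples$tissue)
  samples$sex <- as.character(samples$sex)
  if (anyNA(samples[need]) || any(samples$tissue == "") || any(samples$sex == ""))
    stop("sample sheet contains missing tissue/sex values")
  bad <- !samples$tissue %in% c("ATM", "CAM", "NTM")
  if (any(bad))
    stop("unknown tissue label for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "),
         " (expected ATM, CAM or NTM)")
  bad <- !samples$sex %in% c("male", "female")
  if (any(bad))
    stop("unknown sex label for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "),
         " (expected male or female)")
  if (!all(c("ATM", "CAM", "NTM") %in% samples$tissue))
    stop("every tissue type (ATM, CAM, NTM) must be present")
  samples
}

# align a matrix's columns with a sample sheet, erroring on mismatch
.align_samples <- function(x, samples) {
  samples <- validate_sample_sheet(samples)
  if (ncol(x) != nrow(samples))
    stop("matrix has ", ncol(x), " columns but sample sheet has ",
         nrow(samples), " rows")
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), samples$sample_id))
      stop("matrix column names do not match sample sheet sample_ids")
    x <- x[, samples$sample_id, drop = FALSE]
  }
  list(x = x, samples = samples)
}
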