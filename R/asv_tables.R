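#' ASV count table
#'
#' Constructs the package's central container: a samples x ASVs matrix of
#' non-negative integer read counts with unique sample and ASV identifiers.
#' Counts are stored as integers end-to-end; relative abundances are derived
#' on demand and never stored, so that rarefaction always operates on reads.
#'
#' @param counts numeric matrix (samples in rows, ASVs in columns) with
#'   rownames (sample IDs) and colnames (ASV IDs), or any object coercible
#'   to such a matrix. All entries must be non-negative integers.
#' @param sample_ids,asv_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An object of class `asv_table`: an integer matrix with dimnames.
#' @examples
#' tab <- asv_table(matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'                         dimnames = list(c("s1", "s2"), c("ASV1", "ASV2"))))
#' library_sizes(tab)
#' @export
asv_table <- function(counts, sample_ids = NULL, asv_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(asv_ids)) colnames(counts) <- asv_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("asv_table requires sample IDs (rownames) and ASV IDs (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be non-negative integers; offending cell: sample '%s', ASV '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("asv_table", "matrix", "array"))
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d samples x %d ASVs, %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat("library sizes: ", paste(range(rowSums(x)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @rdname asv_table
#' @param x an `asv_table`
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname asv_table
#' @export
asv_ids <- function(x) colnames(x)

#' @rdname asv_table
#' @export
library_sizes <- function(x) {
  rs <- rowSums(unclass(x))
  stats::setNames(as.integer(rs), names(rs))
}

# subsetting keeps the class and never drops dimensions
#' @export
`[.asv_table` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  structure(out, class = c("asv_table", "matrix", "array"))
}

sample_types <- c("mat", "saliva", "skin", "feces", "negative_control")
timepoint_levels <- c("S", "A", "W")

#' Read an ASV count table
#'
#' Two dialects are supported. `plain_tsv`: header row of ASV IDs, first
#' column holds sample IDs. `mothur_shared`: the mothur "shared" layout with
#' leading `label`, `Group` and `numOtus` columns, which are dropped
#' (`Group` supplies the sample IDs).
#'
#' @param path path to a tab-separated file
#' @param dialect `"plain_tsv"` or `"mothur_shared"`
#' @return an [asv_table]
#' @export
read_count_table <- function(path, dialect = c("plain_tsv", "mothur_shared")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(df)))
      stop("mothur_shared file must have columns label/Group/numOtus; found: ",
           paste(utils::head(names(df), 5), collapse = ", "))
    ids <- df$Group
    df <- df[, setdiff(names(df), need), drop = FALSE]
  } else {
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v))
      stop(sprintf("non-numeric count in column '%s', row '%s'",
                   names(df)[j], ids[which(is.na(v))[1]]))
    m[, j] <- v
  }
  asv_table(m)
}

#' Write an ASV count table
#'
#' Inverse of [read_count_table()]; read-write-read round-trips preserve
#' row/column order and counts exactly.
#'
#' @param x an [asv_table]
#' @param path output path
#' @param dialect output dialect, see [read_count_table()]
#' @param label value for the mothur `label` column (default `"asv"`)
#' @export
write_count_table <- function(x, path, dialect = c("plain_tsv", "mothur_shared"),
                              label = "asv") {
  dialect <- match.arg(dialect)
  m <- unclass(x)
  if (dialect == "plain_tsv") {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  } else {
    df <- data.frame(label = label, Group = rownames(m), numOtus = ncol(m),
                     m, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Expects a TSV with two columns: ASV ID and a semicolon-delimited lineage
#' (domain to genus). Per-rank bootstrap confidence suffixes such as
#' `"(100)"` are stripped; trailing semicolons are tolerated.
#'
#' @param path path to taxonomy TSV (with or without a header line whose
#'   first field is `asv_id` or mothur's `OTU`)
#' @return data.frame with columns `asv_id` (character) and `lineage`
#'   (list column of character vectors)
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (tolower(df[1, 1]) %in% c("asv_id", "otu", "asv"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("taxonomy file must have two tab-separated columns")
  asv_id <- df[[1]]
  if (anyDuplicated(asv_id))
    stop("duplicate ASV IDs in taxonomy: ",
         paste(unique(asv_id[duplicated(asv_id)]), collapse = ", "))
  lineage <- lapply(df[[2]], function(s) {
    s <- gsub("\\([0-9.]+\\)", "", s)          # strip bootstrap values
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts[nzchar(parts)]
  })
  if (any(lengths(lineage) == 0))
    stop("empty lineage for ASV: ", asv_id[which(lengths(lineage) == 0)[1]])
  data.frame(asv_id = asv_id, lineage = I(lineage))
}

#' Read sample and subject metadata
#'
#' One TSV drives both the sample records and the per-(subject, timepoint)
#' covariates. Required columns: `sample_id`, `subject_id`, `sample_type`,
#' `timepoint`, `replicate`. Recognized covariate columns: `built`,
#' `outdoor`, `gardening`, `pets`, `handwashing`, `number_of_persons`,
#' `real_mat_days`, `urban`, `antibiotics_last_6mo`, `cohort`, `sex`.
#' Empty cells become `NA` (missing), never zero: the model-selection
#' protocol branches on missingness, so it must stay explicit.
#'
#' @param path path to metadata TSV
#' @return a list with elements `samples` (one row per sample: sample_id,
#'   subject_id, sample_type, timepoint, replicate) and `subjects` (one row
#'   per subject x timepoint with the covariates)
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = c("", "NA"))
  need <- c("sample_id", "subject_id", "sample_type", "timepoint", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing required columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$sample_type %in% sample_types)
  if (length(bad))
    stop("unknown sample_type in metadata row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$sample_type[bad]), collapse = ", "))
  bad <- which(!df$timepoint %in% timepoint_levels)
  if (length(bad))
    stop("unknown timepoint in metadata row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$timepoint[bad]), collapse = ", "))
  is_nc <- df$sample_type == "negative_control"
  if (any(is_nc & !is.na(df$subject_id)))
    stop("negative-control rows must have empty subject_id; offending row(s): ",
         paste(which(is_nc & !is.na(df$subject_id)), collapse = ", "))
  if (any(!is_nc & is.na(df$subject_id)))
    stop("non-control rows must have a subject_id; offending row(s): ",
         paste(which(!is_nc & is.na(df$subject_id)), collapse = ", "))
  samples <- data.frame(
    sample_id = df$sample_id,
    subject_id = df$subject_id,
    sample_type = df$sample_type,
    timepoint = df$timepoint,
    replicate = as.integer(df$replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_records(samples)

  cov_cols <- intersect(
    c("built", "outdoor", "gardening", "pets", "handwashing",
      "number_of_persons", "real_mat_days", "urban", "antibiotics_last_6mo",
      "cohort", "sex"),
    names(df))
  subjects <- NULL
  if (length(cov_cols)) {
    sub <- df[!is_nc, c("subject_id", "timepoint", cov_cols), drop = FALSE]
    sub <- sub[!duplicated(sub[, c("subject_id", "timepoint")]), , drop = FALSE]
    num_cols <- intersect(c("built", "outdoor", "number_of_persons",
                            "real_mat_days"), cov_cols)
    for (cc in num_cols) sub[[cc]] <- as.numeric(sub[[cc]])
    if ("antibiotics_last_6mo" %in% cov_cols)
      sub$antibiotics_last_6mo <- as.logical(toupper(sub$antibiotics_last_6mo) %in%
                                               c("TRUE", "T", "YES", "1"))
    validate_covariates(sub)
    rownames(sub) <- NULL
    subjects <- sub
  }
  list(samples = samples, subjects = subjects)
}

validate_sample_records <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  nc <- samples$sample_type == "negative_control"
  key <- paste(samples$subject_id, samples$sample_type, samples$timepoint,
               samples$replicate)[!nc]
  if (anyDuplicated(key))
    stop("duplicate (subject, sample_type, timepoint, replicate): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(samples$replicate < 1, na.rm = TRUE))
    stop("replicate index must be >= 1")
  invisible(samples)
}

validate_covariates <- function(subjects) {
  chk <- function(col, lo, hi) {
    v <- subjects[[col]]
    if (!is.null(v) && any(!is.na(v) & (v < lo | v > hi)))
      stop(sprintf("covariate '%s' out of range [%g, %g]", col, lo, hi))
  }
  chk("built", 0, 100); chk("outdoor", 0, 4); chk("number_of_persons", 1, 5)
  enum <- function(col, levels) {
    v <- subjects[[col]]
    if (!is.null(v) && any(!is.na(v) & !v %in% levels))
      stop(sprintf("covariate '%s' must be one of {%s}", col,
                   paste(levels, collapse = ", ")))
  }
  enum("gardening", c("rarely", "at_least_monthly"))
  enum("pets", c("yes", "no"))
  enum("handwashing", c("max_once_a_day", "many_times_a_day"))
  enum("urban", c("u", "r"))
  invisible(subjects)
}

#' Write metadata to TSV
#'
#' Serializes the sample records and covariates back into the single-file
#' layout accepted by [read_metadata()] (covariates repeated on every sample
#' row of the owning subject x timepoint).
#'
#' @param metadata list with `samples` and `subjects` as from [read_metadata()]
#' @param path output path
#' @export
write_metadata <- function(metadata, path) {
  df <- metadata$samples
  if (!is.null(metadata$subjects)) {
    df <- merge(df, metadata$subjects, by = c("subject_id", "timepoint"),
                all.x = TRUE, sort = FALSE)
    df <- df[, c("sample_id", "subject_id", "sample_type", "timepoint",
                 "replicate",
                 setdiff(names(df), c("sample_id", "subject_id", "sample_type",
                                      "timepoint", "replicate")))]
    df <- df[order(match(df$sample_id, metadata$samples$sample_id)), ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Align a count table with sample metadata
#'
#' Restricts the table to samples present in both the table and the sample
#' records. Mismatches are reported, never fatal -- except when the
#' intersection is empty.
#'
#' @param table an [asv_table]
#' @param records sample records data.frame (see [read_metadata()])
#' @return list with `table` (restricted [asv_table]), `records` (restricted
#'   records, table order), and `report` (list `table_only`, `metadata_only`)
#' @export
align_samples <- function(table, records) {
  common <- intersect(sample_ids(table), records$sample_id)
  if (length(common) == 0)
    stop("no samples in common between the count table and the metadata")
  report <- list(table_only = setdiff(sample_ids(table), common),
                 metadata_only = setdiff(records$sample_id, common))
  tab <- table[match(common, sample_ids(table)), , drop = FALSE]
  recs <- records[match(common, records$sample_id), , drop = FALSE]
  rownames(recs) <- NULL
  list(table = tab, records = recs, report = report)
}
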