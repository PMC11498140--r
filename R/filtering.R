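#' @name filtering
#' @title Post-classification filtering chain and rarefaction
#'
#' @description
#' The filters applied, in this fixed order, before any downstream
#' statistic: (1) lineage blacklist removal, (2) global singleton removal,
#' (3) strict negative-control ASV removal, (4) replicate merging,
#' (5) rarefaction to a common depth. Each step returns the filtered table
#' together with a one-row `filter_report` data.frame
#' (step, asvs_removed, samples_removed, reads_removed) for auditing.
NULL

filter_report <- function(step, before, after, samples_removed = NULL) {
  data.frame(
    step = step,
    asvs_removed = ncol(before) - ncol(after),
    samples_removed = nrow(before) - nrow(after),
    reads_removed = sum(as.numeric(before)) - sum(as.numeric(after)),
    stringsAsFactors = FALSE
  )
}

#' Remove ASVs by lineage blacklist
#'
#' Drops every ASV whose lineage contains any blacklisted label
#' (case-insensitive exact label match at any rank). The default blacklist
#' removes non-bacterial and organellar reads: chloroplast, mitochondria,
#' unknown, Archaea, Eukaryota.
#'
#' @param table an [asv_table]
#' @param taxonomy taxonomy data.frame from [read_taxonomy()]; must cover
#'   every ASV in `table`
#' @param blacklist character vector of lineage labels to remove
#' @return list with `table` and `report`
#' @export
remove_by_lineage <- function(table, taxonomy,
                              blacklist = c("Chloroplast", "Mitochondria",
                                            "unknown", "Archaea", "Eukaryota")) {
  miss <- setdiff(asv_ids(table), taxonomy$asv_id)
  if (length(miss))
    stop("ASVs missing from taxonomy: ", paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10) else "")
  bl <- tolower(blacklist)
  lin <- taxonomy$lineage[match(asv_ids(table), taxonomy$asv_id)]
  hit <- vapply(lin, function(l) any(tolower(l) %in% bl), logical(1))
  out <- table[, !hit, drop = FALSE]
  list(table = out, report = filter_report("remove_by_lineage", table, out))
}

#' Remove global singletons and vacant ASVs
#'
#' An ASV whose total count over the WHOLE table (all sample types combined)
#' is exactly one is treated as a sequencing error and removed; all-zero
#' columns are dropped too. Idempotent.
#'
#' @param table an [asv_table]
#' @return list with `table` and `report`
#' @export
remove_global_singletons <- function(table) {
  tot <- colSums(unclass(table))
  out <- table[, tot > 1, drop = FALSE]
  list(table = out, report = filter_report("remove_global_singletons", table, out))
}

#' Strict negative-control ASV removal
#'
#' Drops every ASV detected (count > 0) in at least one negative-control
#' sample, then drops the control samples themselves. This is deliberately a
#' presence-based rule, not a model-based decontamination: contamination
#' shared across sample types would otherwise inflate shared-taxa counts.
#'
#' @param table an [asv_table]
#' @param control_sample_ids character vector of control sample IDs
#'   (must all be present in the table)
#' @return list with `table`, `report`, and `control_asvs` (the removed IDs)
#' @export
remove_control_asvs <- function(table, control_sample_ids) {
  unknown <- setdiff(control_sample_ids, sample_ids(table))
  if (length(unknown))
    stop("unknown control sample IDs: ", paste(unknown, collapse = ", "))
  if (length(control_sample_ids) == 0) {
    rep0 <- filter_report("remove_control_asvs", table, table)
    return(list(table = table, report = rep0, control_asvs = character(0)))
  }
  ctrl <- unclass(table)[sample_ids(table) %in% control_sample_ids, , drop = FALSE]
  bad_asv <- colSums(ctrl > 0) > 0
  keep_samples <- !sample_ids(table) %in% control_sample_ids
  out <- table[keep_samples, !bad_asv, drop = FALSE]
  list(table = out,
       report = filter_report("remove_control_asvs", table, out),
       control_asvs = asv_ids(table)[bad_asv])
}

#' Merge technical replicates
#'
#' Doormat DNA extractions may come as up to three replicates per mat; the
#' analysis needs one community per (subject, sample type, timepoint).
#' Replicate counts are summed element-wise (summation keeps counts integral
#' for the hypergeometric subsampling that follows). The merged sample keeps
#' the replicate-1 ID when present, otherwise the lexicographically first
#' member ID; its record gets `replicate = 1`.
#'
#' @param table an [asv_table]
#' @param records sample records data.frame covering the table's samples
#' @return list with `table` and `records` (one row per merged sample)
#' @export
merge_replicates <- function(table, records) {
  al <- align_samples(table, records)
  table <- al$table; records <- al$records
  key <- ifelse(records$sample_type == "negative_control",
                paste0("nc:", records$sample_id),
                paste(records$subject_id, records$sample_type,
                      records$timepoint, sep = "|"))
  groups <- split(seq_len(nrow(records)), key)
  m <- unclass(table)
  out_counts <- matrix(0L, length(groups), ncol(m),
                       dimnames = list(NULL, colnames(m)))
  out_rec <- records[rep(1L, length(groups)), , drop = FALSE]
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    out_counts[g, ] <- as.integer(colSums(m[idx, , drop = FALSE]))
    first <- idx[order(records$replicate[idx], records$sample_id[idx])][1]
    out_rec[g, ] <- records[first, ]
  }
  out_rec$replicate <- 1L
  rownames(out_counts) <- out_rec$sample_id
  ord <- match(unique(key), names(groups))  # preserve first-appearance order
  out_counts <- out_counts[ord, , drop = FALSE]
  out_rec <- out_rec[ord, , drop = FALSE]
  rownames(out_rec) <- NULL
  list(table = asv_table(out_counts), records = out_rec)
}

# exact multivariate hypergeometric draw: `depth` reads without replacement
rarefy_one <- function(counts, depth) {
  n <- sum(counts)
  if (n == depth) return(counts)
  reads <- rep.int(seq_along(counts), counts)
  kept <- reads[sample.int(n, depth)]
  out <- tabulate(kept, nbins = length(counts))
  storage.mode(out) <- "integer"
  out
}

#' Rarefy samples to a common depth
#'
#' Draws exactly `depth` reads per sample without replacement (a single
#' multivariate-hypergeometric pass, not repeated-rarefaction averaging).
#' With `depth = "auto_per_type"` the depth is the minimum library size
#' within each sample type, computed on the table as given (i.e., after all
#' ASV filters). Samples with fewer reads than the applicable depth are
#' dropped and reported.
#'
#' @param table an [asv_table]
#' @param depth positive integer, or `"auto_per_type"` (requires `records`)
#' @param records sample records (needed for `"auto_per_type"`)
#' @param seed integer seed making the draw reproducible
#' @return list with `table`, `report`, and `depths` (named by sample type
#'   for auto mode, else a single value)
#' @export
rarefy <- function(table, depth = "auto_per_type", records = NULL, seed = 1L) {
  libs <- library_sizes(table)
  if (identical(depth, "auto_per_type")) {
    if (is.null(records)) stop("auto_per_type rarefaction requires sample records")
    al <- align_samples(table, records)
    table <- al$table; records <- al$records
    libs <- library_sizes(table)
    depths_by_type <- c(tapply(libs, records$sample_type, min))
    storage.mode(depths_by_type) <- "integer"
    target <- as.integer(depths_by_type[records$sample_type])
  } else {
    depth <- as.integer(depth)
    if (is.na(depth) || depth < 1) stop("depth must be a positive integer")
    depths_by_type <- depth
    target <- rep(depth, nrow(table))
  }
  keep <- libs >= target
  m <- unclass(table)[keep, , drop = FALSE]
  target <- target[keep]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(nrow(m))) m[i, ] <- rarefy_one(m[i, ], target[i])
  out <- asv_table(m)
  rep_df <- filter_report("rarefy", table, out)
  list(table = out, report = rep_df, depths = depths_by_type, seed = seed)
}

#' Run the full filtering chain
#'
#' Convenience wrapper enforcing the pipeline order: lineage removal,
#' global-singleton removal, negative-control ASV removal, replicate merge,
#' rarefaction.
#'
#' @param table an [asv_table] including negative-control samples
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()])
#' @param records sample records data.frame
#' @param blacklist lineage blacklist (see [remove_by_lineage()])
#' @param depth rarefaction depth or `"auto_per_type"`
#' @param seed rarefaction seed
#' @return list with `table` (filtered, merged, rarefied), `records`
#'   (post-merge, controls removed), `report` (row-bound filter reports),
#'   and `control_asvs`
#' @export
filter_pipeline <- function(table, taxonomy, records,
                            blacklist = c("Chloroplast", "Mitochondria",
                                          "unknown", "Archaea", "Eukaryota"),
                            depth = "auto_per_type", seed = 1L) {
  al <- align_samples(table, records)
  table <- al$table; records <- al$records
  s1 <- remove_by_lineage(table, taxonomy, blacklist)
  s2 <- remove_global_singletons(s1$table)
  ctrl_ids <- records$sample_id[records$sample_type == "negative_control"]
  s3 <- remove_control_asvs(s2$table, ctrl_ids)
  records3 <- records[records$sample_type != "negative_control", , drop = FALSE]
  s4 <- merge_replicates(s3$table, records3)
  s5 <- rarefy(s4$table, depth = depth, records = s4$records, seed = seed)
  kept <- align_samples(s5$table, s4$records)
  list(table = kept$table,
       records = kept$records,
       report = rbind(s1$report, s2$report, s3$report, s5$report),
       control_asvs = s3$control_asvs,
       depths = s5$depths)
}
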