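#' @name shared_taxa
#' @title Shared-taxa statistics between human and doormat samples
#'
#' @description
#' The dispersal-potential statistic: for each human sample (saliva, skin or
#' feces) paired with the same subject's doormat sample at the same
#' timepoint, the count of ASVs present in both, divided by the human
#' sample's ASV richness. Presence means at least one read after
#' rarefaction. The proportion is carried as an integer (k, n) pair so the
#' binomial model downstream keeps its denominator.
NULL

#' Presence set of a sample
#'
#' @param table an [asv_table]
#' @param sample_id a sample ID present in the table
#' @return character vector of ASV IDs with positive count
#' @export
presence_set <- function(table, sample_id) {
  i <- match(sample_id, sample_ids(table))
  if (is.na(i)) stop("unknown sample: ", sample_id)
  asv_ids(table)[unclass(table)[i, ] > 0]
}

#' Pair human samples with doormat samples
#'
#' A pair is emitted iff a subject has BOTH the human sample and a mat
#' sample at the same timepoint. Skin is never sampled in winter, so no
#' skin pair can exist at timepoint W. Unpaired human samples are reported.
#'
#' @param records post-merge sample records (one sample per subject, type,
#'   timepoint)
#' @return list with `pairs` (data.frame: human_sample_id, mat_sample_id,
#'   subject_id, timepoint, human_type) and `unpaired` (character vector of
#'   human sample IDs without a mat partner)
#' @export
pair_samples <- function(records) {
  hum <- records[records$sample_type %in% c("saliva", "skin", "feces"), , drop = FALSE]
  mat <- records[records$sample_type == "mat", , drop = FALSE]
  mkey <- paste(mat$subject_id, mat$timepoint)
  hit <- match(paste(hum$subject_id, hum$timepoint), mkey)
  pairs <- data.frame(
    human_sample_id = hum$sample_id[!is.na(hit)],
    mat_sample_id = mat$sample_id[hit[!is.na(hit)]],
    subject_id = hum$subject_id[!is.na(hit)],
    timepoint = hum$timepoint[!is.na(hit)],
    human_type = hum$sample_type[!is.na(hit)],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, unpaired = hum$sample_id[is.na(hit)])
}

#' Shared-ASV statistic for one human/mat pair
#'
#' @param human_set,mat_set character vectors of ASV IDs (presence sets)
#' @return list with `k` (shared count), `n` (human richness), `proportion`
#'   (k/n), and `shared_asv_ids`
#' @export
shared_statistic <- function(human_set, mat_set) {
  n <- length(unique(human_set))
  if (n == 0) stop("empty human presence set: shared proportion is undefined")
  shared <- intersect(human_set, mat_set)
  list(k = length(shared), n = n, proportion = length(shared) / n,
       shared_asv_ids = shared)
}

#' Shared-taxa table over all pairs
#'
#' One row per human/mat pair: subject, timepoint, human sample type, shared
#' count `k`, human richness `n`, mat richness, and the proportion `k/n`.
#' Zero-share rows are retained (zeros are data, not missing).
#'
#' @param table a rarefied [asv_table]
#' @param records post-merge sample records
#' @return data.frame of class `shared_table` with attribute
#'   `shared_asv_ids` (named list per row)
#' @export
shared_table <- function(table, records) {
  pr <- pair_samples(records)$pairs
  nr <- nrow(pr)
  out <- data.frame(
    subject_id = pr$subject_id, timepoint = pr$timepoint,
    human_type = pr$human_type,
    k = integer(nr), n = integer(nr), mat_richness = integer(nr),
    proportion = numeric(nr), stringsAsFactors = FALSE
  )
  shared_ids <- vector("list", nr)
  for (i in seq_len(nr)) {
    hs <- presence_set(table, pr$human_sample_id[i])
    ms <- presence_set(table, pr$mat_sample_id[i])
    st <- shared_statistic(hs, ms)
    out$k[i] <- st$k; out$n[i] <- st$n
    out$mat_richness[i] <- length(ms)
    out$proportion[i] <- st$proportion
    shared_ids[[i]] <- st$shared_asv_ids
  }
  attr(out, "shared_asv_ids") <- shared_ids
  class(out) <- c("shared_table", "data.frame")
  out
}

#' Data-characteristics summary of a shared table
#'
#' Per (human type, timepoint) stratum: number of pairs, and mean (min-max)
#' of human richness, mat richness, shared richness and percent shared, in
#' the shape of a data-characteristics table.
#'
#' @param shared a [shared_table()] result
#' @return data.frame, one row per human_type x timepoint
#' @export
shared_summaries <- function(shared) {
  key <- interaction(shared$human_type, shared$timepoint, drop = TRUE)
  fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", mean(v), min(v), max(v))
  rows <- lapply(split(seq_len(nrow(shared)), key), function(idx) {
    s <- shared[idx, ]
    data.frame(human_type = s$human_type[1], timepoint = s$timepoint[1],
               n_pairs = nrow(s),
               tot_richness_human = fmt(s$n),
               tot_richness_mat = fmt(s$mat_richness),
               shared_richness = fmt(s$k),
               pct_shared = fmt(100 * s$proportion),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$human_type, match(out$timepoint, timepoint_levels)), ]
}

#' Venn partition of labeled ASV sets
#'
#' Exact disjoint region counts for 2-4 labeled sets: one region per
#' non-empty label subset, counting the ASVs belonging to exactly those
#' sets. Region counts sum to the size of the union.
#'
#' @param sets named list (2-4 elements) of character vectors
#' @return data.frame with columns `region` (labels joined by `&`) and
#'   `count`, ordered by subset size then label order
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set labels")
  L <- length(sets)
  if (L < 2 || L > 4) stop("venn_partition supports 2-4 sets")
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  # signature of each universe element: which labeled sets contain it
  sig <- vapply(univ, function(a) {
    inset <- vapply(sets, function(s) a %in% s, logical(1))
    paste(names(sets)[inset], collapse = "&")
  }, character(1))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), L))[-1, , drop = FALSE]
  region <- apply(subsets, 1, function(w) paste(names(sets)[as.logical(w)], collapse = "&"))
  count <- vapply(region, function(r) sum(sig == r), integer(1))
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(vapply(strsplit(out$region, "&", fixed = TRUE), length, integer(1))), ]
}

#' Venn partition across sample types
#'
#' Builds, for each sample type, the union of presence sets over the
#' included subjects' samples at one timepoint, and partitions them. With
#' `complete_cases = TRUE` (default) only subjects having ALL requested
#' sample types at that timepoint contribute, mirroring a complete-case
#' multi-type Venn diagram.
#'
#' @param table a rarefied [asv_table]
#' @param records post-merge sample records
#' @param timepoint single timepoint code ("S", "A" or "W")
#' @param types sample types to include
#' @param complete_cases restrict to subjects with all `types` available
#' @return list with `partition` (see [venn_partition()]), `n_subjects`,
#'   and `sets` (the per-type union sets)
#' @export
venn_by_type <- function(table, records, timepoint = "S",
                         types = c("mat", "saliva", "skin", "feces"),
                         complete_cases = TRUE) {
  rec <- records[records$timepoint == timepoint &
                   records$sample_type %in% types, , drop = FALSE]
  if (complete_cases) {
    per_subj <- tapply(rec$sample_type, rec$subject_id,
                       function(tt) all(types %in% tt))
    keep <- names(per_subj)[per_subj]
    rec <- rec[rec$subject_id %in% keep, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("no samples left for the Venn partition")
  sets <- lapply(types, function(tt) {
    ids <- rec$sample_id[rec$sample_type == tt]
    unique(unlist(lapply(ids, presence_set, table = table), use.names = FALSE))
  })
  names(sets) <- types
  list(partition = venn_partition(sets),
       n_subjects = length(unique(rec$subject_id)),
       sets = sets)
}
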