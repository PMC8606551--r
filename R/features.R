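# Geometric feature extraction and labeled dataset assembly: four features
# per (model, segment) row - segment myocardial volume, segment ischemic
# percentage, total myocardial volume, total ischemic volume.

#' Extract the four geometric features per AHA segment
#'
#' Volumes are element sums; the segment ischemic percentage is the
#' ischemic volume inside the segment over the segment volume, in percent.
#' The two global features repeat across a model's 17 rows.
#'
#' @param geom a `ventricle_geometry` with segments (and layers) assigned.
#' @return Data frame with 17 rows: `segment_id`, `seg_vol`,
#'   `seg_isch_pct`, `total_vol`, `total_isch_vol`.
#' @export
extract_features <- function(geom) {
  if (all(is.na(geom$segment_id))) stop("segments not assigned")
  segs <- 1:17
  vols <- geometry_volumes(geom)
  rows <- lapply(segs, function(sgid) {
    idx <- which(geom$mask & !is.na(geom$segment_id) &
                   geom$segment_id == sgid)
    if (length(idx) == 0)
      stop(sprintf("AHA segment %d is empty", sgid))
    sv <- sum(geom$element_volume[idx])
    iv <- sum(geom$element_volume[idx][geom$region_label[idx] > 0])
    data.frame(segment_id = sgid, seg_vol = sv,
               seg_isch_pct = 100 * iv / sv,
               total_vol = unname(vols["total"]),
               total_isch_vol = unname(vols["ischemic"]))
  })
  do.call(rbind, rows)
}

#' Assemble a labeled risk dataset
#'
#' Joins per-model feature rows with protocol outcomes into the
#' (model, segment) classification table. UR and R map to the positive
#' (arrhythmia) class, NR to the negative class.
#'
#' @param features named list: per model id, the 17-row feature frame from
#'   [extract_features()].
#' @param outcomes data frame `model_id`, `segment`, `outcome` (as from
#'   [evaluate_population()]).
#' @return A `risk_dataset` data frame with columns `model_id`,
#'   `segment_id`, `seg_vol`, `seg_isch_pct`, `total_vol`,
#'   `total_isch_vol`, `label` (integer 0/1).
#' @export
build_dataset <- function(features, outcomes) {
  stopifnot(is.list(features), length(features) > 0)
  rows <- list()
  for (mid in names(features)) {
    f <- features[[mid]]
    f$model_id <- mid
    rows[[mid]] <- f
  }
  feat <- do.call(rbind, rows)
  key_f <- paste(feat$model_id, feat$segment_id)
  if (anyDuplicated(key_f))
    stop("duplicate (model, segment) feature rows: ",
         paste(head(key_f[duplicated(key_f)], 5), collapse = ", "))
  out_key <- paste(outcomes$model_id, outcomes$segment)
  if (anyDuplicated(out_key))
    stop("duplicate (model, segment) outcome rows: ",
         paste(head(out_key[duplicated(out_key)], 5), collapse = ", "))
  m <- match(key_f, out_key)
  if (anyNA(m))
    stop("missing outcome for key(s): ",
         paste(head(key_f[is.na(m)], 5), collapse = ", "),
         if (sum(is.na(m)) > 5) sprintf(" (+%d more)", sum(is.na(m)) - 5)
         else "")
  feat$label <- as.integer(outcomes$outcome[m] %in% c("UR", "R"))
  ds <- feat[c("model_id", "segment_id", "seg_vol", "seg_isch_pct",
               "total_vol", "total_isch_vol", "label")]
  rownames(ds) <- NULL
  class(ds) <- c("risk_dataset", "data.frame")
  ds
}

#' @export
print.risk_dataset <- function(x, ...) {
  cat(sprintf("risk_dataset: %d rows (%d models), positive rate %.3f\n",
              nrow(x), length(unique(x$model_id)), mean(x$label)))
  NextMethod()
}

#' Write / read a risk dataset as CSV
#'
#' @param ds a `risk_dataset`.
#' @param path CSV path.
#' @return `path` / the dataset.
#' @export
write_dataset <- function(ds, path) {
  write.csv(ds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("model_id", "segment_id", "seg_vol", "seg_isch_pct",
              "total_vol", "total_isch_vol", "label")
  miss <- setdiff(needed, names(ds))
  if (length(miss)) stop("dataset missing column(s): ",
                         paste(miss, collapse = ", "))
  class(ds) <- c("risk_dataset", "data.frame")
  ds
}
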