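# On-disk cohort layout: per subject one tab-separated time-series file
# (header region_001...) and one tab-separated motion file (trans_*/rot_*
# columns); a comma-separated behavior table; a comma-separated centroid
# table; JSON ground truth; and a JSON manifest with md5 checksums. Numeric
# values are written at 17 significant digits so round trips are bit-exact.

write_numeric_table <- function(m, path, sep) {
  m <- as.matrix(m)
  txt <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = sep))
  header <- paste(colnames(m), collapse = sep)
  writeLines(c(header, txt), path)
}

read_numeric_table <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  as.matrix(df)
}

#' Write a synthetic cohort to disk
#'
#' @param cohort a `synthetic_cohort` (see [simulate_cohort()]).
#' @param out_dir output directory (created if absent).
#' @return the manifest (invisibly): list with `files` (name -> md5) and
#'   counts. Layout: `<id>_timeseries.tsv` and `<id>_motion.tsv` per subject,
#'   `behavior.csv`, `centroids.csv`, `ground_truth.json`, `manifest.json`.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  files <- character(0)
  put <- function(name) {
    files[[length(files) + 1]] <<- name
    file.path(out_dir, name)
  }
  for (s in seq_along(cohort$series)) {
    id <- cohort$series[[s]]$subject_id
    write_numeric_table(
      cohort$series[[s]]$data, put(sprintf("%s_timeseries.tsv", id)), "\t"
    )
    write_numeric_table(
      cohort$motion[[s]]$params, put(sprintf("%s_motion.tsv", id)), "\t"
    )
  }
  beh <- cohort$behavior
  beh_path <- put("behavior.csv")
  utils::write.csv(
    data.frame(
      beh[, c("subject_id", "site", "family_id")],
      lapply(beh[, setdiff(names(beh), c("subject_id", "site", "family_id"))],
             sprintf, fmt = "%.17g"),
      check.names = FALSE, stringsAsFactors = FALSE
    ),
    beh_path, row.names = FALSE, quote = FALSE
  )
  cent <- cohort$network$centroids
  cent_df <- cbind(region = seq_len(nrow(cent)), cent)
  write_numeric_table(cent_df, put("centroids.csv"), ",")
  gt_path <- put("ground_truth.json")
  jsonlite::write_json(
    list(
      spec = unclass(cohort$spec),
      coupling_coefficients = cohort$network$coupling_coefficients,
      innovation_covariance = cohort$network$innovation_covariance,
      edge_susceptibility = cohort$ground_truth$edge_susceptibility,
      behavior_weights = cohort$ground_truth$behavior_weights,
      per_subject_motion_severity = cohort$ground_truth$per_subject_motion_severity,
      per_subject_gain = cohort$ground_truth$per_subject_gain
    ),
    gt_path, digits = NA, auto_unbox = TRUE
  )
  sums <- as.character(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    n_subjects = length(cohort$series),
    tr_s = cohort$spec$tr_s,
    subject_ids = vapply(cohort$series, `[[`, "", "subject_id"),
    files = stats::setNames(as.list(sums), files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Verifies every file's md5 checksum against the manifest before reading;
#' any mismatch is an error naming the file.
#'
#' @param dir cohort directory.
#' @return list with `series` (list of `parcellated_ts`), `motion` (list of
#'   `motion_trace`), `behavior` (data.frame), `centroids` (matrix),
#'   `ground_truth` (parsed JSON), `manifest`.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop(sprintf("no manifest.json in '%s'", dir))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (f in names(manifest$files)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop(sprintf("missing cohort file '%s'", path))
    actual <- as.character(tools::md5sum(path))
    if (!identical(actual, manifest$files[[f]])) {
      stop(sprintf("checksum mismatch for '%s' (file edited or corrupted)", path))
    }
  }
  tr_s <- manifest$tr_s
  ids <- manifest$subject_ids
  series <- lapply(ids, function(id) {
    parcellated_ts(
      read_numeric_table(file.path(dir, sprintf("%s_timeseries.tsv", id)), "\t"),
      tr_s, id
    )
  })
  motion <- lapply(ids, function(id) {
    motion_trace(
      read_numeric_table(file.path(dir, sprintf("%s_motion.tsv", id)), "\t"),
      tr_s, id
    )
  })
  behavior <- utils::read.csv(file.path(dir, "behavior.csv"),
    stringsAsFactors = FALSE
  )
  centroids <- read_numeric_table(file.path(dir, "centroids.csv"), ",")[, -1, drop = FALSE]
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
    simplifyVector = TRUE
  )
  list(
    series = series, motion = motion, behavior = behavior,
    centroids = centroids, ground_truth = gt, manifest = manifest
  )
}
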