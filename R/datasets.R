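# Manifest handling, the referable-DR label rule, stratified cross-validation
# splits and label-fraction subsampling.

MANIFEST_COLS <- c("image_id", "path", "dr_grade", "referable", "split")

#' Map a DR grade to the referable label
#'
#' Referable diabetic retinopathy is moderate non-proliferative disease or
#' worse, i.e. grade >= 2 on the 0-4 EyePACS severity scale.
#'
#' @param grade Integer vector of grades in 0..4.
#' @return Logical vector: `TRUE` iff grade >= 2.
#' @export
grade_to_referable <- function(grade) {
  if (length(grade) == 0) return(logical(0))
  if (any(is.na(grade)) || any(grade %% 1 != 0) || any(grade < 0) || any(grade > 4)) {
    stop("grades must be integers in 0..4", call. = FALSE)
  }
  grade >= 2
}

#' Construct a manifest from a data frame
#'
#' Validates the schema and the label invariant `referable == (dr_grade >= 2)`.
#'
#' @param df Data frame with columns image_id, path, dr_grade, referable, split.
#' @param provenance Free-text provenance note.
#' @param check_paths If `TRUE`, error when a referenced image file is missing.
#' @return Object of class `fundus_manifest` (a data.frame).
#' @export
as_manifest <- function(df, provenance = NA_character_, check_paths = FALSE) {
  missing_cols <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, MANIFEST_COLS]
  bad <- which(is.na(df$dr_grade) | df$dr_grade %% 1 != 0 |
                 df$dr_grade < 0 | df$dr_grade > 4)
  if (length(bad)) {
    stop("dr_grade outside 0..4 in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$dr_grade <- as.integer(df$dr_grade)
  df$referable <- as.logical(df$referable)
  contr <- which(df$referable != grade_to_referable(df$dr_grade))
  if (length(contr)) {
    stop("referable label contradicts dr_grade in row(s): ",
         paste(contr, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$image_id)) {
    stop("duplicate image_id in manifest", call. = FALSE)
  }
  if (check_paths) {
    gone <- which(!file.exists(df$path))
    if (length(gone)) {
      stop("missing image file(s) for row(s): ", paste(gone, collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("fundus_manifest", "data.frame"),
            provenance = provenance)
}

#' Write a manifest to CSV
#' @param manifest A `fundus_manifest`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, MANIFEST_COLS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Load a manifest from CSV
#'
#' The referable column is recomputed from the grade and checked against the
#' stored value; contradictions are an error naming the offending rows.
#'
#' @param path CSV path.
#' @param check_paths If `TRUE` (default), require all image paths to resolve.
#' @return A `fundus_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character", split = "character"))
  as_manifest(df, provenance = path, check_paths = check_paths)
}

#' Stratified k-fold cross-validation split
#'
#' Folds are stratified by the referable label: within each class, records are
#' shuffled with the seed and dealt round-robin, so every record appears in
#' exactly one validation fold and per-fold class proportions are within one
#' record of the global proportions.
#'
#' @param manifest A `fundus_manifest`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train = , validation = )`.
#' @export
kfold_split <- function(manifest, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  cls <- manifest$referable
  for (v in c(TRUE, FALSE)) {
    if (sum(cls == v) < k) {
      stop("class ", v, " has fewer than k = ", k, " members", call. = FALSE)
    }
  }
  fold_of <- integer(nrow(manifest))
  for (v in c(FALSE, TRUE)) {
    idx <- which(cls == v)
    perm <- with_seed(derive_seed(seed, paste0("kfold-", v)), sample(idx))
    fold_of[perm] <- rep_len(seq_len(k), length(perm))
  }
  lapply(seq_len(k), function(f) {
    list(
      train = subset_manifest(manifest, fold_of != f),
      validation = subset_manifest(manifest, fold_of == f)
    )
  })
}

subset_manifest <- function(manifest, keep) {
  out <- as.data.frame(manifest)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fundus_manifest", "data.frame"),
            provenance = attr(manifest, "provenance"))
}

#' Stratified label-fraction subsample
#'
#' Takes `round(fraction * n_class)` records from each referable class, using
#' a fixed per-seed permutation prefix within each class. Because the
#' permutation depends only on the seed, samples are nested: the 10\% sample
#' is a subset of the 20\% sample under the same seed, so label-efficiency
#' curves are monotone in data rather than re-drawn.
#'
#' @param manifest A `fundus_manifest`.
#' @param fraction Label fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `fundus_manifest` with the selected rows (original order).
#' @export
subsample_label_fraction <- function(manifest, fraction, seed) {
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  keep <- logical(nrow(manifest))
  for (v in c(FALSE, TRUE)) {
    idx <- which(manifest$referable == v)
    n_take <- round_half_up(fraction * length(idx))
    if (fraction * length(idx) < 1) {
      stop("fraction * class size < 1 for class referable = ", v, call. = FALSE)
    }
    perm <- with_seed(derive_seed(seed, paste0("frac-", v)), sample(idx))
    keep[perm[seq_len(n_take)]] <- TRUE
  }
  subset_manifest(manifest, keep)
}
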