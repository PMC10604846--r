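#' Labeled gait examples and datasets
#'
#' A `gait_example` couples one skeleton sequence with its subject,
#' gait label and walk index; a `gait_dataset` is an ordered collection
#' of examples with a shared class vocabulary.
#'
#' @param sequence a `skeleton_sequence`.
#' @param subject_id nonempty subject identifier string.
#' @param gait_label 1-based integer index into the dataset's
#'   `class_names`.
#' @param walk_index integer walk counter within subject and class.
#' @param mirrored logical, whether this example is a left/right
#'   mirrored copy.
#' @return an object of class `gait_example`.
#' @export
gait_example <- function(sequence, subject_id, gait_label, walk_index = 1L,
                         mirrored = FALSE) {
  stopifnot(inherits(sequence, "skeleton_sequence"))
  if (!nzchar(subject_id)) stop("subject_id must be nonempty")
  structure(
    list(sequence = sequence, subject_id = as.character(subject_id),
         gait_label = as.integer(gait_label),
         walk_index = as.integer(walk_index),
         mirrored = isTRUE(mirrored),
         ground_truth = NULL),
    class = "gait_example"
  )
}

#' @rdname gait_example
#' @param examples list of `gait_example`s.
#' @param class_names ordered character vector of gait class names;
#'   example labels index into it.
#' @param provenance free-form list of manifest metadata.
#' @export
gait_dataset <- function(examples, class_names, provenance = list()) {
  C <- length(class_names)
  labs <- vapply(examples, function(e) e$gait_label, integer(1))
  if (length(labs) > 0L && (min(labs) < 1L || max(labs) > C)) {
    stop("gait_label outside 1..", C)
  }
  structure(
    list(examples = examples, class_names = as.character(class_names),
         provenance = provenance),
    class = "gait_dataset"
  )
}

#' @export
print.gait_dataset <- function(x, ...) {
  labs <- vapply(x$examples, function(e) e$gait_label, integer(1))
  cat("<gait_dataset> ", length(x$examples), " examples, ",
      length(x$class_names), " classes (",
      paste(x$class_names, collapse = ", "), ")\n", sep = "")
  if (length(labs) > 0L) {
    print(table(factor(x$class_names[labs], levels = x$class_names)))
  }
  invisible(x)
}

#' Subject identifiers of a dataset
#' @param ds a `gait_dataset`.
#' @return character vector, one entry per example.
#' @export
dataset_subjects <- function(ds) {
  vapply(ds$examples, function(e) e$subject_id, character(1))
}

#' Class labels of a dataset
#' @param ds a `gait_dataset`.
#' @return integer vector of 1-based class indices, one per example.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$examples, function(e) e$gait_label, integer(1))
}

#' Mirror a labeled example left-to-right
#'
#' Augmentation operator: reflects the skeleton laterally (see
#' [mirror_sequence()]) while preserving the subject identity, label
#' and walk index, and toggling the `mirrored` flag. Keeping the
#' source subject id means subject-disjoint cross-validation can never
#' place an example and its mirror on opposite sides of a fold.
#'
#' @param example a `gait_example`.
#' @return the mirrored `gait_example`.
#' @export
mirror_lr <- function(example) {
  stopifnot(inherits(example, "gait_example"))
  example$sequence <- mirror_sequence(example$sequence)
  example$mirrored <- !example$mirrored
  example
}

#' Drop examples with too few frames
#'
#' Retains exactly the examples whose sequences have at least
#' `min_frames` frames, preserving order. The number removed is
#' reported via `message()`.
#'
#' @param ds a `gait_dataset`.
#' @param min_frames positive minimum frame count.
#' @return the filtered `gait_dataset` (possibly empty).
#' @export
filter_short_sequences <- function(ds, min_frames) {
  stopifnot(inherits(ds, "gait_dataset"), min_frames >= 1)
  keep <- vapply(ds$examples, function(e) n_frames(e$sequence) >= min_frames,
                 logical(1))
  removed <- sum(!keep)
  if (removed > 0L) {
    message("filter_short_sequences: removed ", removed, " of ",
            length(keep), " examples shorter than ", min_frames, " frames")
  }
  ds$examples <- ds$examples[keep]
  ds
}

#' Write a dataset to a directory with a manifest
#'
#' Each sequence is written in the delimited skeleton dialect and a
#' `manifest.csv` with columns `path,subject_id,gait_label,walk_index`
#' is produced (gait_label stored as the class name).
#'
#' @param ds a `gait_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
save_gait_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$examples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    e <- ds$examples[[i]]
    fn <- sprintf("walk_%04d%s.csv", i, if (e$mirrored) "_m" else "")
    save_skeleton_sequence(e$sequence, file.path(dir, fn))
    rows[[i]] <- data.frame(
      path = fn, subject_id = e$subject_id,
      gait_label = ds$class_names[e$gait_label],
      walk_index = e$walk_index, mirrored = e$mirrored
    )
  }
  man <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a dataset from a manifest
#'
#' @param manifest_path path to a `manifest.csv` with columns
#'   `path,subject_id,gait_label,walk_index` (paths relative to the
#'   manifest's directory).
#' @param joints the `joint_set` the files were written with.
#' @param class_names optional class vocabulary; defaults to the sorted
#'   unique labels in the manifest.
#' @return a `gait_dataset`.
#' @export
load_gait_dataset <- function(manifest_path, joints = default_joint_set(),
                              class_names = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "subject_id", "gait_label", "walk_index")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ","))
  }
  if (is.null(class_names)) class_names <- sort(unique(man$gait_label))
  base <- dirname(manifest_path)
  examples <- lapply(seq_len(nrow(man)), function(i) {
    seq <- load_skeleton_sequence(file.path(base, man$path[i]), joints)
    gait_example(
      seq, man$subject_id[i],
      match(man$gait_label[i], class_names),
      man$walk_index[i],
      if ("mirrored" %in% names(man)) isTRUE(as.logical(man$mirrored[i]))
      else FALSE
    )
  })
  gait_dataset(examples, class_names,
               provenance = list(manifest = manifest_path))
}
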