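# Manifest handling: global-ID assignment with cross-source deduplication
# and the deterministic stratified 7:3 split with an internal validation
# carve-out.

#' Round half up
#'
#' `floor(x + 0.5)` — the rounding rule used for per-class split allocation;
#' it reproduces the published per-class train/test counts exactly for the
#' four-class MRI corpus (e.g. 1645 * 0.7 = 1151.5 -> 1152).
#'
#' @param x numeric vector
#' @return rounded values
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Merge source manifests and assign globally unique IDs
#'
#' Concatenates several source manifests, removes later duplicates that
#' share a `source_id` with an earlier record (the cross-source
#' deduplication step that prevents the same subject appearing in more than
#' one split), and assigns fresh sequential global IDs.
#'
#' @param manifests list of data frames, each with at least `source_id`,
#'   `path`, and `class_label` columns
#' @return a merged manifest with unique `global_id` values and an
#'   unassigned `split` column
#' @export
assign_global_ids <- function(manifests) {
  stopifnot(is.list(manifests), length(manifests) >= 1L)
  all <- do.call(rbind, lapply(manifests, function(m) {
    m[, c("source_id", "path", "class_label"), drop = FALSE]
  }))
  keep <- !duplicated(all$source_id)
  all <- all[keep, , drop = FALSE]
  data.frame(global_id = sprintf("g%06d", seq_len(nrow(all))),
             source_id = all$source_id,
             path = all$path,
             class_label = all$class_label,
             split = NA_character_,
             stringsAsFactors = FALSE)
}

#' Per-class train/test counts under the 7:3 split
#'
#' Pure split arithmetic: for each class size `n`, the training portion is
#' `round_half_up(ratio * n)` and the test portion the remainder.
#'
#' @param class_sizes named or unnamed integer vector of per-class counts
#' @param ratio training fraction (default 0.7)
#' @return data frame with columns `class_size`, `train`, `test`
#' @export
split_counts <- function(class_sizes, ratio = 0.7) {
  tr <- round_half_up(ratio * class_sizes)
  data.frame(class_size = as.integer(class_sizes),
             train = as.integer(tr),
             test = as.integer(class_sizes - tr),
             row.names = names(class_sizes))
}

#' Deterministic stratified dataset split
#'
#' Splits a manifest per class into `train`, `internal_val`, and `test`.
#' Per class, `round_half_up(ratio * n)` records form the training portion
#' and the rest the test set; `val_frac` of the training portion (rounded
#' half up) is carved out as the internal validation set used for epoch-wise
#' checkpoint selection. Assignment is a seeded shuffle of the records
#' ordered by global ID, so the same seed always yields the same split, and
#' every global ID lands in exactly one split.
#'
#' @param manifest manifest data frame with `global_id` and `class_label`
#' @param ratio training fraction (default 0.7, the 7:3 protocol)
#' @param val_frac internal-validation fraction of the training portion
#'   (default 0.15)
#' @param seed integer seed for the shuffle
#' @return the manifest with its `split` column filled in
#' @export
split_dataset <- function(manifest, ratio = 0.7, val_frac = 0.15, seed = 1L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  if (anyDuplicated(manifest$global_id)) {
    stop("manifest global IDs must be unique")
  }
  classes <- sort(unique(manifest$class_label))
  split <- rep(NA_character_, nrow(manifest))
  with_local_seed(seed, {
    for (cls in classes) {
      idx <- which(manifest$class_label == cls)
      if (length(idx) < 1L) stop("empty class: ", cls)
      idx <- idx[order(manifest$global_id[idx])]
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_train_total <- round_half_up(ratio * n)
      n_val <- round_half_up(val_frac * n_train_total)
      lab <- rep("test", n)
      if (n_train_total > 0) {
        lab[seq_len(n_train_total)] <- "train"
        if (n_val > 0) lab[seq_len(n_val)] <- "internal_val"
      }
      split[idx] <- lab
    }
  })
  manifest$split <- split
  manifest
}
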