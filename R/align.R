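#' Tolerance windows for feature matching
#'
#' Combined relative + absolute tolerances used both to align features across
#' runs and to match features against a marker library: the retention-time
#' half-width at RT `t` is `t * rt_rel + rt_abs` and the mass half-width at
#' m/z `m` is `m * mz_ppm * 1e-6 + mz_mda`. Defaults are a 0.1% + 0.15 min RT
#' window and a 5 ppm + 2.0 mDa mass window.
#'
#' @param rt_rel Relative RT tolerance (fraction of RT).
#' @param rt_abs Absolute RT tolerance, minutes.
#' @param mz_ppm Relative mass tolerance, ppm.
#' @param mz_mda Absolute mass tolerance, Da.
#' @return A list of class `tolerance_windows`.
#' @examples
#' window_halfwidths(413.3429, 24.81, tolerance_windows())
#' @export
tolerance_windows <- function(rt_rel = 0.001, rt_abs = 0.15,
                              mz_ppm = 5, mz_mda = 0.002) {
  stopifnot(rt_rel >= 0, rt_abs >= 0, mz_ppm >= 0, mz_mda >= 0)
  if (rt_rel + rt_abs <= 0 || mz_ppm + mz_mda <= 0) {
    stop("combined half-widths must be strictly positive", call. = FALSE)
  }
  structure(list(rt_rel = rt_rel, rt_abs = rt_abs,
                 mz_ppm = mz_ppm, mz_mda = mz_mda),
            class = "tolerance_windows")
}

#' @rdname tolerance_windows
#' @param mz,rt Feature coordinates (m/z in Th, RT in minutes).
#' @param windows A `tolerance_windows` object.
#' @return `window_halfwidths()` returns a list with elements `mz_hw` (Da) and
#'   `rt_hw` (min).
#' @export
window_halfwidths <- function(mz, rt, windows = tolerance_windows()) {
  stopifnot(all(mz > 0), all(rt >= 0))
  list(mz_hw = mz * windows$mz_ppm * 1e-6 + windows$mz_mda,
       rt_hw = rt * windows$rt_rel + windows$rt_abs)
}

#' Align features across samples into consensus compounds
#'
#' Groups the molecular features of many runs into consensus compounds by
#' greedy seeded clustering: features are pre-sorted canonically (descending
#' height, then m/z, RT and sample id, so the result does not depend on input
#' order); each still-unassigned feature seeds a consensus and absorbs every
#' unassigned feature whose windows overlap its own, i.e.
#' `|dmz| <= mz_hw(seed) + mz_hw(candidate)` and likewise for RT. A consensus
#' absorbs at most one feature per sample (closest |dmz|, then |dRT|, then
#' canonical order). Consensus m/z and RT are intensity-weighted means of the
#' members.
#'
#' @param features Long feature tibble with columns `sample_id`, `mz`, `rt`,
#'   `height`, `quality` (e.g. `dataset$features` from [simulate_dataset()],
#'   or rows bound from [read_feature_csv()]/[read_cef()]).
#' @param samples Optional sample metadata tibble (`sample_id`, `species`,
#'   `role`, ...); defaults to one `unknown` row per distinct sample id.
#' @param windows [tolerance_windows()].
#' @param min_compound_abundance Per-sample QC gate: samples whose summed
#'   feature height falls below this many counts are dropped with a warning
#'   before alignment (0 disables).
#' @param one_per_sample Restrict each consensus to one feature per sample
#'   (the alignment semantics; turned off internally for co-elution merging).
#' @return An object of class `feature_matrix`: list with `consensus`
#'   (tibble: `feature_id`, `mz`, `rt`, `n_members`), `abundance` (consensus x
#'   sample height matrix, 0 = not detected), `quality` (matching matrix of
#'   quality scores), `members` (provenance tibble) and `samples`.
#' @export
align_features <- function(features, samples = NULL,
                           windows = tolerance_windows(),
                           min_compound_abundance = 0,
                           one_per_sample = TRUE) {
  stopifnot(all(c("sample_id", "mz", "rt", "height") %in% names(features)))
  if (!"quality" %in% names(features)) features$quality <- 100
  if (min_compound_abundance > 0 && nrow(features) > 0) {
    totals <- features %>% group_by(sample_id) %>%
      summarise(total = sum(height), .groups = "drop")
    low <- totals$sample_id[totals$total < min_compound_abundance]
    if (length(low) > 0) {
      warning("dropping ", length(low),
              " sample(s) below the compound-abundance QC gate: ",
              paste(low, collapse = ", "), call. = FALSE)
      features <- features %>% filter(!sample_id %in% low)
    }
  }
  if (is.null(samples)) {
    samples <- tibble(sample_id = sort(unique(features$sample_id)),
                      species = "unknown", producer = "", batch = "",
                      role = "oil")
  } else {
    samples <- as_tibble(samples)
    stopifnot("sample_id" %in% names(samples))
    if (anyDuplicated(samples$sample_id) > 0) {
      stop("duplicate sample ids", call. = FALSE)
    }
  }
  sample_ids <- samples$sample_id

  n <- nrow(features)
  if (n == 0) {
    return(new_feature_matrix(
      consensus = tibble(feature_id = integer(), mz = double(), rt = double(),
                         n_members = integer()),
      abundance = matrix(0, 0, length(sample_ids),
                         dimnames = list(NULL, sample_ids)),
      quality = matrix(0, 0, length(sample_ids),
                       dimnames = list(NULL, sample_ids)),
      members = tibble(feature_id = integer(), sample_id = character(),
                       mz = double(), rt = double(), height = double(),
                       quality = double()),
      samples = samples, windows = windows))
  }

  # canonical pre-sort makes the greedy result invariant to input order
  ord <- order(-features$height, features$mz, features$rt, features$sample_id)
  f <- features[ord, ]
  hw <- window_halfwidths(f$mz, f$rt, windows)
  mz_hw <- hw$mz_hw
  rt_hw <- hw$rt_hw

  # mz-sorted view for window lookups
  mz_ord <- order(f$mz)
  mz_sorted <- f$mz[mz_ord]
  max_mz_hw <- max(mz_hw)

  assign_id <- integer(n)
  n_consensus <- 0L
  for (i in seq_len(n)) {
    if (assign_id[i] != 0L) next
    n_consensus <- n_consensus + 1L
    lo <- findInterval(f$mz[i] - mz_hw[i] - max_mz_hw, mz_sorted) + 1L
    hi <- findInterval(f$mz[i] + mz_hw[i] + max_mz_hw, mz_sorted)
    cand <- mz_ord[seq.int(lo, hi)]
    cand <- cand[assign_id[cand] == 0L]
    dmz <- abs(f$mz[cand] - f$mz[i])
    drt <- abs(f$rt[cand] - f$rt[i])
    ok <- dmz <= mz_hw[i] + mz_hw[cand] & drt <= rt_hw[i] + rt_hw[cand]
    cand <- cand[ok]
    if (one_per_sample && length(cand) > 1) {
      # keep the closest candidate per sample; ties by |dmz|, |drt|, canonical
      # order (candidate index in the pre-sorted table)
      dmz <- dmz[ok]; drt <- drt[ok]
      keep_ord <- order(f$sample_id[cand], dmz, drt, cand)
      cand <- cand[keep_ord]
      cand <- cand[!duplicated(f$sample_id[cand])]
    }
    assign_id[cand] <- n_consensus
  }

  members <- f %>%
    mutate(feature_id = assign_id) %>%
    select(feature_id, sample_id, mz, rt, height, quality)
  consensus <- members %>%
    group_by(feature_id) %>%
    summarise(mz = sum(mz * height) / sum(height),
              rt = sum(rt * height) / sum(height),
              n_members = dplyr::n(), .groups = "drop") %>%
    arrange(mz, rt) %>%
    mutate(new_id = row_number())
  members <- members %>%
    left_join(consensus[, c("feature_id", "new_id")], by = "feature_id") %>%
    mutate(feature_id = new_id) %>%
    select(-new_id) %>%
    arrange(feature_id, sample_id)
  consensus <- consensus %>% mutate(feature_id = new_id) %>% select(-new_id)

  k <- nrow(consensus)
  abundance <- matrix(0, k, length(sample_ids),
                      dimnames = list(NULL, sample_ids))
  qual <- matrix(0, k, length(sample_ids), dimnames = list(NULL, sample_ids))
  idx <- cbind(members$feature_id, match(members$sample_id, sample_ids))
  if (anyNA(idx[, 2])) {
    stop("features reference sample ids absent from the sample table",
         call. = FALSE)
  }
  abundance[idx] <- members$height
  qual[idx] <- members$quality

  new_feature_matrix(consensus, abundance, qual, members, samples, windows)
}

new_feature_matrix <- function(consensus, abundance, quality, members,
                               samples, windows) {
  structure(list(consensus = consensus, abundance = abundance,
                 quality = quality, members = members, samples = samples,
                 windows = windows),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$consensus), " consensus features x ",
      ncol(x$abundance), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$abundance)

# restrict a feature matrix to a subset of consensus rows (logical or integer
# over current rows); feature ids are renumbered to stay 1..k
subset_features <- function(fm, keep) {
  if (is.logical(keep)) keep <- which(keep)
  consensus <- fm$consensus[fm$consensus$feature_id %in% keep, , drop = FALSE]
  id_map <- setNames(seq_len(nrow(consensus)), consensus$feature_id)
  members <- fm$members %>% filter(feature_id %in% keep) %>%
    mutate(feature_id = unname(id_map[as.character(feature_id)]))
  consensus$feature_id <- seq_len(nrow(consensus))
  new_feature_matrix(consensus,
                     fm$abundance[keep, , drop = FALSE],
                     fm$quality[keep, , drop = FALSE],
                     members, fm$samples, fm$windows)
}

# restrict to a subset of sample columns
subset_samples <- function(fm, sample_ids) {
  fm$abundance <- fm$abundance[, sample_ids, drop = FALSE]
  fm$quality <- fm$quality[, sample_ids, drop = FALSE]
  fm$members <- fm$members %>% filter(sample_id %in% sample_ids)
  fm$samples <- fm$samples %>% filter(sample_id %in% sample_ids)
  fm
}

#' Flag filtering of a feature matrix
#'
#' Zeroes matrix cells that fail the peak-height or quality-score thresholds
#' (both inclusive) and drops consensus features left with no detections.
#'
#' @param fm A [align_features()] result.
#' @param min_height Minimum peak height, counts.
#' @param min_quality Minimum quality score.
#' @return A filtered `feature_matrix`.
#' @export
filter_flags <- function(fm, min_height = 600, min_quality = 80) {
  stopifnot(inherits(fm, "feature_matrix"))
  fail <- (fm$abundance > 0 & fm$abundance < min_height) |
    (fm$abundance > 0 & fm$quality < min_quality)
  fm$abundance[fail] <- 0
  fm$quality[fail] <- 0
  drop_cells <- which(fail, arr.ind = TRUE)
  if (nrow(drop_cells) > 0) {
    dropped_keys <- paste(drop_cells[, 1],
                          colnames(fm$abundance)[drop_cells[, 2]])
    fm$members <- fm$members %>%
      filter(!paste(feature_id, sample_id) %in% dropped_keys)
  }
  keep <- which(rowSums(fm$abundance > 0) > 0)
  subset_features(fm, keep)
}

#' Frequency filtering within a class
#'
#' Keeps consensus features detected in at least `min_fraction` of the samples
#' of `class_label` (the species column of the sample table). The default,
#' 1.0, mirrors using only compounds found in all samples of an oil.
#'
#' @param fm A `feature_matrix`.
#' @param class_label Species label to filter on.
#' @param min_fraction Minimum detected fraction within the class.
#' @return A `feature_matrix` restricted to the passing consensus features
#'   (all sample columns are retained).
#' @export
filter_frequency <- function(fm, class_label, min_fraction = 1.0) {
  stopifnot(inherits(fm, "feature_matrix"),
            min_fraction >= 0, min_fraction <= 1)
  ids <- fm$samples$sample_id[fm$samples$species == class_label]
  if (length(ids) == 0) {
    stop("no samples of class '", class_label, "'", call. = FALSE)
  }
  frac <- rowMeans(fm$abundance[, ids, drop = FALSE] > 0)
  subset_features(fm, which(frac >= min_fraction))
}

#' Blank subtraction
#'
#' Removes consensus features detected in any solvent-blank sample, excluding
#' ions that do not originate from the oils; the blank columns themselves are
#' dropped from the matrix.
#'
#' @param fm A `feature_matrix`.
#' @param blank_ids Sample ids of the blanks; defaults to samples whose `role`
#'   is `"blank"`.
#' @return A `feature_matrix` without blank-derived features or blank columns.
#' @export
subtract_blanks <- function(fm, blank_ids = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(blank_ids)) {
    blank_ids <- fm$samples$sample_id[fm$samples$role == "blank"]
  }
  blank_ids <- intersect(blank_ids, colnames(fm$abundance))
  if (length(blank_ids) == 0) return(fm)
  in_blank <- rowSums(fm$abundance[, blank_ids, drop = FALSE] > 0) > 0
  fm <- subset_features(fm, which(!in_blank))
  subset_samples(fm, setdiff(colnames(fm$abundance), blank_ids))
}

#' @export
tidy.feature_matrix <- function(x, ...) {
  as_tibble(x$abundance) %>%
    mutate(feature_id = x$consensus$feature_id,
           mz = x$consensus$mz, rt = x$consensus$rt) %>%
    tidyr::pivot_longer(cols = -c(feature_id, mz, rt),
                        names_to = "sample_id", values_to = "height") %>%
    left_join(x$samples, by = "sample_id")
}
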