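#' Discover species-specific marker candidates
#'
#' Screens a filtered feature matrix for consensus features that behave as
#' markers of one oil species: detected in every sample of the target class
#' (class frequency 1), never detected in any negative-panel sample, and
#' influential in the OPLS-DA model (VIP at or above the threshold). The
#' negative panel for a species is every other species in the matrix — the
#' remaining target oils plus the marker-free panel oils.
#'
#' @param fm A `feature_matrix`, already flag-filtered and blank-subtracted.
#' @param target_class Species to find markers for.
#' @param panel_classes Species forming the negative panel; defaults to every
#'   other species present in the matrix (blanks excluded).
#' @param vip_threshold Minimum VIP score (default 1.5).
#' @param model Optional pre-fitted `opls_da`; by default a model with
#'   `n_predictive = n_oil_classes - 1` and 2 orthogonal components is fitted
#'   on the oil-role samples.
#' @param n_orthogonal Orthogonal components for the default model.
#' @return A tibble of candidate markers: `feature_id`, `mz`, `rt`,
#'   `target_class`, `vip`, `contribution`, `class_frequency`, `panel_hits`,
#'   sorted by VIP, descending.
#' @export
discover_markers <- function(fm, target_class, panel_classes = NULL,
                             vip_threshold = 1.5, model = NULL,
                             n_orthogonal = 2) {
  stopifnot(inherits(fm, "feature_matrix"))
  species <- fm$samples$species
  if (!target_class %in% species) {
    stop("target class '", target_class, "' absent from the matrix",
         call. = FALSE)
  }
  if (is.null(panel_classes)) {
    panel_classes <- setdiff(unique(species[fm$samples$role != "blank"]),
                             target_class)
  }
  target_ids <- fm$samples$sample_id[species == target_class]
  panel_ids <- fm$samples$sample_id[species %in% panel_classes]

  if (is.null(model)) {
    X <- as_sample_matrix(fm, roles = "oil")
    model <- oplsda_clamped(X, attr(X, "classes"),
                            n_predictive = length(unique(attr(X, "classes"))) - 1,
                            n_orthogonal = n_orthogonal, n_folds = NA)
  }
  contrib <- variable_contributions(model, target_class)

  freq <- rowMeans(fm$abundance[, target_ids, drop = FALSE] > 0)
  hits <- rowSums(fm$abundance[, panel_ids, drop = FALSE] > 0)
  stats <- tibble(feature_id = fm$consensus$feature_id,
                  mz = fm$consensus$mz, rt = fm$consensus$rt,
                  class_frequency = freq, panel_hits = as.integer(hits),
                  variable = paste0("f", fm$consensus$feature_id)) %>%
    left_join(contrib, by = "variable")
  # variables dropped by scaling (constant columns) carry no model evidence
  stats$vip[is.na(stats$vip)] <- 0
  stats$contribution[is.na(stats$contribution)] <- 0

  stats %>%
    filter(class_frequency >= 1, panel_hits == 0, vip >= vip_threshold) %>%
    mutate(target_class = .env$target_class) %>%
    select(feature_id, mz, rt, target_class, vip, contribution,
           class_frequency, panel_hits) %>%
    arrange(desc(vip))
}

#' Screen one sample against a marker library
#'
#' Targeted authentication: each library marker is matched against the
#' sample's feature list; a marker is hit when a feature falls within the mass
#' window of the precursor (`mz * ppm + mDa`) and within
#' `rt_tol * rt_tol_multiplier` of the library retention time. When MS/MS
#' spectra are supplied, the number of library fragments found within the
#' mass window is counted per hit, and hits with fewer than `min_fragments`
#' confirmed fragments are discarded.
#'
#' @param features Feature tibble of one sample (`mz`, `rt`, `height`).
#' @param library Marker library (see [read_marker_library()]).
#' @param windows [tolerance_windows()] for mass matching.
#' @param rt_tol_multiplier Multiplier on the library RT spread (default 3).
#' @param ms2 Optional named list of MS/MS spectra (names = marker numbers,
#'   each a tibble/data frame with an `mz` column).
#' @param min_fragments Minimum confirmed fragments per hit when MS/MS is
#'   given (0 = MS1-only screening).
#' @param declared Declared species of the sample (optional), used for the
#'   authenticity verdict.
#' @return An object of class `screening_result`: `hits` (one row per matched
#'   marker with mass error in ppm and RT error in minutes), `summary`
#'   (per-oil marker counts and completeness), and `verdict`
#'   (`"authentic-consistent"` / `"inconsistent"` / `NA`).
#' @export
screen_sample <- function(features, library, windows = tolerance_windows(),
                          rt_tol_multiplier = 3, ms2 = NULL,
                          min_fragments = 0, declared = NULL) {
  if (nrow(library) == 0) stop("empty marker library", call. = FALSE)
  hit_rows <- purrr::map(seq_len(nrow(library)), function(i) {
    mk <- library[i, ]
    mz_hw <- window_halfwidths(mk$precursor_mz, mk$rt_mean, windows)$mz_hw
    rt_hw <- mk$rt_tol * rt_tol_multiplier
    cand <- features %>%
      filter(abs(mz - mk$precursor_mz) <= mz_hw,
             abs(rt - mk$rt_mean) <= rt_hw)
    if (nrow(cand) == 0) return(NULL)
    best <- cand %>% arrange(abs(mz - mk$precursor_mz)) %>% slice(1)
    frag_n <- NA_integer_
    if (!is.null(ms2)) {
      spec <- ms2[[as.character(mk$number)]]
      frag_n <- if (is.null(spec)) 0L else {
        frags <- mk$fragments[[1]]
        sum(purrr::map_lgl(frags, function(fr) {
          hw <- window_halfwidths(fr, mk$rt_mean, windows)$mz_hw
          any(abs(spec$mz - fr) <= hw)
        }))
      }
      if (frag_n < min_fragments) return(NULL)
    }
    tibble(oil = mk$oil, marker_number = mk$number,
           precursor_mz = mk$precursor_mz,
           mz = best$mz, rt = best$rt, height = best$height,
           mz_error_ppm = (best$mz - mk$precursor_mz) / mk$precursor_mz * 1e6,
           rt_error_min = best$rt - mk$rt_mean,
           fragments_matched = frag_n)
  })
  hits <- bind_rows(purrr::compact(hit_rows))
  if (nrow(hits) == 0) {
    hits <- tibble(oil = character(), marker_number = integer(),
                   precursor_mz = double(), mz = double(), rt = double(),
                   height = double(), mz_error_ppm = double(),
                   rt_error_min = double(), fragments_matched = integer())
  }
  summary <- library %>%
    group_by(oil) %>%
    summarise(n_markers = dplyr::n(), .groups = "drop") %>%
    left_join(hits %>% group_by(oil) %>%
                summarise(n_hits = dplyr::n(), .groups = "drop"),
              by = "oil") %>%
    mutate(n_hits = tidyr::replace_na(n_hits, 0L),
           complete = n_hits == n_markers)
  verdict <- NA_character_
  if (!is.null(declared)) {
    if (!declared %in% summary$oil) {
      stop("declared species '", declared, "' not in the library",
           call. = FALSE)
    }
    verdict <- if (summary$complete[summary$oil == declared])
      "authentic-consistent" else "inconsistent"
  }
  structure(list(hits = hits, summary = summary, declared = declared,
                 verdict = verdict),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", nrow(x$hits), " marker hit(s)\n", sep = "")
  print(x$summary, n = Inf)
  if (!is.na(x$verdict)) {
    cat("declared:", x$declared, "->", x$verdict, "\n")
  }
  invisible(x)
}

#' @export
tidy.screening_result <- function(x, ...) x$hits

#' Mixture detection-limit table
#'
#' Evaluates, by simulation, which library markers survive volumetric dilution
#' of their oil into a carrier oil: for each target species and each mixing
#' fraction, every bottle of the minor oil is mixed into a carrier-oil sample
#' ([simulate_mixture()]) and screened against the library; a marker counts as
#' detected when any bottle's mixture yields a hit. Carrier oils follow the
#' mixing scheme of the underlying study design: sunflower is diluted in
#' rapeseed, every other oil in sunflower.
#'
#' @param library Marker library.
#' @param dataset An `oil_dataset` from [simulate_dataset()] providing the
#'   parent samples.
#' @param fractions Mixing fractions to evaluate.
#' @param windows,rt_tol_multiplier Matching tolerances for [screen_sample()].
#' @param carriers Named character vector mapping each minor species to its
#'   carrier species.
#' @return A tibble: `oil`, `marker_number`, `fraction`, `detected`, and the
#'   library's detectability flag for that fraction in `expected` (`NA` for
#'   fractions without a library flag).
#' @export
mixture_detection_table <- function(library, dataset,
                                    fractions = c(0.01, 0.05),
                                    windows = tolerance_windows(),
                                    rt_tol_multiplier = 3,
                                    carriers = NULL) {
  stopifnot(inherits(dataset, "oil_dataset"))
  target_species <- intersect(unique(library$oil), dataset$samples$species)
  if (is.null(carriers)) {
    default_carrier <- if ("sunflower" %in% target_species) "sunflower"
                       else target_species[1]
    carriers <- setNames(rep(default_carrier, length(target_species)),
                         target_species)
    if ("sunflower" %in% target_species) {
      carriers["sunflower"] <- if ("rapeseed" %in% target_species) "rapeseed"
                               else setdiff(target_species, "sunflower")[1]
    }
  }
  sample_features <- function(sid) {
    dataset$features %>% filter(sample_id == sid)
  }
  rows <- list()
  for (sp in target_species) {
    lib_sp <- library %>% filter(oil == sp)
    minor_ids <- dataset$samples$sample_id[dataset$samples$species == sp]
    carrier_sp <- carriers[[sp]]
    major_id <- dataset$samples$sample_id[dataset$samples$species == carrier_sp][1]
    major <- sample_features(major_id)
    for (f in fractions) {
      detected_any <- rep(FALSE, nrow(lib_sp))
      for (mid in minor_ids) {
        mix <- simulate_mixture(sample_features(mid), major, fraction = f,
                                design = dataset$design, windows = windows)
        scr <- screen_sample(mix, lib_sp, windows = windows,
                             rt_tol_multiplier = rt_tol_multiplier)
        detected_any <- detected_any |
          lib_sp$number %in% scr$hits$marker_number
        if (all(detected_any)) break
      }
      rows[[paste(sp, f)]] <- tibble(
        oil = sp, marker_number = lib_sp$number, fraction = f,
        detected = detected_any,
        expected = if (isTRUE(all.equal(f, 0.01))) lib_sp$detect_1pct
                   else if (isTRUE(all.equal(f, 0.05))) lib_sp$detect_5pct
                   else NA)
    }
  }
  bind_rows(rows)
}

#' Abundance variability of a marker
#'
#' Percent difference between the samples with the highest and the lowest
#' marker signal: `100 * (max - min) / max` over the samples where the marker
#' was detected (height > 0). Undetected everywhere gives `NA`; a single
#' detected sample gives 0.
#'
#' @param heights Numeric vector of per-sample marker peak heights (0 or `NA`
#'   = not detected).
#' @return Percent difference (0-100), or `NA` if the marker was never
#'   detected.
#' @examples
#' abundance_variability(c(100, 10.8))  # 89.2
#' @export
abundance_variability <- function(heights) {
  h <- heights[!is.na(heights) & heights > 0]
  if (length(h) == 0) return(NA_real_)
  100 * (max(h) - min(h)) / max(h)
}
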