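#' Read a marker library table
#'
#' A marker library is a TSV with one row per marker ion: the oil species it is
#' specific to, a running number, the precursor m/z of the protonated molecule,
#' the mean retention time and its spread across samples, up to five MS/MS
#' fragment m/z values, the collision energy used for fragmentation, and two
#' flags recording whether the marker was still detectable in two-component
#' mixtures containing 1% and 5% (v/v) of the oil.
#'
#' Columns: `oil`, `no`, `mz`, `rt`, `rt_tol`, `ms2_1`..`ms2_5`, `ce`,
#' `det1`, `det5` (flags written `+`/`-`).
#'
#' @param path Path to a TSV file. Defaults to the library of 29 seed-oil
#'   markers shipped with the package.
#' @return A tibble with one row per marker: `oil`, `number`, `precursor_mz`,
#'   `rt_mean`, `rt_tol`, `fragments` (list column of numeric m/z vectors),
#'   `collision_energy`, `detect_1pct`, `detect_5pct`.
#' @examples
#' lib <- read_marker_library()
#' dplyr::count(lib, oil)
#' @export
read_marker_library <- function(path = oilmarkr_example("marker_library.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("oil", "no", "mz", "rt", "rt_tol", paste0("ms2_", 1:5),
                "ce", "det1", "det5")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("marker library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lib <- tibble(
    oil = as.character(raw$oil),
    number = as.integer(raw$no),
    precursor_mz = as.numeric(raw$mz),
    rt_mean = as.numeric(raw$rt),
    rt_tol = as.numeric(raw$rt_tol),
    fragments = purrr::pmap(raw[paste0("ms2_", 1:5)], function(...) {
      frag <- as.numeric(c(...))
      frag[!is.na(frag)]
    }),
    collision_energy = as.numeric(raw$ce),
    detect_1pct = raw$det1 == "+",
    detect_5pct = raw$det5 == "+"
  )
  validate_marker_library(lib)
  lib
}

#' @rdname read_marker_library
#' @param library A marker library tibble, as returned by
#'   [read_marker_library()].
#' @export
validate_marker_library <- function(library) {
  if (anyDuplicated(library$number) > 0) {
    stop("duplicate marker number(s): ",
         paste(unique(library$number[duplicated(library$number)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(library$rt_tol <= 0)) {
    stop("rt_tol must be > 0 for every marker", call. = FALSE)
  }
  # fragment ions must be lighter than the precursor (allowing for rounding of
  # printed values in the last decimal)
  bad <- purrr::map2_lgl(library$fragments, library$precursor_mz,
                         function(fr, pre) any(fr >= pre + 0.01))
  if (any(bad)) {
    stop("fragment m/z >= precursor m/z for marker number(s): ",
         paste(library$number[bad], collapse = ", "), call. = FALSE)
  }
  invisible(library)
}

#' Path to packaged example data
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
oilmarkr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "oilmarkr")))
  }
  path <- system.file("extdata", file, package = "oilmarkr")
  if (identical(path, "")) {
    stop("no packaged file '", file, "'", call. = FALSE)
  }
  path
}

#' Packaged bioactivity summary table
#'
#' Per-sample bioactivity endpoints of the sixteen oils (four species from four
#' producers), as replicate means and standard deviations (n = 3): Trolox
#' equivalent antioxidant capacity (TEAC, mg Trolox/kg oil), total phenolic
#' content (TPC, mg gallic acid/kg oil) and total carotenoid content (TCC,
#' mg beta-carotene/kg oil). The `*_letters` columns carry the originally
#' reported Tukey homogeneous-group letters; `anova_tukey()` recomputes letters
#' from the means/SDs and never reads them.
#'
#' @return A tibble with one row per oil sample.
#' @export
bioactivity_table <- function() {
  readr::read_tsv(oilmarkr_example("table2_bioactivity.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
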