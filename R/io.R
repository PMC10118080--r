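#' Read and write per-sample feature tables
#'
#' A feature table holds the molecular features detected in a single LC-MS run:
#' mass-to-charge of the protonated molecule (`mz`, Th), retention time
#' (`rt`, minutes), peak height (`height`, counts) and a deconvolution quality
#' score (`quality`, 0-100). A missing `quality` column defaults to 100 so that
#' downstream quality filtering passes.
#'
#' @param path CSV file path.
#' @param sample_id Sample label attached as the `sample_id` column; defaults
#'   to the file name without extension.
#' @return `read_feature_csv()` returns a tibble with columns `sample_id`,
#'   `mz`, `rt`, `height`, `quality`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_feature_csv(tibble::tibble(mz = 301.2172, rt = 13.15, height = 2e5,
#'                                  quality = 95), tf)
#' read_feature_csv(tf, sample_id = "S_a1")
#' @export
read_feature_csv <- function(path, sample_id = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("mz", "rt_min", "height")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("feature CSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"quality" %in% names(raw)) raw$quality <- "100"
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad) > 0) {
      stop("feature CSV '", path, "': non-numeric or missing '", col,
           "' in data row ", bad[1], call. = FALSE)
    }
    out
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  n <- nrow(raw)
  tibble(
    sample_id = rep(sample_id, n),
    mz = parse_num(raw$mz, "mz"),
    rt = parse_num(raw$rt_min, "rt_min"),
    height = parse_num(raw$height, "height"),
    quality = parse_num(raw$quality, "quality")
  )
}

#' @rdname read_feature_csv
#' @param features A tibble with columns `mz`, `rt` (min), `height`, `quality`
#'   (an empty tibble writes a header-only file).
#' @export
write_feature_csv <- function(features, path) {
  out <- tibble(
    mz = round(as.numeric(features$mz), 4),
    rt_min = as.numeric(features$rt),
    height = as.numeric(features$height),
    quality = if ("quality" %in% names(features)) as.numeric(features$quality) else 100
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write compound-exchange XML feature lists
#'
#' Reads a minimal dialect of the compound-exchange format (CEF) used to move
#' molecular-feature lists between vendor tools: a `<CEF>` document whose
#' `<CompoundList>` holds one `<Compound>` element per feature, each carrying a
#' `<Location>` element with `mz`, `rt` and `height` attributes and optionally
#' a `<CpdScore score="..."/>` quality score. Unknown elements are ignored;
#' compounds without a usable location are skipped with a warning.
#'
#' @param path XML file path.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @return `read_cef()` returns a tibble with columns `sample_id`, `mz`, `rt`,
#'   `height`, `quality`.
#' @export
read_cef <- function(path, sample_id = NULL) {
  doc <- xml2::read_xml(path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  compounds <- xml2::xml_find_all(doc, ".//Compound")
  rows <- purrr::imap(compounds, function(cpd, i) {
    loc <- xml2::xml_find_first(cpd, "./Location")
    if (inherits(loc, "xml_missing")) {
      warning("compound ", i, " in '", path, "' has no <Location>; skipped",
              call. = FALSE)
      return(NULL)
    }
    mz <- suppressWarnings(as.numeric(xml2::xml_attr(loc, "mz")))
    rt <- suppressWarnings(as.numeric(xml2::xml_attr(loc, "rt")))
    height <- suppressWarnings(as.numeric(xml2::xml_attr(loc, "height")))
    if (anyNA(c(mz, rt, height))) {
      warning("compound ", i, " in '", path,
              "' is missing mz/rt/height; skipped", call. = FALSE)
      return(NULL)
    }
    score <- xml2::xml_find_first(cpd, ".//CpdScore")
    quality <- if (inherits(score, "xml_missing")) 100 else
      suppressWarnings(as.numeric(xml2::xml_attr(score, "score")))
    if (is.na(quality)) quality <- 100
    tibble(sample_id = sample_id, mz = mz, rt = rt, height = height,
           quality = quality)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble(sample_id = character(), mz = double(), rt = double(),
                  height = double(), quality = double()))
  }
  bind_rows(rows)
}

#' @rdname read_cef
#' @param features A tibble with columns `mz`, `rt`, `height` and optionally
#'   `quality`.
#' @export
write_cef <- function(features, path) {
  doc <- xml2::xml_new_root("CEF", version = "1.0")
  lst <- xml2::xml_add_child(doc, "CompoundList")
  quality <- if ("quality" %in% names(features)) features$quality else
    rep(100, nrow(features))
  for (i in seq_len(nrow(features))) {
    cpd <- xml2::xml_add_child(lst, "Compound")
    xml2::xml_add_child(cpd, "Location",
                        mz = formatC(features$mz[i], format = "f", digits = 4),
                        rt = formatC(features$rt[i], format = "f", digits = 4),
                        height = formatC(features$height[i], format = "f",
                                         digits = 2))
    scores <- xml2::xml_add_child(cpd, "CompoundScores")
    xml2::xml_add_child(scores, "CpdScore",
                        score = formatC(quality[i], format = "f", digits = 2))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
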