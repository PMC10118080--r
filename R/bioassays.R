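#' ABTS radical-scavenging percent reduction
#'
#' `%Reduction = (Ac - As) / Ac * 100`, where `Ac` is the absorbance of the
#' control (radical solution plus solvent) and `As` the absorbance of the
#' sample with the radical reagent. Negative values (pro-oxidant readings) are
#' allowed with a warning.
#'
#' @param ac Control absorbance(s), > 0.
#' @param as_ Sample absorbance(s).
#' @return Percent reduction (vectorised); never exceeds 100 for non-negative
#'   absorbances.
#' @examples
#' percent_reduction(1.0, 0.5)  # 50
#' @export
percent_reduction <- function(ac, as_) {
  if (any(ac <= 0)) stop("control absorbance must be > 0", call. = FALSE)
  if (any(as_ < 0)) stop("sample absorbance must be >= 0", call. = FALSE)
  out <- (ac - as_) / ac * 100
  if (any(out < 0)) {
    warning("negative %reduction (sample absorbs more than control)",
            call. = FALSE)
  }
  out
}

#' EC50 from a dose-response curve
#'
#' Fits a four-parameter logistic (Hill) curve
#' `R(c) = lo + (hi - lo) / (1 + (mid / c)^h)` to (concentration, %reduction)
#' pairs and returns the concentration at 50% reduction. If the fit fails
#' (too few points, degenerate data), the function falls back to linear
#' interpolation between the two points bracketing 50%. The response must
#' bracket 50%.
#'
#' @param concentration Concentrations (any consistent unit; the EC50 is
#'   returned in the same unit).
#' @param response Percent reduction at each concentration.
#' @return The EC50, with the fitting method in attribute `method`
#'   (`"4PL"` or `"interpolation"`).
#' @examples
#' ec50(c(0, 2), c(0, 100))  # 1.0
#' @export
ec50 <- function(concentration, response) {
  stopifnot(length(concentration) == length(response),
            all(concentration >= 0))
  ord <- order(concentration)
  conc <- concentration[ord]
  resp <- response[ord]
  if (max(resp) < 50 || min(resp) > 50) {
    stop("50% not bracketed by the dose-response data", call. = FALSE)
  }
  if (stats::cor(conc, resp, method = "spearman") < 0) {
    stop("response must increase with concentration", call. = FALSE)
  }
  fit <- NULL
  if (length(conc) >= 4 && all(conc > 0)) {
    start <- list(lo = min(resp), hi = max(resp),
                  mid = exp(stats::weighted.mean(log(conc),
                                                 w = 1 / (1 + abs(resp - 50)))),
                  h = 1)
    fit <- tryCatch(
      nls(resp ~ lo + (hi - lo) / (1 + (mid / conc)^h),
          start = start, control = list(maxiter = 200, warnOnly = FALSE),
          algorithm = "port",
          lower = c(lo = -Inf, hi = -Inf, mid = min(conc) / 100, h = 0.05)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- as.list(coef(fit))
    f50 <- function(cc) {
      cf$lo + (cf$hi - cf$lo) / (1 + (cf$mid / cc)^cf$h) - 50
    }
    lo_c <- min(conc[conc > 0]) / 100
    hi_c <- max(conc) * 100
    root <- tryCatch(uniroot(f50, lower = lo_c, upper = hi_c,
                             tol = 1e-12)$root,
                     error = function(e) NULL)
    if (!is.null(root)) {
      return(structure(root, method = "4PL"))
    }
  }
  # bracketing linear interpolation
  below <- max(which(resp <= 50))
  above <- min(which(resp >= 50))
  if (resp[above] == resp[below]) {
    return(structure(conc[below], method = "interpolation"))
  }
  est <- conc[below] + (50 - resp[below]) *
    (conc[above] - conc[below]) / (resp[above] - resp[below])
  structure(est, method = "interpolation")
}

#' Trolox-equivalent antioxidant capacity
#'
#' `TEAC = EC50_trolox / EC50_sample`. With the Trolox EC50 in mg Trolox per
#' litre of assay volume and the sample EC50 in kg oil per litre, the ratio is
#' directly mg Trolox per kg oil.
#'
#' @param ec50_sample Sample EC50 (kg oil / L assay).
#' @param ec50_trolox Trolox EC50 (mg Trolox / L assay).
#' @return TEAC, mg Trolox per kg oil.
#' @export
teac <- function(ec50_sample, ec50_trolox) {
  stopifnot(ec50_sample > 0, ec50_trolox > 0)
  ec50_trolox / ec50_sample
}

#' Linear standard curve
#'
#' Ordinary least-squares calibration line `absorbance ~ concentration`.
#'
#' @param points A tibble/data frame with columns `concentration` and
#'   `absorbance` (at least two distinct concentrations).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and the calibrated concentration `range`.
#' @export
standard_curve <- function(points) {
  stopifnot(all(c("concentration", "absorbance") %in% names(points)))
  if (length(unique(points$concentration)) < 2) {
    stop("need at least two distinct standard concentrations", call. = FALSE)
  }
  fit <- lm(absorbance ~ concentration, data = points)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((points$absorbance - mean(points$absorbance))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 range = range(points$concentration),
                 n = nrow(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> A = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " * conc; R2 = ", round(x$r_squared, 5),
      "; range ", x$range[1], "-", x$range[2], "\n", sep = "")
  invisible(x)
}

#' Concentration from absorbance via a standard curve
#'
#' Inverts the calibration line — `conc = (A - blank - intercept) / slope` —
#' applies the dilution factor, and normalises by the oil content of the
#' extract to yield mg analyte per kg oil. Readings that invert outside the
#' calibrated range are flagged with a warning.
#'
#' @param curve A [standard_curve()].
#' @param absorbance Sample absorbance(s).
#' @param dilution Dilution factor of the extract (>= 1 undoes dilution).
#' @param oil_conc Oil content of the undiluted extract, g oil per ml
#'   (mg analyte/kg oil = (ug/ml in extract) / (g oil/ml)).
#' @param blank Blank absorbance subtracted before inversion.
#' @return mg analyte per kg oil (vectorised).
#' @export
concentration_from_absorbance <- function(curve, absorbance, dilution = 1,
                                          oil_conc = 1, blank = 0) {
  stopifnot(inherits(curve, "standard_curve"), dilution > 0, oil_conc > 0)
  conc_well <- (absorbance - blank - curve$intercept) / curve$slope
  outside <- conc_well < curve$range[1] - 1e-9 |
    conc_well > curve$range[2] + 1e-9
  if (any(outside)) {
    warning(sum(outside), " reading(s) extrapolate beyond the standard-curve",
            " range", call. = FALSE)
  }
  conc_well * dilution / oil_conc
}

#' Reduce a simulated assay plate to its endpoint
#'
#' Applies the matching reduction to an [simulate_assay_plate()] object:
#' * TPC/TCC: fit the standard curve, invert each replicate absorbance
#'   (blank-subtracted), average replicates after conversion;
#' * ABTS: convert absorbances to %reduction against the control, fit the
#'   dose-response, take the EC50 and express it as TEAC against the supplied
#'   Trolox EC50.
#'
#' @param plate An `assay_plate`.
#' @param ec50_trolox Trolox EC50 (mg/L) for ABTS plates.
#' @return A tibble with `kind`, `value` (mg analyte or Trolox per kg oil;
#'   EC50 in the plate's units for ABTS alongside), `sd` (replicate SD, `NA`
#'   for ABTS) and `n`.
#' @export
assay_value <- function(plate, ec50_trolox = NULL) {
  stopifnot(inherits(plate, "assay_plate"))
  if (plate$kind %in% c("TPC", "TCC")) {
    curve <- standard_curve(plate$standards)
    per_rep <- concentration_from_absorbance(
      curve, plate$samples$absorbance, dilution = plate$samples$dilution,
      oil_conc = plate$oil_conc, blank = plate$blank_absorbance)
    tibble(kind = plate$kind, value = mean(per_rep),
           sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
           n = length(per_rep), ec50 = NA_real_)
  } else {
    red <- plate$samples %>%
      mutate(reduction = percent_reduction(plate$control_absorbance,
                                           absorbance)) %>%
      group_by(concentration) %>%
      summarise(reduction = mean(reduction), .groups = "drop")
    est <- ec50(red$concentration, red$reduction)
    value <- if (is.null(ec50_trolox)) NA_real_ else
      teac(as.numeric(est), ec50_trolox)
    tibble(kind = "ABTS", value = value, sd = NA_real_,
           n = length(unique(plate$samples$replicate)),
           ec50 = as.numeric(est))
  }
}

#' One-way ANOVA with Tukey HSD letters from summary statistics
#'
#' Reconstructs a one-way ANOVA from per-group replicate summaries (mean, SD,
#' n): the pooled error mean square is `sum((n_i - 1) s_i^2) / sum(n_i - 1)`,
#' pairwise comparisons use the Tukey-Kramer studentized-range statistic
#' `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))` at the pooled error df, and
#' homogeneous groups are lettered by insert-and-absorb: groups share a letter
#' exactly when their Tukey p-value is at least `alpha`. Letters are assigned
#' in descending order of the group means ('a' contains the largest mean).
#'
#' @param groups Tibble with columns `group`, `mean`, `sd`, `n` (n >= 2 per
#'   group, at least two groups).
#' @param alpha Significance level for the homogeneous groups.
#' @return An object of class `anova_tukey`: `groups` (input plus a `letters`
#'   column, ordered by descending mean), `pairwise` (tibble of all pairs with
#'   `q` and `p`), and `anova` (F statistic, df, p-value).
#' @examples
#' anova_tukey(tibble::tibble(group = c("A", "B"), mean = c(0, 100),
#'                            sd = c(1, 1), n = 3))
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(groups)))
  k <- nrow(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (any(groups$n < 2)) stop("need n >= 2 in every group", call. = FALSE)
  if (anyDuplicated(groups$group) > 0) {
    stop("duplicate group labels", call. = FALSE)
  }
  n_i <- groups$n
  df_err <- sum(n_i - 1)
  mse <- sum((n_i - 1) * groups$sd^2) / df_err
  grand <- sum(n_i * groups$mean) / sum(n_i)
  ms_between <- sum(n_i * (groups$mean - grand)^2) / (k - 1)
  f_stat <- if (mse > 0) ms_between / mse else Inf
  p_anova <- if (is.finite(f_stat)) pf(f_stat, k - 1, df_err,
                                       lower.tail = FALSE)
             else as.numeric(ms_between == 0)

  pairs <- utils::combn(k, 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / n_i[i1] + 1 / n_i[i2]))
    diff <- abs(groups$mean[i1] - groups$mean[i2])
    q <- if (se > 0) diff / se else if (diff > 0) Inf else 0
    p <- if (is.finite(q)) ptukey(q, nmeans = k, df = df_err,
                                  lower.tail = FALSE)
         else 0
    tibble(group1 = groups$group[i1], group2 = groups$group[i2],
           diff = groups$mean[i1] - groups$mean[i2], q = q, p = p)
  }) %>% bind_rows()

  letters_tbl <- compact_letter_display(groups$group, groups$mean,
                                        pairwise, alpha)
  out_groups <- groups %>%
    left_join(letters_tbl, by = "group") %>%
    arrange(desc(mean))
  structure(list(groups = out_groups, pairwise = pairwise,
                 anova = tibble(f = f_stat, df1 = k - 1, df2 = df_err,
                                mse = mse, p = p_anova),
                 alpha = alpha),
            class = "anova_tukey")
}

# insert-and-absorb compact letter display; pairwise must contain group1,
# group2, p
compact_letter_display <- function(group, mean, pairwise, alpha) {
  ord <- order(-mean)
  labels <- group[ord]
  sig <- pairwise[pairwise$p < alpha, c("group1", "group2")]
  # columns: list of character vectors of member groups
  cols <- list(labels)
  for (j in seq_len(nrow(sig))) {
    g1 <- sig$group1[j]; g2 <- sig$group2[j]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) ||
             (length(new_cols[[a]]) == length(new_cols[[b]]) && a > b))) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the position of their highest-mean member, letter them
  first_pos <- purrr::map_dbl(cols, function(col) min(match(col, labels)))
  cols <- cols[order(first_pos)]
  lab <- character(length(labels))
  for (ci in seq_along(cols)) {
    letter <- make_letter(ci)
    members <- cols[[ci]]
    idx <- match(members, labels)
    lab[idx] <- paste0(lab[idx], letter)
  }
  tibble(group = labels, letters = lab)
}

make_letter <- function(i) {
  # a..z, then aa, ab, ...
  if (i <= 26) return(letters[i])
  paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("<anova_tukey> F(", x$anova$df1, ",", x$anova$df2, ") = ",
      signif(x$anova$f, 5), ", p = ", format.pval(x$anova$p),
      ", alpha = ", x$alpha, "\n", sep = "")
  print(x$groups, n = Inf)
  invisible(x)
}

#' @export
tidy.anova_tukey <- function(x, ...) x$groups

#' @export
glance.anova_tukey <- function(x, ...) x$anova
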