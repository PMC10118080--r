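#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded at `seed`, restoring the
#' previous RNG state afterwards, so simulation functions are reproducible
#' without clobbering the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulation design for a synthetic oil study
#'
#' Captures the study layout and noise model used by [simulate_dataset()]:
#' four producers (labelled a-d) each contributing two bottles (batches) per
#' oil, lognormal producer- and batch-level variation of compound intensity,
#' ppm-scaled Gaussian mass error, absolute Gaussian retention-time jitter,
#' and a detection floor below which peaks are censored.
#'
#' @param n_producers Number of producers per species (labelled `a`, `b`, ...).
#' @param n_batches Bottles (lots) per producer.
#' @param producer_log_sd,batch_log_sd Lognormal SDs of the multiplicative
#'   intensity factors across producers and across batches within a producer.
#' @param mass_error_ppm_sd SD of the relative m/z error, in ppm.
#' @param rt_jitter_sd SD of the absolute retention-time jitter, minutes.
#' @param detection_floor Peak-height censoring threshold, counts.
#' @param n_background Number of background compounds shared across species.
#' @param background_share Fraction of the background set expressed by each
#'   species.
#' @param n_species_specific Species-distinguishing compounds planted per
#'   target species beyond its markers; each is also expressed by two
#'   negative-panel species, so the exclusivity screen removes it from marker
#'   candidacy while it still contributes class structure to the model, as
#'   the common ions excluded by a negative panel do in real profiles.
#' @param n_blanks Number of solvent-blank injections.
#' @param n_solvent_features Solvent-contaminant compounds seen in blanks.
#' @param seed RNG seed; the same seed reproduces the dataset bit for bit.
#' @return A list of class `simulation_design`.
#' @examples
#' noise_free <- simulation_design(producer_log_sd = 0, batch_log_sd = 0,
#'                                 mass_error_ppm_sd = 0, rt_jitter_sd = 0)
#' @export
simulation_design <- function(n_producers = 4,
                              n_batches = 2,
                              producer_log_sd = 0.5,
                              batch_log_sd = 0.2,
                              mass_error_ppm_sd = 1.5,
                              rt_jitter_sd = 0.05,
                              detection_floor = 600,
                              n_background = 500,
                              background_share = 0.8,
                              n_species_specific = 15,
                              n_blanks = 3,
                              n_solvent_features = 30,
                              seed = 1L) {
  stopifnot(n_producers >= 1, n_batches >= 1,
            producer_log_sd >= 0, batch_log_sd >= 0,
            mass_error_ppm_sd >= 0, rt_jitter_sd >= 0,
            detection_floor > 0, n_background >= 0,
            background_share >= 0, background_share <= 1,
            n_species_specific >= 0,
            n_blanks >= 0, n_solvent_features >= 0)
  if (n_producers > 26) stop("at most 26 producers (labels a-z)", call. = FALSE)
  structure(list(
    n_producers = as.integer(n_producers),
    n_batches = as.integer(n_batches),
    producer_log_sd = producer_log_sd,
    batch_log_sd = batch_log_sd,
    mass_error_ppm_sd = mass_error_ppm_sd,
    rt_jitter_sd = rt_jitter_sd,
    detection_floor = detection_floor,
    n_background = as.integer(n_background),
    background_share = background_share,
    n_species_specific = as.integer(n_species_specific),
    n_blanks = as.integer(n_blanks),
    n_solvent_features = as.integer(n_solvent_features),
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Species specifications for the simulator
#'
#' One row per simulated oil species. The four target species carry the
#' packaged marker library; the five negative-panel species (pumpkin, evening
#' primrose, black cumin, hemp, thistle) carry no markers and only express the
#' shared background. Marker base intensities are set from the library's 1%
#' detectability flag: markers still seen in a 1% (v/v) mixture get a base of
#' `base_detectable` counts, the rest `base_faint` counts, so that with a
#' 600-count floor the 1% flags emerge at a mixing fraction of 0.01 in the
#' noise-free limit (boundary at 600 / 0.01 = 60000 counts).
#'
#' @param library Marker library tibble (see [read_marker_library()]).
#' @param panel_species Names of marker-free negative-panel species.
#' @param background_share Fraction of background compounds each target
#'   species expresses. The default, 1, encodes the background as the common
#'   seed-oil metabolome: present in every target oil, so that species
#'   specificity is carried by the markers alone.
#' @param panel_background_share Fraction of the background expressed by each
#'   negative-panel species.
#' @param base_detectable,base_faint Marker base peak heights (counts) for
#'   markers flagged detectable / not detectable at 1%.
#' @return A tibble with columns `name`, `markers` (list column), and
#'   `background_share`.
#' @export
oil_species_specs <- function(library = read_marker_library(),
                              panel_species = c("pumpkin", "evening_primrose",
                                                "black_cumin", "hemp", "thistle"),
                              background_share = 1,
                              panel_background_share = 0.8,
                              base_detectable = 120000,
                              base_faint = 30000) {
  target <- library %>%
    mutate(base_height = ifelse(detect_1pct, base_detectable, base_faint)) %>%
    select(oil, number, precursor_mz, rt_mean, base_height) %>%
    tidyr::nest(markers = c(number, precursor_mz, rt_mean, base_height)) %>%
    rename(name = oil)
  empty_markers <- tibble(number = integer(), precursor_mz = double(),
                          rt_mean = double(), base_height = double())
  panel <- tibble(name = panel_species,
                  markers = rep(list(empty_markers), length(panel_species)),
                  background_share = panel_background_share)
  target$background_share <- background_share
  specs <- bind_rows(target, panel)
  # marker precursors must be resolvable within the mass window inside a species
  for (i in seq_len(nrow(specs))) {
    mk <- specs$markers[[i]]
    if (nrow(mk) > 1) {
      d <- diff(sort(mk$precursor_mz))
      if (any(d < 0.004 + 5e-6 * sort(mk$precursor_mz)[-1])) {
        stop("marker precursors of '", specs$name[i],
             "' are not unique within the mass window", call. = FALSE)
      }
    }
  }
  specs
}

# deterministic solvent-contaminant feature set for a design (shared between
# simulate_dataset() and simulate_blank())
solvent_features <- function(design, avoid = NULL) {
  with_seed(design$seed + 104729L, {
    n <- design$n_solvent_features
    feats <- tibble(
      mz = runif(n, 100, 1200),
      rt = runif(n, 0.5, 29.5),
      base_height = rlnorm(n, meanlog = log(20000), sdlog = 0.5)
    )
    push_apart(feats, avoid)
  })
}

# shift mz of rows that fall within a (0.01 Da, 0.6 min) guard zone of any
# 'avoid' compound, so planted identities stay unambiguous under the alignment
# windows
push_apart <- function(feats, avoid) {
  if (is.null(avoid) || nrow(avoid) == 0 || nrow(feats) == 0) return(feats)
  repeat {
    clash <- purrr::map_lgl(seq_len(nrow(feats)), function(i) {
      any(abs(avoid$mz - feats$mz[i]) < 0.01 & abs(avoid$rt - feats$rt[i]) < 0.6)
    })
    if (!any(clash)) return(feats)
    feats$mz[clash] <- feats$mz[clash] + 0.05
  }
}

#' Simulate a full oil-profiling dataset
#'
#' Generates per-sample molecular-feature lists for every species in `species`
#' under the layout and noise model in `design`, plus solvent blanks and a
#' ground-truth manifest. Each species sample contains its planted markers and
#' its share of a common background metabolome; peak heights are
#' `base x producer factor x batch factor`, with both factors lognormal;
#' observed m/z carries ppm-scaled Gaussian error and retention times absolute
#' Gaussian jitter. Features below the detection floor are censored (absent
#' from the feature list, recorded as censored in the truth table).
#'
#' The ground-truth manifest exists for validation only: no analysis function
#' in the package reads it.
#'
#' @param design A [simulation_design()].
#' @param species A species table from [oil_species_specs()].
#' @return An object of class `oil_dataset`: a list with tibbles `samples`
#'   (sample metadata), `features` (long feature table: `sample_id`, `mz`,
#'   `rt`, `height`, `quality`), `truth` (planted identities), and the
#'   `design` and `species` used.
#' @examples
#' ds <- simulate_dataset(simulation_design(n_background = 50, seed = 7))
#' dplyr::count(ds$samples, role)
#' @export
simulate_dataset <- function(design = simulation_design(),
                             species = oil_species_specs()) {
  stopifnot(inherits(design, "simulation_design"), nrow(species) >= 1)
  if (anyDuplicated(species$name) > 0) {
    stop("duplicate species names", call. = FALSE)
  }
  producers <- letters[seq_len(design$n_producers)]
  batches <- seq_len(design$n_batches)

  all_markers <- bind_rows(purrr::map2(species$name, species$markers,
                                       ~ mutate(.y, species = .x))) %>%
    rename(mz = precursor_mz, rt = rt_mean)

  with_seed(design$seed, {
    # shared background metabolome
    nb <- design$n_background
    background <- tibble(
      background_id = seq_len(nb),
      mz = runif(nb, 100, 1200),
      rt = runif(nb, 0.5, 29.5),
      base_height = rlnorm(nb, meanlog = log(50000), sdlog = 0.8)
    )
    if (nb > 0 && nrow(all_markers) > 0) {
      background <- push_apart(background,
                               all_markers[, c("mz", "rt")])
    }
    # which species expresses which background compound; compounds drawn for
    # fewer than two species are promoted to all species so that no background
    # compound can masquerade as species-specific
    expr <- matrix(FALSE, nrow = nb, ncol = nrow(species))
    for (s in seq_len(nrow(species))) {
      expr[, s] <- runif(nb) < species$background_share[s]
    }
    if (nb > 0 && nrow(species) > 1) {
      lonely <- rowSums(expr) < 2
      expr[lonely, ] <- TRUE
    }
    # the common background rises and falls together: a global intensity
    # factor per producer and per bottle (raw-material and pressing effects),
    # shared across species, plus per-compound residual scatter. This puts
    # correlated, class-neutral structure into X -- the variation the
    # orthogonal components of an OPLS-DA model are there to strip.
    bg_prod_g <- rlnorm(design$n_producers, 0, design$producer_log_sd)
    bg_batch_g <- matrix(rlnorm(design$n_producers * design$n_batches,
                                0, design$batch_log_sd),
                         nrow = design$n_producers)

    # species-distinguishing non-marker compounds: expressed by one target
    # species and by two panel species, mimicking class-informative ions that
    # a negative-panel screen later rejects as shared
    target_names <- species$name[purrr::map_int(species$markers, nrow) > 0]
    panel_names <- setdiff(species$name, target_names)
    ss <- tibble(species = character(), mz = double(), rt = double(),
                 base_height = double(), partner1 = character(),
                 partner2 = character())
    if (design$n_species_specific > 0 && length(target_names) > 0 &&
        length(panel_names) > 0) {
      avoid <- bind_rows(all_markers[, c("mz", "rt")],
                         background[, c("mz", "rt")])
      for (tn in target_names) {
        nss <- design$n_species_specific
        block <- tibble(
          species = tn,
          mz = runif(nss, 100, 1200),
          rt = runif(nss, 0.5, 29.5),
          base_height = rlnorm(nss, meanlog = log(40000), sdlog = 0.6),
          partner1 = sample(panel_names, nss, replace = TRUE),
          partner2 = sample(panel_names, nss, replace = TRUE)
        )
        block[, c("mz", "rt", "base_height")] <-
          push_apart(block[, c("mz", "rt", "base_height")], avoid)
        avoid <- bind_rows(avoid, block[, c("mz", "rt")])
        ss <- bind_rows(ss, block)
      }
    }

    feature_rows <- list()
    truth_rows <- list()
    sample_rows <- list()

    for (s in seq_len(nrow(species))) {
      sp <- species$name[s]
      markers <- all_markers %>% filter(species == sp)
      ss_here <- ss %>%
        filter(species == sp | partner1 == sp | partner2 == sp)
      bg_idx <- if (nb > 0) which(expr[, s]) else integer()
      compounds <- bind_rows(
        if (nrow(markers) > 0)
          tibble(kind = "marker", marker_number = markers$number,
                 mz = markers$mz, rt = markers$rt,
                 base_height = markers$base_height),
        if (nrow(ss_here) > 0)
          tibble(kind = "species_specific", marker_number = NA_integer_,
                 mz = ss_here$mz, rt = ss_here$rt,
                 base_height = ss_here$base_height),
        if (length(bg_idx) > 0)
          tibble(kind = "background",
                 marker_number = NA_integer_,
                 mz = background$mz[bg_idx],
                 rt = background$rt[bg_idx],
                 base_height = background$base_height[bg_idx])
      )
      nf <- nrow(compounds)
      nm <- nrow(markers) + nrow(ss_here)
      mk_prod <- matrix(rlnorm(nm * design$n_producers,
                               0, design$producer_log_sd),
                        nrow = nm, ncol = design$n_producers)
      for (pi in seq_along(producers)) {
        for (bi in batches) {
          sid <- paste0(sp, "_", producers[pi], bi)
          mk_batch <- rlnorm(nm, 0, design$batch_log_sd)
          bg_resid <- rlnorm(length(bg_idx), 0, design$batch_log_sd)
          prod_factor <- c(mk_prod[, pi], rep(bg_prod_g[pi], length(bg_idx)))
          batch_factor <- c(mk_batch, bg_batch_g[pi, bi] * bg_resid)
          h_true <- compounds$base_height * prod_factor * batch_factor
          mz_obs <- compounds$mz *
            (1 + rnorm(nf, 0, design$mass_error_ppm_sd) * 1e-6)
          rt_obs <- pmax(0, compounds$rt + rnorm(nf, 0, design$rt_jitter_sd))
          qual <- runif(nf, 85, 100)
          keep <- h_true >= design$detection_floor
          role <- if (nrow(markers) > 0) "oil" else "panel"
          sample_rows[[sid]] <- tibble(sample_id = sid, species = sp,
                                       producer = producers[pi],
                                       batch = as.character(bi), role = role)
          feature_rows[[sid]] <- tibble(sample_id = sid, mz = mz_obs[keep],
                                        rt = rt_obs[keep],
                                        height = h_true[keep],
                                        quality = qual[keep])
          truth_rows[[sid]] <- tibble(sample_id = sid, kind = compounds$kind,
                                      species = sp,
                                      marker_number = compounds$marker_number,
                                      mz_true = compounds$mz,
                                      rt_true = compounds$rt,
                                      height_true = h_true,
                                      censored = !keep)
        }
      }
    }

    # solvent blanks
    solvent <- solvent_features(
      design, avoid = bind_rows(all_markers[, c("mz", "rt")],
                                background[, c("mz", "rt")],
                                ss[, c("mz", "rt")]))
    for (b in seq_len(design$n_blanks)) {
      sid <- paste0("blank_", b)
      nf <- nrow(solvent)
      h_true <- solvent$base_height * rlnorm(nf, 0, design$batch_log_sd)
      mz_obs <- solvent$mz * (1 + rnorm(nf, 0, design$mass_error_ppm_sd) * 1e-6)
      rt_obs <- pmax(0, solvent$rt + rnorm(nf, 0, design$rt_jitter_sd))
      qual <- runif(nf, 85, 100)
      keep <- h_true >= design$detection_floor
      sample_rows[[sid]] <- tibble(sample_id = sid, species = "blank",
                                   producer = "", batch = as.character(b),
                                   role = "blank")
      feature_rows[[sid]] <- tibble(sample_id = sid, mz = mz_obs[keep],
                                    rt = rt_obs[keep], height = h_true[keep],
                                    quality = qual[keep])
      truth_rows[[sid]] <- tibble(sample_id = sid, kind = "solvent",
                                  species = "blank",
                                  marker_number = NA_integer_,
                                  mz_true = solvent$mz, rt_true = solvent$rt,
                                  height_true = h_true, censored = !keep)
    }

    structure(list(
      samples = bind_rows(sample_rows),
      features = bind_rows(feature_rows),
      truth = bind_rows(truth_rows),
      design = design,
      species = species
    ), class = "oil_dataset")
  })
}

#' @export
print.oil_dataset <- function(x, ...) {
  cat("<oil_dataset> ", nrow(x$samples), " samples, ",
      nrow(x$features), " features\n", sep = "")
  print(dplyr::count(x$samples, species, role), n = Inf)
  invisible(x)
}

#' Simulate a solvent blank injection
#'
#' Emits the design's solvent-contaminant feature set (disjoint, by
#' construction, from every marker and background compound of the dataset
#' simulated under the same design) with the design's measurement noise.
#'
#' @param design A [simulation_design()].
#' @param sample_id Label for the blank.
#' @return A feature tibble (`sample_id`, `mz`, `rt`, `height`, `quality`).
#' @export
simulate_blank <- function(design = simulation_design(), sample_id = "blank") {
  solvent <- solvent_features(design)
  with_seed(design$seed + 7919L, {
    nf <- nrow(solvent)
    h <- solvent$base_height * rlnorm(nf, 0, design$batch_log_sd)
    keep <- h >= design$detection_floor
    tibble(sample_id = sample_id,
           mz = (solvent$mz * (1 + rnorm(nf, 0, design$mass_error_ppm_sd) * 1e-6))[keep],
           rt = pmax(0, solvent$rt + rnorm(nf, 0, design$rt_jitter_sd))[keep],
           height = h[keep],
           quality = runif(nf, 85, 100)[keep])
  })
}

#' Simulate a two-component oil mixture
#'
#' Mimics volumetric mixing of two oils: every feature height of the minor
#' parent is scaled by the mixing fraction `fraction` and every feature of the
#' major parent by `1 - fraction`; features that co-elute within the alignment
#' windows are summed; the detection floor is then re-applied.
#'
#' @param minor,major Feature tibbles of the two parent samples (columns `mz`,
#'   `rt`, `height`, `quality`), simulated under the same design.
#' @param fraction Volume fraction of the minor oil, strictly between 0 and 1.
#' @param design The [simulation_design()] supplying the detection floor.
#' @param windows [tolerance_windows()] used for co-elution merging.
#' @param sample_id Label for the mixture sample.
#' @return A feature tibble for the mixture.
#' @export
simulate_mixture <- function(minor, major, fraction,
                             design = simulation_design(),
                             windows = tolerance_windows(),
                             sample_id = "mixture") {
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction < 1)) {
    stop("fraction must be a single number in (0, 1)", call. = FALSE)
  }
  scaled <- bind_rows(
    mutate(minor, height = height * fraction),
    mutate(major, height = height * (1 - fraction))
  ) %>%
    mutate(sample_id = "mix")
  if (nrow(scaled) == 0) {
    return(tibble(sample_id = character(), mz = double(), rt = double(),
                  height = double(), quality = double()))
  }
  # co-elution: cluster the pooled list with the alignment rule, ignoring the
  # one-feature-per-sample restriction, and sum heights within a cluster
  fm <- align_features(scaled, windows = windows, one_per_sample = FALSE)
  merged <- fm$members %>%
    group_by(feature_id) %>%
    summarise(mz = sum(mz * height) / sum(height),
              rt = sum(rt * height) / sum(height),
              height = sum(height),
              quality = min(quality), .groups = "drop")
  merged %>%
    filter(height >= design$detection_floor) %>%
    transmute(sample_id = .env$sample_id, mz, rt, height, quality) %>%
    arrange(mz)
}

#' Simulate a spectrophotometric assay plate
#'
#' Builds plate readings consistent with the measurement model of each assay
#' so that the corresponding reduction functions recover `true_value` exactly
#' at zero noise:
#' * `"TPC"` / `"TCC"`: linear calibration `A = intercept + slope * conc` over
#'   the standard series, plus replicate sample absorbances at
#'   `conc = true_value * oil_conc / dilution`;
#' * `"ABTS"`: a control absorbance and a dose-response series where
#'   %reduction follows a Hill curve with midpoint `ec50_true`.
#' Noise is multiplicative Gaussian on absorbances with SD `noise_sd`
#' (a fraction, e.g. 0.02 for 2%).
#'
#' @param kind `"TPC"`, `"TCC"` or `"ABTS"`.
#' @param true_value True analyte content, mg/kg oil (TPC/TCC), or the true
#'   EC50 for ABTS in kg oil per litre of assay volume.
#' @param noise_sd Relative SD of absorbance noise.
#' @param n_replicates Replicate readings per level (default 3).
#' @param slope,intercept Calibration line (absorbance per ug/ml).
#' @param standards Standard concentrations, ug/ml.
#' @param dilution Dilution factor applied to the oil extract.
#' @param oil_conc Oil content of the undiluted extract, g oil per ml.
#' @param control_absorbance ABTS control (radical only) absorbance.
#' @param doses ABTS oil concentrations assayed, kg oil per litre.
#' @param hill Hill exponent of the simulated dose-response.
#' @param seed RNG seed.
#' @return An object of class `assay_plate`.
#' @export
simulate_assay_plate <- function(kind = c("TPC", "TCC", "ABTS"),
                                 true_value,
                                 noise_sd = 0,
                                 n_replicates = 3,
                                 slope = 0.005,
                                 intercept = 0.02,
                                 standards = NULL,
                                 dilution = 1,
                                 oil_conc = 1,
                                 control_absorbance = 0.7,
                                 doses = NULL,
                                 hill = 1,
                                 seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(true_value > 0, noise_sd >= 0, n_replicates >= 1, dilution > 0,
            oil_conc > 0)
  jitter <- function(x) x * (1 + rnorm(length(x), 0, noise_sd))
  with_seed(seed, {
    if (kind %in% c("TPC", "TCC")) {
      if (is.null(standards)) {
        standards <- if (kind == "TPC") c(25, 50, 100, 150, 200)
                     else c(5, 50, 100, 250, 500)
      }
      std <- tibble(concentration = standards,
                    absorbance = jitter(intercept + slope * standards))
      conc_well <- true_value * oil_conc / dilution
      smp <- tibble(replicate = seq_len(n_replicates),
                    dilution = dilution,
                    absorbance = jitter(rep(intercept + slope * conc_well,
                                            n_replicates)))
      structure(list(kind = kind, standards = std, samples = smp,
                     oil_conc = oil_conc, blank_absorbance = 0,
                     truth = true_value),
                class = "assay_plate")
    } else {
      if (is.null(doses)) {
        doses <- true_value * c(0.2, 0.5, 1, 2, 5)
      }
      red <- 100 * doses^hill / (doses^hill + true_value^hill)
      rows <- purrr::map(seq_len(n_replicates), function(r) {
        tibble(replicate = r, concentration = doses,
               absorbance = jitter(control_absorbance * (1 - red / 100)))
      })
      structure(list(kind = "ABTS",
                     control_absorbance = jitter(control_absorbance),
                     samples = bind_rows(rows),
                     truth = true_value),
                class = "assay_plate")
    }
  })
}

#' @export
print.assay_plate <- function(x, ...) {
  cat("<assay_plate> kind=", x$kind, ", ", nrow(x$samples), " readings\n",
      sep = "")
  invisible(x)
}
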