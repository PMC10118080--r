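# shared fixtures and independent oracles

noise_free_design <- function(seed = 5, ...) {
  simulation_design(producer_log_sd = 0, batch_log_sd = 0,
                    mass_error_ppm_sd = 0, rt_jitter_sd = 0, seed = seed, ...)
}

# a small single-species spec with one synthetic marker
one_marker_species <- function(base_height = 10000, mz = 300.1234, rt = 10,
                               background_share = 1) {
  tibble::tibble(
    name = "testoil",
    markers = list(tibble::tibble(number = 1L, precursor_mz = mz,
                                  rt_mean = rt, base_height = base_height)),
    background_share = background_share
  )
}

# count how many library markers of one oil are matched (by m/z) in a
# discovered candidate table
n_matched <- function(found, library, oil_name) {
  planted <- library$precursor_mz[library$oil == oil_name]
  sum(vapply(planted, function(m) any(abs(found$mz - m) < 0.01), logical(1)))
}

# independent two-block NIPALS PLS2 oracle (centering only); returns scores
pls2_oracle <- function(X, Y, n_components) {
  E <- scale(X, scale = FALSE)
  F <- scale(Y, scale = FALSE)
  scores <- NULL
  for (a in seq_len(n_components)) {
    u <- F[, which.max(colSums(F^2))]
    repeat {
      w <- crossprod(E, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_vec <- E %*% w
      q <- crossprod(F, t_vec) / sum(t_vec^2)
      u_new <- F %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-16 * max(sum(u_new^2), 1e-300)) {
        u <- u_new
        break
      }
      u <- u_new
    }
    t_vec <- E %*% w
    p <- crossprod(E, t_vec) / sum(t_vec^2)
    q <- crossprod(F, t_vec) / sum(t_vec^2)
    E <- E - t_vec %*% t(p)
    F <- F - t_vec %*% t(q)
    scores <- cbind(scores, t_vec)
  }
  scores
}

# exhaustive single-linkage clustering oracle: connected components of the
# window-overlap graph
single_linkage_oracle <- function(features, windows) {
  n <- nrow(features)
  hw <- window_halfwidths(features$mz, features$rt, windows)
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(features$mz[i] - features$mz[j]) <= hw$mz_hw[i] + hw$mz_hw[j] &&
          abs(features$rt[i] - features$rt[j]) <= hw$rt_hw[i] + hw$rt_hw[j]) {
        ri <- find(i); rj <- find(j)
        comp[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# mean silhouette width on a score matrix with class labels
silhouette_mean <- function(scores, classes) {
  d <- as.matrix(dist(scores))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    same <- classes == classes[i]
    a <- mean(d[i, same & seq_len(n) != i])
    b <- min(vapply(unique(classes[!same]), function(cl) {
      mean(d[i, classes == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# exact-summary replicates: n = 3 values with a given mean and sd
replicates_from_summary <- function(mean, sd, n = 3) {
  stopifnot(n == 3)
  mean + sd * c(-1, 0, 1)
}
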