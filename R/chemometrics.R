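#' Samples-by-variables matrix from a feature matrix
#'
#' @param fm A `feature_matrix` from [align_features()].
#' @param roles Sample roles to keep (default `"oil"`).
#' @return A numeric matrix (samples in rows, consensus features in columns,
#'   named `f<feature_id>`), with the per-sample species labels attached as
#'   attribute `classes`.
#' @export
as_sample_matrix <- function(fm, roles = "oil") {
  stopifnot(inherits(fm, "feature_matrix"))
  ids <- fm$samples$sample_id[fm$samples$role %in% roles]
  X <- t(fm$abundance[, ids, drop = FALSE])
  colnames(X) <- paste0("f", fm$consensus$feature_id)
  attr(X, "classes") <- fm$samples$species[match(ids, fm$samples$sample_id)]
  X
}

#' Pareto scaling
#'
#' Mean-centers each variable and divides it by the square root of its sample
#' standard deviation, damping the dominance of high-abundance features while
#' keeping some weight on magnitude. Zero-variance variables cannot be scaled
#' and are dropped with a warning.
#'
#' @param x A samples-by-variables numeric matrix, data frame, or
#'   `feature_matrix`.
#' @return An object of class `scaled_matrix`: list with the scaled matrix
#'   `X`, per-variable `centers` and `scales` (sqrt of SD), and the names of
#'   `dropped` variables.
#' @examples
#' pareto_scale(cbind(a = c(1, 2, 3), b = c(0, 0, 4)))$X
#' @export
pareto_scale <- function(x) {
  X <- if (inherits(x, "feature_matrix")) as_sample_matrix(x) else
    as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  centers <- colMeans(X)
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-variance variable(s)",
            call. = FALSE)
  }
  keep <- sds > 0
  scales <- sqrt(sds[keep])
  Xs <- sweep(X[, keep, drop = FALSE], 2, centers[keep], `-`)
  Xs <- sweep(Xs, 2, scales, `/`)
  structure(list(X = Xs, centers = centers[keep], scales = scales,
                 dropped = dropped),
            class = "scaled_matrix")
}

# apply a fitted scaling to new data (columns matched by name; unnamed input
# must already carry all training variables in order)
apply_scaling <- function(scaling, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) < length(scaling$centers)) {
      stop("new data has fewer variables than the training scaling",
           call. = FALSE)
    }
    colnames(X) <- paste0("v", seq_len(ncol(X)))
  }
  miss <- setdiff(names(scaling$centers), colnames(X))
  if (length(miss) > 0) {
    stop("new data lacks variable(s): ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  X <- X[, names(scaling$centers), drop = FALSE]
  sweep(sweep(X, 2, scaling$centers, `-`), 2, scaling$scales, `/`)
}

resolve_xy <- function(x, classes) {
  if (inherits(x, "feature_matrix")) {
    X <- as_sample_matrix(x)
    if (is.null(classes)) classes <- attr(X, "classes")
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  }
  list(X = X, classes = classes)
}

#' Principal component analysis by NIPALS
#'
#' @param x A samples-by-variables matrix or `feature_matrix`.
#' @param n_components Number of components to extract.
#' @param scale `"pareto"` (centering + Pareto scaling, the default) or
#'   `"center"`.
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `pca_model` with orthonormal `loadings`,
#'   orthogonal `scores`, per-component `r2x` and cumulative `r2x_cum`.
#' @export
fit_pca <- function(x, n_components = 2, scale = c("pareto", "center"),
                    tol = 1e-16, max_iter = 5000) {
  scale <- match.arg(scale)
  X <- if (inherits(x, "feature_matrix")) as_sample_matrix(x) else as.matrix(x)
  classes <- attr(X, "classes")
  scaling <- if (scale == "pareto") pareto_scale(X) else {
    ctr <- colMeans(X)
    structure(list(X = sweep(X, 2, ctr, `-`), centers = ctr,
                   scales = rep(1, ncol(X)) %>% setNames(colnames(X)),
                   dropped = character()), class = "scaled_matrix")
  }
  E <- scaling$X
  tss <- sum(E^2)
  n_components <- min(n_components, qr(E)$rank)
  scores <- matrix(0, nrow(E), n_components)
  loadings <- matrix(0, ncol(E), n_components,
                     dimnames = list(colnames(E), NULL))
  r2x <- numeric(n_components)
  for (a in seq_len(n_components)) {
    t_vec <- E[, which.max(apply(E, 2, var))]
    for (it in seq_len(max_iter)) {
      p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
      p <- p / sqrt(sum(p^2))
      t_new <- drop(E %*% p)
      if (sum((t_new - t_vec)^2) < tol * sum(t_new^2)) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    scores[, a] <- t_vec
    loadings[, a] <- p
    r2x[a] <- sum(t_vec^2) / tss
    E <- E - tcrossprod(t_vec, p)
  }
  structure(list(scores = scores, loadings = loadings, r2x = r2x,
                 r2x_cum = cumsum(r2x), scaling = scaling,
                 classes = classes, n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", x$n_components, " components, R2X(cum) = ",
      round(tail(x$r2x_cum, 1), 4), "\n", sep = "")
  invisible(x)
}

# first NIPALS PLS component of (E, F); returns w (unit), t, p, q
pls_component <- function(E, F, tol = 1e-16, max_iter = 2000) {
  u <- F[, which.max(colSums(F^2))]
  w <- NULL
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(E, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t_vec <- drop(E %*% w)
    q <- drop(crossprod(F, t_vec)) / sum(t_vec^2)
    u_new <- drop(F %*% q) / sum(q^2)
    if (sum((u_new - u)^2) < tol * max(sum(u_new^2), 1e-300)) {
      u <- u_new
      break
    }
    u <- u_new
  }
  t_vec <- drop(E %*% w)
  q <- drop(crossprod(F, t_vec)) / sum(t_vec^2)
  p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
  list(w = w, t = t_vec, p = p, q = q)
}

#' Orthogonal PLS discriminant analysis
#'
#' Fits an OPLS-DA model on a class-labelled abundance matrix: class labels
#' are dummy-coded (one 0/1 column per class), the X matrix is centered and
#' Pareto-scaled, structured X-variation orthogonal to the class matrix is
#' stripped by orthogonal signal correction (each orthogonal weight is a PLS
#' loading projected off the X'Y subspace, so orthogonal scores are exactly
#' uncorrelated with every class column), and a NIPALS PLS2 model with
#' `n_predictive` components is fitted on the filtered matrix. Component
#' counts follow the "A+O+0" notation: A predictive plus O X-orthogonal
#' components (Y-orthogonal components are not modelled).
#'
#' Reported statistics: per-component and cumulative `R2X` (both blocks),
#' `R2Y`, the residual class-matrix variance `S2Y`, the root-mean-square
#' error of estimates `SEE = sqrt(RSS / (N - A - O - 1))`, cross-validated
#' `Q2` (venetian-blind folds, scaling re-estimated inside each training
#' fold) and per-variable VIP scores.
#'
#' @param x A samples-by-variables matrix or a `feature_matrix` (oil samples).
#' @param classes Class labels (one per sample); taken from the sample table
#'   when `x` is a `feature_matrix`.
#' @param n_predictive Number of predictive components (default: number of
#'   classes minus one).
#' @param n_orthogonal Number of X-orthogonal components.
#' @param scale `"pareto"` or `"center"`.
#' @param n_folds Cross-validation folds for Q2 (default 7); `NA` skips CV.
#' @return An object of class `opls_da`.
#' @export
fit_oplsda <- function(x, classes = NULL, n_predictive = NULL,
                       n_orthogonal = 0, scale = c("pareto", "center"),
                       n_folds = 7) {
  scale <- match.arg(scale)
  xy <- resolve_xy(x, classes)
  X <- xy$X
  classes <- as.character(xy$classes)
  if (is.null(classes) || length(classes) != nrow(X)) {
    stop("classes must supply one label per sample", call. = FALSE)
  }
  lev <- sort(unique(classes))
  if (length(lev) < 2) {
    stop("OPLS-DA needs at least two classes", call. = FALSE)
  }
  if (is.null(n_predictive)) n_predictive <- length(lev) - 1
  stopifnot(n_predictive >= 1, n_orthogonal >= 0)

  fit <- oplsda_core(X, classes, lev, n_predictive, n_orthogonal, scale)
  q2 <- if (!is.na(n_folds)) {
    cross_validate_q2(X, classes, n_predictive = n_predictive,
                      n_orthogonal = n_orthogonal, n_folds = n_folds,
                      scale = scale)
  } else NA_real_
  fit$q2 <- q2
  fit$call_scale <- scale
  fit$n_folds <- n_folds
  class(fit) <- "opls_da"
  fit
}

# core fit on one training set; X raw (unscaled)
oplsda_core <- function(X, classes, lev, n_predictive, n_orthogonal, scale) {
  Y <- outer(classes, lev, `==`) * 1
  colnames(Y) <- lev
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means, `-`)

  scaling <- if (scale == "pareto") pareto_scale(X) else {
    ctr <- colMeans(X)
    structure(list(X = sweep(X, 2, ctr, `-`), centers = ctr,
                   scales = setNames(rep(1, ncol(X)), colnames(X)),
                   dropped = character()), class = "scaled_matrix")
  }
  X0 <- scaling$X
  tss_x <- sum(X0^2)
  tss_y <- sum(Yc^2)
  rank_x <- qr(X0)$rank
  if (n_predictive + n_orthogonal > rank_x) {
    stop("requested ", n_predictive + n_orthogonal,
         " components but the scaled matrix has rank ", rank_x, call. = FALSE)
  }

  # orthonormal basis of the Y-correlated X subspace
  covXY <- crossprod(X0, Yc)
  sv <- svd(covXY)
  B <- sv$u[, sv$d > max(sv$d) * 1e-12, drop = FALSE]

  E <- X0
  W_o <- matrix(0, ncol(X0), n_orthogonal)
  P_o <- matrix(0, ncol(X0), n_orthogonal)
  T_o <- matrix(0, nrow(X0), n_orthogonal)
  r2x_orth <- numeric(n_orthogonal)
  for (j in seq_len(n_orthogonal)) {
    comp <- pls_component(E, Yc)
    w_o <- comp$p - B %*% crossprod(B, comp$p)
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) {
      stop("no orthogonal variation left for component ", j, call. = FALSE)
    }
    w_o <- drop(w_o) / nrm
    t_o <- drop(E %*% w_o)
    p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    W_o[, j] <- w_o
    P_o[, j] <- p_o
    T_o[, j] <- t_o
    r2x_orth[j] <- sum(tcrossprod(t_o, p_o)^2) / tss_x
  }

  W <- matrix(0, ncol(X0), n_predictive)
  P <- matrix(0, ncol(X0), n_predictive)
  Q <- matrix(0, ncol(Yc), n_predictive)
  T <- matrix(0, nrow(X0), n_predictive)
  r2x_pred <- numeric(n_predictive)
  Fres <- Yc
  for (a in seq_len(n_predictive)) {
    comp <- pls_component(E, Fres)
    W[, a] <- comp$w
    T[, a] <- comp$t
    P[, a] <- comp$p
    Q[, a] <- comp$q
    r2x_pred[a] <- sum(tcrossprod(comp$t, comp$p)^2) / tss_x
    E <- E - tcrossprod(comp$t, comp$p)
    Fres <- Fres - tcrossprod(comp$t, comp$q)
  }

  rss <- sum(Fres^2)
  n <- nrow(X0)
  a_tot <- n_predictive + n_orthogonal
  r2y <- 1 - rss / tss_y
  see <- if (n - a_tot - 1 > 0) sqrt(rss / (n - a_tot - 1)) else NA_real_
  s2y <- rss / ((n - 1) * ncol(Yc))

  # VIP over predictive components; normalised over all variables submitted
  # to the model (variables dropped as zero-variance count as VIP 0), so an
  # informative variable's score does not depend on how many constant columns
  # accompany it in degenerate (e.g. noise-free) data
  ssy_a <- colSums(T^2) * colSums(Q^2)
  v_total <- ncol(X0) + length(scaling$dropped)
  vip <- sqrt(v_total * drop(W^2 %*% ssy_a) / sum(ssy_a))
  names(vip) <- colnames(X0)

  list(levels = lev, classes = classes, y_means = y_means,
       scaling = scaling,
       weights = W, scores = T, loadings = P, y_loadings = Q,
       weights_orth = W_o, scores_orth = T_o, loadings_orth = P_o,
       n_predictive = n_predictive, n_orthogonal = n_orthogonal,
       r2x = r2x_pred, r2x_orth = r2x_orth,
       r2x_cum = sum(r2x_pred) + sum(r2x_orth),
       r2y = r2y, s2y = s2y, see = see, rss = rss, vip = vip,
       tss_x = tss_x, tss_y = tss_y)
}

#' @export
print.opls_da <- function(x, ...) {
  cat("<opls_da> (", x$n_predictive, "+", x$n_orthogonal, "+0), classes: ",
      paste(x$levels, collapse = ", "), "\n",
      "  R2X(cum) = ", round(x$r2x_cum, 4),
      ", R2Y = ", round(x$r2y, 4),
      ", Q2 = ", round(x$q2, 4),
      ", SEE = ", signif(x$see, 4), "\n", sep = "")
  invisible(x)
}

# project new raw data through a fitted model; returns predictive scores and
# predicted class-membership matrix
oplsda_project <- function(fit, newdata) {
  Xs <- apply_scaling(fit$scaling, newdata)
  for (j in seq_len(fit$n_orthogonal)) {
    t_o <- drop(Xs %*% fit$weights_orth[, j])
    Xs <- Xs - tcrossprod(t_o, fit$loadings_orth[, j])
  }
  # T = X W (P'W)^-1
  PW <- crossprod(fit$loadings, fit$weights)
  Tn <- Xs %*% fit$weights %*% solve(PW)
  Yhat <- sweep(tcrossprod(Tn, fit$y_loadings), 2, fit$y_means, `+`)
  colnames(Yhat) <- fit$levels
  list(scores = Tn, y_hat = Yhat)
}

#' @param object A fitted `opls_da` model.
#' @param newdata Samples-by-variables matrix with the training variables.
#' @param ... Unused.
#' @return A tibble with predicted class-membership values per class and the
#'   assigned class (largest predicted membership).
#' @rdname fit_oplsda
#' @export
predict.opls_da <- function(object, newdata, ...) {
  pr <- oplsda_project(object, newdata)
  cls <- object$levels[max.col(pr$y_hat, ties.method = "first")]
  out <- as_tibble(pr$y_hat)
  out$.class <- cls
  out
}

# fit with the orthogonal-component count clamped to what the matrix rank
# supports (degenerate limits, e.g. noise-free simulations, have rank
# n_classes - 1)
oplsda_clamped <- function(X, classes, n_predictive, n_orthogonal, n_folds) {
  sc <- suppressWarnings(pareto_scale(X))
  rank_x <- qr(sc$X)$rank
  n_orth <- max(0L, min(n_orthogonal, rank_x - n_predictive))
  suppressWarnings(
    fit_oplsda(X, classes, n_predictive = n_predictive,
               n_orthogonal = n_orth, n_folds = n_folds))
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Deterministic venetian-blind folds (sample i goes to fold
#' `((i - 1) mod n_folds) + 1`); within each round the model, including
#' centering and scaling, is re-estimated on the training samples only, and
#' the held-out class matrix is predicted. `Q2 = 1 - PRESS / SS` where PRESS
#' accumulates squared prediction errors over folds and SS the squared
#' deviations of the held-out rows from the training class means.
#'
#' @inheritParams fit_oplsda
#' @param n_folds Number of folds; `n_folds = N` gives leave-one-out.
#' @return A single numeric Q2 value.
#' @export
cross_validate_q2 <- function(x, classes = NULL, n_predictive = NULL,
                              n_orthogonal = 0, n_folds = 7,
                              scale = c("pareto", "center")) {
  scale <- match.arg(scale)
  xy <- resolve_xy(x, classes)
  X <- xy$X
  classes <- as.character(xy$classes)
  lev <- sort(unique(classes))
  if (is.null(n_predictive)) n_predictive <- length(lev) - 1
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  fold <- ((seq_len(n) - 1) %% n_folds) + 1
  Y <- outer(classes, lev, `==`) * 1
  press <- 0
  ss <- 0
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(classes[train])) < 2) {
      stop("training fold ", f, " has a single class; use fewer folds",
           call. = FALSE)
    }
    fit <- suppressWarnings(
      oplsda_core(X[train, , drop = FALSE], classes[train], lev,
                  n_predictive, n_orthogonal, scale))
    pr <- oplsda_project(fit, X[test, , drop = FALSE])
    y_train_mean <- colMeans(Y[train, , drop = FALSE])
    press <- press + sum((Y[test, , drop = FALSE] - pr$y_hat)^2)
    ss <- ss + sum(sweep(Y[test, , drop = FALSE], 2, y_train_mean, `-`)^2)
  }
  1 - press / ss
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model under `n_perm` random permutations of the class labels
#' and records the permuted R2Y and cross-validated Q2. The p-value is
#' `(1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)` (and analogously for R2Y),
#' so it is bounded below by `1/(n_perm + 1)`.
#'
#' @inheritParams fit_oplsda
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return An object of class `opls_permutation`: observed statistics, a
#'   tibble of permuted `(r2y, q2)` pairs, and p-values.
#' @export
permutation_test <- function(x, classes = NULL, n_predictive = NULL,
                             n_orthogonal = 0, n_perm = 200, seed = 1,
                             n_folds = 7, scale = c("pareto", "center")) {
  scale <- match.arg(scale)
  xy <- resolve_xy(x, classes)
  X <- xy$X
  classes <- as.character(xy$classes)
  lev <- sort(unique(classes))
  if (is.null(n_predictive)) n_predictive <- length(lev) - 1
  obs_fit <- suppressWarnings(
    oplsda_core(X, classes, lev, n_predictive, n_orthogonal, scale))
  obs_q2 <- cross_validate_q2(X, classes, n_predictive = n_predictive,
                              n_orthogonal = n_orthogonal, n_folds = n_folds,
                              scale = scale)
  perms <- with_seed(seed, {
    purrr::map(seq_len(n_perm), function(i) {
      perm <- sample(classes)
      r2y <- tryCatch(
        suppressWarnings(oplsda_core(X, perm, lev, n_predictive,
                                     n_orthogonal, scale)$r2y),
        error = function(e) NA_real_)
      q2 <- tryCatch(
        cross_validate_q2(X, perm, n_predictive = n_predictive,
                          n_orthogonal = n_orthogonal, n_folds = n_folds,
                          scale = scale),
        error = function(e) NA_real_)
      tibble(permutation = i, r2y = r2y, q2 = q2)
    })
  })
  perms <- bind_rows(perms)
  ok <- !is.na(perms$q2)
  p_q2 <- (1 + sum(perms$q2[ok] >= obs_q2)) / (sum(ok) + 1)
  p_r2y <- (1 + sum(perms$r2y[!is.na(perms$r2y)] >= obs_fit$r2y)) /
    (sum(!is.na(perms$r2y)) + 1)
  structure(list(observed = list(r2y = obs_fit$r2y, q2 = obs_q2),
                 permutations = perms, p_q2 = p_q2, p_r2y = p_r2y,
                 n_perm = n_perm),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat("<opls_permutation> observed Q2 = ", round(x$observed$q2, 4),
      ", p(Q2) = ", signif(x$p_q2, 3),
      ", p(R2Y) = ", signif(x$p_r2y, 3),
      " over ", x$n_perm, " permutations\n", sep = "")
  invisible(x)
}

#' Per-variable contributions of a class
#'
#' Ranks variables by their contribution to the difference between one class
#' and the grand mean, reconstructed through the predictive components of an
#' OPLS-DA model: the class-mean predictive scores are back-projected through
#' the weights, giving each variable's model-explained elevation (positive) or
#' depletion (negative) in the class, in Pareto-scaled units. VIP scores are
#' returned alongside.
#'
#' @param model A fitted `opls_da`.
#' @param class_label Class to profile.
#' @return A tibble (`variable`, `vip`, `contribution`) in descending
#'   contribution order.
#' @export
variable_contributions <- function(model, class_label) {
  stopifnot(inherits(model, "opls_da"))
  if (!class_label %in% model$levels) {
    stop("class '", class_label, "' not in the model", call. = FALSE)
  }
  in_class <- model$classes == class_label
  t_bar <- colMeans(model$scores[in_class, , drop = FALSE])
  contribution <- drop(model$loadings %*% t_bar)
  tibble(variable = names(model$vip),
         vip = unname(model$vip),
         contribution = contribution) %>%
    arrange(desc(contribution))
}
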