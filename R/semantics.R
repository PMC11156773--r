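# Semantic directions in latent space: the unit normal of a linear SVM
# hyperplane separating two cohorts of flattened W+ codes, with k-fold
# cross-validated stability, conditional orthogonalization against nuisance
# directions, and latent editing along a direction.

#' Flatten an extended latent code
#'
#' @param x An L x d matrix, a `projection_result`, or an already-flat
#'   vector.
#' @return Numeric vector of length L*d.
#' @export
flatten_wplus <- function(x) {
  if (inherits(x, "projection_result")) x <- x$wplus
  as.vector(x)
}

latents_to_matrix <- function(latents) {
  if (is.matrix(latents)) return(latents)
  do.call(rbind, lapply(latents, flatten_wplus))
}

svm_normal <- function(X, y, cost) {
  fit <- e1071::svm(x = X, y = factor(y, levels = c("A", "B")),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  # orient from class A toward class B regardless of solver label convention
  mu_a <- colMeans(X[y == "A", , drop = FALSE])
  mu_b <- colMeans(X[y == "B", , drop = FALSE])
  if (sum(w * (mu_b - mu_a)) < 0) { w <- -w; rho <- -rho }
  nrm <- sqrt(sum(w^2))
  list(n = w / nrm, offset = -rho / nrm)
}

#' Fit a semantic latent direction with a linear SVM
#'
#' Trains a linear support vector machine separating two sets of flattened
#' W+ codes and returns the unit normal of the hyperplane, oriented from set
#' A toward set B, together with a k-fold cross-validation report (per-fold
#' hold-out accuracy and the pairwise cosines between fold directions). The
#' released direction comes from the full-data fit.
#'
#' @param latents_A,latents_B Matrices (subjects x L*d) or lists of
#'   `projection_result` / L x d matrices.
#' @param folds Number of cross-validation folds (default 10).
#' @param cost SVM regularization parameter C.
#' @param attribute Name of the attribute the direction encodes (e.g.,
#'   `"MS"`, `"age"`, `"slice_position"`).
#' @return Object of class `semantic_direction` with fields `n` (unit
#'   vector), `attribute`, `hyperplane_offset`, and `cv_report`.
#' @export
fit_direction <- function(latents_A, latents_B, folds = 10L, cost = 1,
                          attribute = "MS") {
  A <- latents_to_matrix(latents_A)
  B <- latents_to_matrix(latents_B)
  if (ncol(A) != ncol(B)) stop("latent sets have different dimensionality")
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 samples per class")
  X <- rbind(A, B)
  y <- c(rep("A", nrow(A)), rep("B", nrow(B)))
  full <- svm_normal(X, y, cost)

  folds <- min(folds, nrow(A), nrow(B))
  fold_dirs <- NULL
  fold_acc <- NULL
  if (folds >= 2) {
    fa <- rep_len(seq_len(folds), nrow(A))
    fb <- rep_len(seq_len(folds), nrow(B))
    fold_of <- c(sample(fa), sample(fb))
    fold_dirs <- matrix(0, folds, ncol(X))
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- svm_normal(X[tr, , drop = FALSE], y[tr], cost)
      fold_dirs[f, ] <- fit$n
      proj <- X[!tr, , drop = FALSE] %*% fit$n - fit$offset
      pred <- ifelse(proj > 0, "B", "A")
      fold_acc[f] <- mean(pred == y[!tr])
    }
  }
  cosines <- if (!is.null(fold_dirs)) fold_dirs %*% t(fold_dirs) else NULL
  structure(list(
    n = full$n, attribute = attribute, hyperplane_offset = full$offset,
    cv_report = list(
      folds = folds,
      accuracy = fold_acc,
      direction_cosines = cosines,
      fold_directions = fold_dirs
    )
  ), class = "semantic_direction")
}

#' @export
print.semantic_direction <- function(x, ...) {
  acc <- if (length(x$cv_report$accuracy)) {
    sprintf(", CV accuracy %.2f", mean(x$cv_report$accuracy))
  } else ""
  cat(sprintf("semantic_direction '%s': length %d%s\n",
              x$attribute, length(x$n), acc))
  invisible(x)
}

direction_vec <- function(d) {
  if (inherits(d, "semantic_direction")) d$n else as.numeric(d)
}

#' Conditional manipulation: orthogonalize one direction against another
#'
#' Removes from `n1` its component along `n2`,
#' \eqn{n_1 - (n_1^T n_2)\, n_2}, so that moving along the result changes
#' the first attribute while leaving the second attribute's latent
#' coordinate unchanged. The result is renormalized to unit length so the
#' scaling factor alpha keeps a consistent scale.
#'
#' @param n1,n2 Unit direction vectors (or `semantic_direction` objects) of
#'   equal length.
#' @return Unit vector exactly orthogonal to `n2`.
#' @export
conditionalize <- function(n1, n2) {
  v1 <- direction_vec(n1); v2 <- direction_vec(n2)
  if (length(v1) != length(v2)) stop("direction length mismatch")
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  r <- v1 - sum(v1 * v2) * v2
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("directions are parallel: conditional direction is degenerate")
  r / nr
}

#' Inner product between two unit directions
#'
#' @param d1,d2 Unit vectors (or `semantic_direction` objects) of equal
#'   length.
#' @return Scalar in \[-1, 1\].
#' @export
direction_similarity <- function(d1, d2) {
  v1 <- direction_vec(d1); v2 <- direction_vec(d2)
  if (length(v1) != length(v2)) stop("direction length mismatch")
  sum(v1 * v2)
}

#' Edit a latent code along a semantic direction
#'
#' Synthesizes the image series \eqn{G_{syn}(w^+ + \alpha n)} over a grid of
#' scaling factors alpha, using fixed noise maps (the projection's optimized
#' maps when `wplus` is a `projection_result`) so that the alpha = 0 entry
#' reproduces the unedited reconstruction exactly. Positive alpha moves
#' toward the B side of the fitted hyperplane.
#'
#' @param model A `generator_model`.
#' @param wplus An L x d latent matrix or a `projection_result`.
#' @param direction A `semantic_direction` (or unit vector of length L*d).
#' @param alpha_grid Strictly increasing scalars containing 0.
#' @param noise Noise maps used for synthesis (`"zero"`, or list of
#'   matrices); ignored when `wplus` is a `projection_result`, whose maps
#'   are used.
#' @return Object of class `manipulation_series`: `alpha_grid`, `images`
#'   (list of arrays), `wplus_series`, `baseline_index`.
#' @export
manipulate_latent <- function(model, wplus, direction, alpha_grid,
                              noise = "zero") {
  if (inherits(wplus, "projection_result")) {
    noise <- wplus$noise_maps
    wplus <- wplus$wplus
  }
  v <- direction_vec(direction)
  if (length(v) != model$L * model$d) {
    stop(sprintf("direction length %d does not match L*d = %d",
                 length(v), model$L * model$d))
  }
  alpha_grid <- as.numeric(alpha_grid)
  if (is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("alpha_grid must be strictly increasing")
  }
  baseline <- which(alpha_grid == 0)
  if (length(baseline) != 1) stop("alpha_grid must contain 0 (the baseline)")
  step <- matrix(v, model$L, model$d)
  images <- vector("list", length(alpha_grid))
  codes <- vector("list", length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    codes[[i]] <- wplus + alpha_grid[i] * step
    images[[i]] <- synthesize(model, codes[[i]], noise)
  }
  structure(list(
    alpha_grid = alpha_grid, images = images, wplus_series = codes,
    baseline_index = baseline
  ), class = "manipulation_series")
}

#' @export
print.manipulation_series <- function(x, ...) {
  cat(sprintf("manipulation_series: %d alphas in [%g, %g]\n",
              length(x$alpha_grid), min(x$alpha_grid), max(x$alpha_grid)))
  invisible(x)
}
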