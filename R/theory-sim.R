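#' Probability that the rule-based labeler agrees with the true label
#'
#' For a binary task with uniformly distributed labels and m independent
#' rules, rule i labeling the document correctly with probability phi_i, the
#' weak-label distribution puts mass proportional to prod(phi_i) on agreement
#' and prod(1 - phi_i) on disagreement. The normalized agreement probability
#' is therefore
#' `prod(phi) / (prod(phi) + prod(1 - phi))`.
#' It is symmetric in the phi's and strictly increasing in each phi_i above
#' 0.5; uninformative rules (all phi = 0.5) give 0.5.
#'
#' @param phi Numeric vector of per-rule correctness probabilities in (0, 1).
#' @return The probability that the weak label equals the true label.
#' @export
agreement_probability <- function(phi) {
  if (length(phi) < 1 || any(!is.finite(phi)) || any(phi <= 0) || any(phi >= 1 + 1e-15))
    stop("phi must be a non-empty vector of probabilities in (0, 1]", call. = FALSE)
  a <- prod(phi)
  b <- prod(1 - phi)
  a / (a + b)
}

#' Sample weak labels from the weak-label distribution
#'
#' Independently per document, the weak label equals the true label with
#' probability [agreement_probability()]`(phi)` and is flipped otherwise.
#'
#' @param true_labels Integer/numeric vector with values in \{+1, -1\}.
#' @param phi Per-rule correctness probabilities.
#' @param seed Integer seed (mandatory; sampling is reproducible).
#' @return Vector of weak labels in \{+1, -1\} of the same length.
#' @export
sample_weak_labels <- function(true_labels, phi, seed) {
  if (!all(true_labels %in% c(-1, 1)))
    stop("true labels must be +1/-1 (the theory is stated for binary tasks)",
         call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  q <- agreement_probability(phi)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  flip <- stats::runif(length(true_labels)) > q
  out <- true_labels
  out[flip] <- -out[flip]
  out
}

logistic_term <- function(s) {
  # log(1 + exp(-s)) computed stably
  ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s)))
}

#' Empirical regularized logistic losses under true and weak labels
#'
#' `true_loss` is the ridge-regularized logistic loss
#' `(1/|D|) sum_d log(1 + exp(-w'f(d) Y_d)) + rho ||w||^2`.
#' `weak_loss` replaces the per-document term by its conditional expectation
#' given the observed weak label Lambda_d, under the weak-label distribution
#' with agreement probability q = [agreement_probability()]`(phi)`:
#' `q log(1 + exp(-w'f(d) Lambda_d)) + (1 - q) log(1 + exp(+w'f(d) Lambda_d))`.
#' The conditional expectation is evaluated in closed form via q (exact under
#' the binary/uniform assumptions) rather than by Monte Carlo.
#'
#' @param features n x d numeric matrix of document features f(d).
#' @param labels Vector in \{+1, -1\}: true labels Y for `true_loss`, weak
#'   labels Lambda for `weak_loss`.
#' @param phi Per-rule correctness probabilities (weak loss only).
#' @param w Weight vector of length d.
#' @param rho Ridge coefficient (> 0).
#' @return The scalar loss.
#' @export
true_loss <- function(features, labels, w, rho) {
  check_loss_args(features, labels, w, rho)
  s <- as.numeric(features %*% w)
  mean(logistic_term(s * labels)) + rho * sum(w^2)
}

#' @rdname true_loss
#' @export
weak_loss <- function(features, labels, phi, w, rho) {
  check_loss_args(features, labels, w, rho)
  q <- agreement_probability(phi)
  s <- as.numeric(features %*% w)
  mean(q * logistic_term(s * labels) + (1 - q) * logistic_term(-s * labels)) +
    rho * sum(w^2)
}

check_loss_args <- function(features, labels, w, rho) {
  if (!is.matrix(features)) stop("`features` must be a matrix", call. = FALSE)
  if (length(labels) != nrow(features)) stop("label/feature length mismatch", call. = FALSE)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(w) != ncol(features)) stop("`w` does not match the feature dimension", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("`rho` must be a positive scalar", call. = FALSE)
  invisible(TRUE)
}

weak_loss_grad <- function(features, labels, q, w, rho) {
  s <- as.numeric(features %*% w)
  sig <- function(x) 1 / (1 + exp(-x))
  # d/ds [q*l(s*L) + (1-q)*l(-s*L)] = L * ((1-q)*sigma(s*L) - q*sigma(-s*L))
  g_s <- labels * ((1 - q) * sig(s * labels) - q * sig(-s * labels))
  as.numeric(crossprod(features, g_s)) / nrow(features) + 2 * rho * w
}

#' Fit w by minimizing the weak loss
#'
#' Deterministic full-batch gradient descent with backtracking line search on
#' the (convex) ridge-regularized weak logistic loss. The loss theory is
#' about the objective, not about any particular optimizer; a deterministic
#' convex solver keeps bound reports reproducible.
#'
#' @inheritParams true_loss
#' @param phi Per-rule correctness probabilities.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Iteration cap.
#' @return A list with `w`, `loss`, `converged`, `iterations`.
#' @export
fit_weak_logistic <- function(features, labels, phi, rho,
                              tol = 1e-8, max_iter = 1e4) {
  q <- agreement_probability(phi)
  w <- numeric(ncol(features))
  f <- weak_loss(features, labels, phi, w, rho)
  step <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- weak_loss_grad(features, labels, q, w, rho)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    # backtracking (Armijo)
    step <- min(step * 2, 1e3)
    repeat {
      w_new <- w - step * g
      f_new <- weak_loss(features, labels, phi, w_new, rho)
      if (f_new <= f - 0.5 * step * sum(g^2) || step < 1e-14) break
      step <- step / 2
    }
    if (step < 1e-14) break
    w <- w_new; f <- f_new
  }
  list(w = w, loss = f, converged = converged, iterations = it)
}

#' Empirically verify the weak-supervision loss bound
#'
#' For each grid cell (a data size |D|, a rule-accuracy profile phi, a ridge
#' coefficient rho) and each replicate, the simulator:
#'
#' 1. draws synthetic document features f(d) (isotropic Gaussian,
#'    L2-normalized so that every ||f(d)|| <= 1);
#' 2. derives the weak labels Lambda deterministically from the features
#'    (Lambda = sign(w0'f), playing the role of a rule-based labeler reading
#'    the document) and then draws the true labels Y by flipping Lambda with
#'    probability 1 - q — the generative model under which the weak loss's
#'    conditional expectation over Y given Lambda is exact;
#' 3. fits w by minimizing the weak loss (the fit never sees Y);
#' 4. evaluates both empirical losses at the fitted w and reports the gap
#'    |L - L_phi|, the parameter estimate error eps = |D|^(-1/2), the implied
#'    constant c-hat = 2 |L - L_phi| / (||w|| eps), and whether
#'    ||w|| <= 1/(2 rho) holds.
#'
#' Feature normalization to ||f|| <= 1 makes the norm condition a theorem at
#' any stationary point of the regularized weak loss (the stationarity
#' identity gives 2 rho ||w|| <= mean ||f||).
#'
#' @param sizes Integer vector of data sizes |D|.
#' @param phi Rule-accuracy profile (shared across the grid).
#' @param rho Ridge coefficient.
#' @param n_rep Replicates per grid cell.
#' @param seed Integer seed for all randomness.
#' @param dim Feature dimension of the synthetic documents.
#' @return A tibble of class `weaktext_bound` with one row per (size, rep):
#'   columns `size`, `rep`, `eps`, `gap` (|L - L_phi|), `w_norm`, `c_hat`,
#'   `norm_bound_ok`, `converged`.
#' @export
verify_bound <- function(sizes = c(400, 1600, 6400), phi = 0.9, rho = 0.1,
                         n_rep = 20, seed = 1, dim = 10) {
  if (length(sizes) < 1) stop("the size grid must be non-empty", call. = FALSE)
  q <- agreement_probability(phi)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rows <- list()
  for (n in sizes) {
    for (r in seq_len(n_rep)) {
      x <- matrix(stats::rnorm(n * dim), nrow = n)
      x <- x / pmax(sqrt(rowSums(x^2)), 1)     # ||f(d)|| <= 1
      w0 <- stats::rnorm(dim)
      lambda <- ifelse(as.numeric(x %*% w0) >= 0, 1, -1)
      flip <- stats::runif(n) > q
      y <- lambda
      y[flip] <- -y[flip]
      fit <- fit_weak_logistic(x, lambda, phi, rho)
      gap <- abs(true_loss(x, y, fit$w, rho) -
                   weak_loss(x, lambda, phi, fit$w, rho))
      wn <- sqrt(sum(fit$w^2))
      eps <- 1 / sqrt(n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size = n, rep = r, eps = eps, gap = gap, w_norm = wn,
        c_hat = if (wn > 0) 2 * gap / (wn * eps) else 0,
        norm_bound_ok = wn <= 1 / (2 * rho) + 1e-6,
        converged = fit$converged)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weaktext_bound", class(out))
  attr(out, "phi") <- phi
  attr(out, "rho") <- rho
  out
}
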