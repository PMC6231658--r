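# Numeric confirmation of detected correlations. A totally correlated set
# phi spans a null direction v of the sensitivity matrix: perturbing the
# unknowns along v changes the measured outputs only at second order in the
# step size, whereas a direction orthogonal to the null space changes them
# at first order. Checking both slopes numerically replaces a symbolic
# null-space verification.

#' First-order output invariance along a null direction
#'
#' Perturbs the parameter point by `eps * ||point|| * w`, where `w` is the
#' record's unit null direction mapped back to unnormalized coordinates
#' (entry-wise multiplication by the parameter values when the sensitivity
#' matrix was normalized: the normalized matrix is the raw matrix with
#' columns scaled by theta_j and rows by 1/y_i, so `S v = 0` in normalized
#' coordinates corresponds to the raw direction `theta * v`). The change in
#' the measured outputs (those not in the record's psi) is computed over the
#' grid for each step size, together with the change along a control
#' direction orthogonal to the null space. Order-of-magnitude slopes are
#' estimated by log-log regression: the null direction should scale at least
#' quadratically (or vanish to integration accuracy for exact symmetries),
#' the control direction linearly.
#'
#' @param model A `mosid_model`.
#' @param point Parameter point at which the record was produced.
#' @param record A `mosid_record` (from [sweep_omissions()] /
#'   [find_minimal_output_sets()]), or a list with fields `psi` and
#'   `null_basis`.
#' @param eps Relative step sizes (default `c(1e-3, 1e-4, 1e-5)`).
#' @param grid Time grid (default [time_grid()]).
#' @param normalized Was the null basis computed from a normalized matrix
#'   (default TRUE, matching the pipeline default)?
#' @param control_seed Seed for the random control direction.
#' @return A `mosid_verification`: data frame `changes` (columns `eps`,
#'   `null_change`, `control_change`, relative Frobenius norms; NA where the
#'   perturbed integration failed), `null_slope`, `control_slope`,
#'   `exact` (TRUE when the null-direction change is at integration noise
#'   level for all steps), and the inputs.
#' @export
null_direction_invariance <- function(model, point, record,
                                      eps = c(1e-3, 1e-4, 1e-5),
                                      grid = NULL, normalized = TRUE,
                                      control_seed = 1L) {
  stopifnot(length(record$psi) >= 0, !is.null(record$null_basis))
  if (is.null(grid)) grid <- time_grid(model)
  nms <- unknown_names(model)
  P <- length(nms)
  basis <- record$null_basis
  if (is.null(dim(basis))) basis <- matrix(basis, ncol = 1)
  stopifnot(nrow(basis) == P)

  # map all null vectors back to raw parameter coordinates
  raw_basis <- if (normalized) basis * as.numeric(point) else basis
  raw_basis <- apply(raw_basis, 2, function(v) v / sqrt(sum(v^2)))
  if (is.null(dim(raw_basis))) raw_basis <- matrix(raw_basis, ncol = 1)
  w <- raw_basis[, 1]

  # control direction: random, orthogonalized against the whole null basis
  ctrl <- with_seed(control_seed, {
    cv <- runif(P, -1, 1)
    for (j in seq_len(ncol(raw_basis)))
      cv <- cv - sum(cv * raw_basis[, j]) * raw_basis[, j]
    cv / sqrt(sum(cv^2))
  })

  measured <- setdiff(output_labels(model), record$psi)
  if (length(measured) == 0L)
    stop("record omits every output; the invariance check is vacuous with nothing measured",
         call. = FALSE)
  base <- simulate_model(model, point, grid)
  Y0 <- base$outputs[, measured, drop = FALSE]
  scale0 <- sqrt(sum(Y0^2))
  if (scale0 == 0) scale0 <- 1
  pnorm0 <- sqrt(sum(point^2))

  change_at <- function(direction, e) {
    pt <- point + e * pnorm0 * direction
    names(pt) <- nms
    out <- tryCatch(simulate_model(model, pt, grid), error = function(err) NULL)
    if (is.null(out)) return(NA_real_)
    sqrt(sum((out$outputs[, measured, drop = FALSE] - Y0)^2)) / scale0
  }

  changes <- data.frame(
    eps = eps,
    null_change = vapply(eps, function(e) change_at(w, e), 0),
    control_change = vapply(eps, function(e) change_at(ctrl, e), 0)
  )

  loglog_slope <- function(x, y) {
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(log10(y[ok]) ~ log10(x[ok])))[2])
  }
  noise_floor <- 1e-8
  exact <- all(is.finite(changes$null_change)) &&
    all(changes$null_change < noise_floor)
  structure(list(
    changes = changes,
    null_slope = loglog_slope(changes$eps, changes$null_change),
    control_slope = loglog_slope(changes$eps, changes$control_change),
    exact = exact,
    record = record, point = point, direction = w, control = ctrl
  ), class = "mosid_verification")
}

#' @export
print.mosid_verification <- function(x, ...) {
  cat("<mosid_verification>\n")
  print(x$changes, row.names = FALSE)
  cat(sprintf("  null slope: %s%s | control slope: %s\n",
              format(x$null_slope, digits = 3),
              if (x$exact) " (exact to integration accuracy)" else "",
              format(x$control_slope, digits = 3)))
  invisible(x)
}

#' Verdict stability across random regular points
#'
#' Repeats the identifiability test at `n_points` independently drawn regular
#' points; the analysis is consistent when every point yields the same
#' verdict, the same number of vanishing singular values, and the same
#' correlated support. Disagreement flags a suspected non-generic point.
#'
#' @inheritParams test_identifiability
#' @param n_points Number of points (>= 2).
#' @return List with `consistent` (logical), `verdicts`, `n_vanishing`,
#'   `supports`, and `points`.
#' @export
multipoint_consistency <- function(model, active_outputs = output_labels(model),
                                   n_points = 3L, seed = 1L, grid = NULL,
                                   gap_decades = 3, tau = 1e-3,
                                   normalize = TRUE) {
  stopifnot(n_points >= 2L)
  points <- draw_nominal_point(model, seed, n_points)
  sys <- assemble_extended_system(model)
  verdicts <- character(n_points)
  nvan <- integer(n_points)
  supports <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    traj <- simulate_sensitivities(sys, points[[i]], grid)
    S <- build_sensitivity_matrix(traj, model, active_outputs, normalize = normalize)
    sig <- detect_rank_gap(singular_spectrum(S), gap_decades)
    verdicts[i] <- sig$verdict
    nvan[i] <- length(sig$vanishing_indices)
    supports[[i]] <- if (sig$verdict == "unidentifiable")
      sort(correlated_support(sig, tau)$support) else character(0)
  }
  consistent <- length(unique(verdicts)) == 1L &&
    length(unique(nvan)) == 1L &&
    all(vapply(supports, identical, TRUE, supports[[1]]))
  list(consistent = consistent, verdicts = verdicts, n_vanishing = nvan,
       supports = supports, points = points)
}
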