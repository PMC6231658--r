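# The identifiability signature: singular spectrum of the sensitivity
# matrix, the rank verdict from the spectral gap, and the correlated
# parameter support read off the near-null right singular vectors.

#' Singular spectrum of a sensitivity matrix
#'
#' Computes the full SVD `S = U diag(sigma) V^T`. When the matrix has fewer
#' rows than columns it is padded with zero rows first so that all `P` right
#' singular vectors (and the implied exact zero singular values) are
#' returned.
#'
#' @param S A `mosid_sensmat` or a plain numeric matrix.
#' @param column_labels Optional column labels when `S` is a plain matrix.
#' @return A `mosid_signature` with fields `singular_values` (descending),
#'   `right_vectors` (P x P orthonormal columns), `left_vectors`,
#'   `column_labels`, and rank fields left unset until [detect_rank_gap()].
#' @export
singular_spectrum <- function(S, column_labels = NULL) {
  if (inherits(S, "mosid_sensmat")) {
    column_labels <- S$column_labels
    S <- S$entries
  }
  stopifnot(is.matrix(S))
  if (!all(is.finite(S))) stop("sensitivity matrix has non-finite entries", call. = FALSE)
  P <- ncol(S)
  if (nrow(S) < P) S <- rbind(S, matrix(0, P - nrow(S), P))
  dec <- tryCatch(svd(S), error = function(e)
    stop("SVD did not converge: ", conditionMessage(e), call. = FALSE))
  structure(list(
    singular_values = dec$d,
    right_vectors = dec$v,
    left_vectors = dec$u,
    column_labels = column_labels %||% colnames(S) %||% sprintf("p%d", seq_len(P)),
    rank_q = NA_integer_, vanishing_indices = integer(0),
    gap_decades = NA_real_, gap_threshold = NA_real_,
    verdict = NA_character_
  ), class = "mosid_signature")
}

#' Detect the rank gap in a singular spectrum
#'
#' Scans consecutive ratios `sigma_i / sigma_(i+1)` of the ordered spectrum;
#' the first ratio of at least `10^gap_decades` marks the gap and every later
#' singular value is declared vanishing (numerically zero). Exact zeros are
#' always vanishing. With no qualifying ratio the matrix is full rank and the
#' model (for the measured output set) is structurally identifiable.
#'
#' @param signature A `mosid_signature` from [singular_spectrum()].
#' @param gap_decades Gap size on the log10 scale counted as significant
#'   (default 3).
#' @return The signature with `rank_q`, `vanishing_indices`, `gap_decades`
#'   (the log10 ratio at the detected gap, `NA` if none) and `verdict`
#'   (`"identifiable"` or `"unidentifiable"`) filled in.
#' @export
detect_rank_gap <- function(signature, gap_decades = 3) {
  stopifnot(inherits(signature, "mosid_signature"))
  sv <- signature$singular_values
  P <- length(sv)
  thr <- 10^gap_decades
  gap_at <- NA_integer_
  if (P >= 1L && sv[1] == 0) {
    vanish <- seq_len(P)
  } else {
    vanish <- integer(0)
    for (i in seq_len(max(P - 1L, 0L))) {
      ratio <- if (sv[i + 1] == 0) Inf else sv[i] / sv[i + 1]
      if (ratio >= thr) { gap_at <- i; break }
    }
    if (!is.na(gap_at)) vanish <- (gap_at + 1L):P
  }
  signature$vanishing_indices <- vanish
  signature$rank_q <- P - length(vanish)
  signature$gap_threshold <- gap_decades
  signature$gap_decades <- if (!is.na(gap_at)) {
    if (sv[gap_at + 1] == 0) Inf else log10(sv[gap_at] / sv[gap_at + 1])
  } else if (length(vanish) == length(sv) && length(sv) > 0) Inf else NA_real_
  signature$verdict <- if (length(vanish)) "unidentifiable" else "identifiable"
  signature
}

#' @export
print.mosid_signature <- function(x, ...) {
  sv <- x$singular_values
  cat(sprintf("<mosid_signature> P = %d", length(sv)))
  if (!is.na(x$rank_q)) cat(sprintf(", rank %d, verdict %s", x$rank_q, x$verdict))
  cat("\n  singular values: ", paste(format(head(sv, 6), digits = 3), collapse = " "),
      if (length(sv) > 6) "..." else "", "\n")
  if (length(x$vanishing_indices))
    cat("  vanishing indices:", paste(x$vanishing_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Correlated parameter support from the near-null right singular vectors
#'
#' For an unidentifiable signature, reads the union, over the right singular
#' vectors attached to vanishing singular values, of the entries whose
#' magnitude exceeds `tau` times the largest magnitude in that vector. These
#' entries name the parameters and unknown initial conditions that are
#' totally correlated given the measured outputs.
#'
#' @param signature A `mosid_signature` after [detect_rank_gap()].
#' @param tau Relative support threshold (default 1e-3).
#' @return List with `support` (character vector of unknown names, in column
#'   order) and `basis` (the vanishing columns of V, a P x k matrix).
#' @export
correlated_support <- function(signature, tau = 1e-3) {
  stopifnot(inherits(signature, "mosid_signature"))
  if (is.na(signature$verdict))
    stop("run detect_rank_gap() before correlated_support()", call. = FALSE)
  if (signature$verdict == "identifiable")
    stop("signature is identifiable: there is no null space to read", call. = FALSE)
  V <- signature$right_vectors
  idx <- signature$vanishing_indices
  basis <- V[, idx, drop = FALSE]
  rownames(basis) <- signature$column_labels
  in_support <- rep(FALSE, nrow(basis))
  for (k in seq_len(ncol(basis))) {
    col <- abs(basis[, k])
    in_support <- in_support | (col > tau * max(col))
  }
  list(support = signature$column_labels[in_support], basis = basis)
}

#' Structural identifiability test for a choice of measured outputs
#'
#' Runs the full pipeline - forward sensitivity integration, (normalized)
#' sensitivity matrix, SVD, gap detection, support reading - at one or more
#' regular parameter points. The verdict is accepted only when all points
#' agree; disagreement marks a suspected non-generic point and is flagged.
#'
#' @param model A `mosid_model`.
#' @param active_outputs Sensor labels to measure (default: all).
#' @param points List of parameter points (see [draw_nominal_point()]); by
#'   default `n_points` points drawn with `seed`.
#' @param grid Time grid (default [time_grid()]).
#' @param gap_decades,tau,normalize,rtol,atol Pipeline settings, see
#'   [detect_rank_gap()], [correlated_support()],
#'   [build_sensitivity_matrix()] and [simulate_sensitivities()].
#' @param n_points,seed Used only when `points` is NULL.
#' @return A `mosid_idtest`: list with `verdict` (`"identifiable"`,
#'   `"unidentifiable"` or `"inconsistent"`), `consistent`, `signatures`
#'   (one per point), `support`, `null_basis`, `points`, `active_outputs`.
#' @export
test_identifiability <- function(model, active_outputs = output_labels(model),
                                 points = NULL, grid = NULL,
                                 gap_decades = 3, tau = 1e-3, normalize = TRUE,
                                 rtol = 1e-10, atol = 1e-12,
                                 n_points = 2L, seed = 1L) {
  if (is.null(points)) points <- draw_nominal_point(model, seed, n_points)
  if (!is.list(points)) points <- list(points)
  sys <- assemble_extended_system(model)
  sigs <- vector("list", length(points))
  supports <- vector("list", length(points))
  bases <- vector("list", length(points))
  for (i in seq_along(points)) {
    traj <- simulate_sensitivities(sys, points[[i]], grid, rtol = rtol, atol = atol)
    S <- build_sensitivity_matrix(traj, model, active_outputs, normalize = normalize)
    sig <- detect_rank_gap(singular_spectrum(S), gap_decades)
    sigs[[i]] <- sig
    if (sig$verdict == "unidentifiable") {
      cs <- correlated_support(sig, tau)
      supports[[i]] <- cs$support; bases[[i]] <- cs$basis
    } else {
      supports[[i]] <- character(0)
    }
  }
  verdicts <- vapply(sigs, function(s) s$verdict, "")
  consistent <- length(unique(verdicts)) == 1L
  verdict <- if (consistent) verdicts[1] else "inconsistent"
  structure(list(
    verdict = verdict, consistent = consistent,
    signatures = sigs, support = supports[[1]],
    supports = supports, null_basis = bases[[1]],
    points = points, active_outputs = active_outputs,
    normalized = normalize,
    options = list(gap_decades = gap_decades, tau = tau, normalize = normalize,
                   rtol = rtol, atol = atol)
  ), class = "mosid_idtest")
}

#' @export
print.mosid_idtest <- function(x, ...) {
  cat(sprintf("<mosid_idtest> verdict: %s (outputs: %s)\n",
              x$verdict, paste(x$active_outputs, collapse = ", ")))
  if (length(x$support))
    cat("  correlated support:", paste(x$support, collapse = ", "), "\n")
  invisible(x)
}

#' Export a signature's data (ordered singular values and null-vector
#' entries) to CSV or JSON
#' @param signature A `mosid_signature` after [detect_rank_gap()].
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return The exported list, invisibly.
#' @export
export_signature <- function(signature, path) {
  idx <- signature$vanishing_indices
  out <- list(
    singular_values = signature$singular_values,
    rank_q = signature$rank_q,
    vanishing_indices = idx,
    column_labels = signature$column_labels,
    vanishing_columns = if (length(idx))
      unclass(as.data.frame(signature$right_vectors[, idx, drop = FALSE])) else list()
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    sv <- data.frame(index = seq_along(out$singular_values),
                     singular_value = out$singular_values,
                     vanishing = seq_along(out$singular_values) %in% idx)
    utils::write.csv(sv, path, row.names = FALSE)
  }
  invisible(out)
}

#' Plot a singular spectrum (identifiability signature)
#' @param x A `mosid_signature`.
#' @param ... Passed to `plot()`.
#' @export
plot.mosid_signature <- function(x, ...) {
  sv <- pmax(x$singular_values, .Machine$double.xmin)
  graphics::plot(seq_along(sv), sv, log = "y", pch = 19,
                 xlab = "index", ylab = "singular value", ...)
  if (length(x$vanishing_indices))
    graphics::points(x$vanishing_indices, sv[x$vanishing_indices],
                     pch = 19, col = "red")
  invisible(x)
}
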