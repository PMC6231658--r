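# Minimal output set search: iterative k-sensor omission with branch
# bookkeeping, realized as minimal-hitting-set enumeration over the family
# of omitted-sensor sets (psi), plus re-verification of every candidate.
#
# The state sensitivities dx/dtheta do not depend on which outputs are
# measured, so the search integrates the variational system once per
# parameter point and evaluates every output subset by selecting rows of the
# full stacked sensitivity matrix. Row-wise normalization commutes with row
# selection, so the subset matrix equals the matrix that would have been
# built from scratch for that subset.

#' Create the search context / state for a sensor-omission search
#'
#' Simulates the forward sensitivities at each parameter point and builds the
#' full-output (normalized) sensitivity matrices that all subset tests reuse.
#'
#' @inheritParams test_identifiability
#' @return A `mosid_search_state` holding `y_max`, the per-point matrices,
#'   accumulated `records`, and the option set.
#' @export
new_search_state <- function(model, points = NULL, grid = NULL,
                             gap_decades = 3, tau = 1e-3, normalize = TRUE,
                             rtol = 1e-10, atol = 1e-12,
                             n_points = 2L, seed = 1L) {
  if (is.null(points)) points <- draw_nominal_point(model, seed, n_points)
  if (!is.list(points)) points <- list(points)
  if (is.null(grid)) grid <- time_grid(model)
  sys <- assemble_extended_system(model)
  mats <- lapply(points, function(pt) {
    traj <- simulate_sensitivities(sys, pt, grid, rtol = rtol, atol = atol)
    build_sensitivity_matrix(traj, model, normalize = normalize)
  })
  structure(list(
    model = model, y_max = output_labels(model),
    points = points, grid = grid, mats = mats,
    records = list(), log = character(),
    n_tests = 0L,
    options = list(gap_decades = gap_decades, tau = tau, normalize = normalize,
                   rtol = rtol, atol = atol, seed = seed)
  ), class = "mosid_search_state")
}

# Rank-test a measured output subset against all points in the state.
# Returns verdict ("identifiable"/"unidentifiable"/"inconsistent") plus the
# support/basis from the first point. An empty measured set is unidentifiable
# by convention (nothing constrains the unknowns).
.subset_test <- function(state, measured) {
  model <- state$model
  if (length(measured) == 0L) {
    P <- n_unknowns(model)
    return(list(verdict = "unidentifiable",
                support = unknown_names(model),
                basis = diag(P), signature = NULL))
  }
  verdicts <- character(length(state$mats))
  supports <- list(); basis <- NULL; sig1 <- NULL
  for (i in seq_along(state$mats)) {
    Sm <- state$mats[[i]]
    keep <- Sm$row_labels$output %in% measured
    sig <- singular_spectrum(Sm$entries[keep, , drop = FALSE], Sm$column_labels)
    sig <- detect_rank_gap(sig, state$options$gap_decades)
    verdicts[i] <- sig$verdict
    if (sig$verdict == "unidentifiable") {
      cs <- correlated_support(sig, state$options$tau)
      supports[[i]] <- cs$support
      if (i == 1L) basis <- cs$basis
    } else supports[[i]] <- character(0)
    if (i == 1L) sig1 <- sig
  }
  verdict <- if (length(unique(verdicts)) == 1L) verdicts[1] else "inconsistent"
  support <- if (verdict == "unidentifiable") Reduce(union, supports) else character(0)
  list(verdict = verdict, support = support, basis = basis, signature = sig1)
}

# Branch pools: one mandatory pick from each non-singleton psi recorded so
# far, plus every singleton psi sensor. Each branch's candidate pool is
# y_max minus its mandatory set; by construction no recorded psi fits inside
# a pool, which is exactly the paper's branching bookkeeping.
.branch_pools <- function(state) {
  psis <- lapply(state$records, `[[`, "psi")
  singletons <- unique(unlist(psis[lengths(psis) == 1L]))
  multis <- psis[lengths(psis) > 1L]
  if (length(multis) == 0L) {
    return(list(setdiff(state$y_max, singletons)))
  }
  picks <- expand.grid(multis, stringsAsFactors = FALSE)
  pools <- list()
  for (r in seq_len(nrow(picks))) {
    mandatory <- union(singletons, unique(unlist(picks[r, ])))
    pools[[length(pools) + 1L]] <- setdiff(state$y_max, mandatory)
  }
  unique(pools)
}

#' Sweep all k-sensor omissions
#'
#' For each branch pool, omits every k-subset (or a Bernoulli sample when the
#' pool is large, see [bernoulli_subsets()]) while always measuring the
#' branch's mandatory sensors, and records each unidentifiable outcome as a
#' (phi, psi) pair: phi the correlated unknowns read from the null space,
#' psi the omitted sensors. Records are deduplicated by psi, and a psi that
#' contains an already recorded psi is skipped (its constraint is implied).
#'
#' @param state A `mosid_search_state`.
#' @param k Number of sensors to omit at a time (>= 1).
#' @param bernoulli Use Bernoulli sampling for pools whose subset count
#'   exceeds `exhaustive_threshold`.
#' @param exhaustive_threshold Maximum per-branch subset count enumerated
#'   exhaustively (default 5000).
#' @param target_prob Detection probability target for the Bernoulli design.
#' @return The updated state; new records are in `state$records`.
#' @export
sweep_omissions <- function(state, k, bernoulli = TRUE,
                            exhaustive_threshold = 5000, target_prob = 0.995) {
  stopifnot(inherits(state, "mosid_search_state"), k >= 1)
  y_max <- state$y_max
  tested <- character(0)
  found <- 0L
  psi_known <- function() lapply(state$records, `[[`, "psi")
  for (pool in .branch_pools(state)) {
    if (length(pool) < k) next
    n_sub <- choose(length(pool), k)
    use_bern <- bernoulli && n_sub > exhaustive_threshold
    omit_sets <- if (use_bern) {
      meas <- bernoulli_subsets(pool, k, mandatory = setdiff(y_max, pool),
                                detection_prob = target_prob,
                                seed = state$options$seed + 1000L * k,
                                exhaustive_threshold = exhaustive_threshold)
      lapply(meas, function(ms) setdiff(y_max, ms))
    } else {
      apply(combn(pool, k), 2, identity, simplify = FALSE)
    }
    for (omit in omit_sets) {
      if (length(omit) == 0L) next
      key <- paste(sort(omit), collapse = "|")
      if (key %in% tested) next
      tested <- c(tested, key)
      if (any(vapply(psi_known(), function(ps) all(ps %in% omit), TRUE))) next
      res <- .subset_test(state, setdiff(y_max, omit))
      state$n_tests <- state$n_tests + 1L
      if (res$verdict == "unidentifiable") {
        rec <- structure(list(
          phi = res$support, psi = sort_by_ymax(omit, y_max),
          k = length(omit), null_basis = res$basis,
          signature = res$signature,
          source = if (use_bern) "bernoulli" else "exhaustive"
        ), class = "mosid_record")
        state$records[[length(state$records) + 1L]] <- rec
        found <- found + 1L
        state$log <- c(state$log, sprintf(
          "k=%d: psi={%s} -> phi={%s} [%s]", length(omit),
          paste(rec$psi, collapse = ","), paste(rec$phi, collapse = ","), rec$source))
      } else if (res$verdict == "inconsistent") {
        state$log <- c(state$log, sprintf(
          "k=%d: omission {%s} gave inconsistent verdicts across points (non-generic point suspected)",
          k, paste(omit, collapse = ",")))
      }
    }
  }
  state$log <- c(state$log, sprintf("sweep k=%d: %d new record(s), %d subset test(s) so far",
                                    k, found, state$n_tests))
  state
}

sort_by_ymax <- function(x, y_max) x[order(match(x, y_max))]

#' Bernoulli-sampled output subsets for large sensor pools
#'
#' When exhaustively omitting k-subsets of a large pool is infeasible, each
#' trial excludes every pool sensor independently with probability
#' `q = k / |pool|` and measures the rest (always including the mandatory
#' sensors). The number of trials R is the smallest integer with
#' `1 - (1 - p_hit)^R >= detection_prob`, where
#' `p_hit = q^k (1-q)^(|pool|-k)` is the probability that one trial excludes
#' exactly a fixed k-subset, so any particular unidentifiable omission set is
#' detected with at least the target probability. When the pool admits no
#' more than `exhaustive_threshold` k-subsets the function falls back to
#' exhaustive enumeration (documented fallback, not an error).
#'
#' @param pool Candidate sensors eligible for omission.
#' @param k Intended omission size.
#' @param mandatory Sensors included in every emitted subset.
#' @param detection_prob Target detection probability (default 0.995).
#' @param seed Integer seed; trials are deterministic given the seed.
#' @param exhaustive_threshold Subset count at or below which enumeration is
#'   exhaustive.
#' @return List of measured output subsets (each contains all of
#'   `mandatory`), with attribute `source` = `"bernoulli"` or
#'   `"exhaustive"` and, for Bernoulli, attribute `trials` = R.
#' @export
bernoulli_subsets <- function(pool, k, mandatory = character(),
                              detection_prob = 0.995, seed = 1L,
                              exhaustive_threshold = 5000) {
  stopifnot(k >= 1, k <= length(pool))
  n_sub <- choose(length(pool), k)
  if (n_sub <= exhaustive_threshold) {
    subsets <- apply(combn(pool, k), 2, function(omit)
      c(mandatory, setdiff(pool, omit)), simplify = FALSE)
    return(structure(subsets, source = "exhaustive"))
  }
  q <- k / length(pool)
  p_hit <- q^k * (1 - q)^(length(pool) - k)
  R <- ceiling(log(1 - detection_prob) / log(1 - p_hit))
  subsets <- with_seed(seed, lapply(seq_len(R), function(r) {
    excl <- pool[runif(length(pool)) < q]
    c(mandatory, setdiff(pool, excl))
  }))
  structure(subsets, source = "bernoulli", trials = R)
}

#' Enumerate all minimal hitting sets of a family of sensor sets
#'
#' A hitting set intersects every member of the family; the inclusion-minimal
#' ones are exactly the candidate minimal output sets implied by the omitted
#' sensor family psi: at least one sensor of every psi must be measured.
#' Enumeration is exact (branch on the elements of an unhit set) and the
#' result is deduplicated, filtered to inclusion-minimal sets, and ordered
#' lexicographically by position in `y_max`.
#'
#' @param psi_family List of nonempty character vectors (subsets of `y_max`).
#' @param y_max Full ordered sensor list.
#' @return List of character vectors. An empty family yields the single
#'   empty set.
#' @export
minimal_hitting_sets <- function(psi_family, y_max) {
  if (length(psi_family) == 0L) return(list(character(0)))
  stopifnot(all(lengths(psi_family) > 0L),
            all(unlist(psi_family) %in% y_max))
  fam <- lapply(psi_family, function(s) sort(unique(match(s, y_max))))

  results <- list()
  recurse <- function(chosen, remaining) {
    if (length(remaining) == 0L) {
      results[[length(results) + 1L]] <<- chosen
      return(invisible())
    }
    target <- remaining[[1]]
    for (e in target) {
      # avoid building the same set along permuted branches: only extend with
      # elements; dedupe happens at the end
      hit <- vapply(remaining, function(s) e %in% s, TRUE)
      recurse(c(chosen, e), remaining[!hit])
    }
  }
  recurse(integer(0), fam)

  sets <- unique(lapply(results, function(s) sort(unique(s))))
  minimal <- sets[vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j)
      j != i && all(sets[[j]] %in% sets[[i]]) && length(sets[[j]]) < length(sets[[i]]),
      TRUE))
  }, TRUE)]
  keys <- vapply(minimal, function(s) paste(sprintf("%06d", s), collapse = ","), "")
  minimal <- minimal[order(keys)]
  lapply(minimal, function(s) y_max[s])
}

#' Early-stop check: do the current candidates already identify the model?
#'
#' Tests each candidate output set (typically the minimal hitting sets of the
#' psi family accumulated so far) by measuring only that set. If every
#' candidate is identifiable, the search can stop and the candidates are the
#' minimal output sets; any unidentifiable candidate shows that further
#' correlations remain and the sweep must continue at larger k.
#'
#' @param state A `mosid_search_state`.
#' @param candidate_sets List of output label vectors.
#' @return Data frame with one row per candidate: `candidate` (comma-joined
#'   labels) and `verdict`.
#' @export
early_stop_check <- function(state, candidate_sets) {
  stopifnot(inherits(state, "mosid_search_state"))
  verdicts <- vapply(candidate_sets, function(cs) .subset_test(state, cs)$verdict, "")
  data.frame(candidate = vapply(candidate_sets, paste, "", collapse = ","),
             verdict = verdicts)
}

#' Find all minimal output sets of a model
#'
#' Implements the iterative sensor-omission search: starting from the full
#' sensor set `y_max` (which must make the model identifiable - otherwise no
#' output set can), sensors are omitted k-at-a-time for k = 1, 2, ...,
#' `max_k`; every omission that destroys identifiability is recorded as a
#' (phi, psi) pair, and after each level the minimal hitting sets of the psi
#' family are checked directly: if they all make the model identifiable the
#' search stops and they are exactly the minimal output sets. Every returned
#' set is re-verified.
#'
#' @param model A `mosid_model`.
#' @param max_k Largest omission size swept (default 3; in practice k <= 3
#'   captures the large majority of correlated sets, and the early-stop check
#'   decides whether continuing is needed). Capped at the number of outputs.
#' @param bernoulli,exhaustive_threshold,target_prob Sampling controls for
#'   large pools, see [bernoulli_subsets()].
#' @inheritParams test_identifiability
#' @return A `mosid_mos`: list with `records` (phi/psi pairs),
#'   `minimal_output_sets`, `verification` (per-candidate verdicts),
#'   `search_log`, `y_max`, `complete`, `options`.
#' @export
find_minimal_output_sets <- function(model, max_k = 3L, points = NULL,
                                     grid = NULL, gap_decades = 3, tau = 1e-3,
                                     normalize = TRUE, bernoulli = TRUE,
                                     exhaustive_threshold = 5000,
                                     target_prob = 0.995,
                                     rtol = 1e-10, atol = 1e-12,
                                     n_points = 2L, seed = 1L) {
  state <- new_search_state(model, points = points, grid = grid,
                            gap_decades = gap_decades, tau = tau,
                            normalize = normalize, rtol = rtol, atol = atol,
                            n_points = n_points, seed = seed)
  full <- .subset_test(state, state$y_max)
  if (full$verdict != "identifiable") {
    stop(structure(class = c("mosid_full_output_unidentifiable", "error", "condition"),
                   list(message = paste0(
                     "model is not identifiable even when measuring all outputs",
                     if (length(full$support)) paste0(" (correlated: ",
                                                      paste(full$support, collapse = ", "), ")"),
                     "; searching for minimal output sets is not possible"),
                        call = sys.call())))
  }
  state$log <- c(state$log, "full output set: identifiable")

  max_k <- min(as.integer(max_k), length(state$y_max))
  stopped <- FALSE
  for (k in seq_len(max_k)) {
    state <- sweep_omissions(state, k, bernoulli = bernoulli,
                             exhaustive_threshold = exhaustive_threshold,
                             target_prob = target_prob)
    psis <- lapply(state$records, `[[`, "psi")
    if (length(psis)) {
      candidates <- minimal_hitting_sets(psis, state$y_max)
      chk <- early_stop_check(state, candidates)
      state$log <- c(state$log, sprintf(
        "early-stop after k=%d: %d candidate(s), %d identifiable",
        k, nrow(chk), sum(chk$verdict == "identifiable")))
      if (all(chk$verdict == "identifiable")) { stopped <- TRUE; break }
    }
  }

  psis <- lapply(state$records, `[[`, "psi")
  candidates <- minimal_hitting_sets(psis, state$y_max)
  chk <- early_stop_check(state, candidates)
  ok <- chk$verdict == "identifiable"
  complete <- all(ok) && (stopped || max_k == length(state$y_max) || length(psis) == 0L)
  if (!all(ok))
    state$log <- c(state$log,
                   "warning: some hitting-set candidates remain unidentifiable at max_k; result flagged incomplete")

  structure(list(
    records = state$records,
    minimal_output_sets = candidates[ok],
    verification = chk,
    search_log = state$log,
    y_max = state$y_max,
    complete = complete,
    n_tests = state$n_tests,
    points = state$points,
    options = c(state$options, list(max_k = max_k, bernoulli = bernoulli,
                                    exhaustive_threshold = exhaustive_threshold,
                                    target_prob = target_prob))
  ), class = "mosid_mos")
}

#' @export
print.mosid_mos <- function(x, ...) {
  cat(sprintf("<mosid_mos> %d record(s), %d minimal output set(s)%s\n",
              length(x$records), length(x$minimal_output_sets),
              if (x$complete) "" else " [INCOMPLETE]"))
  for (r in x$records)
    cat(sprintf("  k=%d  psi={%s}  phi={%s}\n", r$k,
                paste(r$psi, collapse = ", "), paste(r$phi, collapse = ", ")))
  for (s in x$minimal_output_sets)
    cat("  MOS: {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' Tabulate the unidentifiable records of a search
#' @param x A `mosid_mos`.
#' @param ... Unused.
#' @return Data frame with columns `k`, `psi`, `phi`, `source`.
#' @export
as.data.frame.mosid_mos <- function(x, ...) {
  if (length(x$records) == 0L)
    return(data.frame(k = integer(), psi = character(), phi = character(),
                      source = character()))
  data.frame(
    k = vapply(x$records, `[[`, 0L, "k"),
    psi = vapply(x$records, function(r) paste(r$psi, collapse = ","), ""),
    phi = vapply(x$records, function(r) paste(r$phi, collapse = ","), ""),
    source = vapply(x$records, `[[`, "", "source")
  )
}
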