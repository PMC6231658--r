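# Independent oracles used across the suite.

# Brute-force hitting-set oracle: scan the whole subset lattice of y_max and
# keep the inclusion-minimal sets that intersect every family member.
brute_hitting_sets <- function(psi_family, y_max) {
  if (length(psi_family) == 0L) return(list(character(0)))
  m <- length(y_max)
  hits <- list()
  for (mask in 0:(2^m - 1)) {
    s <- y_max[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    if (all(vapply(psi_family, function(ps) length(intersect(s, ps)) > 0, TRUE)))
      hits[[length(hits) + 1L]] <- s
  }
  minimal <- hits[vapply(seq_along(hits), function(i) {
    !any(vapply(seq_along(hits), function(j)
      j != i && all(hits[[j]] %in% hits[[i]]) && length(hits[[j]]) < length(hits[[i]]),
      TRUE))
  }, TRUE)]
  keys <- vapply(minimal, function(s)
    paste(sprintf("%06d", match(s, y_max)), collapse = ","), "")
  minimal[order(keys)]
}

# Brute-force minimal-output-set oracle: test every nonempty output subset
# for identifiability (via the package's rank test on row subsets of the
# full matrix, the part under test being the search logic) and collect the
# minimal identifiable subsets.
brute_mos <- function(model, seed = 1L, n_points = 2L) {
  state <- new_search_state(model, seed = seed, n_points = n_points)
  y_max <- state$y_max
  m <- length(y_max)
  ident <- list()
  for (mask in 1:(2^m - 1)) {
    s <- y_max[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    if (mosid:::.subset_test(state, s)$verdict == "identifiable")
      ident[[length(ident) + 1L]] <- s
  }
  minimal <- ident[vapply(seq_along(ident), function(i) {
    !any(vapply(seq_along(ident), function(j)
      j != i && all(ident[[j]] %in% ident[[i]]) && length(ident[[j]]) < length(ident[[i]]),
      TRUE))
  }, TRUE)]
  keys <- vapply(minimal, function(s)
    paste(sprintf("%06d", match(s, y_max)), collapse = ","), "")
  minimal[order(keys)]
}

# Central-difference output sensitivities: an oracle for the forward
# (variational) integration, using only plain model solves.
fd_output_sensitivities <- function(model, point, grid, active = output_labels(model),
                                    h_rel = 1e-6) {
  P <- n_unknowns(model)
  N1 <- length(grid)
  m <- length(active)
  out <- array(0, dim = c(N1, m, P))
  for (j in seq_len(P)) {
    h <- h_rel * max(abs(point[j]), 1)
    pp <- point; pp[j] <- pp[j] + h
    pm <- point; pm[j] <- pm[j] - h
    yp <- simulate_model(model, pp, grid)$outputs[, active, drop = FALSE]
    ym <- simulate_model(model, pm, grid)$outputs[, active, drop = FALSE]
    out[, , j] <- (yp - ym) / (2 * h)
  }
  out
}

# Convert a mosid_sensmat (raw, unnormalized) back to the (time, output, P)
# array layout used by the FD oracle.
sensmat_array <- function(S, active) {
  N1 <- nrow(S$entries) / length(active)
  arr <- array(0, dim = c(N1, length(active), ncol(S$entries)))
  for (r in seq_len(nrow(S$entries))) {
    ti <- (r - 1) %/% length(active) + 1
    oi <- (r - 1) %% length(active) + 1
    arr[ti, oi, ] <- S$entries[r, ]
  }
  arr
}

set_key <- function(s) paste(sort(s), collapse = "|")
sets_equal <- function(a, b) setequal(vapply(a, set_key, ""), vapply(b, set_key, ""))
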