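# JSON report document (versioned schema) plus a plain-text summary in the
# style of a per-k results table: k, number of sets, phi, psi.

.mosid_schema_version <- "1.0"

#' Assemble and validate a run configuration
#'
#' @param model_source Builtin model name or path to a model document.
#' @param max_k,gap_decades,tau,grid_n,seed,n_points,bernoulli,target_prob,normalize
#'   Analysis options (see [find_minimal_output_sets()]).
#' @param outputs Optional sensor subset for single analyses.
#' @param horizon Optional `c(t0, tend)` override.
#' @return A validated `mosid_config` list.
#' @export
run_config <- function(model_source, max_k = 3L, gap_decades = 3, tau = 1e-3,
                       grid_n = NULL, horizon = NULL, seed = 1L, n_points = 2L,
                       bernoulli = TRUE, target_prob = 0.995, normalize = TRUE,
                       outputs = NULL) {
  stopifnot(is.character(model_source), length(model_source) == 1L)
  if (max_k < 1L) stop("max_k must be >= 1", call. = FALSE)
  for (v in c(gap_decades = gap_decades, tau = tau, target_prob = target_prob))
    if (!is.finite(v) || v <= 0) stop("thresholds must be positive", call. = FALSE)
  structure(list(model_source = model_source, max_k = as.integer(max_k),
                 gap_decades = gap_decades, tau = tau,
                 grid_n = grid_n, horizon = horizon,
                 seed = as.integer(seed), n_points = as.integer(n_points),
                 bernoulli = isTRUE(bernoulli), target_prob = target_prob,
                 normalize = isTRUE(normalize), outputs = outputs),
            class = "mosid_config")
}

# Resolve a config's model: builtin name first, then file path.
config_model <- function(config) {
  src <- config$model_source
  model <- if (src %in% zoo_models()) builtin_model(src)
  else if (file.exists(src)) parse_model(readLines(src), name = NULL)
  else stop(sprintf("model source '%s' is neither a builtin name nor a readable file; builtins: %s",
                    src, paste(zoo_models(), collapse = ", ")), call. = FALSE)
  if (!is.null(config$horizon)) model$time <- config$horizon
  if (!is.null(config$grid_n)) model$grid_n <- as.integer(config$grid_n)
  model
}

record_to_list <- function(r) {
  sv <- r$signature$singular_values
  list(k = r$k, psi = as.list(r$psi), phi = as.list(r$phi),
       source = r$source,
       null_basis = if (!is.null(r$null_basis)) unname(apply(r$null_basis, 2, as.list, simplify = FALSE)) else NULL,
       unknowns = if (!is.null(r$null_basis)) as.list(rownames(r$null_basis)) else NULL,
       singular_values = if (!is.null(sv)) list(
         largest = sv[1], smallest = sv[length(sv)],
         n_vanishing = length(r$signature$vanishing_indices),
         gap_decades = r$signature$gap_decades) else NULL)
}

#' Write a search result as a JSON report plus text summary
#'
#' The JSON document carries the schema version, the configuration echo, all
#' (phi, psi) records with singular-spectrum summaries, the minimal output
#' sets with their verification verdicts, and the search log. A
#' human-readable summary table (one row per k: number of sets, phi, psi) is
#' written next to it with extension `.txt`.
#'
#' @param result A `mosid_mos` from [find_minimal_output_sets()].
#' @param config A `mosid_config`.
#' @param path Output path for the JSON document.
#' @param verification Optional list of `mosid_verification` summaries.
#' @return The report list, invisibly.
#' @export
write_report <- function(result, config, path, verification = NULL) {
  report <- list(
    schema_version = .mosid_schema_version,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(config),
    y_max = as.list(result$y_max),
    records = lapply(result$records, record_to_list),
    minimal_output_sets = lapply(result$minimal_output_sets, as.list),
    verification = list(
      candidates = result$verification$candidate,
      verdicts = result$verification$verdict,
      invariance = verification
    ),
    complete = result$complete,
    n_subset_tests = result$n_tests,
    search_log = as.list(result$search_log)
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  txt <- c(sprintf("Minimal output set analysis: %s", config$model_source),
           sprintf("Sensors (y_max): %s", paste(result$y_max, collapse = ", ")),
           "",
           sprintf("%-8s %-14s %-42s %s", "k", "Number of sets",
                   "Unidentifiable parameter sets", "Omitted sensors"))
  ks <- vapply(result$records, `[[`, 0L, "k")
  for (k in seq_len(max(c(config$max_k, ks, 1L)))) {
    recs <- result$records[ks == k]
    if (length(recs) == 0L) {
      txt <- c(txt, sprintf("%-8d %-14d", k, 0L))
    } else {
      for (i in seq_along(recs)) {
        txt <- c(txt, sprintf("%-8s %-14s {%s} %s", if (i == 1) k else "",
                              if (i == 1) length(recs) else "",
                              paste(recs[[i]]$phi, collapse = ", "),
                              sprintf("{%s}", paste(recs[[i]]$psi, collapse = ", "))))
      }
    }
  }
  txt <- c(txt, "", "Minimal output sets:",
           vapply(result$minimal_output_sets,
                  function(s) sprintf("  {%s}", paste(s, collapse = ", ")), ""),
           if (!result$complete) "WARNING: search flagged incomplete" else character(0))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(structure(report, class = "mosid_report"))
}

#' Read a JSON report written by [write_report()]
#' @param path Report path.
#' @return The report list (class `mosid_report`).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(rep, class = "mosid_report")
}

#' Validate a report document against the schema and its own consistency
#'
#' Checks required fields, and that every minimal output set in the document
#' intersects every recorded psi (the hitting-set property).
#' @param report A `mosid_report`.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  need <- c("schema_version", "config", "y_max", "records",
            "minimal_output_sets", "verification", "complete", "search_log")
  missing <- setdiff(need, names(report))
  if (length(missing))
    stop("report is missing field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  psis <- lapply(report$records, function(r) unlist(r$psi))
  for (mos in report$minimal_output_sets) {
    mos <- unlist(mos)
    for (psi in psis) {
      if (length(intersect(mos, psi)) == 0L)
        stop(sprintf("minimal output set {%s} misses recorded psi {%s}",
                     paste(mos, collapse = ","), paste(psi, collapse = ",")),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
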