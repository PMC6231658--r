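#' @importFrom stats D runif setNames lm coef
#' @importFrom utils combn head
NULL

# Functions allowed inside model expressions. Anything else is rejected at
# parse time so that typos surface as parse errors, not integration failures.
.mosid_allowed_funs <- c("+", "-", "*", "/", "^", "(",
                         "sin", "cos", "tan", "exp", "log", "sqrt")

# Symbols that are always in scope inside expressions.
.mosid_implicit_syms <- c("t", "pi")

.mosid_name_rx <- "[A-Za-z][A-Za-z0-9_.]*"

#' Parse a declarative ODE model document
#'
#' Reads the plain-text model format used throughout the package and returns a
#' validated model object. The format is line based; `#` starts a comment.
#' Recognised directives:
#'
#' \preformatted{
#' model NAME
#' state NAME            # initial condition unknown
#' state NAME = 1.3      # known numeric initial condition
#' state NAME = ?        # explicitly unknown initial condition
#' state NAME = ? nominal 2   # unknown, with a nominal value for analysis
#' param NAME            # unknown parameter
#' param NAME = 0.5      # unknown parameter with nominal value
#' const NAME = 1        # known numeric constant
#' input NAME = EXPR     # input signal, an expression in t (often a constant)
#' ddt NAME = EXPR       # right-hand side of d NAME / dt
#' output LABEL = EXPR   # measurable output (sensor)
#' time T0 TEND [NPOINTS]    # horizon and default grid size (default 101)
#' }
#'
#' Expressions use standard infix math and may call `sin`, `cos`, `tan`,
#' `exp`, `log` and `sqrt`; `t` and `pi` are always available. Every other
#' symbol must be a declared state, parameter, constant or input. Unknown
#' initial conditions are treated as additional unknown parameters, named
#' `"x(0)"` after their state. If no state declares an initial condition the
#' conventional "all initial conditions unknown" reading applies
#' automatically, because a bare `state` line means unknown.
#'
#' @param text Character scalar (or vector of lines) holding the document.
#' @param name Optional model name overriding any `model` directive.
#' @return A `mosid_model` object.
#' @seealso [format_model()] for the inverse operation, [builtin_model()] for
#'   the bundled model zoo.
#' @export
#' @examples
#' m <- parse_model("
#'   model decay
#'   state x1 = ? nominal 2
#'   param th1 = 0.5
#'   ddt x1 = -th1*x1
#'   output y1 = x1
#'   time 0 2 3
#' ")
#' m
parse_model <- function(text, name = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  raw <- lines
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  mod <- list(
    name = name %||% "model",
    state_names = character(), param_names = character(),
    rhs = list(), outputs = list(),
    init = numeric(), ic_nominal = numeric(),
    param_nominal = numeric(),
    constants = numeric(), inputs = list(),
    time = c(0, 10), grid_n = 101L
  )
  ic_seen <- FALSE

  num_rx <- "[-+]?(?:[0-9]*\\.?[0-9]+)(?:[eE][-+]?[0-9]+)?"
  perr <- function(i, msg) {
    stop(sprintf("model parse error on line %d: %s [%s]", i, msg, trimws(raw[i])),
         call. = FALSE)
  }
  parse_expr <- function(s, i) {
    e <- tryCatch(str2lang(s), error = function(err) NULL)
    if (is.null(e)) perr(i, sprintf("cannot parse expression '%s'", s))
    e
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    kw <- sub("\\s.*$", "", ln)
    rest <- trimws(sub("^\\S+\\s*", "", ln))
    if (kw == "model") {
      if (is.null(name)) mod$name <- rest
    } else if (kw == "state") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*(?:=\\s*(\\?|%s))?\\s*(?:nominal\\s+(%s))?$",
                .mosid_name_rx, num_rx, num_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed state declaration")
      nm <- m[2]
      if (nm %in% mod$state_names) perr(i, sprintf("duplicate state name '%s'", nm))
      if (nm %in% mod$param_names) perr(i, sprintf("name '%s' already used as a parameter", nm))
      mod$state_names <- c(mod$state_names, nm)
      if (nzchar(m[3]) && m[3] != "?") {
        mod$init[nm] <- as.numeric(m[3]); ic_seen <- TRUE
      } else {
        mod$init[nm] <- NA_real_
        if (m[3] == "?") ic_seen <- TRUE
      }
      if (nzchar(m[4])) mod$ic_nominal[nm] <- as.numeric(m[4])
    } else if (kw == "param") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*(?:=\\s*(%s))?$", .mosid_name_rx, num_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed param declaration")
      nm <- m[2]
      if (nm %in% mod$param_names) perr(i, sprintf("duplicate parameter name '%s'", nm))
      if (nm %in% mod$state_names) perr(i, sprintf("name '%s' already used as a state", nm))
      mod$param_names <- c(mod$param_names, nm)
      mod$param_nominal[nm] <- if (nzchar(m[3])) as.numeric(m[3]) else NA_real_
    } else if (kw == "const") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*=\\s*(%s)$", .mosid_name_rx, num_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed const declaration (need NAME = NUMBER)")
      if (m[2] %in% names(mod$constants)) perr(i, sprintf("duplicate constant '%s'", m[2]))
      mod$constants[m[2]] <- as.numeric(m[3])
    } else if (kw == "input") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*=\\s*(.+)$", .mosid_name_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed input declaration")
      if (m[2] %in% names(mod$inputs)) perr(i, sprintf("duplicate input '%s'", m[2]))
      mod$inputs[[m[2]]] <- parse_expr(m[3], i)
    } else if (kw == "ddt") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*=\\s*(.+)$", .mosid_name_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed ddt declaration")
      if (m[2] %in% names(mod$rhs)) perr(i, sprintf("duplicate ddt for state '%s'", m[2]))
      mod$rhs[[m[2]]] <- parse_expr(m[3], i)
    } else if (kw == "output") {
      m <- regmatches(rest, regexec(
        sprintf("^(%s)\\s*=\\s*(.+)$", .mosid_name_rx), rest))[[1]]
      if (length(m) == 0) perr(i, "malformed output declaration")
      if (m[2] %in% names(mod$outputs)) perr(i, sprintf("duplicate output label '%s'", m[2]))
      mod$outputs[[m[2]]] <- parse_expr(m[3], i)
    } else if (kw == "time") {
      parts <- strsplit(rest, "\\s+")[[1]]
      if (!length(parts) %in% c(2L, 3L)) perr(i, "time needs T0 TEND [NPOINTS]")
      mod$time <- as.numeric(parts[1:2])
      if (length(parts) == 3L) mod$grid_n <- as.integer(parts[3])
      if (anyNA(mod$time) || mod$time[2] <= mod$time[1]) perr(i, "invalid time horizon")
    } else {
      perr(i, sprintf("unknown directive '%s'", kw))
    }
  }

  # all-ICs-unknown convention: a bare `state x` already yields NA, so nothing
  # to do; ic_seen only documents intent.
  mod$line_of <- NULL
  structure(mod, class = "mosid_model") |> validate_model()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model object
#'
#' Checks the structural invariants: at least one state and one output, one
#' RHS per state, and every free symbol in every expression declared.
#' @param model A `mosid_model`.
#' @return The model, invisibly usable in a pipe; errors on violation.
#' @export
validate_model <- function(model) {
  n <- length(model$state_names)
  m <- length(model$outputs)
  if (n < 1) stop("model must declare at least one state", call. = FALSE)
  if (m < 1) stop("model must declare at least one output", call. = FALSE)
  missing_rhs <- setdiff(model$state_names, names(model$rhs))
  if (length(missing_rhs))
    stop("no ddt equation for state(s): ", paste(missing_rhs, collapse = ", "),
         call. = FALSE)
  orphan_rhs <- setdiff(names(model$rhs), model$state_names)
  if (length(orphan_rhs))
    stop("ddt declared for undeclared state(s): ",
         paste(orphan_rhs, collapse = ", "), call. = FALSE)
  model$rhs <- model$rhs[model$state_names]

  declared <- c(model$state_names, model$param_names,
                names(model$constants), names(model$inputs),
                .mosid_implicit_syms)
  check_expr <- function(e, where) {
    bad <- setdiff(all.vars(e), declared)
    if (length(bad))
      stop(sprintf("undeclared symbol '%s' in %s", bad[1], where), call. = FALSE)
    funs <- setdiff(all.names(e), all.vars(e))
    badf <- setdiff(funs, .mosid_allowed_funs)
    if (length(badf))
      stop(sprintf("unsupported function '%s' in %s", badf[1], where), call. = FALSE)
  }
  for (s in model$state_names) check_expr(model$rhs[[s]], sprintf("ddt %s", s))
  for (o in names(model$outputs)) check_expr(model$outputs[[o]], sprintf("output %s", o))
  for (u in names(model$inputs)) {
    e <- model$inputs[[u]]
    bad <- setdiff(all.vars(e), .mosid_implicit_syms)
    if (length(bad))
      stop(sprintf("input '%s' may only depend on t (found '%s')", u, bad[1]),
           call. = FALSE)
  }
  model
}

#' Names of the unknown quantities of a model
#'
#' The unknown vector stacks the model parameters first, then the unknown
#' initial conditions (labelled `"state(0)"`), matching the column order of
#' every sensitivity matrix built from the model.
#' @param model A `mosid_model`.
#' @return Character vector of length `P = p + n_u`.
#' @export
unknown_names <- function(model) {
  c(model$param_names, sprintf("%s(0)", unknown_ic_states(model)))
}

#' @rdname unknown_names
#' @export
unknown_ic_states <- function(model) {
  model$state_names[is.na(model$init[model$state_names])]
}

#' @rdname unknown_names
#' @export
n_unknowns <- function(model) {
  length(model$param_names) + length(unknown_ic_states(model))
}

#' Output labels of a model
#' @param model A `mosid_model`.
#' @return Character vector of sensor labels, in declaration order (`y_max`).
#' @export
output_labels <- function(model) names(model$outputs)

#' Serialize a model back to its document format
#'
#' The emitted text parses back to a semantically identical model
#' (round-trip identity on states, parameters, expressions, initial
#' conditions, nominal values, constants, inputs and horizon).
#' @param model A `mosid_model`.
#' @return A single character string.
#' @export
format_model <- function(model) {
  out <- c(sprintf("model %s", model$name))
  for (s in model$state_names) {
    ic <- model$init[[s]]
    ln <- if (is.na(ic)) sprintf("state %s = ?", s) else sprintf("state %s = %.17g", s, ic)
    if (s %in% names(model$ic_nominal) && !is.na(model$ic_nominal[[s]]))
      ln <- sprintf("%s nominal %.17g", ln, model$ic_nominal[[s]])
    out <- c(out, ln)
  }
  for (p in model$param_names) {
    nom <- model$param_nominal[[p]]
    out <- c(out, if (is.na(nom)) sprintf("param %s", p)
             else sprintf("param %s = %.17g", p, nom))
  }
  for (cn in names(model$constants))
    out <- c(out, sprintf("const %s = %.17g", cn, model$constants[[cn]]))
  for (u in names(model$inputs))
    out <- c(out, sprintf("input %s = %s", u, deparse1(model$inputs[[u]])))
  for (s in model$state_names)
    out <- c(out, sprintf("ddt %s = %s", s, deparse1(model$rhs[[s]])))
  for (o in names(model$outputs))
    out <- c(out, sprintf("output %s = %s", o, deparse1(model$outputs[[o]])))
  out <- c(out, sprintf("time %.17g %.17g %d", model$time[1], model$time[2], model$grid_n))
  paste(out, collapse = "\n")
}

#' @export
print.mosid_model <- function(x, ...) {
  nu <- unknown_ic_states(x)
  cat(sprintf("<mosid_model> %s\n", x$name))
  cat(sprintf("  states:  %d (%s)\n", length(x$state_names),
              paste(head(x$state_names, 8), collapse = ", ")))
  cat(sprintf("  params:  %d | unknown ICs: %d | unknowns P = %d\n",
              length(x$param_names), length(nu), n_unknowns(x)))
  cat(sprintf("  outputs: %d (%s)\n", length(x$outputs),
              paste(head(names(x$outputs), 8), collapse = ", ")))
  cat(sprintf("  horizon: [%g, %g], default grid %d points\n",
              x$time[1], x$time[2], x$grid_n))
  invisible(x)
}

#' Default time grid of a model
#'
#' Uniform grid of `n` points on the model's declared horizon. The stacked
#' sensitivity matrix has `m * n` rows; a warning is issued downstream when
#' that falls below the number of unknowns.
#' @param model A `mosid_model`.
#' @param n Number of grid points (defaults to the model's declared size).
#' @return Strictly increasing numeric vector.
#' @export
time_grid <- function(model, n = model$grid_n) {
  if (n < 2) stop("time grid needs at least 2 points", call. = FALSE)
  seq(model$time[1], model$time[2], length.out = n)
}

#' Draw nominal (regular) points for a model
#'
#' Structural conclusions from the rank test are generic: they hold at almost
#' every parameter value, so analyses are run at one or more randomly drawn
#' regular points. If the model declares nominal values, the first point
#' equals them (missing entries are filled by draw) and further points are
#' log-uniform perturbations in the vicinity of the nominals (factor range
#' `vicinity`), following the recommendation to repeat the analysis near a
#' chosen regular point. Without nominal values, entries are drawn
#' log-uniformly from `range`.
#'
#' @param model A `mosid_model`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param count Number of points (>= 1).
#' @param range Log-uniform draw range for models without nominal values.
#' @param vicinity Multiplicative perturbation range around declared nominals.
#' @return List of `count` named numeric vectors of length `P`
#'   (parameters first, then unknown initial conditions), each with a
#'   `"seed"` attribute.
#' @export
draw_nominal_point <- function(model, seed, count = 1L,
                               range = c(0.1, 10), vicinity = c(0.5, 2)) {
  stopifnot(count >= 1)
  nms <- unknown_names(model)
  P <- length(nms)
  nom <- c(model$param_nominal[model$param_names],
           vapply(unknown_ic_states(model),
                  function(s) if (s %in% names(model$ic_nominal)) model$ic_nominal[[s]] else NA_real_,
                  0))
  names(nom) <- nms
  pts <- with_seed(seed, {
    lapply(seq_len(count), function(i) {
      if (i == 1L) {
        v <- nom
        miss <- is.na(v)
        v[miss] <- exp(runif(sum(miss), log(range[1]), log(range[2])))
      } else if (!anyNA(nom)) {
        v <- nom * exp(runif(P, log(vicinity[1]), log(vicinity[2])))
      } else {
        v <- exp(runif(P, log(range[1]), log(range[2])))
      }
      names(v) <- nms
      structure(v, seed = seed)
    })
  })
  pts
}

# Evaluate thunk with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Validate a parameter point against a model; normalization additionally
# forbids zero entries (a zero nominal value would null its normalized
# column spuriously).
check_point <- function(point, model, normalize = FALSE) {
  P <- n_unknowns(model)
  if (length(point) != P)
    stop(sprintf("parameter point has length %d, expected P = %d",
                 length(point), P), call. = FALSE)
  if (!all(is.finite(point)))
    stop("parameter point has non-finite entries", call. = FALSE)
  if (normalize && any(point == 0))
    stop("parameter point has zero entries; not a regular point for the normalized sensitivity matrix",
         call. = FALSE)
  invisible(point)
}
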