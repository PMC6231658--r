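# Bundled model zoo. Each entry is a document in the package's declarative
# format; builtin_model() parses on demand so the zoo is exercised through
# the same code path as user files.

.mosid_zoo <- new.env(parent = emptyenv())

.zoo_add <- function(name, doc) assign(name, doc, envir = .mosid_zoo)

# Exponential decay, the smallest non-trivial example: one state, one rate
# parameter, unknown initial condition. Closed forms: x(t) = x0 exp(-th1 t),
# dx/dth1 = -t x0 exp(-th1 t), dx/dx0 = exp(-th1 t).
.zoo_add("exp_decay", "
model exp_decay
state x1 = ? nominal 2
param th1 = 0.5
ddt x1 = -th1*x1
output y1 = x1
time 0 2 3
")

# Two rate constants entering only through their sum: th1 and th2 are
# totally correlated whatever is measured.
.zoo_add("toy_sum", "
model toy_sum
state x1 = ? nominal 2
param th1 = 0.7
param th2 = 0.4
ddt x1 = -(th1+th2)*x1
output y1 = x1
time 0 2 21
")

# One state observed through two proportional sensors; either sensor alone
# makes the model identifiable, so the only omitted-sensor set causing
# unidentifiability is the full pair.
.zoo_add("toy_two_outputs", "
model toy_two_outputs
state x1 = ? nominal 1.5
param th1 = 0.8
ddt x1 = -th1*x1
output y1 = x1
output y2 = 2*x1
time 0 3 21
")

# Linear three-compartment cascade with all initial conditions unknown.
# x3 is downstream of everything; measuring it alone is enough, while
# leaving it out loses th3 and x3(0).
.zoo_add("cascade3", "
model cascade3
state x1 = ? nominal 2
state x2 = ? nominal 1
state x3 = ? nominal 0.5
param th1 = 0.9
param th2 = 0.5
param th3 = 0.3
ddt x1 = -th1*x1
ddt x2 = th1*x1 - th2*x2
ddt x3 = th2*x2 - th3*x3
output x1 = x1
output x2 = x2
output x3 = x3
time 0 6 31
")

# Non-rational JAK/STAT signalling model: 14 states, rate parameters
# th1..th20, unknown x2(0) (the paper's th21), and eight predefined sensors,
# several of which are parameter-scaled sums of states. The trigonometric
# term in ddt x13 makes the system non-rational. u1, c1, c2 are not fixed by
# the source; generic value 1 is used (structural conclusions are generic).
# Nominal parameter values are generic unit-scale positives chosen so the
# dynamics stay regular over the horizon.
.zoo_add("jakstat_nonrational", "
model jakstat_nonrational
state x1 = 1.3
state x2 = ? nominal 0.8
state x3 = 0
state x4 = 1
state x5 = 0
state x6 = 2.8
state x7 = 0
state x8 = 165
state x9 = 0
state x10 = 0
state x11 = 0.34
state x12 = 0
state x13 = 0
state x14 = 0
param th1 = 0.62
param th2 = 0.41
param th3 = 1.7
param th4 = 0.93
param th5 = 1.3
param th6 = 0.55
param th7 = 0.28
param th8 = 1.1
param th9 = 0.74
param th10 = 0.35
param th11 = 1.9
param th12 = 0.47
param th13 = 2.2
param th14 = 1.5
param th15 = 0.83
param th16 = 1.2
param th17 = 0.66
param th18 = 1.4
param th19 = 0.52
param th20 = 0.97
const c1 = 1
const c2 = 1
input u1 = 1
ddt x1 = th1*c1*u1*x1 - th2*x1*pi + th3*x2
ddt x2 = th2*x1 - th3*x2
ddt x3 = th1*c1*u1*x1 - th4*x3*x7
ddt x4 = th4*x3*x7 - th5*x4
ddt x5 = th5*x4 - th6*x5
ddt x6 = -th7*x3*x6/(1 + th8*x13) - th7*x4*x6^2/(1 + th8*x13) + c2*th9*x7
ddt x7 = th7*x3*x6/(1 + th8*x13) + th7*x4*x6^2/(1 + th8*x13) - c2*th9*x7
ddt x8 = -th10*x8*x7 + c2*th11*x9
ddt x9 = th10*x8*x7 - c2*th11*x9
ddt x10 = x9
ddt x11 = -th12*c1*u1*x11
ddt x12 = th12*c1*u1*x11
ddt x13 = th13*sin(x10)/(th14 + x10) - th15*x13
ddt x14 = x9
output y1 = x1 + x3 + x4
output y2 = th16*(x3 + x4 + x5 + x12)
output y3 = th17*(x4 + x5)
output y4 = th18*x7
output y5 = th19*x10
output y6 = th20*x14
output y7 = x13
output y8 = x9
time 0 10 101
")

#' List the bundled models
#' @return Character vector of registered model names.
#' @export
zoo_models <- function() sort(ls(envir = .mosid_zoo))

#' Retrieve a bundled model by name
#'
#' The zoo holds the non-rational JAK/STAT signalling model
#' (`"jakstat_nonrational"`, 14 states, 20 rate parameters plus unknown
#' x2(0), 8 sensors) and a set of small analytic models used as ground truth
#' in tests: `"exp_decay"`, `"toy_sum"`, `"toy_two_outputs"`, `"cascade3"`.
#'
#' @param name Registered model name.
#' @return A `mosid_model`.
#' @export
#' @examples
#' builtin_model("toy_sum")
builtin_model <- function(name) {
  if (!is.character(name) || length(name) != 1L || !exists(name, envir = .mosid_zoo))
    stop(sprintf("unknown builtin model '%s'; available: %s",
                 as.character(name)[1], paste(zoo_models(), collapse = ", ")),
         call. = FALSE)
  parse_model(get(name, envir = .mosid_zoo))
}

#' Generate a model with a planted parameter correlation
#'
#' Builds a small ODE model whose unidentifiable set is known by
#' construction, for use as ground truth when testing the rank test and the
#' null-space support reading. Mechanisms:
#' \describe{
#'   \item{`"product-pair"`}{`th1` and `th2` enter the dynamics only through
#'     the product `th1*th2`; planted set `{th1, th2}`.}
#'   \item{`"sum-pair"`}{`th1`, `th2` enter only through `th1+th2`.}
#'   \item{`"output-scale"`}{the first output is `th1*x1` with `x1`
#'     autonomous and `x1(0)` unknown; only the product `th1*x1(0)` is
#'     visible, so the planted set is `{th1, x1(0)}`.}
#'   \item{`"none"`}{no mechanism: all parameters act independently and the
#'     sensitivity matrix is full rank at any regular point.}
#' }
#' Remaining parameters are attached one per state as independent decay
#' rates, all states are observed directly, and nominal values/known initial
#' conditions are drawn from the seed, so the same seed reproduces the same
#' model.
#'
#' @param mechanism One of `"product-pair"`, `"sum-pair"`, `"output-scale"`,
#'   `"none"`.
#' @param n Number of states (>= 1).
#' @param p Number of parameters; pair mechanisms need `p >= 2` and at most
#'   `n + 1` parameters can be hosted (`n` for `"none"`).
#' @param seed Integer seed.
#' @return List with elements `model` (a `mosid_model`) and `planted`
#'   (character vector of unknown names forming the planted correlated set;
#'   empty for `"none"`).
#' @export
make_correlated_fixture <- function(mechanism = c("product-pair", "sum-pair",
                                                  "output-scale", "none"),
                                    n = 3L, p = 3L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  n <- as.integer(n); p <- as.integer(p)
  if (n < 1L) stop("fixture needs n >= 1", call. = FALSE)
  pair <- mechanism %in% c("product-pair", "sum-pair", "output-scale")
  if (pair && p < 2L)
    stop(sprintf("mechanism '%s' needs at least 2 parameters", mechanism), call. = FALSE)
  pmax_host <- if (pair) n + 1L else n
  if (p > pmax_host)
    stop(sprintf("size too small to host mechanism: %d parameters but only %d slots for n = %d",
                 p, pmax_host, n), call. = FALSE)

  vals <- with_seed(seed, list(
    nom = round(exp(runif(p, log(0.3), log(3))), 3),
    ic  = round(exp(runif(n, log(0.5), log(2))), 3)
  ))
  doc <- c(sprintf("model fixture_%s_%d", gsub("-", "_", mechanism), seed))
  params <- sprintf("th%d", seq_len(p))

  # state declarations
  for (i in seq_len(n)) {
    if (mechanism == "output-scale" && i == 1L) {
      doc <- c(doc, sprintf("state x1 = ? nominal %g", vals$ic[1]))
    } else {
      doc <- c(doc, sprintf("state x%d = %g", i, vals$ic[i]))
    }
  }
  doc <- c(doc, sprintf("param %s = %g", params, vals$nom))

  # assign rates: mechanism consumes parameters from the front
  next_par <- 1L
  take <- function() { v <- params[next_par]; next_par <<- next_par + 1L; v }
  for (i in seq_len(n)) {
    rate <- if (i == 1L && mechanism == "product-pair") {
      sprintf("(%s*%s)", take(), take())
    } else if (i == 1L && mechanism == "sum-pair") {
      sprintf("(%s+%s)", take(), take())
    } else if (i == 1L && mechanism == "output-scale") {
      take()  # reserve th1 for the output scale, th2 is the rate
      r <- take(); r
    } else if (next_par <= p) take() else "1"
    doc <- c(doc, sprintf("ddt x%d = -%s*x%d", i, rate, i))
  }
  for (i in seq_len(n)) {
    expr <- if (i == 1L && mechanism == "output-scale") "th1*x1" else sprintf("x%d", i)
    doc <- c(doc, sprintf("output x%d = %s", i, expr))
  }
  doc <- c(doc, "time 0 4 21")

  planted <- switch(mechanism,
    "product-pair" = c("th1", "th2"),
    "sum-pair" = c("th1", "th2"),
    "output-scale" = c("th1", "x1(0)"),
    "none" = character()
  )
  list(model = parse_model(paste(doc, collapse = "\n")), planted = planted)
}
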