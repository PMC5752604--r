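#' Care settings recognised by the model
#'
#' The cohort is stratified into exactly three care settings, ordered from
#' least to most capable: `home < clinic < hospital`. Transfers may only move
#' patients up this ladder.
#'
#' @return Character vector `c("home", "clinic", "hospital")`.
#' @export
settings <- function() c("home", "clinic", "hospital")

#' Population types recognised by the model
#'
#' @return Character vector `c("maternal", "fetal", "neonatal")`.
#' @export
population_types <- function() c("maternal", "fetal", "neonatal")

setting_rank <- function(s) match(s, settings())

# relative tolerance used for internal mass-conservation assertions
MASS_TOL <- 1e-9

abort_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s: %s", field, msg)
  stop(errorCondition(msg, class = c("mnh_validation_error", "error", "condition")))
}

abort_parse <- function(msg) {
  stop(errorCondition(msg, class = c("mnh_parse_error", "error", "condition")))
}

check_prob <- function(x, what) {
  if (length(x) == 0) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_validation(sprintf("must be a probability in [0, 1], got [%s]",
                             paste(format(x), collapse = ", ")), field = what)
  }
  invisible(x)
}

check_setting <- function(s, what) {
  bad <- setdiff(s, settings())
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown setting '%s' (must be one of %s)",
                             bad[1], paste(settings(), collapse = ", ")), field = what)
  }
  invisible(s)
}

# named-vector helper: recycle a scalar over all settings, validate names
per_setting <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), 3), settings())
  }
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !setequal(names(x), settings())) {
    abort_validation("must be named by the three settings home/clinic/hospital",
                     field = what)
  }
  check_prob(x, what)
  x[settings()]
}

#' Content hash of a model or parameter object
#'
#' Every result embeds the hash of the model definition and scenario
#' parameters it was computed from, so any output row is traceable to exact
#' inputs and cross-scenario comparisons can refuse mismatched models.
#'
#' @param x Any R object.
#' @return A character scalar (128-bit hash, hex encoded).
#' @export
content_hash <- function(x) rlang::hash(x)

# conservation check: parts must sum to parent within relative tolerance
assert_conserved <- function(parent, parts, where) {
  total <- sum(parts)
  denom <- max(abs(parent), 1)
  if (abs(total - parent) > MASS_TOL * denom) {
    stop(sprintf("internal mass-conservation failure at %s: parent %.12g, parts sum %.12g",
                 where, parent, total))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
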