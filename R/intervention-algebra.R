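#' Probability that an eligible person actually receives an intervention
#'
#' Coverage is the product of penetration (the intervention is available in
#' the setting) and utilization (it is appropriately used when available),
#' assuming availability and use are independent.
#'
#' @param penetration,utilization Probabilities in `[0, 1]` (vectorized).
#' @return `penetration * utilization`.
#' @export
coverage <- function(penetration, utilization) {
  check_prob(penetration, "penetration")
  check_prob(utilization, "utilization")
  penetration * utilization
}

#' Probability of receipt and success
#'
#' @param coverage Probability of receipt, see [coverage()].
#' @param efficacy Probability of success under ideal conditions.
#' @return `coverage * efficacy`.
#' @export
success <- function(coverage, efficacy) {
  check_prob(coverage, "coverage")
  check_prob(efficacy, "efficacy")
  coverage * efficacy
}

#' Combine layered (order-independent) interventions
#'
#' Layered interventions act as independent events: the combined success is
#' the complement of every layer failing, `1 - prod(1 - s_i)`. The result is
#' invariant under permutation of the input.
#'
#' @param successes Numeric vector of per-layer success probabilities
#'   (receipt and success, see [success()]). May be empty.
#' @return Combined success probability; `0` for an empty input.
#' @export
compose_layers <- function(successes) {
  check_prob(successes, "successes")
  if (length(successes) == 0) return(0)
  1 - prod(1 - successes)
}

#' Collapse an ordered cascade of intervention lines
#'
#' Line `1` is administered with probability `c1` (its receive probability).
#' Line `k > 1` is administered only to those who actually received line
#' `k - 1` *and* failed on it; among those, receipt has probability `ck`.
#' People who never received line `k - 1` drop out of the cascade, which makes
#' lines numerically distinct from layers and order-dependent.
#'
#' @param lines Ordered list (first line first) of length-2 numeric vectors
#'   `c(receive, efficacy)`, or a 2-column matrix/data frame with columns
#'   `receive` and `efficacy`.
#' @return A list with `overall` (total success probability,
#'   `sum(administered_k * efficacy_k)`) and `administered` (the population
#'   fraction reached by each line).
#' @export
compose_lines <- function(lines) {
  lt <- normalize_lines(lines)
  k <- nrow(lt)
  if (k == 0) return(list(overall = 0, administered = numeric(0)))
  administered <- numeric(k)
  active <- 1 # mass still eligible for the next line (received previous & failed)
  for (i in seq_len(k)) {
    administered[i] <- if (i == 1) lt$receive[1] else active * lt$receive[i]
    active <- administered[i] * (1 - lt$efficacy[i])
  }
  list(overall = sum(administered * lt$efficacy), administered = administered)
}

normalize_lines <- function(lines) {
  if (is.data.frame(lines)) {
    lt <- lines
  } else if (is.matrix(lines)) {
    lt <- data.frame(receive = lines[, 1], efficacy = lines[, 2])
  } else if (is.list(lines)) {
    if (length(lines) == 0) {
      lt <- data.frame(receive = numeric(0), efficacy = numeric(0))
    } else {
      lt <- data.frame(receive = vapply(lines, function(x) as.numeric(x[[1]]), 0),
                       efficacy = vapply(lines, function(x) as.numeric(x[[2]]), 0))
    }
  } else {
    abort_validation("lines must be a list of (receive, efficacy) pairs", "lines")
  }
  names(lt)[1:2] <- c("receive", "efficacy")
  check_prob(lt$receive, "lines.receive")
  check_prob(lt$efficacy, "lines.efficacy")
  lt
}

#' Combine the layers and line cascades available at one care stage
#'
#' Each line group first collapses via [compose_lines()] into a single
#' success probability; that probability then enters [compose_layers()]
#' alongside the plain layer successes. Line groups and layers act
#' independently of each other.
#'
#' @param layers Numeric vector of layer success probabilities, optionally
#'   named by intervention id.
#' @param line_groups List of line cascades, each in a format accepted by
#'   [compose_lines()]; rows/elements may be named by intervention id.
#' @return Combined stage success probability.
#' @export
combine_stage <- function(layers = numeric(), line_groups = list()) {
  ids <- c(names(layers),
           unlist(lapply(line_groups, function(g) {
             if (is.data.frame(g)) rownames(g) else names(g)
           })))
  ids <- ids[!is.null(ids) & ids != ""]
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("intervention '%s' appears in more than one group",
                             ids[duplicated(ids)][1]), "combine_stage")
  }
  group_successes <- vapply(line_groups, function(g) compose_lines(g)$overall, 0)
  compose_layers(c(unname(layers), group_successes))
}

#' Check single-use and timing constraints on a sub-condition pathway
#'
#' Flags any single-use intervention id appearing more than once across the
#' stages of one sub-condition pathway, while permitting the same id to recur
#' when the occurrences carry distinct timing tags (e.g. oxytocin as labour
#' prophylaxis and again as hemorrhage treatment).
#'
#' @param pathway Data frame with columns `intervention_id`, `stage`,
#'   `single_use` (logical) and optionally `timing` (character; distinct
#'   values legitimise re-use). An empty frame yields an empty report.
#' @return Data frame report with one row per distinct intervention id:
#'   `intervention_id`, `occurrences`, `distinct_timings`, `violation`.
#' @export
check_usage_constraints <- function(pathway) {
  if (is.null(pathway) || nrow(pathway) == 0) {
    return(data.frame(intervention_id = character(), occurrences = integer(),
                      distinct_timings = integer(), violation = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(pathway$timing)) pathway$timing <- ""
  if (is.null(pathway$single_use)) pathway$single_use <- FALSE
  ids <- unique(pathway$intervention_id)
  report <- do.call(rbind, lapply(ids, function(id) {
    rows <- pathway[pathway$intervention_id == id, , drop = FALSE]
    occ <- nrow(rows)
    timings <- length(unique(rows$timing))
    data.frame(intervention_id = id, occurrences = occ,
               distinct_timings = timings,
               violation = any(rows$single_use) && occ > 1 && timings < occ,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  report
}
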