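# Ductal disease staging. A staging scheme is an ordered set of components,
# each mapping one echo measurement to an integer severity score. Numeric
# components partition [0, Inf): an exact-zero bin (no measurable signal),
# then contiguous interval bins. Boundary convention: printed ranges such as
# "1.5-3" are closed on both ends while "<x" / ">y" bins are open, so a value
# on a shared edge belongs to the closed middle bin; where two closed bins
# would meet, the milder (lower-score) bin wins.

new_staging_component <- function(variable, kind, zero_score = 0L,
                                  breaks = numeric(), scores = integer(),
                                  categories = NULL) {
  comp <- list(variable = variable, kind = kind)
  if (kind == "numeric") {
    if (length(scores) != length(breaks) + 1L) {
      stop(sprintf("scheme validation failed for component `%s`: %d breaks need %d bin scores",
                   variable, length(breaks), length(breaks) + 1L), call. = FALSE)
    }
    if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
      stop(sprintf("scheme validation failed for component `%s`: breaks must be positive and strictly increasing",
                   variable), call. = FALSE)
    }
    full <- c(zero_score, scores)
    if (is.unsorted(full)) {
      stop(sprintf("scheme validation failed for component `%s`: scores must be non-decreasing with severity",
                   variable), call. = FALSE)
    }
    comp$zero_score <- as.integer(zero_score)
    comp$breaks <- as.numeric(breaks)
    comp$scores <- as.integer(scores)
    comp$max_component_score <- max(as.integer(full))
  } else if (kind == "categorical") {
    if (is.null(categories) || is.null(names(categories)) ||
        anyDuplicated(names(categories))) {
      stop(sprintf("scheme validation failed for component `%s`: categorical component needs uniquely named category scores",
                   variable), call. = FALSE)
    }
    comp$categories <- vapply(categories, as.integer, integer(1))
    comp$max_component_score <- max(comp$categories)
  } else {
    stop(sprintf("scheme validation failed for component `%s`: unknown kind `%s`",
                 variable, kind), call. = FALSE)
  }
  structure(comp, class = "staging_component")
}

new_staging_scheme <- function(name, components) {
  vars <- vapply(components, `[[`, character(1), "variable")
  if (anyDuplicated(vars)) {
    stop("scheme validation failed: duplicated component variables", call. = FALSE)
  }
  structure(list(name = name,
                 components = stats::setNames(components, vars),
                 max_score = sum(vapply(components, `[[`, integer(1),
                                        "max_component_score"))),
            class = "staging_scheme")
}

#' Built-in ductal disease staging scheme (0-11 points)
#'
#' Returns the four-component ductal staging scheme used for screening:
#' transductal diameter (mm), ductal Vmax/Vmin velocity ratio, antegrade LPA
#' end-diastolic velocity (cm/s) — each scored 0-3 — and descending-aorta
#' diastolic flow direction (forward/absent/reverse, scored 0-2). The maximum
#' attainable total is 11 and the minimum is 0.
#'
#' @return a `staging_scheme` object.
#' @examples
#' sch <- model5_scheme()
#' sch$max_score  # 11
#' @export
model5_scheme <- function() {
  new_staging_scheme(
    name = "model5",
    components = list(
      new_staging_component("transductal_diameter", "numeric",
                            zero_score = 0L, breaks = c(1.5, 3),
                            scores = c(1L, 2L, 3L)),
      new_staging_component("ductal_vmax_vmin_ratio", "numeric",
                            zero_score = 0L, breaks = c(1.5, 2),
                            scores = c(1L, 2L, 3L)),
      new_staging_component("lpa_diastolic_velocity", "numeric",
                            zero_score = 0L, breaks = c(30, 50),
                            scores = c(1L, 2L, 3L)),
      new_staging_component("dao_flow_direction", "categorical",
                            categories = c(forward = 0L, absent = 1L,
                                           reverse = 2L))
    ))
}

#' @export
print.staging_scheme <- function(x, ...) {
  cat(sprintf("Staging scheme `%s`: %d components, max score %d\n",
              x$name, length(x$components), x$max_score))
  for (comp in x$components) {
    if (comp$kind == "numeric") {
      cat(sprintf("  %s: 0 -> %d; breaks %s -> scores %s\n", comp$variable,
                  comp$zero_score, paste(comp$breaks, collapse = ", "),
                  paste(comp$scores, collapse = ", ")))
    } else {
      cat(sprintf("  %s: %s\n", comp$variable,
                  paste(sprintf("%s -> %d", names(comp$categories),
                                comp$categories), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Stage a single measurement with one scheme component
#'
#' @param value a non-negative numeric measurement, or a category label for a
#'   categorical component.
#' @param component a `staging_component` (element of a scheme's
#'   `components` list).
#' @return integer component score.
#' @examples
#' sch <- model5_scheme()
#' stage_component(1.5, sch$components$transductal_diameter)  # 2
#' stage_component("reverse", sch$components$dao_flow_direction)  # 2
#' @export
stage_component <- function(value, component) {
  stopifnot(inherits(component, "staging_component"))
  if (component$kind == "categorical") {
    value <- as.character(value)
    if (length(value) != 1L || is.na(value) ||
        !value %in% names(component$categories)) {
      stop_invalid(component$variable,
                   sprintf("unknown category `%s` (expected one of %s)",
                           value,
                           paste(names(component$categories), collapse = ", ")))
    }
    return(unname(component$categories[[value]]))
  }
  if (length(value) != 1L || !is.numeric(value) || is.na(value) || value < 0) {
    stop_invalid(component$variable, "must be a single non-negative number")
  }
  if (value == 0) return(component$zero_score)
  idx <- sum(component$breaks < value)
  # the first break is the only edge whose lower neighbour is an open bin:
  # its value belongs to the closed bin above it
  if (idx == 0L && length(component$breaks) && value == component$breaks[1L]) {
    idx <- 1L
  }
  component$scores[[idx + 1L]]
}

#' Total staged score of an exam
#'
#' Applies every component of a staging scheme to the corresponding exam
#' measurement and sums the per-component scores.
#'
#' @param exam an [echo_exam()] object, or any named list / one-row data frame
#'   carrying the fields the scheme stages.
#' @param scheme a `staging_scheme`, by default [model5_scheme()].
#' @return an object of class `staged_score` with elements `per_component`
#'   (named integer vector) and `total`.
#' @examples
#' ex <- echo_exam(transductal_diameter = 2.0, ductal_vmax_vmin_ratio = 1.6,
#'                 lpa_diastolic_velocity = 35, dao_flow_direction = "reverse")
#' compute_score(ex)$total  # 8
#' @export
compute_score <- function(exam, scheme = model5_scheme()) {
  stopifnot(inherits(scheme, "staging_scheme"))
  exam <- as.list(exam)
  per <- integer(0)
  for (comp in scheme$components) {
    v <- resolve_cohort_column(exam, comp$variable)
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      stop(sprintf("missing measurement `%s` required by scheme `%s`",
                   comp$variable, scheme$name), call. = FALSE)
    }
    per[[comp$variable]] <- stage_component(v, comp)
  }
  structure(list(per_component = per, total = sum(per)),
            class = "staged_score")
}

#' @export
print.staged_score <- function(x, ...) {
  cat(sprintf("Staged score: total %d (%s)\n", x$total,
              paste(sprintf("%s=%d", names(x$per_component), x$per_component),
                    collapse = ", ")))
  invisible(x)
}

#' Score every infant in a cohort table
#'
#' Computes (or recomputes) the `pda_score` column of a cohort data frame
#' from its staged measurement columns.
#'
#' @param cohort a cohort data frame (see [read_cohort()] for the schema).
#' @param scheme a `staging_scheme`.
#' @return the cohort with an integer `pda_score` column.
#' @export
score_cohort <- function(cohort, scheme = model5_scheme()) {
  stopifnot(is.data.frame(cohort))
  total <- rep(0L, nrow(cohort))
  for (comp in scheme$components) {
    v <- resolve_cohort_column(cohort, comp$variable)
    if (is.null(v) || anyNA(v)) {
      stop(sprintf("missing measurement `%s` required by scheme `%s`",
                   comp$variable, scheme$name), call. = FALSE)
    }
    total <- total + stage_values(v, comp)
  }
  cohort$pda_score <- total
  cohort
}

# vectorized counterpart of stage_component
stage_values <- function(values, component) {
  if (component$kind == "categorical") {
    values <- as.character(values)
    if (!all(values %in% names(component$categories))) {
      stop_invalid(component$variable, "unknown category")
    }
    return(unname(component$categories[values]))
  }
  if (any(values < 0)) stop_invalid(component$variable, "must be >= 0")
  idx <- rowSums(outer(values, component$breaks, `>`))
  idx[idx == 0L & values == component$breaks[1L]] <- 1L
  out <- component$scores[idx + 1L]
  out[values == 0] <- component$zero_score
  as.integer(out)
}

#' Load a staging scheme from a configuration file or list
#'
#' The configuration is JSON-compatible: a `name` plus a `components` list.
#' Numeric components give an optional `zero_score` (default 0) and ordered
#' `bins`, each `{from, to, score}` with `to = null` for the unbounded last
#' bin; bins must start at 0 and chain without gaps or overlaps (`to` of one
#' bin equals `from` of the next). Categorical components give a
#' `categories` object mapping labels to scores. The shipped fixture
#' `system.file("extdata", "model5_scheme.json", package = "pdaclose")`
#' encodes the built-in 0-11 scheme.
#'
#' @param config path to a JSON file, or an already-parsed list.
#' @return a validated `staging_scheme`.
#' @examples
#' path <- system.file("extdata", "model5_scheme.json", package = "pdaclose")
#' sch <- load_scheme(path)
#' sch$max_score  # 11
#' @export
load_scheme <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (is.null(config$components) || !length(config$components)) {
    stop("scheme validation failed: no components", call. = FALSE)
  }
  comps <- lapply(config$components, function(cc) {
    variable <- cc$variable
    if (is.null(variable)) {
      stop("scheme validation failed: component without `variable`",
           call. = FALSE)
    }
    kind <- if (!is.null(cc$kind)) cc$kind
            else if (!is.null(cc$categories)) "categorical" else "numeric"
    if (kind == "categorical") {
      return(new_staging_component(variable, "categorical",
                                   categories = unlist(cc$categories)))
    }
    bins <- cc$bins
    if (is.null(bins) || !length(bins)) {
      stop(sprintf("scheme validation failed for component `%s`: no bins",
                   variable), call. = FALSE)
    }
    from <- vapply(bins, function(b) as.numeric(b$from), numeric(1))
    to <- vapply(bins, function(b) {
      if (is.null(b$to)) Inf else as.numeric(b$to)
    }, numeric(1))
    score <- vapply(bins, function(b) as.integer(b$score), integer(1))
    ord <- order(from)
    from <- from[ord]; to <- to[ord]; score <- score[ord]
    if (from[1L] != 0) {
      stop(sprintf("scheme validation failed for component `%s`: bins must start at 0",
                   variable), call. = FALSE)
    }
    if (!is.infinite(to[length(to)])) {
      stop(sprintf("scheme validation failed for component `%s`: last bin must be unbounded (`to` = null)",
                   variable), call. = FALSE)
    }
    inner <- seq_len(length(bins) - 1L)
    if (length(inner) && any(to[inner] != from[inner + 1L])) {
      bad <- which(to[inner] != from[inner + 1L])[1L]
      word <- if (to[bad] < from[bad + 1L]) "gap" else "overlap"
      stop(sprintf("scheme validation failed for component `%s`: %s between bins ending at %g and starting at %g",
                   variable, word, to[bad], from[bad + 1L]), call. = FALSE)
    }
    zero <- if (is.null(cc$zero_score)) 0L else as.integer(cc$zero_score)
    new_staging_component(variable, "numeric", zero_score = zero,
                          breaks = to[is.finite(to)], scores = score)
  })
  name <- if (is.null(config$name)) "custom" else config$name
  new_staging_scheme(name, comps)
}
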