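#' Protocol constraint rule
#'
#' One row of a trial scorecard: a DVH metric on a named structure, a
#' comparator, a per-protocol bound and an optional (weaker) acceptable-
#' variation bound. Values meeting the per-protocol bound classify as
#' `within_protocol`, values meeting only the acceptable bound as
#' `acceptable_variation`, all others as `deviation`; bounds are inclusive.
#' Coverage rules use the same schema with a `>=` comparator and, when
#' `relative_to_rx` is set, bounds expressed as a fraction of the structure's
#' prescribed dose.
#'
#' @param structure Structure name the rule applies to.
#' @param metric Metric spec: `D{p}%`, `D{v}cc`, `Dmean`, `Dmax` or `V{d}Gy`.
#' @param comparator `"<="` (constraint) or `">="` (coverage).
#' @param per_protocol Per-protocol bound (Gy for D-metrics, cc for V-metrics;
#'   a fraction of prescription if `relative_to_rx`).
#' @param acceptable Optional acceptable-variation bound; must be weaker than
#'   `per_protocol` under the comparator.
#' @param scope Plan scope: `"both"` (default), `"standard"`, `"experimental"`.
#' @param relative_to_rx If `TRUE`, bounds are multiplied by the structure's
#'   prescribed dose at evaluation time.
#' @return A `constraint_rule` object.
#' @export
constraint_rule <- function(structure, metric, comparator = c("<=", ">="),
                            per_protocol, acceptable = NA_real_,
                            scope = c("both", "standard", "experimental"),
                            relative_to_rx = FALSE) {
  comparator <- match.arg(comparator)
  scope <- match.arg(scope)
  parse_metric_spec(metric)  # validates; errors on unknown specs
  per_protocol <- as.numeric(per_protocol)
  acceptable <- as.numeric(acceptable)
  if (!is.finite(per_protocol)) {
    abort(paste0("rule ", structure, "/", metric, ": per_protocol bound must be numeric"),
          class = "planqa_parameter_error")
  }
  if (is.finite(acceptable)) {
    weaker <- if (comparator == "<=") acceptable >= per_protocol else acceptable <= per_protocol
    if (!weaker) {
      abort(paste0("rule ", structure, "/", metric,
                   ": acceptable bound must be weaker than per_protocol under '",
                   comparator, "'"),
            class = "planqa_parameter_error")
    }
  }
  structure(
    list(structure = structure, metric = metric, comparator = comparator,
         per_protocol = per_protocol, acceptable = acceptable, scope = scope,
         relative_to_rx = isTRUE(relative_to_rx)),
    class = "constraint_rule"
  )
}

#' Load a constraint table from YAML or JSON
#'
#' The config is a list of rule maps with the fields of [constraint_rule()].
#' The example config shipped with the package
#' (`system.file("extdata", "constraints_example.yaml", package = "planqa")`)
#' carries illustrative bounds only — real trial bounds live in the protocol
#' manual and must be supplied per trial.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [constraint_rule()]s (possibly empty).
#' @export
load_constraints <- function(path) {
  if (!file.exists(path)) abort(paste0("constraint file not found: ", path),
                                class = "planqa_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0) return(list())
  purrr::imap(raw, function(r, i) {
    tryCatch(
      constraint_rule(
        structure = r$structure, metric = r$metric,
        comparator = r$comparator %||% "<=",
        per_protocol = r$per_protocol,
        acceptable = r$acceptable %||% NA_real_,
        scope = r$scope %||% "both",
        relative_to_rx = isTRUE(r$relative_to_rx)
      ),
      error = function(e) {
        abort(paste0("malformed constraint rule #", i, " (",
                     r$structure %||% "?", " ", r$metric %||% "?", "): ",
                     conditionMessage(e)),
              class = "planqa_parameter_error")
      }
    )
  })
}

classification_levels <- c("within_protocol", "acceptable_variation",
                           "deviation", "not_evaluable")

#' Evaluate one constraint rule on a plan
#'
#' Computes the rule's metric through the DVH machinery and classifies the
#' observed value. A structure missing from the bundle yields a
#' `not_evaluable` result, not an error.
#'
#' @param bundle A [plan_bundle()].
#' @param rule A [constraint_rule()].
#' @param bin_width DVH bin width in Gy.
#' @return One-row tibble: `structure`, `metric`, `comparator`, `bound_pp`,
#'   `bound_acc`, `observed`, `classification`.
#' @export
evaluate_constraint <- function(bundle, rule, bin_width = 0.1) {
  res <- function(observed, class) {
    tibble::tibble(structure = rule$structure, metric = rule$metric,
                   comparator = rule$comparator,
                   bound_pp = rule$per_protocol, bound_acc = rule$acceptable,
                   observed = observed,
                   classification = factor(class, levels = classification_levels))
  }
  if (!has_structure(bundle$structures, rule$structure)) {
    return(res(NA_real_, "not_evaluable"))
  }
  mask <- get_structure(bundle$structures, rule$structure)
  if (!any(mask$occupancy)) return(res(NA_real_, "not_evaluable"))
  spec <- parse_metric_spec(rule$metric)
  dvh <- if (spec$kind %in% c("Dpct", "Dcc")) cumulative_dvh(bundle$dose, mask, bin_width)
  observed <- evaluate_metric_spec(spec, bundle$dose, mask, dvh)
  if (!is.finite(observed)) return(res(NA_real_, "not_evaluable"))
  scale <- 1
  if (rule$relative_to_rx) {
    rx <- bundle$prescription[[rule$structure]]
    if (is.null(rx)) return(res(observed, "not_evaluable"))
    scale <- rx
  }
  meets <- function(bound) {
    if (rule$comparator == "<=") observed <= bound * scale else observed >= bound * scale
  }
  cls <- if (meets(rule$per_protocol)) "within_protocol"
  else if (is.finite(rule$acceptable) && meets(rule$acceptable)) "acceptable_variation"
  else "deviation"
  res(observed, cls)
}

#' Evaluate a full scorecard
#'
#' Applies every rule whose scope matches the bundle's plan label and
#' aggregates the worst classification as the overall verdict (deviation
#' beats acceptable variation beats within protocol; not-evaluable rows are
#' reported but do not drive the verdict unless nothing was evaluable).
#'
#' @param bundle A [plan_bundle()].
#' @param rules Non-empty list of [constraint_rule()]s.
#' @param bin_width DVH bin width in Gy.
#' @return A `scorecard` object; `tidy()` yields the per-rule table,
#'   `glance()` the one-row verdict.
#' @export
evaluate_plan <- function(bundle, rules, bin_width = 0.1) {
  if (length(rules) == 0) abort("`rules` must be non-empty", class = "planqa_parameter_error")
  applicable <- purrr::keep(rules, function(r) {
    r$scope == "both" || r$scope == bundle$dose$plan_label
  })
  results <- purrr::map_dfr(applicable, evaluate_constraint, bundle = bundle,
                            bin_width = bin_width)
  evaluated <- results$classification[results$classification != "not_evaluable"]
  overall <- if (length(evaluated) == 0) "not_evaluable"
  else classification_levels[max(as.integer(evaluated))]
  structure(
    list(table = results, overall = overall, center_label = bundle$center_label,
         plan_label = bundle$dose$plan_label),
    class = "scorecard"
  )
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("<scorecard> center '%s', %s plan — overall: %s\n",
              x$center_label, x$plan_label, x$overall))
  print(x$table, n = Inf)
  invisible(x)
}

#' @describeIn evaluate_plan Per-rule result tibble.
#' @param x A `scorecard`.
#' @param ... Unused.
#' @export
tidy.scorecard <- function(x, ...) x$table

#' @describeIn evaluate_plan One-row verdict summary.
#' @export
glance.scorecard <- function(x, ...) {
  tab <- table(x$table$classification)
  tibble::tibble(
    center = x$center_label, plan = x$plan_label, overall = x$overall,
    n_rules = nrow(x$table),
    n_within = unname(tab["within_protocol"]),
    n_acceptable = unname(tab["acceptable_variation"]),
    n_deviation = unname(tab["deviation"]),
    n_not_evaluable = unname(tab["not_evaluable"])
  )
}

#' Render a scorecard as markdown
#'
#' Text rendering of the three-class color semantics (green = within
#' protocol, yellow = acceptable variation, red = deviation).
#'
#' @param x A `scorecard`.
#' @return Character vector of markdown lines.
#' @export
format_scorecard_md <- function(x) {
  lab <- c(within_protocol = "GREEN (within protocol)",
           acceptable_variation = "YELLOW (acceptable variation)",
           deviation = "RED (deviation)",
           not_evaluable = "n/a (not evaluable)")
  c(
    sprintf("## Scorecard — center '%s', %s plan", x$center_label, x$plan_label),
    sprintf("Overall: **%s**", lab[[x$overall]]),
    "",
    "| Structure | Metric | Rule | Observed | Class |",
    "|---|---|---|---|---|",
    apply(x$table, 1, function(r) {
      sprintf("| %s | %s | %s %s | %s | %s |",
              r[["structure"]], r[["metric"]], r[["comparator"]],
              format(as.numeric(r[["bound_pp"]])),
              ifelse(is.na(r[["observed"]]), "-",
                     format(round(as.numeric(r[["observed"]]), 2))),
              lab[[as.character(r[["classification"]])]])
    })
  )
}
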