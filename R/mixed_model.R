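## Statistical stage: Tukey-fence outlier screening of the movement
## metrics, assembly of the long model table (participant x round), and a
## random-slopes linear mixed model linking each movement metric to the
## self-reported state scores, fitted by REML via lmerTest/lme4 with
## Satterthwaite denominator degrees of freedom.

#' State-score predictors
#'
#' Canonical column names of the questionnaire constructs entering the
#' fixed-effects formula (each a 1-7 scale mean, plus the binary
#' illegal-card indicator and the round number).
#' @export
STATE_PREDICTORS <- c(
  "illegal_card", "alertness_target", "cognitive_self_regulation",
  "situational_self_awareness", "fright", "suppressed_impulses",
  "contemplation_hostile_intent", "awareness_movement_change"
)

#' Tukey-fence outlier mask
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles by
#' linear interpolation (`stats::quantile` type 7). With fewer than 4
#' finite values nothing is flagged and a warning is raised. Note the rule
#' is not idempotent: re-running it on the survivors may flag more values.
#'
#' @param x Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` where `x` is an outlier (`NA` values are
#'   never flagged).
#' @export
tukey_outliers <- function(x, k = 1.5) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  fin <- is.finite(x)
  if (sum(fin) < 4) {
    warning("fewer than 4 finite values; no outlier masking", call. = FALSE)
    return(rep(FALSE, length(x)))
  }
  q <- stats::quantile(x[fin], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- fin & (x < q[1] - k * iqr | x > q[2] + k * iqr)
  out[is.na(out)] <- FALSE
  out
}

#' Build the model table
#'
#' Joins the metric table with the state-score table on
#' `(participant_id, round)` and applies the Tukey fence to the chosen
#' outcome column — except for intra-team distance, which is exempt from
#' outlier removal. Flagged rows are retained with `outlier = TRUE` but
#' excluded from fitting by [fit_state_model()].
#'
#' @param metrics Metric table from [track_metrics()] (or any table with
#'   `participant_id`, `round` and the outcome column).
#' @param states State table with `participant_id`, `round` and the
#'   [STATE_PREDICTORS] columns.
#' @param outcome Name of the outcome column in `metrics`.
#' @param k Tukey fence multiplier.
#' @param exempt Outcome names never screened for outliers.
#' @return A tibble, one row per participant and round, with `outlier`.
#' @export
build_model_table <- function(metrics, states, outcome, k = 1.5,
                              exempt = "intra_team_distance_m") {
  if (!outcome %in% names(metrics)) {
    stop("outcome '", outcome, "' not in metric table", call. = FALSE)
  }
  if (anyDuplicated(metrics[c("participant_id", "round")])) {
    stop("duplicate (participant_id, round) rows in metrics", call. = FALSE)
  }
  by <- intersect(c("participant_id", "team_id", "round"), names(states))
  by <- intersect(by, names(metrics))
  tab <- dplyr::inner_join(metrics, states, by = by)
  if (nrow(tab) == 0) stop("empty join of metrics and states", call. = FALSE)
  if (outcome %in% exempt) {
    tab$outlier <- FALSE
  } else {
    tab$outlier <- tukey_outliers(tab[[outcome]], k = k)
  }
  tab
}

#' Fit the state-movement mixed model
#'
#' REML linear mixed model of one movement metric on the state predictors
#' and round, with a random slope for round and intercepts grouped by team
#' and by participant nested in team. Which grouping level carries the
#' round slope is configurable (`random`), since the maximal structure can
#' place it at either or both levels:
#' \describe{
#'   \item{`"both"`}{`(round | team) + (round | team:participant)` (default)}
#'   \item{`"team"`}{`(round | team) + (1 | team:participant)`}
#'   \item{`"participant"`}{`(1 | team) + (round | team:participant)`}
#' }
#' Rows flagged as outliers or with a missing outcome are excluded from
#' fitting. Non-convergence is reported in the result, not raised.
#' P-values use the Satterthwaite approximation (via lmerTest).
#'
#' @param table Model table from [build_model_table()] (or a compatible
#'   tibble with `team_id`, `participant_id`, `round`, predictors and the
#'   outcome).
#' @param outcome Outcome column name.
#' @param predictors Fixed-effect predictor columns; defaults to the
#'   [STATE_PREDICTORS] present in `table`.
#' @param random Random-effects layout, see above.
#' @param standardize If `TRUE`, scale the numeric predictors to unit SD
#'   before fitting (coefficients are per-SD). Default `FALSE`: predictors
#'   enter on their questionnaire scale.
#' @return An object of class `state_model` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_state_model <- function(table, outcome,
                            predictors = NULL,
                            random = c("both", "team", "participant"),
                            standardize = FALSE) {
  random <- match.arg(random)
  need <- c("team_id", "participant_id", "round", outcome)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("model table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(predictors)) {
    predictors <- intersect(STATE_PREDICTORS, names(table))
  }
  dat <- table
  if (!"outlier" %in% names(dat)) dat$outlier <- FALSE
  dat <- dat[!dat$outlier & is.finite(dat[[outcome]]), ]
  dat <- tidyr::drop_na(dat, dplyr::all_of(predictors))
  if (length(unique(dat$team_id)) < 2) {
    stop("at least 2 teams required", call. = FALSE)
  }
  if (length(unique(dat$round)) < 2) {
    stop("at least 2 rounds required", call. = FALSE)
  }
  if (standardize) {
    for (p in predictors) {
      if (is.numeric(dat[[p]]) && stats::sd(dat[[p]]) > 0) {
        dat[[p]] <- as.numeric(scale(dat[[p]], center = TRUE, scale = TRUE))
      }
    }
  }
  fixed <- paste(c("round", predictors), collapse = " + ")
  ## rank check on the fixed design, naming collinear terms
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", fixed)), data = dat
  )
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient fixed design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  re <- switch(random,
    both = "(round | team_id) + (round | team_id:participant_id)",
    team = "(round | team_id) + (1 | team_id:participant_id)",
    participant = "(1 | team_id) + (round | team_id:participant_id)"
  )
  fml <- stats::as.formula(paste(outcome, "~", fixed, "+", re))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = dat, REML = TRUE)
  ))
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  ## a boundary (singular) fit is a zero variance component, not a failure
  conv_msgs <- conv_msgs[!grepl("boundary \\(singular\\)", conv_msgs)]
  singular <- lme4::isSingular(fit, tol = 1e-4)
  coefs <- summary(fit)$coefficients
  coef_tab <- tibble::tibble(
    term = rownames(coefs),
    estimate = unname(coefs[, "Estimate"]),
    std.error = unname(coefs[, "Std. Error"]),
    df = unname(coefs[, "df"]),
    statistic = unname(coefs[, "t value"]),
    p.value = unname(coefs[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fit = fit, outcome = outcome, predictors = predictors,
      random = random, formula = fml,
      coefficients = coef_tab,
      varcomp = tibble::as_tibble(vc),
      converged = length(conv_msgs) == 0,
      convergence_messages = conv_msgs,
      singular = singular,
      n_obs = nrow(dat),
      n_teams = length(unique(dat$team_id)),
      n_participants = length(unique(paste(dat$team_id, dat$participant_id))),
      n_outliers_removed = if ("outlier" %in% names(table)) {
        sum(table$outlier, na.rm = TRUE)
      } else 0L,
      p_value_method = "Satterthwaite"
    ),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat("State-movement mixed model (REML, Satterthwaite p-values)\n")
  cat("  outcome:", x$outcome, "\n")
  cat("  random layout:", x$random, "\n")
  cat("  n =", x$n_obs, "rows,", x$n_participants, "participants,",
      x$n_teams, "teams\n")
  if (!x$converged) cat("  NOTE: convergence warnings reported\n")
  if (x$singular) cat("  NOTE: singular fit (variance component at zero)\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a state-movement model
#'
#' Fixed-effect estimates, standard errors, Satterthwaite degrees of
#' freedom and p-values, one row per term (the shape of a per-estimate
#' regression table).
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`.
#' @importFrom generics tidy
#' @export
tidy.state_model <- function(x, ...) {
  x$coefficients
}

#' One-row model summary
#'
#' @param x A `state_model`.
#' @param ... Unused.
#' @return A one-row tibble with fit metadata (sizes, residual SD, REML
#'   criterion, convergence and singularity flags).
#' @importFrom generics glance
#' @export
glance.state_model <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    nobs = x$n_obs,
    n_teams = x$n_teams,
    n_participants = x$n_participants,
    sigma = stats::sigma(x$fit),
    REMLcrit = as.numeric(lme4::REMLcrit(x$fit)),
    converged = x$converged,
    singular = x$singular,
    n_outliers_removed = x$n_outliers_removed
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance
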