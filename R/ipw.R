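#' Stabilized inverse-propensity weights for a binary exposure
#'
#' Computes per-record stabilized weights for a dichotomous exposure (e.g.
#' self-rated health) and for remaining uncensored, for use as record weights
#' in [fit_multistate_cox]. Both components use standard logistic regression;
#' the stabilization numerator is the marginal (intercept-only) probability
#' of the observed exposure level, so the exposure component is
#' p0 / p(Z) evaluated at the record's covariates, and the censoring
#' component the analogous marginal/conditional ratio for remaining
#' uncensored. Because covariates are episode-constant snapshots of
#' time-dependent quantities, one weight is computed for each record.
#' Administrative censoring (pension age, end of follow-up) is
#' covariate-independent by design and is not modeled.
#'
#' @param records an `event_history`.
#' @param exposure name of a binary (0/1 or two-level) covariate column.
#' @param adjusters covariate names entering the conditional models; default
#'   all non-exposure covariates.
#' @return [fit_propensity]: data.frame with per-record conditional
#'   probability of the observed exposure level (`p_cond`) and the marginal
#'   one (`p_marg`).
#' @export
fit_propensity <- function(records, exposure,
                           adjusters = setdiff(covariate_names(records),
                                               exposure)) {
  x <- records[[exposure]]
  if (is.null(x)) stop("exposure column '", exposure, "' not found")
  x <- normalize_binary(x, exposure)
  if (length(unique(x)) < 2L)
    stop("exposure '", exposure, "' has no variation")
  df <- as.data.frame(records)[, adjusters, drop = FALSE]
  df$.y <- x
  if (length(adjusters)) {
    fml <- stats::as.formula(paste(".y ~", paste(adjusters, collapse = "+")))
    fit <- stats::glm(fml, family = stats::binomial(), data = df)
    big <- abs(stats::coef(fit)[-1L]) > 10
    if (any(big, na.rm = TRUE))
      stop("separation suspected in propensity model for adjuster(s): ",
           paste(names(big)[big], collapse = ", "))
    p1 <- stats::fitted(fit)
  } else {
    p1 <- rep(mean(x), length(x))
  }
  p_marg1 <- mean(x)  # intercept-only MLE is the sample exposure fraction
  data.frame(p_cond = ifelse(x == 1, p1, 1 - p1),
             p_marg = ifelse(x == 1, p_marg1, 1 - p_marg1))
}

normalize_binary <- function(x, name) {
  ux <- sort(unique(x))
  if (length(ux) > 2L)
    stop("'", name, "' must be binary; found levels: ",
         paste(utils::head(ux, 4L), collapse = ", "))
  if (is.numeric(x) && all(ux %in% c(0, 1))) return(as.numeric(x))
  as.numeric(x == ux[length(ux)])
}

#' @rdname fit_propensity
#' @return [censoring_weights]: data.frame with per-record stabilized
#'   uncensored-probability ratio `sw_censor` (marginal over conditional
#'   probability of remaining uncensored); all 1 with a message when no
#'   non-administrative censoring is present.
#' @export
censoring_weights <- function(records,
                              adjusters = covariate_names(records)) {
  space <- attr(records, "space")
  cens <- as.numeric(records$to_state == CENSORED &
                       records$exit_age < space$pension_age - 1e-9)
  if (sum(cens) == 0L) {
    message("no non-administrative censoring; censoring weights are 1")
    return(data.frame(sw_censor = rep(1, nrow(records))))
  }
  df <- as.data.frame(records)[, adjusters, drop = FALSE]
  df$.y <- cens
  if (length(adjusters)) {
    fml <- stats::as.formula(paste(".y ~", paste(adjusters, collapse = "+")))
    fit <- stats::glm(fml, family = stats::binomial(), data = df)
    unc_cond <- 1 - stats::fitted(fit)
  } else {
    unc_cond <- rep(1 - mean(cens), length(cens))
  }
  unc_marg <- 1 - mean(cens)
  data.frame(sw_censor = unc_marg / unc_cond)
}

#' @rdname fit_propensity
#' @param truncate optional length-2 numeric vector of weight percentiles
#'   (e.g. `c(0.005, 0.995)`) at which the final weights are winsorized;
#'   `NULL` (default) leaves weights untouched.
#' @return [stabilized_weights]: a `weight_table` data.frame with
#'   `subject_id`, `entry_age`, the exposure and censoring components, the
#'   final stabilized `weight` and a `truncated` flag; ready to pass as
#'   `weights` to [fit_multistate_cox].
#' @export
stabilized_weights <- function(records, exposure,
                               adjusters = setdiff(covariate_names(records),
                                                   exposure),
                               truncate = NULL) {
  pe <- fit_propensity(records, exposure, adjusters)
  pc <- suppressMessages(censoring_weights(records, adjusters))
  if (any(pe$p_cond <= 0) || any(pc$sw_censor <= 0))
    stop("nonpositive fitted probabilities in weight components")
  sw_exposure <- pe$p_marg / pe$p_cond
  weight <- sw_exposure * pc$sw_censor
  truncated <- rep(FALSE, length(weight))
  if (!is.null(truncate)) {
    q <- stats::quantile(weight, truncate)
    truncated <- weight < q[1L] | weight > q[2L]
    weight <- pmin(pmax(weight, q[1L]), q[2L])
  }
  structure(data.frame(subject_id = records$subject_id,
                       entry_age = records$entry_age,
                       sw_exposure = sw_exposure,
                       sw_censor = pc$sw_censor,
                       weight = weight, truncated = truncated),
            class = c("weight_table", "data.frame"))
}
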