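#' Construct a habitat-quality (invasion probability) model
#'
#' Habitat quality HQ is the logistic-regression probability that a forest
#' cell is invaded: `HQ = logistic(alpha + X' beta)`. The odds ratio of a
#' covariate equals `exp(beta_j)`.
#'
#' @param intercept scalar intercept (alpha).
#' @param coefficients named numeric vector of covariate coefficients (beta);
#'   names must match cell-attribute columns.
#' @return An object of class `hq_model`.
#' @export
hq_model <- function(intercept, coefficients) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         covariate_order = names(coefficients)),
    class = "hq_model"
  )
}

#' @export
print.hq_model <- function(x, ...) {
  cat("<hq_model> logistic habitat quality\n")
  print(data.frame(
    term = c("(intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    odds_ratio = c(NA, exp(unname(x$coefficients)))
  ), row.names = FALSE)
  invisible(x)
}

#' Published regional habitat-quality coefficients
#'
#' The logistic habitat-quality coefficients reported for exotic privet
#' invasion of Alabama/Mississippi forest plots: invasion probability rises
#' with water adjacency, maximum temperature, site productivity and private
#' ownership, and falls with slope, stand age, artificial regeneration, road
#' distance and fire disturbance.
#'
#' @return An `hq_model` with the reported coefficient values.
#' @export
reference_hq_model <- function() {
  hq_model(
    intercept = -8.2364,
    coefficients = c(
      slope = -0.0512,
      water_adjacent = 0.2595,
      tmax = 0.9295,
      stand_age = -0.0083,
      site_productivity = 0.3281,
      artificial_regen = -0.2323,
      road_distance = -0.1950,
      fire_disturbance = -0.4267,
      private_ownership = 1.1145
    )
  )
}

#' Predict habitat quality for cells
#'
#' @param model an `hq_model`.
#' @param cells a data frame of cell attributes (or a `landscape_grid`).
#' @return numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' m <- hq_model(0, c(slope = 0))
#' predict_hq(m, data.frame(slope = 5))  # 0.5
predict_hq <- function(model, cells) {
  stopifnot(inherits(model, "hq_model"))
  if (inherits(cells, "landscape_grid")) cells <- cells$cells
  needed <- names(model$coefficients)
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) {
    stop("cells are missing covariate(s) required by the model: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(cells[needed])
  storage.mode(X) <- "double"
  eta <- model$intercept + drop(X %*% model$coefficients)
  plogis(eta)
}

#' Fit a logistic habitat-quality model with stepwise AIC selection
#'
#' Maximum-likelihood logistic regression of invasion presence on candidate
#' cell covariates, with bidirectional stepwise selection by AIC from the full
#' candidate set. Perfect separation aborts the fit with a diagnostic.
#'
#' @param cells data frame of cell attributes (or `landscape_grid`).
#' @param presence binary vector (1 = invaded).
#' @param candidates character vector of candidate covariate names.
#' @return A list of class `hq_fit`: `model` (`hq_model`), `report` (term,
#'   estimate, odds_ratio, p_value), `aic`, and the underlying `glm` object.
#' @export
fit_logistic <- function(cells, presence, candidates) {
  if (inherits(cells, "landscape_grid")) cells <- cells$cells
  missing <- setdiff(candidates, names(cells))
  if (length(missing) > 0) {
    stop("candidate covariate(s) absent from cells: ",
         paste(missing, collapse = ", "))
  }
  if (sum(presence == 1) < 2 || sum(presence == 0) < 2) {
    stop("need at least 2 presence and 2 absence records")
  }
  df <- cells[sort(candidates)]  # deterministic covariate order
  constant <- vapply(df, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    stop("constant covariate(s): ", paste(names(df)[constant], collapse = ", "))
  }
  df$.presence <- presence
  full <- suppressWarnings(
    glm(.presence ~ ., family = binomial(), data = df)
  )
  fit_p <- fitted(full)
  if (all(fit_p[presence == 1] > 1 - 1e-6) &&
      all(fit_p[presence == 0] < 1e-6)) {
    stop("perfect separation detected: fitted probabilities are all 0/1; ",
         "logistic ML estimates do not exist")
  }
  sel <- suppressWarnings(
    step(full, direction = "both", trace = 0,
         scope = list(lower = ~1, upper = stats::formula(full)))
  )
  cf <- summary(sel)$coefficients
  terms_kept <- setdiff(rownames(cf), "(Intercept)")
  beta <- cf[terms_kept, "Estimate"]
  names(beta) <- terms_kept
  model <- hq_model(intercept = cf["(Intercept)", "Estimate"],
                    coefficients = beta)
  report <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    odds_ratio = ifelse(rownames(cf) == "(Intercept)", NA, exp(cf[, "Estimate"])),
    p_value = cf[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(model = model, report = report, aic = stats::AIC(sel),
                 fit = sel),
            class = "hq_fit")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups records into equal-count bins of predicted risk (deciles by
#' default), compares observed and expected event counts with a chi-square
#' statistic on `groups - 2` degrees of freedom. Groups whose expected event
#' or non-event count is zero are merged with the next group (logged via
#' `message()`).
#'
#' @param predicted predicted probabilities.
#' @param observed binary outcomes, same length.
#' @param groups number of risk groups (>= 2).
#' @return list with `statistic`, `p_value`, `df`, and the group table.
#' @export
hosmer_lemeshow <- function(predicted, observed, groups = 10) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length")
  }
  if (groups < 2) stop("groups must be >= 2")
  n <- length(predicted)
  ord <- order(predicted, seq_len(n))  # stable sort
  p <- predicted[ord]
  y <- observed[ord]
  g <- ceiling(seq_len(n) * groups / n)
  tab <- data.frame(
    group = seq_len(groups),
    n = as.vector(tapply(y, g, length)),
    obs1 = as.vector(tapply(y, g, sum)),
    exp1 = as.vector(tapply(p, g, sum))
  )
  tab$obs0 <- tab$n - tab$obs1
  tab$exp0 <- tab$n - tab$exp1
  # merge groups with zero expected counts into the following group
  i <- 1
  while (i <= nrow(tab) && nrow(tab) > 2) {
    if (tab$exp1[i] < .Machine$double.eps || tab$exp0[i] < .Machine$double.eps) {
      j <- if (i < nrow(tab)) i + 1 else i - 1
      message("hosmer_lemeshow: merging group ", tab$group[i],
              " (zero expected count) with group ", tab$group[j])
      tab[j, c("n", "obs1", "exp1", "obs0", "exp0")] <-
        tab[j, c("n", "obs1", "exp1", "obs0", "exp0")] +
        tab[i, c("n", "obs1", "exp1", "obs0", "exp0")]
      tab <- tab[-i, ]
    } else {
      i <- i + 1
    }
  }
  stat <- sum((tab$obs1 - tab$exp1)^2 / tab$exp1 +
                (tab$obs0 - tab$exp0)^2 / tab$exp0)
  df <- nrow(tab) - 2
  list(statistic = stat,
       p_value = pchisq(stat, df = df, lower.tail = FALSE),
       df = df, table = tab)
}

#' Classification accuracy at a probability threshold
#'
#' Fraction of records for which `predicted >= threshold` matches the observed
#' binary outcome.
#'
#' @param predicted predicted probabilities.
#' @param observed binary outcomes.
#' @param threshold classification threshold in (0, 1).
#' @return fraction in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, observed, threshold = 0.5) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mean((predicted >= threshold) == (observed == 1))
}
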