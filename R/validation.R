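# Model-evaluation arithmetic: fold errors, fold-range verdicts, R^2 and
# surgery percent-change statistics.

#' Fold error between predicted and observed values
#'
#' @param predicted,observed numeric vectors; \code{observed} must be
#'   strictly positive.
#' @return predicted/observed.
#' @examples
#' foldError(7.78, 7.20)
#' @export
foldError <- function(predicted, observed) {
    if (any(!is.finite(observed) | observed <= 0))
        stop("observed values must be positive")
    predicted / observed
}

#' Fold-error range verdict
#'
#' TRUE when 1/criterion <= foldError <= criterion; the 1.25 criterion
#' mirrors the 0.80-1.25 bioequivalence range.
#'
#' @param foldError positive numeric vector.
#' @param criterion one of 1.25, 1.5, 2, 2.5 (any value > 1 accepted).
#' @return logical vector.
#' @export
withinFold <- function(foldError, criterion = 1.25) {
    stopifnot(all(foldError > 0), criterion > 1)
    foldError >= 1 / criterion & foldError <= criterion
}

#' Coefficient of determination of paired observed/predicted values
#'
#' Squared Pearson correlation on the raw (untransformed) pairs.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3).
#' @return R-squared in [0, 1].
#' @export
rSquared <- function(observed, predicted) {
    stopifnot(length(observed) == length(predicted), length(observed) >= 3)
    if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
        stop("zero variance: R^2 undefined")
    stats::cor(observed, predicted)^2
}

#' Percent change of a parameter after surgery
#'
#' (pre - post) * 100 / pre: positive values denote a post-surgery
#' decrease.
#'
#' @param pre,post pre- and post-surgery values; \code{pre} must be
#'   non-zero.
#' @return percent change.
#' @export
percentChange <- function(pre, post) {
    if (any(pre == 0)) stop("pre-surgery value must be non-zero")
    (pre - post) * 100 / pre
}

#' Build a model-validation report
#'
#' Pairs observed with predicted pharmacokinetic parameters, computes fold
#' errors (reported rounded to two decimals, and the range verdict is taken
#' on the rounded value, matching how such tables are conventionally
#' presented), and the R-squared across all pairs.
#'
#' @param observed data.frame with columns \code{parameter}, \code{dose},
#'   \code{value}.
#' @param predicted data.frame with the same columns.
#' @param criterion fold-error acceptance bound.
#' @return A \linkS4class{ValidationReport}.
#' @export
validationReport <- function(observed, predicted, criterion = 1.25) {
    need <- c("parameter", "dose", "value")
    stopifnot(all(need %in% names(observed)), all(need %in% names(predicted)))
    tab <- merge(observed, predicted, by = c("parameter", "dose"),
                 suffixes = c(".obs", ".pred"))
    if (!nrow(tab)) stop("no matching (parameter, dose) pairs")
    tab <- tab[order(tab$dose, tab$parameter), ]
    fe <- round(foldError(tab$value.pred, tab$value.obs), 2)
    out <- data.frame(parameter = tab$parameter, dose = tab$dose,
                      observed = tab$value.obs, predicted = tab$value.pred,
                      foldError = fe, within = withinFold(fe, criterion))
    r2 <- if (nrow(out) >= 3) rSquared(out$observed, out$predicted)
          else NA_real_
    new("ValidationReport", table = out, rSquared = r2,
        criterion = criterion)
}
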